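## Transition-state ensemble sampling: Metropolis simulated annealing
## of the coarse-grained model under the Phi-value restraint.

#' Define an annealing schedule
#'
#' Each cycle ramps the temperature linearly from `T_high` down to
#' `T_low` over `sweeps_per_cycle` Monte Carlo sweeps and contributes
#' its final (cold) conformation to the ensemble; the next cycle
#' re-heats from that endpoint.  The defaults mirror the reference
#' protocol: 300 cycles between 383 K and 283 K, with one experimental
#' "150 ps" cycle mapped onto 2000 sweeps of the coarse-grained
#' sampler.
#'
#' @param n_cycles Number of annealing cycles (= ensemble size).
#' @param sweeps_per_cycle MC sweeps per cycle.
#' @param T_high,T_low Temperature ramp endpoints in K.
#' @return List of class `annealing_schedule`.
#' @export
annealing_schedule <- function(n_cycles = 300L, sweeps_per_cycle = 2000L,
                               T_high = 383, T_low = 283) {
  if (!is_count(n_cycles)) tf_stop("domain_error", "n_cycles must be >= 1")
  if (!is_count(sweeps_per_cycle))
    tf_stop("domain_error", "sweeps_per_cycle must be >= 1")
  if (!(T_high >= T_low && T_low > 0))
    tf_stop("domain_error", "need T_high >= T_low > 0")
  structure(list(n_cycles = as.integer(n_cycles),
                 sweeps_per_cycle = as.integer(sweeps_per_cycle),
                 T_high = T_high, T_low = T_low, ramp = "linear"),
            class = "annealing_schedule")
}

.new_ensemble <- function(raw, model, kind, seed, schedule, restraints,
                          k_phi) {
  rt <- model$residues
  colnames(raw$phi_sim) <- paste0(rt$chain, rt$resid)
  structure(list(
    coords = array(raw$frames,
                   dim = c(nrow(model$coords0), 3L, length(raw$mechanical))),
    mechanical_energy = raw$mechanical,
    restraint_energy = raw$restraint,
    temperature = raw$temperature,
    phi_sim = raw$phi_sim,
    acceptance = c(site = raw$acceptance_site, rigid = raw$acceptance_rigid),
    n_retune = raw$n_retune,
    model = model,
    provenance = list(
      kind = kind, seed = seed, schedule = schedule,
      restraints = restraints, k_phi = k_phi,
      engine = "coarse-grained Go model + Metropolis MC (substitutes atomistic restrained MD)")),
    class = "ts_ensemble")
}

#' @export
print.ts_ensemble <- function(x, ...) {
  cat(sprintf("Transition-state ensemble (%s): %d conformations, %d sites\n",
              x$provenance$kind, dim(x$coords)[3], dim(x$coords)[1]))
  cat(sprintf("  acceptance: site %.2f, rigid %.2f; <E_mech> = %.1f, <E_phi> = %.2f kcal/mol\n",
              x$acceptance[["site"]], x$acceptance[["rigid"]],
              mean(x$mechanical_energy), mean(x$restraint_energy)))
  invisible(x)
}

#' Number of conformations in an ensemble
#' @param e A `ts_ensemble`.
#' @return Integer count.
#' @export
n_conformations <- function(e) {
  stopifnot(inherits(e, "ts_ensemble"))
  dim(e$coords)[3]
}

#' Ensemble-mean simulated Phi per residue
#'
#' @param e A `ts_ensemble`.
#' @param restrained_only Restrict to restrained residues.
#' @return Named numeric vector.
#' @export
mean_phi_sim <- function(e, restrained_only = FALSE) {
  stopifnot(inherits(e, "ts_ensemble"))
  m <- colMeans(e$phi_sim)
  if (restrained_only) {
    rs <- e$provenance$restraints
    if (is.null(rs)) tf_stop("domain_error", "ensemble has no restraints")
    m <- m[paste0(rs$chain, rs$resid)]
  }
  m
}

#' Generate a transition-state ensemble by restrained annealing
#'
#' Metropolis Monte Carlo (single-site displacements plus rigid-body
#' ligand moves) on `E_Go + E_phi`.  Each cycle ramps the temperature
#' linearly from `T_high` to `T_low`, starts from the previous cycle's
#' endpoint (cycle 1 from a randomised ligand pose within
#' `pose_radius` of the binding site) and contributes its final
#' conformation to the ensemble.  Bit-reproducible for a given seed.
#' If the acceptance rate over a cycle falls below 1%, step sizes are
#' halved (auto-tuning; the count of such events is reported in
#' `n_retune`).
#'
#' @param model A [build_cg_model()] object.
#' @param restraints A [phi_restraint_set()] (built against the same
#'   reference map).
#' @param schedule An [annealing_schedule()].
#' @param seed RNG seed (mandatory).
#' @param k_phi Restraint force constant; default from the model.
#' @param random_pose Randomise the ligand pose before cycle 1
#'   (default TRUE: a transition-state search should not start at the
#'   product).
#' @param burn_in Equilibration cycles run (and discarded) before the
#'   `n_cycles` recorded ones, so the stochastic capture of the ligand
#'   from its randomised initial pose does not contaminate the
#'   ensemble average (default 10).  Burn-in cycles use a widened
#'   smooth-switching width (`burn_in_width`), whose longer-ranged
#'   restraint force funnels the ligand into the interface quickly;
#'   a second discarded segment (`burn_in_sharp`, default 10 cycles)
#'   then re-equilibrates at the model's sharp width before recording
#'   starts.
#' @param burn_in_width Logistic switching width (nm) used during the
#'   first burn-in segment only.
#' @param burn_in_sharp Discarded cycles at the model's own width.
#' @return A `ts_ensemble` with one conformation per recorded cycle,
#'   per-conformation energies and hard-criterion Phi_sim values, and
#'   full provenance.
#' @export
anneal <- function(model, restraints, schedule = annealing_schedule(),
                   seed, k_phi = model$params$k_phi, random_pose = TRUE,
                   burn_in = 10L, burn_in_width = 0.08,
                   burn_in_sharp = 10L) {
  stopifnot(inherits(model, "cg_model"),
            inherits(schedule, "annealing_schedule"))
  phi <- .phi_exp_vector(model, restraints)
  p <- model$params
  start <- model$coords0
  run_segment <- function(mlist, start, n, seed, pose) {
    out <- cpp_run_mc(mlist, start, phi, k_phi,
                      as.integer(n), schedule$sweeps_per_cycle,
                      schedule$T_high, schedule$T_low, as.double(seed),
                      pose, p$pose_radius,
                      p$step_site, p$step_trans, p$step_rot,
                      p$rigid_per_sweep, 0L)
    out$last <- array(out$frames,
                      dim = c(nrow(start), 3L, as.integer(n)))[, , n]
    out
  }
  if (burn_in > 0L) {
    mb <- .model_for_cpp(model)
    mb$params$smooth_width <- max(p$smooth_width, burn_in_width)
    pre <- run_segment(mb, start, burn_in, seed, random_pose)
    start <- pre$last
    random_pose <- FALSE
  }
  if (burn_in_sharp > 0L) {
    pre2 <- run_segment(.model_for_cpp(model), start, burn_in_sharp,
                        derive_seed(seed, "anneal/sharp"), random_pose)
    start <- pre2$last
    random_pose <- FALSE
  }
  raw <- cpp_run_mc(.model_for_cpp(model), start, phi, k_phi,
                    schedule$n_cycles, schedule$sweeps_per_cycle,
                    schedule$T_high, schedule$T_low,
                    as.double(derive_seed(seed, "anneal/recorded")),
                    random_pose, p$pose_radius,
                    p$step_site, p$step_trans, p$step_rot,
                    p$rigid_per_sweep, 0L)
  .new_ensemble(raw, model, "annealed TS ensemble", seed, schedule,
                restraints, k_phi)
}

#' Constant-temperature native reference ensemble
#'
#' Unrestrained sampling at a fixed temperature started from the
#' native conformation: the baseline for fluctuation comparisons and
#' for ensemble-averaged SASA, standing in for the long native-state
#' reference simulation of the original protocol.
#'
#' @param model A [build_cg_model()] object.
#' @param temperature Temperature in K (default 283).
#' @param sweeps Total MC sweeps.
#' @param seed RNG seed.
#' @param record_stride Record a conformation every this many sweeps.
#' @return A `ts_ensemble` (kind "native reference").
#' @export
native_reference <- function(model, temperature = 283, sweeps = 20000L,
                             seed = 1L, record_stride = 100L) {
  stopifnot(inherits(model, "cg_model"))
  phi <- rep(NA_real_, model$nres)
  p <- model$params
  raw <- cpp_run_mc(.model_for_cpp(model), model$coords0, phi, 0,
                    1L, as.integer(sweeps), temperature, temperature,
                    as.double(seed), FALSE, p$pose_radius,
                    p$step_site, p$step_trans, p$step_rot,
                    p$rigid_per_sweep, as.integer(record_stride))
  sched <- annealing_schedule(1L, as.integer(sweeps), temperature, temperature)
  .new_ensemble(raw, model, "native reference", seed, sched, NULL, 0)
}

#' Subset-restraint control ensemble
#'
#' Repeats the annealing with restraints only on a subset of the
#' restrained residues -- the robustness control of the protocol
#' (classically run with four positions).  Alongside the ensemble, a
#' comparison against the full-restraint ensemble is reported: the
#' mean absolute difference of native-contact frequencies and the two
#' mean total native-contact fractions.
#'
#' @param model A [build_cg_model()] object.
#' @param restraints The full [phi_restraint_set()].
#' @param residue_subset Integer residue indices (within the
#'   restrained chain) to keep.
#' @param schedule An [annealing_schedule()].
#' @param seed RNG seed (same seed family as the full run for paired
#'   comparison).
#' @param full_ensemble Optional pre-computed full-restraint ensemble;
#'   computed here (same seed) when omitted.
#' @return The subset `ts_ensemble`, with the comparison in
#'   `$subset_comparison`.
#' @export
subset_restraint_control <- function(model, restraints, residue_subset,
                                     schedule = annealing_schedule(), seed,
                                     full_ensemble = NULL) {
  if (length(residue_subset) == 0L)
    tf_stop("domain_error", "empty residue subset")
  keep <- restraints$resid %in% residue_subset
  if (!any(keep))
    tf_stop("domain_error", "subset does not intersect the restrained residues")
  if (!all(residue_subset %in% restraints$resid))
    tf_stop("domain_error", "subset residues must be restrained residues")
  sub <- restraints[keep, , drop = FALSE]
  class(sub) <- class(restraints)
  e_sub <- anneal(model, sub, schedule, seed)
  if (is.null(full_ensemble))
    full_ensemble <- anneal(model, restraints, schedule, seed)
  f_sub <- contact_frequency_map(e_sub, model$map)
  f_full <- contact_frequency_map(full_ensemble, model$map)
  nat_sub <- f_sub$native$frequency
  nat_full <- f_full$native$frequency
  e_sub$subset_comparison <- list(
    mean_abs_freq_diff = mean(abs(nat_sub - nat_full)),
    native_fraction_subset = mean(nat_sub),
    native_fraction_full = mean(nat_full))
  e_sub
}

#' Write an ensemble as a multi-MODEL PDB plus a per-conformation CSV
#'
#' Coarse-grained sites are written as CA / CB pseudo-atom records.
#'
#' @param e A `ts_ensemble`.
#' @param pdb_path,csv_path Output files.
#' @return Invisibly, the two paths.
#' @export
write_ensemble <- function(e, pdb_path, csv_path) {
  stopifnot(inherits(e, "ts_ensemble"))
  m <- e$model
  atoms <- data.frame(chain = m$sites$chain, resid = m$sites$resid,
                      restype = m$residues$restype[m$sites$res],
                      atom = ifelse(m$sites$type == "CA", "CA", "CB"),
                      element = "C",
                      x = m$coords0[, 1], y = m$coords0[, 2],
                      z = m$coords0[, 3])
  s <- complex_structure(atoms,
                         attr(m$structure, "receptor_chain"),
                         attr(m$structure, "ligand_chain"))
  write_pdb(s, pdb_path, coords = e$coords)
  df <- data.frame(frame = seq_along(e$mechanical_energy),
                   mechanical_energy = e$mechanical_energy,
                   restraint_energy = e$restraint_energy,
                   temperature = e$temperature)
  df <- cbind(df, as.data.frame(e$phi_sim))
  write.csv(df, csv_path, row.names = FALSE)
  invisible(c(pdb_path, csv_path))
}
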