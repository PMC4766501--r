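## Synthetic-data module: ground-truthed generators for every input of
## the pipeline.  All generators are pure functions of their arguments
## and a seed (RNG state is restored afterwards), and their outputs
## satisfy the invariants of the consuming modules unchanged.

#' Generate a noisy single-exponential binding trace
#'
#' Emulates a stopped-flow pseudo-first-order experiment: the observed
#' rate embedded in the trace is `k_obs = k_on * ligand_conc + k_off`
#' and the signal is `offset + amplitude * exp(-k_obs t)` plus Gaussian
#' noise with sd `noise_sd_frac * |amplitude|`.  The time grid spans
#' `6 / k_obs`, comfortably past the `5 / k_obs` needed to see the
#' plateau.
#'
#' @param k_on Association rate constant, uM^-1 s^-1 (> 0).
#' @param k_off Dissociation rate constant, s^-1.
#' @param ligand_conc Ligand concentration in uM.
#' @param probe_conc Probe concentration in uM.
#' @param noise_sd_frac Noise sd as a fraction of the amplitude.
#' @param n_points Number of time points.
#' @param seed RNG seed.
#' @param amplitude,offset Signal parameters (arbitrary units).
#' @return A [binding_trace()] with attribute `k_obs_true`.
#' @export
gen_trace <- function(k_on, k_off, ligand_conc, probe_conc = 3,
                      noise_sd_frac = 0.02, n_points = 200L, seed = 1L,
                      amplitude = 1, offset = 0.1) {
  if (!is_num1(k_on) || k_on <= 0) tf_stop("domain_error", "k_on must be > 0")
  if (!is_num1(ligand_conc) || ligand_conc <= 0)
    tf_stop("domain_error", "ligand_conc must be > 0")
  if (!is_num1(probe_conc) || probe_conc <= 0)
    tf_stop("domain_error", "probe_conc must be > 0")
  if (!is_num1(noise_sd_frac) || noise_sd_frac < 0)
    tf_stop("domain_error", "noise_sd_frac must be >= 0")
  k_obs <- k_on * ligand_conc + k_off
  if (k_obs <= 0) tf_stop("domain_error", "embedded k_obs must be > 0")
  t <- seq(0, 6 / k_obs, length.out = n_points)
  y <- offset + amplitude * exp(-k_obs * t)
  if (noise_sd_frac > 0)
    y <- y + with_seed(seed, rnorm(n_points, 0, noise_sd_frac * abs(amplitude)))
  tr <- suppressWarnings(binding_trace(t, y, ligand_conc, probe_conc))
  attr(tr, "k_obs_true") <- k_obs
  tr
}

#' Generate a replicated pseudo-first-order trace series
#'
#' Mirrors the experimental design: a fixed probe concentration mixed
#' against increasing ligand concentrations (default 8-80 uM), each
#' repeated several times (experimentally 3-6).
#'
#' @param rc A [rate_constants()] object providing the ground truth.
#' @param concs Ligand concentrations in uM (>= 3 values).
#' @param probe_conc Probe concentration in uM.
#' @param noise_sd_frac Fractional noise sd per trace.
#' @param replicates Replicates per concentration.
#' @param seed Master seed; per-trace seeds are derived from it.
#' @param n_points Points per trace.
#' @return List with `traces` (list of [binding_trace()]) and
#'   `manifest` (data frame: `trace`, `ligand_conc_uM`,
#'   `probe_conc_uM`, `replicate`, `variant_receptor`,
#'   `variant_ligand`).
#' @export
gen_trace_series <- function(rc, concs = c(8, 16, 32, 64, 80),
                             probe_conc = 3, noise_sd_frac = 0.02,
                             replicates = 3L, seed = 1L, n_points = 200L) {
  stopifnot(inherits(rc, "rate_constants"))
  if (length(concs) < 3L)
    tf_stop("insufficient_data", "need >= 3 concentrations")
  traces <- list()
  manifest <- NULL
  i <- 0L
  for (conc in concs) for (rep in seq_len(replicates)) {
    i <- i + 1L
    traces[[i]] <- gen_trace(rc$k_on, rc$k_off, conc, probe_conc,
                             noise_sd_frac, n_points,
                             seed = derive_seed(seed, sprintf("trace/%g/%d", conc, rep)))
    manifest <- rbind(manifest, data.frame(
      trace = i, ligand_conc_uM = conc, probe_conc_uM = probe_conc,
      replicate = rep, variant_receptor = rc$variant_receptor,
      variant_ligand = rc$variant_ligand))
  }
  list(traces = traces, manifest = manifest)
}

## base sequences for the toy complex; repeated/truncated to length.
## Ligand phase puts the LEU/ILE face into the groove.
.TOY_RECEPTOR_SEQ <- c("GLU", "LEU", "LYS", "ILE", "LEU", "SER", "ALA", "LEU",
                       "GLY", "VAL")
.TOY_LIGAND_SEQ <- c("LEU", "SER", "GLU", "ILE", "LEU", "LYS", "SER", "LEU",
                     "ALA", "GLU")

## Ideal alpha-helix CA trace along z: radius 0.23 nm, rise 0.15
## nm/residue, 100 degrees/residue.
.helix_ca <- function(n, center_xy, z0, dir = 1, phase0 = 0,
                      radius = 0.23, rise = 0.15) {
  th <- phase0 + (seq_len(n) - 1L) * 100 * pi / 180
  cbind(center_xy[1] + radius * cos(th),
        center_xy[2] + radius * sin(th),
        z0 + dir * rise * (seq_len(n) - 1L))
}

## Side-chain heavy atoms for one residue: laid out along the radial
## direction u from the helix axis, from 0.15 nm to 0.40 nm past the
## CA, with small fixed perpendicular offsets so atoms do not stack.
.sidechain_blob <- function(ca, u, restype) {
  names <- sidechain_atoms(restype)
  n <- length(names)
  if (n == 0L) return(NULL)
  perp <- if (abs(u[3]) < 0.9) c(-u[2], u[1], 0) else c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  perp2 <- c(u[2] * perp[3] - u[3] * perp[2],
             u[3] * perp[1] - u[1] * perp[3],
             u[1] * perp[2] - u[2] * perp[1])
  d <- if (n == 1L) 0.15 else seq(0.15, 0.40, length.out = n)
  off <- 0.05 * rep_len(c(0, 1, -1, 0.5, -0.5), n)
  off2 <- 0.05 * rep_len(c(0, -0.5, 0.5, 1, -1), n)
  xyz <- t(vapply(seq_len(n), function(k)
    ca + d[k] * u + off[k] * perp + off2[k] * perp2, numeric(3)))
  data.frame(atom = names, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Generate a toy helix-in-groove complex
#'
#' A desk-scale stand-in for a folded receptor domain binding an
#' amphipathic helical peptide: the receptor is built as two packed
#' antiparallel helices whose side chains form a hydrophobic groove,
#' and the ligand as a single helix docked into that groove with its
#' LEU/ILE face buried.  Backbones are ideal helices; side chains are
#' compact pseudo-atom blobs with the correct heavy-atom count per
#' residue type, so contact counting and deletion mutations behave as
#' on a real structure.  The construction guarantees at least one
#' native inter-chain contact per ligand residue at the 0.65 nm
#' analysis cutoff.
#'
#' @param receptor_len,ligand_len Chain lengths (>= 4).
#' @param seed RNG seed for the small symmetry-breaking jitter
#'   (0.005 nm) applied to all coordinates.
#' @param groove_sep Separation of the two receptor helix axes (nm).
#' @param ligand_height Height of the ligand helix axis above the
#'   receptor axes plane (nm).
#' @return A [complex_structure()] with receptor chain "A" (residues
#'   1..receptor_len) and ligand chain "B" (1..ligand_len).
#' @export
gen_toy_complex <- function(receptor_len = 30L, ligand_len = 10L, seed = 1L,
                            groove_sep = 1.4, ligand_height = 0.95) {
  if (!is_count(receptor_len, 4L) || !is_count(ligand_len, 4L))
    tf_stop("domain_error", "chain lengths must be >= 4")
  n1 <- ceiling(receptor_len / 2)
  n2 <- receptor_len - n1
  ## receptor helix 1 (residues 1..n1) and antiparallel helix 2
  z_span <- 0.15 * (max(n1, n2) - 1L)
  ca1 <- .helix_ca(n1, c(-groove_sep / 2, 0), 0, dir = 1, phase0 = pi / 4)
  ca2 <- .helix_ca(n2, c(groove_sep / 2, 0), z_span, dir = -1,
                   phase0 = 3 * pi / 4)
  ## ligand: axis along z at (0, ligand_height), phase -90 deg so the
  ## first residue's side chain points into the groove; centred on the
  ## receptor in z.
  z_mid <- z_span / 2 - 0.15 * (ligand_len - 1L) / 2
  cal <- .helix_ca(ligand_len, c(0, ligand_height), z_mid, dir = 1,
                   phase0 = -pi / 2)
  rseq <- rep_len(.TOY_RECEPTOR_SEQ, receptor_len)
  lseq <- rep_len(.TOY_LIGAND_SEQ, ligand_len)
  build_chain <- function(ca, seq, chain, axes_xy, bias = c(0, 0, 0)) {
    rows <- list()
    for (i in seq_len(nrow(ca))) {
      u <- c(ca[i, 1] - axes_xy[1], ca[i, 2] - axes_xy[2], 0)
      u <- u / sqrt(sum(u^2)) + bias
      u <- u / sqrt(sum(u^2))
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resid = i, restype = seq[i], atom = "CA",
        element = "C", x = ca[i, 1], y = ca[i, 2], z = ca[i, 3])
      sc <- .sidechain_blob(ca[i, ], u, seq[i])
      if (!is.null(sc))
        rows[[length(rows) + 1L]] <- data.frame(
          chain = chain, resid = i, restype = seq[i], atom = sc$atom,
          element = substr(sc$atom, 1, 1), x = sc$x, y = sc$y, z = sc$z)
    }
    do.call(rbind, rows)
  }
  recA <- build_chain(ca1, rseq[seq_len(n1)], "A", c(-groove_sep / 2, 0))
  recB <- build_chain(ca2, rseq[n1 + seq_len(n2)], "A", c(groove_sep / 2, 0))
  recB$resid <- recB$resid + n1
  ## ligand side chains are tilted toward the groove (construction
  ## device guaranteeing every ligand residue an inter-chain contact)
  lig <- build_chain(cal, lseq, "B", c(0, ligand_height),
                     bias = c(0, -1.4, 0))
  atoms <- rbind(recA, recB, lig)
  jit <- with_seed(seed, matrix(rnorm(3 * nrow(atoms), 0, 0.005), ncol = 3))
  atoms$x <- atoms$x + jit[, 1]
  atoms$y <- atoms$y + jit[, 2]
  atoms$z <- atoms$z + jit[, 3]
  complex_structure(atoms, receptor_chain = "A", ligand_chain = "B")
}

#' Generate a synthetic Phi restraint set
#'
#' Draws one experimental-style Phi value per ligand residue that has
#' at least one native contact, from a Beta distribution rescaled to
#' `[0, 1.2]` and moment-matched to the requested mean and spread
#' (values above 1 are possible experimentally but were not observed
#' for this system; the generator permits them).
#'
#' @param ref A [native_contacts()] map of the reference complex.
#' @param ligand_chain Chain whose residues are restrained.
#' @param mean_phi Target mean in `[0, 1.2]`.
#' @param spread Target standard deviation (0 gives a constant set).
#' @param seed RNG seed.
#' @return A data frame of class `phi_restraint_set` with columns
#'   `chain`, `resid`, `phi`, `phi_sd`.
#' @export
gen_phi_set <- function(ref, ligand_chain = "B", mean_phi = 0.9,
                        spread = 0.1, seed = 1L) {
  stopifnot(inherits(ref, "native_contact_map"))
  if (!is_num1(mean_phi) || mean_phi < 0 || mean_phi > 1.2)
    tf_stop("domain_error", "mean_phi must be in [0, 1.2]")
  res <- sort(unique(c(ref$res_i[ref$chain_i == ligand_chain],
                       ref$res_j[ref$chain_j == ligand_chain])))
  if (length(res) == 0L)
    tf_stop("domain_error", "no ligand residues with native contacts")
  phis <- if (spread <= 1e-8) rep(mean_phi, length(res)) else {
    m <- mean_phi / 1.2
    s <- min(spread / 1.2, sqrt(m * (1 - m)) * 0.95)
    nu <- m * (1 - m) / s^2 - 1
    nu <- max(nu, 0.1)
    with_seed(seed, 1.2 * rbeta(length(res), m * nu, (1 - m) * nu))
  }
  phi_restraint_set(chain = ligand_chain, resid = res, phi = phis,
                    phi_sd = rep(spread, length(res)), ref = ref)
}

#' Construct a Phi restraint set
#'
#' @param chain,resid Restrained residues.
#' @param phi Experimental Phi values (finite, typically in
#'   `[0, 1.2]`).
#' @param phi_sd Optional uncertainties.
#' @param ref Optional [native_contacts()] map used to check that
#'   every restrained residue has at least one native contact.
#' @return Data frame of class `phi_restraint_set`.
#' @export
phi_restraint_set <- function(chain, resid, phi, phi_sd = NA_real_,
                              ref = NULL) {
  if (any(!is.finite(phi)))
    tf_stop("domain_error", "Phi values must be finite")
  out <- data.frame(chain = as.character(chain), resid = as.integer(resid),
                    phi = as.numeric(phi),
                    phi_sd = rep_len(as.numeric(phi_sd),
                                     length.out = length(phi)))
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "native_contact_map"))
    rk <- c(paste(ref$chain_i, ref$res_i), paste(ref$chain_j, ref$res_j))
    bad <- !(paste(out$chain, out$resid) %in% rk)
    if (any(bad))
      tf_stop("domain_error", "restrained residues without native contacts: %s",
              paste(paste0(out$chain, out$resid)[bad], collapse = ", "))
  }
  structure(out, class = c("phi_restraint_set", "data.frame"))
}

#' Generate a synthetic LFER dataset
#'
#' Ground-truthed recovery harness for [lfer_fit()]: `ddG_eq` values
#' drawn uniformly over `ddg_range` and
#' `ddG_ts = alpha * ddG_eq + intercept + N(0, noise_sd)`.
#'
#' @param alpha Generating slope.
#' @param intercept Generating intercept (kcal/mol).
#' @param n Number of mutants (>= 3).
#' @param ddg_range Range of `ddG_eq` in kcal/mol.
#' @param noise_sd Gaussian noise sd on `ddG_ts` (kcal/mol).
#' @param seed RNG seed.
#' @return Data frame of energetic records (with [phi_value()] already
#'   applied, so the exclusion flags are set).
#' @export
gen_lfer_dataset <- function(alpha, intercept = 0, n = 12L,
                             ddg_range = c(0.1, 2.5), noise_sd = 0.15,
                             seed = 1L) {
  if (!is_count(n, 3L)) tf_stop("domain_error", "n must be >= 3")
  with_seed(seed, {
    x <- runif(n, ddg_range[1], ddg_range[2])
    y <- alpha * x + intercept + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    rec <- energetic_record(sprintf("M%02d", seq_len(n)), x, y,
                            ddG_eq_sd = rep(noise_sd, n),
                            ddG_ts_sd = rep(noise_sd, n))
    phi_value(rec)
  })
}

#' The packaged "study-like" scenario
#'
#' Bundles the published wild-type and variant rate constants (Fig-4
#' style validation kinetics), the four alpha-ordered Phi scenarios and
#' the toy-complex defaults, so the end-to-end demo runs without any
#' external data.
#'
#' @param master_seed Master seed fanned out to the per-stage
#'   generators.
#' @return List of class `scenario_spec`.
#' @export
scenario_paper_like <- function(master_seed = 1L) {
  rates <- list(
    WT = rate_constants(3.2, 25, 0.3, 3, variant_receptor = "WT"),
    T11A = rate_constants(2.7, 28, 0.5, 3, variant_receptor = "T11A"),
    I72V = rate_constants(1.46, 6, 0.09, 1, variant_receptor = "I72V"),
    `I72V/T11A` = rate_constants(0.6, 16, 0.1, 2,
                                 variant_receptor = "I72V/T11A"))
  ## per-variant transition-state scenarios: generating alpha values and
  ## the Phi-set means/spreads that emulate them
  scen <- data.frame(
    variant = c("WT", "L43A", "I26V", "I72V"),
    alpha = c(0.89, 0.54, 0.51, 0.19),
    alpha_sd = c(0.09, 0.13, 0.16, 0.11),
    intercept = c(0.5, 0, 0, 0),
    mean_phi = c(0.9, 0.55, 0.5, 0.2),
    spread = c(0.09, 0.13, 0.16, 0.11),
    k_on = c(3.2, NA, NA, 1.46))
  ## association rates for the intermediate variants are not part of the
  ## validation set; interpolate on log k_on for the demo correlations
  scen$k_on[2:3] <- exp(seq(log(3.2), log(1.46), length.out = 4))[2:3]
  structure(list(name = "paper_like",
                 rates = rates,
                 ts_scenarios = scen,
                 concs = c(8, 16, 32, 64, 80),
                 probe_conc = 3,
                 noise_sd_frac = 0.02,
                 replicates = 5L,
                 lfer_n = 12L,
                 lfer_noise_sd = 0.15,
                 receptor_len = 30L,
                 ligand_len = 10L,
                 master_seed = as.integer(master_seed)),
            class = "scenario_spec")
}
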