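## Coarse-grained structure-based (Go-type) model.  The atomistic
## engine used in the original study (explicit-solvent molecular
## dynamics) is deliberately replaced by a two-site-per-residue Go
## model sampled with Metropolis Monte Carlo: desk-scale, seedable and
## exactly reproducible, while preserving the bespoke part of the
## method -- the Phi-value pseudo-energy restraint -- unchanged.  The
## substitution is recorded in every ensemble's provenance.

#' Default force-field constants of the coarse-grained model
#'
#' All energies in kcal/mol, lengths in nm.  The restraint constant
#' `k_phi` must dominate the Go term for the ensemble to track the
#' targets: breaking one native pair of a residue with `n` contacts
#' changes its Phi by `1/n`, so at `k_phi = 120` a residue with 6
#' contacts and a 0.25 Phi mismatch gains about 2.4 kcal/mol per
#' corrective step -- an order of magnitude above the per-pair Go
#' depth.  Weaker settings (e.g. a few k_B T at mismatch 0.5) leave a
#' systematic native-ward bias of 0.1-0.3 Phi units.
#'
#' @return Named list of constants.
#' @export
cg_defaults <- function() {
  list(
    k_bond = 200,          # CA-CA and CA-SC pseudo-bonds
    k_angle = 15,          # 1-3 CA distance surrogate
    k_dihedral = 3,        # 1-4 CA distance surrogate
    k_tether_ca = 50,      # receptor backbone tether
    k_tether_sc = 10,      # weak receptor side-chain tether
    eps_go = 0.12,         # Go well depth per native atom pair
    go_depth_base = 0.9,   # base Go well depth per contact (native stability)
    go_depth_cap = 10,     # cap on atom pairs counted per residue pair
    eps_rep = 1,           # generic repulsion scale
    sig_rep = 0.35,        # repulsion sigma ceiling
    sig_native_frac = 0.85,# sigma = min(sig_rep, frac * native distance)
    conf_radius = 3.5,     # flat-bottom sphere on the ligand centroid
    conf_k = 10,
    contact_factor = 1.2,  # formed iff r < factor * native distance
    smooth_width = 0.015,  # logistic width of the smooth indicator
    k_phi = 120,           # restraint force constant
    step_site = 0.03,      # site move sd (nm)
    step_trans = 0.2,      # rigid translation sd (nm)
    step_rot = 0.25,       # rigid rotation sd (rad)
    rigid_per_sweep = 8L,
    pose_radius = 3.0)     # first-cycle ligand randomization radius
}

#' Build the coarse-grained model of a two-chain complex
#'
#' Each residue contributes a CA site and a side-chain centroid site
#' (glycine: CA only).  Chain geometry is held by harmonic pseudo-bonds
#' (1-2 CA, CA-SC) plus 1-3 and 1-4 CA distance terms; attraction is
#' restricted to native contacts (a 12-10 well at the native
#' side-chain centroid distance, depth proportional to the capped
#' native atom-pair count); everything else repels softly.  The
#' receptor is harmonically tethered near its native coordinates (the
#' transition-state search concerns the ligand and the interface), and
#' the ligand centroid is kept inside a flat-bottom sphere so it
#' cannot diffuse away irreversibly.
#'
#' @param s A [complex_structure()] (the native complex).
#' @param map Optional [native_contacts()] map (computed from `s` at
#'   the default 0.65 nm cutoff when omitted).
#' @param params Named list overriding entries of [cg_defaults()].
#' @return Object of class `cg_model`.
#' @export
build_cg_model <- function(s, map = NULL, params = list()) {
  stopifnot(inherits(s, "complex_structure"))
  if (is.null(map)) map <- native_contacts(s)
  p <- modifyList(cg_defaults(), params)
  rt <- residue_table(s)
  nres <- nrow(rt)
  rt$ord <- seq_len(nres)
  ## chain-local index for the nearest-neighbour exclusion
  rt$local <- stats::ave(seq_len(nres), rt$chain, FUN = seq_along)

  sc_mask <- .sidechain_mask(s, gly_ca_proxy = FALSE)
  sites <- NULL
  coords <- NULL
  sc_site <- integer(nres)   # side-chain proxy site per residue
  ca_site <- integer(nres)
  for (r in seq_len(nres)) {
    sel <- s$chain == rt$chain[r] & s$resid == rt$resid[r]
    ca <- sel & s$atom == "CA"
    if (!any(ca)) tf_stop("structure_invalid", "residue %s/%d lacks a CA",
                          rt$chain[r], rt$resid[r])
    coords <- rbind(coords, as.matrix(s[ca, c("x", "y", "z")])[1, , drop = FALSE])
    sites <- rbind(sites, data.frame(res = r, type = "CA",
                                     chain = rt$chain[r], resid = rt$resid[r]))
    ca_site[r] <- nrow(sites)
    scsel <- sel & sc_mask
    if (any(scsel)) {
      cen <- colMeans(as.matrix(s[scsel, c("x", "y", "z")]))
      coords <- rbind(coords, matrix(cen, 1))
      sites <- rbind(sites, data.frame(res = r, type = "SC",
                                       chain = rt$chain[r], resid = rt$resid[r]))
      sc_site[r] <- nrow(sites)
    } else sc_site[r] <- ca_site[r]   # glycine proxy
  }
  n <- nrow(sites)
  rownames(coords) <- NULL
  d0 <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))

  bonds <- NULL
  add_bond <- function(i, j, k) bonds <<- rbind(bonds, c(i, j, d0(i, j), k))
  for (r in seq_len(nres)) {
    if (sc_site[r] != ca_site[r])
      add_bond(ca_site[r], sc_site[r], p$k_bond)
    nxt <- which(rt$chain == rt$chain[r] & rt$local == rt$local[r] + 1L)
    if (length(nxt) == 1L) add_bond(ca_site[r], ca_site[nxt], p$k_bond)
    n3 <- which(rt$chain == rt$chain[r] & rt$local == rt$local[r] + 2L)
    if (length(n3) == 1L) add_bond(ca_site[r], ca_site[n3], p$k_angle)
    n4 <- which(rt$chain == rt$chain[r] & rt$local == rt$local[r] + 3L)
    if (length(n4) == 1L) add_bond(ca_site[r], ca_site[n4], p$k_dihedral)
  }

  rec <- rt$role == "receptor"
  tether_idx <- c(ca_site[rec],
                  sc_site[rec][sc_site[rec] != ca_site[rec]])
  tether_k <- c(rep(p$k_tether_ca, sum(rec)),
                rep(p$k_tether_sc, sum(sc_site[rec] != ca_site[rec])))

  res_of <- function(chain, resid)
    rt$ord[match(paste(chain, resid), paste(rt$chain, rt$resid))]
  contacts <- NULL
  if (nrow(map) > 0L) {
    ra <- res_of(map$chain_i, map$res_i)
    rb <- res_of(map$chain_j, map$res_j)
    if (any(is.na(ra)) || any(is.na(rb)))
      tf_stop("mismatch", "contact map references residues absent from the structure")
    for (k in seq_len(nrow(map))) {
      i <- sc_site[ra[k]]; j <- sc_site[rb[k]]
      depth <- p$go_depth_base +
        p$eps_go * min(map$n_atom_pairs[k], p$go_depth_cap)
      contacts <- rbind(contacts, c(i, j, d0(i, j), depth, ra[k], rb[k]))
    }
  }
  n_native <- integer(nres)
  if (!is.null(contacts)) {
    tab <- table(factor(c(contacts[, 5], contacts[, 6]), levels = seq_len(nres)))
    n_native <- as.integer(tab)
  }
  lig_cen <- colMeans(coords[sites$chain == attr(s, "ligand_chain"), , drop = FALSE])

  structure(list(
    coords0 = coords,
    sites = sites,
    chain = as.integer(sites$chain == attr(s, "ligand_chain")),
    resord = sites$res,
    res_local = rt$local[sites$res],
    nres = nres,
    residues = rt,
    sc_site = sc_site,
    ca_site = ca_site,
    bonds = bonds,
    tether_idx = as.integer(tether_idx),
    tether_k = tether_k,
    contacts = if (is.null(contacts))
      matrix(numeric(0), ncol = 6) else contacts,
    n_native = n_native,
    params = c(p, list(conf_center = lig_cen)),
    map = map,
    structure = s),
    class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat(sprintf("Coarse-grained Go model: %d sites (%d residues), %d bonded terms, %d native contacts\n",
              nrow(x$coords0), x$nres, nrow(x$bonds), nrow(x$contacts)))
  invisible(x)
}

## model list in the exact shape the C++ engine expects
.model_for_cpp <- function(model) {
  list(coords0 = model$coords0, chain = model$chain,
       resord = as.integer(model$resord), res_local = as.integer(model$res_local),
       nres = as.integer(model$nres), bonds = model$bonds,
       tether_idx = model$tether_idx, tether_k = model$tether_k,
       contacts = model$contacts, n_native = model$n_native,
       params = model$params)
}

## per-residue Phi_exp vector (NA = unrestrained) from a restraint set
.phi_exp_vector <- function(model, restraints) {
  phi <- rep(NA_real_, model$nres)
  if (is.null(restraints) || nrow(restraints) == 0L) return(phi)
  rt <- model$residues
  idx <- match(paste(restraints$chain, restraints$resid),
               paste(rt$chain, rt$resid))
  if (any(is.na(idx)))
    tf_stop("mismatch", "restrained residues absent from the model")
  if (any(model$n_native[idx] == 0L))
    tf_stop("domain_error", "restrained residue without native contacts")
  phi[idx] <- restraints$phi
  phi
}

#' Total energy of a conformation under the coarse-grained model
#'
#' @param model A [build_cg_model()] object.
#' @param coords Site coordinates (n_sites x 3, nm); default native.
#' @param restraints Optional [phi_restraint_set()].
#' @param k_phi Restraint force constant (default from the model).
#' @return List with `total`, `mechanical`, `restraint` (kcal/mol) and
#'   the per-residue hard-criterion `phi_sim`.
#' @export
cg_energy <- function(model, coords = model$coords0, restraints = NULL,
                      k_phi = model$params$k_phi) {
  stopifnot(inherits(model, "cg_model"))
  phi <- .phi_exp_vector(model, restraints)
  cpp_cg_energy(.model_for_cpp(model), as.matrix(coords), phi, k_phi)
}

#' Simulated Phi value of a residue in a conformation
#'
#' The fraction of a residue's native contact pairs that are formed in
#' the conformation; a pair is formed when its side-chain centroid
#' distance is within `contact_factor` (1.2) times the native
#' distance, so the native conformation scores 1 by construction.
#' Values above 1 cannot arise under this per-pair criterion (a
#' residue cannot form more native pairs than it has), but are
#' possible for full-atom conformations scored against an absolute
#' cutoff; they are reported unclamped either way.
#'
#' @param model A [build_cg_model()] object (carries the reference
#'   map).
#' @param coords Site coordinates (n_sites x 3, nm).
#' @param chain,resid Optional residue selector; default all residues.
#' @return Named numeric vector of Phi_sim values (NA for residues
#'   without native contacts); with a selector, a single value (error
#'   if that residue has no native contacts).
#' @export
phi_sim <- function(model, coords, chain = NULL, resid = NULL) {
  stopifnot(inherits(model, "cg_model"))
  v <- cpp_phi_sim(.model_for_cpp(model), as.matrix(coords))
  rt <- model$residues
  names(v) <- paste0(rt$chain, rt$resid)
  if (is.null(chain)) return(v)
  i <- match(paste(chain, resid), paste(rt$chain, rt$resid))
  if (is.na(i)) tf_stop("missing_residue", "no residue %s/%s", chain, resid)
  if (model$n_native[i] == 0L)
    tf_stop("undefined_phi", "residue %s/%s has no native contacts", chain, resid)
  v[[i]]
}

#' Phi-restraint pseudo-energy of a conformation
#'
#' `E_phi = k_phi * sum_residues (phi_exp - phi_sim)^2`, evaluated
#' with the hard contact criterion; non-negative, and zero exactly
#' when every restrained residue matches its target.
#'
#' @param model A [build_cg_model()] object.
#' @param coords Site coordinates.
#' @param restraints A [phi_restraint_set()].
#' @param k_phi Force constant (kcal/mol per squared Phi unit).
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(model, coords, restraints,
                             k_phi = model$params$k_phi) {
  phi_exp <- .phi_exp_vector(model, restraints)
  ps <- phi_sim(model, coords)
  ok <- is.finite(phi_exp)
  sum(k_phi * (phi_exp[ok] - ps[ok])^2)
}
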