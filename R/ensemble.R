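## Ensemble analysis: fluctuation about the mean structure,
## contact-frequency maps, ensemble-averaged SASA and the
## cross-correlations connecting ensemble heterogeneity to kinetics
## and thermodynamics.

## Kabsch superposition: rotation + translation minimising the RMSD of
## mov[idx, ] onto ref[idx, ]; returns mov transformed entirely.
.kabsch <- function(mov, ref, idx) {
  A <- mov[idx, , drop = FALSE]
  B <- ref[idx, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2L, ca), sweep(B, 2L, cb))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(mov, 2L, ca) %*% t(R), 2L, cb, "+")
}

## site indices for a selection spec
.selection_sites <- function(model, selection) {
  st <- model$sites
  lig <- model$chain == 1L
  switch(selection,
         ligand_ca = which(lig & st$type == "CA"),
         ligand_all = which(lig),
         receptor_ca = which(!lig & st$type == "CA"),
         all = seq_len(nrow(st)),
         tf_stop("domain_error", "unknown selection '%s'", selection))
}

#' Fluctuation of an ensemble about its mean structure
#'
#' All members are iteratively superposed (Kabsch) on the evolving
#' mean over the receptor CA sites -- the folded partner defines the
#' frame -- and the mean structure is the coordinate average.  The
#' statistic is the mean over members of the RMS deviation of the
#' selected sites (default: ligand CA, the disordered chain whose
#' heterogeneity is under study) from that mean structure, in nm.
#'
#' @param e A `ts_ensemble`.
#' @param selection One of `"ligand_ca"` (default), `"ligand_all"`,
#'   `"receptor_ca"`, `"all"`.
#' @param align Alignment selection (default `"receptor_ca"`).
#' @param max_iter,tol Iterative-superposition controls.
#' @return List with `fluctuation` (nm), `mean_structure`
#'   (n_sites x 3) and `per_member` deviations.
#' @export
ensemble_fluctuation <- function(e, selection = "ligand_ca",
                                 align = "receptor_ca",
                                 max_iter = 10L, tol = 1e-6) {
  stopifnot(inherits(e, "ts_ensemble"))
  nf <- dim(e$coords)[3]
  if (nf < 2L) tf_stop("insufficient_data", "need >= 2 conformations")
  sel <- .selection_sites(e$model, selection)
  ali <- .selection_sites(e$model, align)
  if (length(sel) == 0L) tf_stop("domain_error", "empty selection")
  frames <- lapply(seq_len(nf), function(k) e$coords[, , k])
  mean_s <- frames[[1L]]
  for (it in seq_len(max_iter)) {
    frames <- lapply(frames, .kabsch, ref = mean_s, idx = ali)
    new_mean <- Reduce(`+`, frames) / nf
    shift <- sqrt(mean((new_mean - mean_s)^2))
    mean_s <- new_mean
    if (shift < tol) break
  }
  dev <- vapply(frames, function(f)
    sqrt(mean(rowSums((f[sel, , drop = FALSE] -
                         mean_s[sel, , drop = FALSE])^2))), numeric(1))
  list(fluctuation = mean(dev), mean_structure = mean_s, per_member = dev)
}

#' Contact-frequency map of an ensemble
#'
#' For every native residue pair, the fraction of conformations in
#' which it is formed (side-chain centroid distance within 1.2 times
#' the native distance -- the same criterion as the simulated Phi
#' values).  Non-native pairs -- residue pairs absent from the
#' reference map but formed (centroid distance below the absolute
#' reference cutoff) in at least `non_native_threshold` of the members
#' -- are tracked separately; a cluster of such pairs at the interface
#' is the signature of a shifted, non-native binding mode.
#'
#' @param e A `ts_ensemble`.
#' @param ref The reference [native_contacts()] map (default: the
#'   model's own).
#' @param non_native_threshold Minimum frequency for reporting a
#'   non-native pair (default 0.1).
#' @return List with data frames `native` (map columns +
#'   `frequency`) and `non_native`.
#' @export
contact_frequency_map <- function(e, ref = e$model$map,
                                  non_native_threshold = 0.1) {
  stopifnot(inherits(e, "ts_ensemble"))
  m <- e$model
  nf <- dim(e$coords)[3]
  if (nf < 1L) tf_stop("insufficient_data", "empty ensemble")
  sc <- m$sc_site
  rt <- m$residues
  ## map residues -> model ordinals
  ra <- match(paste(ref$chain_i, ref$res_i), paste(rt$chain, rt$resid))
  rb <- match(paste(ref$chain_j, ref$res_j), paste(rt$chain, rt$resid))
  native <- ref
  if (nrow(ref) > 0L) {
    cnt <- numeric(nrow(ref))
    rnat <- vapply(seq_len(nrow(ref)), function(k)
      sqrt(sum((m$coords0[sc[ra[k]], ] - m$coords0[sc[rb[k]], ])^2)),
      numeric(1))
    for (f in seq_len(nf)) {
      xyz <- e$coords[, , f]
      d <- sqrt(rowSums((xyz[sc[ra], , drop = FALSE] -
                           xyz[sc[rb], , drop = FALSE])^2))
      cnt <- cnt + (d < m$params$contact_factor * rnat)
    }
    native$frequency <- cnt / nf
  } else native$frequency <- numeric(0)

  ## non-native pairs: all residue pairs not in ref and not nearest
  ## neighbours, scored against the absolute reference cutoff
  nres <- m$nres
  pair_in_ref <- matrix(FALSE, nres, nres)
  if (nrow(ref) > 0L) {
    pair_in_ref[cbind(ra, rb)] <- TRUE
    pair_in_ref[cbind(rb, ra)] <- TRUE
  }
  cutoff <- attr(ref, "cutoff")
  if (is.null(cutoff)) cutoff <- 0.65
  cand <- which(upper.tri(matrix(0, nres, nres)), arr.ind = TRUE)
  same <- rt$chain[cand[, 1]] == rt$chain[cand[, 2]]
  nn <- same & abs(rt$local[cand[, 1]] - rt$local[cand[, 2]]) <= 1L
  cand <- cand[!nn & !pair_in_ref[cand], , drop = FALSE]
  nn_freq <- numeric(nrow(cand))
  if (nrow(cand) > 0L) {
    for (f in seq_len(nf)) {
      xyz <- e$coords[, , f]
      d <- sqrt(rowSums((xyz[sc[cand[, 1]], , drop = FALSE] -
                           xyz[sc[cand[, 2]], , drop = FALSE])^2))
      nn_freq <- nn_freq + (d < cutoff)
    }
    nn_freq <- nn_freq / nf
  }
  keep <- nn_freq >= non_native_threshold
  non_native <- data.frame(
    chain_i = rt$chain[cand[keep, 1]], res_i = rt$resid[cand[keep, 1]],
    chain_j = rt$chain[cand[keep, 2]], res_j = rt$resid[cand[keep, 2]],
    frequency = nn_freq[keep])
  list(native = native, non_native = non_native)
}

#' Ensemble-averaged SASA of coarse-grained conformations
#'
#' Approximates each site by a single sphere (CA: 0.22 nm; side-chain
#' centroid: an effective radius growing with the residue's heavy-atom
#' count, `0.23 * n^(1/3)` nm) and averages the Shrake-Rupley site
#' SASA over the ensemble members.  A coarse-grained stand-in for the
#' all-atom ensemble average of the reference protocol; use
#' [hydrophobic_sasa()] on the all-atom structure for the static mode.
#'
#' @param e A `ts_ensemble` (typically a [native_reference()]).
#' @param site A [binding_site()].
#' @param probe,n_points Passed to [shrake_rupley()].
#' @param max_frames Subsample the ensemble to at most this many
#'   frames (SASA is the slow step).
#' @return List with `mean` and `sd` of the site SASA (nm^2) over the
#'   frames used.
#' @export
ensemble_sasa <- function(e, site, probe = 0.14, n_points = 240L,
                          max_frames = 25L) {
  stopifnot(inherits(e, "ts_ensemble"), inherits(site, "binding_site"))
  m <- e$model
  rt <- m$residues
  nsc <- rt$n_sidechain_atoms[m$sites$res]
  radii <- ifelse(m$sites$type == "CA", 0.22, 0.23 * pmax(nsc, 1)^(1 / 3))
  key <- paste(m$sites$chain, m$sites$resid)
  want <- paste(site$chain, site$resid)
  if (!all(want %in% key))
    tf_stop("missing_residue", "site residues absent from the model")
  sel <- key %in% want & (m$sites$type == "SC" | m$sc_site[m$sites$res] ==
                            m$ca_site[m$sites$res])
  nf <- dim(e$coords)[3]
  use <- if (nf > max_frames)
    round(seq(1L, nf, length.out = max_frames)) else seq_len(nf)
  vals <- vapply(use, function(f) {
    a <- shrake_rupley(e$coords[, , f], radii, probe = probe,
                       n_points = n_points)
    sum(a[sel])
  }, numeric(1))
  list(mean = mean(vals), sd = if (length(vals) > 1L) sd(vals) else NA_real_,
       n_frames = length(use))
}

#' Pearson correlation with fitted line
#'
#' @param x,y Equal-length numeric series (n >= 3).
#' @param labels Optional point labels.
#' @param xlab,ylab Series names for the report.
#' @return One-row data frame of class `correlation_report`: `xlab`,
#'   `ylab`, `r`, `slope`, `intercept`, `n`.
#' @export
correlate <- function(x, y, labels = NULL, xlab = deparse(substitute(x)),
                      ylab = deparse(substitute(y))) {
  if (length(x) != length(y) || length(x) < 3L)
    tf_stop("insufficient_data", "need equal-length series with n >= 3")
  if (var(x) == 0 || var(y) == 0)
    tf_stop("domain_error", "zero-variance series")
  cf <- .ols(x, y)
  out <- data.frame(xlab = xlab, ylab = ylab, r = cor(x, y),
                    slope = cf[2L], intercept = cf[1L], n = length(x))
  attr(out, "points") <- data.frame(label = labels %||% as.character(seq_along(x)),
                                    x = x, y = y)
  class(out) <- c("correlation_report", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Correlation %s vs %s (n = %d): r = %.3f, slope = %.3g, intercept = %.3g\n",
              x$ylab, x$xlab, x$n, x$r, x$slope, x$intercept))
  invisible(x)
}
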