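## Energetics module: mutational free-energy changes, Phi values and
## the linear free-energy relationship (Bronsted alpha).

.check_comparable <- function(wt, mut) {
  stopifnot(inherits(wt, "rate_constants"), inherits(mut, "rate_constants"))
  if (!identical(wt$variant_receptor, mut$variant_receptor))
    tf_stop("mismatch", "receptor variants differ (%s vs %s)",
            wt$variant_receptor, mut$variant_receptor)
  if (abs(wt$temperature - mut$temperature) > 1e-9)
    tf_stop("mismatch", "temperatures differ (%.2f vs %.2f K)",
            wt$temperature, mut$temperature)
  invisible(TRUE)
}

#' Equilibrium free-energy change of a mutation
#'
#' `ddG_eq = R T log(K_D_mut / K_D_wt)` with `K_D = k_off/k_on`,
#' `R = 1.98720425e-3` kcal/(mol K) and `T` taken from the records
#' (283.15 K for experiments at 10 C).  Destabilising mutations (larger
#' `K_D`) are positive.  First-order error propagation over the four
#' rate constants.
#'
#' @param wt,mut [rate_constants()] for wild type and mutant; the
#'   receptor variant and temperature must match.
#' @return List with `ddG` (kcal/mol) and `ddG_sd`.
#' @export
ddG_eq <- function(wt, mut) {
  .check_comparable(wt, mut)
  kdw <- dissociation_constant(wt)
  kdm <- dissociation_constant(mut)
  if (kdw$K_D <= 0 || kdm$K_D <= 0)
    tf_stop("domain_error", "K_D must be positive for ddG_eq (k_off = 0?)")
  RT <- .GAS_CONSTANT_KCAL * wt$temperature
  ddG <- RT * log(kdm$K_D / kdw$K_D)
  rel2 <- (kdw$K_D_sd / kdw$K_D)^2 + (kdm$K_D_sd / kdm$K_D)^2
  list(ddG = ddG, ddG_sd = RT * sqrt(rel2))
}

#' Transition-state free-energy change of a mutation
#'
#' `ddG_ts = R T log(k_on_wt / k_on_mut)`: slower association means a
#' destabilised transition state and a positive value.  Built from the
#' association side only, matching the transition-state-for-binding
#' framing; see [ddG_ts_off()] for the dissociation-side alternative.
#'
#' @inheritParams ddG_eq
#' @return List with `ddG` (kcal/mol) and `ddG_sd`.
#' @export
ddG_ts <- function(wt, mut) {
  .check_comparable(wt, mut)
  RT <- .GAS_CONSTANT_KCAL * wt$temperature
  ddG <- RT * log(wt$k_on / mut$k_on)
  rel2 <- 0
  if (is.finite(wt$k_on_sd)) rel2 <- rel2 + (wt$k_on_sd / wt$k_on)^2
  if (is.finite(mut$k_on_sd)) rel2 <- rel2 + (mut$k_on_sd / mut$k_on)^2
  list(ddG = ddG, ddG_sd = RT * sqrt(rel2))
}

#' Dissociation-side transition-state free-energy change
#'
#' `RT log(k_off_mut / k_off_wt)`: the barrier change seen from the
#' bound state.  Provided as an alternative; not the default axis of
#' the LFER analysis.
#'
#' @inheritParams ddG_eq
#' @return List with `ddG` and `ddG_sd` (kcal/mol).
#' @export
ddG_ts_off <- function(wt, mut) {
  .check_comparable(wt, mut)
  if (wt$k_off <= 0 || mut$k_off <= 0)
    tf_stop("domain_error", "k_off must be positive for the dissociation side")
  RT <- .GAS_CONSTANT_KCAL * wt$temperature
  ddG <- RT * log(mut$k_off / wt$k_off)
  rel2 <- 0
  if (is.finite(wt$k_off_sd)) rel2 <- rel2 + (wt$k_off_sd / wt$k_off)^2
  if (is.finite(mut$k_off_sd)) rel2 <- rel2 + (mut$k_off_sd / mut$k_off)^2
  list(ddG = ddG, ddG_sd = RT * sqrt(rel2))
}

#' Build an energetic record for one ligand variant
#'
#' @param ligand_variant Variant label.
#' @param ddG_eq,ddG_ts Free-energy changes in kcal/mol.
#' @param ddG_eq_sd,ddG_ts_sd Standard errors.
#' @return One-row data frame of class `energetic_record` with `phi`
#'   and `included_in_phi` unset (see [phi_value()]).
#' @export
energetic_record <- function(ligand_variant, ddG_eq, ddG_ts,
                             ddG_eq_sd = NA_real_, ddG_ts_sd = NA_real_) {
  structure(data.frame(ligand_variant = ligand_variant,
                       ddG_eq = ddG_eq, ddG_ts = ddG_ts,
                       ddG_eq_sd = ddG_eq_sd, ddG_ts_sd = ddG_ts_sd,
                       phi = NA_real_, phi_sd = NA_real_,
                       included_in_phi = NA),
            class = c("energetic_record", "data.frame"))
}

#' Compute the Phi value of a mutation, applying the exclusion rule
#'
#' `Phi = ddG_ts / ddG_eq` normalises the destabilisation of the
#' transition state to that of the ground state: values near 1 mean the
#' mutated contact is formed in the transition state, near 0 unformed.
#' Because the ratio is unreliable for small perturbations, variants
#' with `|ddG_eq|` below the threshold (0.4 kcal/mol, the customary
#' cutoff) are excluded: `phi` stays `NA` and `included_in_phi` is
#' `FALSE`.  Exclusion is the graceful path, not an error.
#'
#' @param rec An [energetic_record()] (or data frame with the same
#'   columns; vectorised over rows).
#' @param threshold Exclusion threshold on `|ddG_eq|` in kcal/mol.
#' @return The record(s) with `phi`, `phi_sd` and `included_in_phi`
#'   filled in.  `phi_sd` is first-order propagation of the two ddG
#'   uncertainties.
#' @export
phi_value <- function(rec, threshold = 0.4) {
  stopifnot(is.data.frame(rec), all(c("ddG_eq", "ddG_ts") %in% names(rec)))
  inc <- abs(rec$ddG_eq) >= threshold
  rec$included_in_phi <- inc
  rec$phi <- ifelse(inc, rec$ddG_ts / rec$ddG_eq, NA_real_)
  rel2 <- (rec$ddG_ts_sd / rec$ddG_ts)^2 + (rec$ddG_eq_sd / rec$ddG_eq)^2
  rec$phi_sd <- ifelse(inc & is.finite(rel2), abs(rec$phi) * sqrt(rel2),
                       NA_real_)
  rec
}

#' Energetic records for a table of rate constants
#'
#' Runs [ddG_eq()], [ddG_ts()] and [phi_value()] for every mutant
#' against the designated wild type.
#'
#' @param rates List of [rate_constants()] objects (same receptor
#'   variant, same temperature).
#' @param wt_ligand Label of the reference (wild-type) ligand variant.
#' @param threshold Passed to [phi_value()].
#' @return Data frame, one row per non-reference ligand variant.
#' @export
energetics_table <- function(rates, wt_ligand = "WT", threshold = 0.4) {
  labs <- vapply(rates, function(r) r$variant_ligand, character(1))
  iwt <- match(wt_ligand, labs)
  if (is.na(iwt)) tf_stop("mismatch", "wild-type ligand '%s' not found", wt_ligand)
  wt <- rates[[iwt]]
  recs <- lapply(rates[-iwt], function(mut) {
    eq <- ddG_eq(wt, mut)
    ts <- ddG_ts(wt, mut)
    energetic_record(mut$variant_ligand, eq$ddG, ts$ddG, eq$ddG_sd, ts$ddG_sd)
  })
  phi_value(do.call(rbind, recs), threshold = threshold)
}

#' Linear free-energy relationship (Bronsted) fit
#'
#' Ordinary least squares of `ddG_ts` on `ddG_eq` across mutants.  The
#' slope is the alpha value: 0 for a reactant-like and 1 for a
#' product-like transition state.  The intercept (kcal/mol) is reported
#' separately; a non-zero offset can flag additional kinetically silent
#' steps in the recognition mechanism.  Uncertainties are the standard
#' deviations of slope and intercept over case-resampling bootstrap
#' replicates (drawn with replacement; replicates with fewer than 3
#' distinct x values are redrawn).
#'
#' By default all records with both ddG values enter the fit, including
#' those excluded from Phi analysis: the small-`|ddG_eq|` exclusion is
#' justified for the ratio Phi, not for the individual free energies.
#' Set `use_excluded = FALSE` for the stricter alternative.
#'
#' @param records Data frame with columns `ddG_eq` and `ddG_ts`
#'   (e.g. from [energetics_table()]).
#' @param bootstrap Number of bootstrap replicates (>= 200 for reported
#'   sds).
#' @param seed RNG seed for the bootstrap (mandatory for
#'   reproducibility).
#' @param use_excluded Keep Phi-excluded records in the fit
#'   (default `TRUE`).
#' @return List of class `lfer_result`: `alpha`, `intercept`,
#'   `alpha_sd`, `intercept_sd`, `r`, `n_points`, `bootstrap_samples`,
#'   `seed`.
#' @export
lfer_fit <- function(records, bootstrap = 1000L, seed = 1L,
                     use_excluded = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("ddG_eq", "ddG_ts") %in% names(records)))
  keep <- is.finite(records$ddG_eq) & is.finite(records$ddG_ts)
  if (!use_excluded && "included_in_phi" %in% names(records))
    keep <- keep & records$included_in_phi %in% TRUE
  x <- records$ddG_eq[keep]
  y <- records$ddG_ts[keep]
  n <- length(x)
  if (n < 3L) tf_stop("insufficient_data", "LFER needs >= 3 records (got %d)", n)
  if (length(unique(x)) < 2L)
    tf_stop("rank_deficient", "ddG_eq values are all equal")
  cf <- .ols(x, y)
  sds <- c(NA_real_, NA_real_)
  if (bootstrap > 0L) {
    if (bootstrap < 200L)
      tf_warn("few_bootstrap", "bootstrap < 200: reported sds are unreliable")
    boots <- with_seed(seed, {
      out <- matrix(NA_real_, nrow = bootstrap, ncol = 2L)
      b <- 1L
      guard <- 0L
      while (b <= bootstrap && guard < bootstrap * 50L) {
        guard <- guard + 1L
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(x[idx])) < 3L) next   # degenerate draw: redraw
        out[b, ] <- .ols(x[idx], y[idx])
        b <- b + 1L
      }
      out
    })
    sds <- apply(boots, 2L, sd, na.rm = TRUE)
  }
  structure(list(alpha = cf[2L], intercept = cf[1L],
                 alpha_sd = sds[2L], intercept_sd = sds[1L],
                 r = if (var(y) > 0) cor(x, y) else NA_real_, n_points = n,
                 bootstrap_samples = as.integer(bootstrap),
                 seed = as.integer(seed)),
            class = "lfer_result")
}

## closed-form OLS, returns c(intercept, slope); used by the bootstrap
## loop where lm() overhead would dominate.
.ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sl <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(my - sl * mx, sl)
}

#' @export
print.lfer_result <- function(x, ...) {
  cat(sprintf("LFER fit (n = %d): alpha = %.3f +/- %.3f, intercept = %.3f +/- %.3f kcal/mol (r = %.3f)\n",
              x$n_points, x$alpha, x$alpha_sd, x$intercept, x$intercept_sd, x$r))
  invisible(x)
}
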