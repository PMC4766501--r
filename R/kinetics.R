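## Kinetics module: single-exponential trace fitting and
## pseudo-first-order analysis of stopped-flow binding data.

#' Construct a binding trace
#'
#' A stopped-flow fluorescence trace recorded after mixing a constant
#' (probe) concentration of receptor with an excess (ligand)
#' concentration of the disordered peptide.  Under pseudo-first-order
#' conditions the trace relaxes as a single exponential with observed
#' rate `k_obs = k_on * [L] + k_off`.
#'
#' A warning is raised when the ligand excess is below 10-fold (the
#' pseudo-first-order approximation starts to degrade); an excess below
#' 2-fold is refused outright.
#'
#' @param time Time points in seconds, strictly increasing, length >= 10.
#' @param signal Fluorescence signal (arbitrary units), same length.
#' @param ligand_conc Ligand (excess species) concentration in uM.
#' @param probe_conc Probe (constant species) concentration in uM.
#' @return An object of class `binding_trace`: a data frame with columns
#'   `time_s` and `signal`, with concentrations stored as attributes.
#' @export
binding_trace <- function(time, signal, ligand_conc, probe_conc) {
  if (length(time) < 10L)
    tf_stop("trace_invalid", "a binding trace needs >= 10 time points (got %d)",
            length(time))
  if (length(signal) != length(time))
    tf_stop("trace_invalid", "time and signal lengths differ")
  if (any(!is.finite(time)) || any(!is.finite(signal)))
    tf_stop("trace_invalid", "non-finite values in trace")
  if (any(diff(time) <= 0))
    tf_stop("trace_invalid", "time must be strictly increasing")
  if (!is_num1(ligand_conc) || ligand_conc <= 0)
    tf_stop("trace_invalid", "ligand_conc must be a positive number (uM)")
  if (!is_num1(probe_conc) || probe_conc <= 0)
    tf_stop("trace_invalid", "probe_conc must be a positive number (uM)")
  excess <- ligand_conc / probe_conc
  if (excess < 2)
    tf_stop("pseudo_first_order_violation",
            "ligand/probe ratio %.2f < 2: pseudo-first-order analysis refused",
            excess)
  if (excess < 10)
    tf_warn("pseudo_first_order_marginal",
            "ligand/probe ratio %.1f < 10: pseudo-first-order approximation is marginal",
            excess)
  structure(data.frame(time_s = as.numeric(time), signal = as.numeric(signal)),
            ligand_conc = as.numeric(ligand_conc),
            probe_conc = as.numeric(probe_conc),
            class = c("binding_trace", "data.frame"))
}

#' Fit a single-exponential relaxation to a binding trace
#'
#' Least-squares fit of `signal(t) = offset + amplitude * exp(-k_obs t)`.
#' The offset and amplitude are linear given the rate, so they are
#' projected out and the profiled residual sum of squares is minimised
#' over `k_obs` alone: a log-spaced scan seeded by a deterministic
#' starting guess (log-linearised early decay), refined with
#' [stats::optimize()].  This remains robust on noiseless traces,
#' where Gauss-Newton iterations stall on zero residuals.
#' Standard errors come from the covariance of
#' the least-squares Jacobian; [bootstrap_k_obs()] offers an independent
#' resampling cross-check.
#'
#' @param trace A [binding_trace()].
#' @return A list of class `exp_fit` with elements `ok`, `k_obs`,
#'   `k_obs_sd`, `amplitude`, `offset`, `residual_norm`, `n`.  On
#'   non-convergence `ok` is `FALSE` and the parameter fields are `NA`
#'   (the residual norm of the best starting point is still reported).
#'   A warning is raised when fewer than 5 points lie beyond `3/k_obs`
#'   (under-sampled plateau).
#' @export
fit_single_exponential <- function(trace) {
  stopifnot(inherits(trace, "binding_trace"))
  t <- trace$time_s
  y <- trace$signal
  if (max(y) - min(y) <= .Machine$double.eps * max(1, abs(max(y))) ||
      isTRUE(all.equal(var(y), 0)))
    return(structure(list(ok = FALSE, k_obs = NA_real_, k_obs_sd = NA_real_,
                          amplitude = NA_real_, offset = NA_real_,
                          residual_norm = 0, n = length(y),
                          reason = "constant signal"),
                     class = "exp_fit"))

  start <- .exp_fit_start(t, y)
  ## profiled RSS: offset/amplitude are linear given k
  lin <- function(k) {
    X <- cbind(1, exp(-k * t))
    cf <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA_real_, NA_real_))
    if (any(!is.finite(cf))) return(list(rss = Inf, cf = cf))
    list(rss = sum((y - X %*% cf)^2), cf = cf)
  }
  rss <- function(k) lin(k)$rss
  kgrid <- start$k * 2^seq(-8, 8, by = 0.5)
  rs <- vapply(kgrid, rss, numeric(1))
  kbest <- kgrid[which.min(rs)]
  opt <- optimize(rss, c(kbest / 2.2, kbest * 2.2), tol = kbest * 1e-10)
  k_obs <- opt$minimum
  sol <- lin(k_obs)
  if (!is.finite(sol$rss) || k_obs <= 0 ||
      abs(sol$cf[2L]) < 1e-12 * max(abs(y), 1)) {
    return(structure(list(ok = FALSE, k_obs = NA_real_, k_obs_sd = NA_real_,
                          amplitude = NA_real_, offset = NA_real_,
                          residual_norm = sqrt(min(rs[is.finite(rs)],
                                                   sol$rss, na.rm = TRUE)),
                          n = length(y), reason = "non-convergence"),
                     class = "exp_fit"))
  }
  offset <- unname(sol$cf[1L])
  amplitude <- unname(sol$cf[2L])
  ## Jacobian-based covariance of (offset, amplitude, k)
  ek <- exp(-k_obs * t)
  J <- cbind(1, ek, -amplitude * t * ek)
  s2 <- sol$rss / max(length(y) - 3L, 1L)
  k_sd <- tryCatch(sqrt(s2 * solve(crossprod(J))[3L, 3L]),
                   error = function(e) NA_real_)
  if (sum(t > 3 / k_obs) < 5L)
    tf_warn("under_sampled",
            "fewer than 5 points beyond 3/k_obs = %.3g s: plateau under-sampled",
            3 / k_obs)
  structure(list(ok = TRUE,
                 k_obs = k_obs,
                 k_obs_sd = k_sd,
                 amplitude = amplitude,
                 offset = offset,
                 residual_norm = sqrt(sol$rss),
                 n = length(y)),
            class = "exp_fit")
}

## Deterministic starting values: offset from the tail, amplitude from
## the endpoints, k from a log-linear fit to the early decay.
.exp_fit_start <- function(t, y) {
  n <- length(y)
  offset <- mean(y[max(1L, n - max(3L, n %/% 10L)):n])
  amplitude <- y[1L] - offset
  if (abs(amplitude) < .Machine$double.eps) amplitude <- diff(range(y))
  z <- (y - offset) / amplitude          # ~ exp(-k t)
  use <- which(z > 0.05 & z < 1.5)
  k <- if (length(use) >= 3L) {
    cf <- tryCatch(qr.coef(qr(cbind(1, t[use])), log(z[use])),
                   error = function(e) c(0, -1))
    max(-cf[2L], .Machine$double.eps)
  } else 1 / max(t[n %/% 2L], .Machine$double.eps)
  if (!is.finite(k) || k <= 0) k <- 1 / mean(t)
  list(offset = offset, amplitude = amplitude, k = k)
}

#' Bootstrap standard error of the fitted observed rate
#'
#' Residual-resampling bootstrap around the single-exponential fit:
#' residuals of the converged fit are resampled with replacement, added
#' back to the fitted curve, and the trace is refit.  Provides an
#' independent cross-check on the Jacobian-based standard error.
#'
#' @param trace A [binding_trace()].
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @return List with `k_obs_sd` (bootstrap sd) and the vector of
#'   replicate estimates `k_obs`.
#' @export
bootstrap_k_obs <- function(trace, n_boot = 200L, seed = 1L) {
  fit <- fit_single_exponential(trace)
  if (!fit$ok) tf_stop("fit_failure", "cannot bootstrap a failed fit")
  t <- trace$time_s
  yhat <- fit$offset + fit$amplitude * exp(-fit$k_obs * t)
  res <- trace$signal - yhat
  ks <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      yb <- yhat + sample(res, length(res), replace = TRUE)
      tb <- trace
      tb$signal <- yb
      fb <- suppressWarnings(fit_single_exponential(tb))
      if (fb$ok) fb$k_obs else NA_real_
    }, numeric(1))
  })
  ks <- ks[is.finite(ks)]
  list(k_obs_sd = sd(ks), k_obs = ks)
}

#' Construct an observed-rate record
#'
#' @param ligand_conc Ligand concentration in uM.
#' @param k_obs Observed rate in 1/s (must be > 0).
#' @param k_obs_sd Optional standard error of `k_obs`.
#' @return A one-row data frame of class `observed_rate`.
#' @export
observed_rate <- function(ligand_conc, k_obs, k_obs_sd = NA_real_) {
  if (!is_num1(k_obs) || k_obs <= 0)
    tf_stop("rate_invalid", "k_obs must be > 0")
  structure(data.frame(ligand_conc = ligand_conc, k_obs = k_obs,
                       k_obs_sd = k_obs_sd),
            class = c("observed_rate", "data.frame"))
}

#' Construct a rate-constant record
#'
#' Holds the association (`k_on`, uM^-1 s^-1) and dissociation
#' (`k_off`, s^-1) rate constants of one receptor-variant x
#' ligand-variant pair, with uncertainties and temperature.
#'
#' @param k_on Association rate constant, uM^-1 s^-1 (> 0).
#' @param k_off Dissociation rate constant, s^-1 (>= 0; a negative
#'   regression intercept is stored as given but flagged).
#' @param k_on_sd,k_off_sd Standard errors.
#' @param temperature Temperature in K (default 283.15 K, i.e. 10 C).
#' @param variant_receptor,variant_ligand Variant labels.
#' @return A list of class `rate_constants`.
#' @export
rate_constants <- function(k_on, k_off, k_on_sd = NA_real_, k_off_sd = NA_real_,
                           temperature = 283.15,
                           variant_receptor = "WT", variant_ligand = "WT") {
  if (!is_num1(k_on) || k_on <= 0)
    tf_stop("rate_invalid", "k_on must be > 0")
  if (!is_num1(k_off))
    tf_stop("rate_invalid", "k_off must be a finite number")
  flagged <- k_off < 0
  if (flagged)
    tf_warn("negative_intercept",
            "negative k_off (%.3g s^-1): reported but physically suspect", k_off)
  structure(list(k_on = k_on, k_off = k_off,
                 k_on_sd = k_on_sd, k_off_sd = k_off_sd,
                 temperature = temperature,
                 variant_receptor = variant_receptor,
                 variant_ligand = variant_ligand,
                 negative_intercept = flagged),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("Rate constants [%s receptor / %s ligand, %.2f K]\n",
              x$variant_receptor, x$variant_ligand, x$temperature))
  cat(sprintf("  k_on  = %.4g +/- %.2g uM^-1 s^-1\n", x$k_on, x$k_on_sd))
  cat(sprintf("  k_off = %.4g +/- %.2g s^-1\n", x$k_off, x$k_off_sd))
  cat(sprintf("  K_D   = %.4g uM\n", x$k_off / x$k_on))
  invisible(x)
}

#' Fit a pseudo-first-order series
#'
#' Linear regression of observed rates on ligand concentration,
#' `k_obs = k_on * [L] + k_off`: the slope is the association rate
#' constant and the intercept the dissociation rate constant obtained
#' by linear extrapolation to zero ligand.  When standard deviations
#' are available for every point the regression is weighted by
#' `1/sd^2`; otherwise it is unweighted.
#'
#' @param series A data frame with columns `ligand_conc`, `k_obs` and
#'   optionally `k_obs_sd` (e.g. rbind-ed [observed_rate()] rows).
#' @param weighted Use `1/sd^2` weights when sds are present
#'   (default `TRUE`).
#' @param temperature,variant_receptor,variant_ligand Metadata copied
#'   into the result.
#' @return A [rate_constants()] object.  A negative intercept is
#'   reported but flagged via the `negative_intercept` field.
#' @export
fit_pseudo_first_order <- function(series, weighted = TRUE,
                                   temperature = 283.15,
                                   variant_receptor = "WT",
                                   variant_ligand = "WT") {
  stopifnot(is.data.frame(series),
            all(c("ligand_conc", "k_obs") %in% names(series)))
  conc <- series$ligand_conc
  if (length(unique(conc)) < 3L)
    tf_stop("insufficient_data",
            "need >= 3 distinct ligand concentrations (got %d)",
            length(unique(conc)))
  if (length(unique(conc)) == 1L || isTRUE(all.equal(var(conc), 0)))
    tf_stop("rank_deficient", "all ligand concentrations are equal")
  w <- NULL
  sds <- series$k_obs_sd
  if (weighted && !is.null(sds) && all(is.finite(sds)) && all(sds > 0))
    w <- 1 / sds^2
  fit <- lm(k_obs ~ ligand_conc, data = series, weights = w)
  cf <- coef(fit)
  ## vcov warns on exactly-collinear (noiseless) data; the zero SEs it
  ## returns are correct there
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  if (cf[["ligand_conc"]] <= 0)
    tf_warn("nonpositive_slope", "fitted k_on slope is <= 0")
  rate_constants(k_on = max(unname(cf[["ligand_conc"]]), .Machine$double.eps),
                 k_off = unname(cf[["(Intercept)"]]),
                 k_on_sd = unname(se[["ligand_conc"]]),
                 k_off_sd = unname(se[["(Intercept)"]]),
                 temperature = temperature,
                 variant_receptor = variant_receptor,
                 variant_ligand = variant_ligand)
}

#' Equilibrium dissociation constant from rate constants
#'
#' `K_D = k_off / k_on`, with first-order error propagation
#' `(sd_KD/KD)^2 = (sd_on/k_on)^2 + (sd_off/k_off)^2`.
#'
#' @param rc A [rate_constants()] object.
#' @return List with `K_D` (uM) and `K_D_sd`.
#' @export
dissociation_constant <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  if (rc$k_on <= 0) tf_stop("domain_error", "k_on must be > 0")
  K_D <- rc$k_off / rc$k_on
  rel2 <- 0
  if (is.finite(rc$k_on_sd)) rel2 <- rel2 + (rc$k_on_sd / rc$k_on)^2
  if (is.finite(rc$k_off_sd) && rc$k_off != 0)
    rel2 <- rel2 + (rc$k_off_sd / rc$k_off)^2
  list(K_D = K_D, K_D_sd = abs(K_D) * sqrt(rel2))
}

#' Fit a set of traces and their pseudo-first-order series in one call
#'
#' Convenience wrapper: fits every trace with
#' [fit_single_exponential()], then regresses all replicate `k_obs`
#' values on concentration with [fit_pseudo_first_order()].  Keeping
#' the replicates as individual points (rather than averaging per
#' concentration) leaves the regression enough residual degrees of
#' freedom for reliable standard errors; set `aggregate = TRUE` for
#' the per-concentration mean/sd variant.
#'
#' @param traces List of [binding_trace()] objects.
#' @param aggregate Average replicates per concentration first.
#' @param weighted Passed to [fit_pseudo_first_order()] (default
#'   FALSE: between-replicate scatter, not the per-trace fit error,
#'   dominates).
#' @param ... Passed to [fit_pseudo_first_order()].
#' @return A [rate_constants()] object with the fitted series attached
#'   as attribute `series`.
#' @export
fit_trace_set <- function(traces, aggregate = FALSE, weighted = FALSE, ...) {
  stopifnot(length(traces) >= 3L)
  rows <- lapply(traces, function(tr) {
    f <- suppressWarnings(fit_single_exponential(tr))
    if (!f$ok) return(NULL)
    data.frame(ligand_conc = attr(tr, "ligand_conc"), k_obs = f$k_obs,
               k_obs_se = f$k_obs_sd)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) < 3L)
    tf_stop("insufficient_data", "fewer than 3 traces fitted successfully")
  ser <- if (aggregate) {
    do.call(rbind, lapply(split(rows, rows$ligand_conc), function(d) {
      data.frame(ligand_conc = d$ligand_conc[1],
                 k_obs = mean(d$k_obs),
                 k_obs_sd = if (nrow(d) > 1L) sd(d$k_obs) else d$k_obs_se[1])
    }))
  } else data.frame(ligand_conc = rows$ligand_conc, k_obs = rows$k_obs,
                    k_obs_sd = rows$k_obs_se)
  rc <- fit_pseudo_first_order(ser, weighted = weighted, ...)
  attr(rc, "series") <- ser
  rc
}
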