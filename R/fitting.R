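## Nonlinear least-squares fitting of time-activity models.
##
## Fitting uses minpack.lm::nls.lm: plain Levenberg-Marquardt when the fit
## is unconstrained, and the same minimizer with box bounds when the decay
## constants are constrained to be at least the physical decay constant.
## Initial guesses are deterministic and documented; there is no random
## restarting by default.

POINT_SELECTORS <- c("all", "last3", "pts2to4")
WEIGHTING_SCHEMES <- c("unweighted", "relative", "user_supplied")

#' Fit specification
#'
#' Bundles the choices that define one curve fit: the model family, whether
#' decay constants are constrained from below by the physical decay
#' constant, the residual weighting scheme, and which time points enter the
#' fit.
#'
#' @param model_family one of `"monoexp"`, `"biexp3"`, `"biexp4"`
#' @param constrain_lambda_physical if `TRUE`, every fitted decay constant
#'   is bounded below by `lam_physical` of the nuclide in use
#' @param weighting `"unweighted"` (default), `"relative"` (sigma
#'   proportional to the measured activity, floored at 1% of the peak), or
#'   `"user_supplied"` (requires `sigma`)
#' @param sigma numeric vector of per-point standard deviations, only with
#'   `weighting = "user_supplied"`
#' @param points_used `"all"`, `"last3"`, or `"pts2to4"` (drop the first
#'   point)
#' @param n_restarts number of additional deterministic perturbed starts
#'   (default 0); the best residual sum of squares wins
#' @return object of class `fit_spec`
#' @export
fit_spec <- function(model_family,
                     constrain_lambda_physical = FALSE,
                     weighting = "unweighted",
                     sigma = NULL,
                     points_used = "all",
                     n_restarts = 0L) {
  .check_family(model_family)
  weighting <- match.arg(weighting, WEIGHTING_SCHEMES)
  points_used <- match.arg(points_used, POINT_SELECTORS)
  if (weighting == "user_supplied" && is.null(sigma))
    stop("'sigma' must be given when weighting = 'user_supplied'")
  structure(
    list(model_family = model_family,
         constrain_lambda_physical = isTRUE(constrain_lambda_physical),
         weighting = weighting,
         sigma = sigma,
         points_used = points_used,
         n_restarts = as.integer(n_restarts)),
    class = "fit_spec"
  )
}

.select_points <- function(series, points_used) {
  n <- length(series$times)
  idx <- switch(points_used,
                all = seq_len(n),
                last3 = {
                  if (n < 3L) stop("'last3' selector needs >= 3 points")
                  (n - 2L):n
                },
                pts2to4 = {
                  if (n < 3L) stop("'pts2to4' selector needs >= 3 points")
                  2L:n
                })
  idx
}

#' Deterministic initial parameter guess
#'
#' Produces the documented starting values used by [fit_curve()]:
#' log-linear regression on the positive activities for `monoexp`; for the
#' biexponential families the washout rate comes from the last two points,
#' the uptake rate is set ten times faster, and amplitudes are scaled to
#' the observed peak.
#'
#' @param series a [ta_series()]
#' @param model_family model family name
#' @return named numeric parameter vector
#' @export
initial_guess <- function(series, model_family) {
  .check_family(model_family)
  t <- series$times; y <- series$activities
  n <- length(t)
  pos <- y > 0
  if (sum(pos) < 2L) stop("fewer than 2 positive activities; cannot guess")
  lam_floor <- 1e-6
  if (model_family == "monoexp") {
    co <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
    lam <- max(-co[[2]], lam_floor)
    A <- exp(co[[1]])
    return(c(A = A, lam = lam))
  }
  # washout rate from the last two points (floored for flat tails)
  l1 <- if (y[n - 1L] > 0 && y[n] > 0) {
    log(y[n - 1L] / y[n]) / (t[n] - t[n - 1L])
  } else lam_floor
  l1 <- max(l1, lam_floor)
  l2 <- 10 * l1
  if (model_family == "biexp3") {
    ipk <- which.max(y)
    shape_pk <- exp(-l1 * t[ipk]) - exp(-l2 * t[ipk])
    A <- if (shape_pk > 0) y[ipk] / shape_pk else max(y)
    return(c(A = A, lam1 = l1, lam2 = l2))
  }
  # biexp4: slow phase pinned to the last point, fast phase to the first
  A1 <- y[n] * exp(l1 * t[n])
  A2 <- (y[1L] - A1 * exp(-l1 * t[1L])) / exp(-l2 * t[1L])
  if (!is.finite(A2) || A2 == 0) A2 <- 0.1 * max(y)
  c(A1 = A1, A2 = A2, lam1 = l1, lam2 = l2)
}

# map user-facing params to the internal optimizer parameterization.
# biexp3 is optimized as (A, lam1, dlam) with dlam = lam2 - lam1 >= 0 so a
# box bound keeps the uptake rate above the washout rate.
.to_internal <- function(model_family, p) {
  if (model_family == "biexp3")
    c(A = p[["A"]], lam1 = p[["lam1"]], dlam = p[["lam2"]] - p[["lam1"]])
  else p
}

.from_internal <- function(model_family, q) {
  if (model_family == "biexp3")
    c(A = q[["A"]], lam1 = q[["lam1"]], lam2 = q[["lam1"]] + q[["dlam"]])
  else q
}

.fit_bounds <- function(model_family, constrain, lam_physical) {
  lam_lb <- if (constrain) lam_physical else -Inf
  switch(model_family,
    monoexp = list(lower = c(A = 0, lam = lam_lb),
                   upper = c(A = Inf, lam = Inf)),
    biexp3 = list(lower = c(A = 0, lam1 = lam_lb, dlam = 0),
                  upper = c(A = Inf, lam1 = Inf, dlam = Inf)),
    biexp4 = list(lower = c(A1 = -Inf, A2 = -Inf, lam1 = lam_lb,
                            lam2 = lam_lb),
                  upper = c(A1 = Inf, A2 = Inf, lam1 = Inf, lam2 = Inf))
  )
}

.fit_sigma <- function(spec, y, idx) {
  switch(spec$weighting,
    unweighted = rep(1, length(idx)),
    relative = pmax(y[idx], 0.01 * max(y)),
    user_supplied = {
      s <- spec$sigma
      if (length(s) == length(y)) s <- s[idx]
      if (length(s) != length(idx) || any(s <= 0))
        stop("'sigma' must be positive, one per (selected) point")
      s
    })
}

#' Fit a time-activity model to a series
#'
#' Weighted nonlinear least squares via the Levenberg-Marquardt algorithm
#' (bounded trust-region variant when the physical decay-rate constraint is
#' enabled).  Non-convergence is reported through `converged = FALSE`
#' rather than an error.
#'
#' @param series a [ta_series()]
#' @param spec a [fit_spec()]
#' @param constants a [nuclide_constants()] (needed for the constraint)
#' @return object of class `fit_result` with fields `params` (named, in the
#'   family's natural parameterization), `residuals` (observed - fitted at
#'   the points used), `r_squared`, `rss`, `aic` (`n*log(RSS/n) + 2k`),
#'   `aicc` (`NA` and flagged when `n - k - 1 <= 0`), `converged`, and
#'   `warnings` (e.g. `"ill_conditioned_4param"` for the 4-parameter
#'   biexponential on exactly 4 points).
#' @examples
#' s <- ta_series("kidney_left", patient_schedules()$patientA,
#'                eval_model("monoexp", c(A = 20, lam = 0.015),
#'                           patient_schedules()$patientA))
#' fit <- fit_curve(s, fit_spec("monoexp"))
#' fit$params
#' @export
fit_curve <- function(series, spec, constants = nuclide_constants()) {
  stopifnot(inherits(series, "ta_series"), inherits(spec, "fit_spec"))
  fam <- spec$model_family
  idx <- .select_points(series, spec$points_used)
  t <- series$times[idx]; y <- series$activities[idx]
  k <- .n_params(fam)
  n <- length(idx)
  warn <- character()
  if (fam == "biexp4" && n <= k) warn <- c(warn, "ill_conditioned_4param")
  if (n < k && !(fam == "biexp4" && n == 4L))
    stop(sprintf("%d points selected for a %d-parameter model", n, k))
  if (all(y == 0)) stop("all selected activities are zero; nothing to fit")

  sig <- .fit_sigma(spec, series$activities, idx)
  bounds <- .fit_bounds(fam, spec$constrain_lambda_physical,
                        constants$lam_physical)

  resid_fn <- function(q) {
    p <- .from_internal(fam, q)
    (y - eval_model(fam, .check_params(fam, p, strict = FALSE), t)) / sig
  }

  start0 <- .to_internal(fam, initial_guess(series, fam))
  # push the start strictly inside the feasible box
  inner_lo <- ifelse(is.finite(bounds$lower),
                     bounds$lower + pmax(abs(bounds$lower), 1) * 1e-10,
                     -Inf)
  start0 <- pmin(pmax(start0, inner_lo), bounds$upper)
  starts <- list(start0)
  if (spec$n_restarts > 0L) {
    factors <- c(0.5, 2, 0.2, 5, 0.1, 10)[seq_len(min(spec$n_restarts, 6L))]
    for (f in factors) {
      s <- start0 * f
      starts[[length(starts) + 1L]] <-
        pmin(pmax(s, bounds$lower + 1e-12), bounds$upper)
    }
  }

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fn,
        lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
      error = function(e) e)
    if (inherits(res, "error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }

  if (is.null(best)) {
    return(structure(
      list(model_family = fam, params = NULL, residuals = NULL,
           r_squared = NA_real_, rss = NA_real_, n = n, k = k,
           aic = NA_real_, aicc = NA_real_, aicc_defined = FALSE,
           converged = FALSE, warnings = c(warn, "optimizer_error"),
           spec = spec, times_used = t, activities_used = y, sigma = sig),
      class = "fit_result"))
  }

  params <- .from_internal(fam, stats::coef(best))
  params <- .check_params(fam, params, strict = FALSE)
  converged <- best$info %in% 1:4 && all(is.finite(params))
  fitted <- eval_model(fam, params, t)
  residuals <- y - fitted
  rss <- sum(residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  aic <- n * log(max(rss, 1e-300) / n) + 2 * k
  aicc_defined <- (n - k - 1L) > 0L
  aicc <- if (aicc_defined) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  if (fam %in% c("monoexp", "biexp3") && params[[1L]] < 0)
    warn <- c(warn, "negative_amplitude")

  structure(
    list(model_family = fam, params = params, residuals = residuals,
         fitted = fitted, r_squared = r2, rss = rss, n = n, k = k,
         aic = aic, aicc = aicc, aicc_defined = aicc_defined,
         converged = converged, warnings = warn, spec = spec,
         times_used = t, activities_used = y, sigma = sig),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit (%s): converged = %s\n", x$model_family, x$converged))
  if (!is.null(x$params)) print(signif(x$params, 6))
  cat(sprintf("  R^2 = %.6g, AIC = %.6g, AICc = %s\n", x$r_squared, x$aic,
              if (x$aicc_defined) sprintf("%.6g", x$aicc) else "undefined"))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = ", "),
                              "\n")
  invisible(x)
}

#' Goodness-of-fit diagnostics
#'
#' Summarizes a converged fit: coefficient of determination, AIC and (when
#' defined) corrected AIC, a residual table, and physiological sanity
#' checks.  The fitted activity at time 0 is compared with the injected
#' activity when the series records one: an organ cannot contain more
#' activity than was injected.
#'
#' @param fit a converged [fit_curve()] result
#' @param series the [ta_series()] the fit was made on
#' @return list with `r_squared`, `aic`, `aicc`, `aicc_defined`,
#'   `residual_table` (data.frame), and `warnings`
#' @export
fit_diagnostics <- function(fit, series) {
  stopifnot(inherits(fit, "fit_result"))
  if (!fit$converged) stop("diagnostics require a converged fit")
  warn <- fit$warnings
  a0 <- eval_model(fit$model_family, fit$params, 0)
  if (is.finite(series$injected_activity) &&
      a0 > series$injected_activity) {
    warn <- c(warn, "nonphysiological_t0_activity")
  }
  list(
    r_squared = fit$r_squared,
    aic = fit$aic,
    aicc = fit$aicc,
    aicc_defined = fit$aicc_defined,
    activity_at_t0 = a0,
    residual_table = data.frame(
      time_h = fit$times_used,
      observed_MBq = fit$activities_used,
      fitted_MBq = fit$fitted,
      residual_MBq = fit$residuals),
    warnings = unique(warn)
  )
}
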