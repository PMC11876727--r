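## Time-activity model families and their closed-form integrals.
##
## Three families are supported, all with activity in MBq and time in hours
## post-injection:
##   monoexp : A(t) = A exp(-lam t)                       params A, lam
##   biexp3  : A(t) = A (exp(-lam1 t) - exp(-lam2 t))     params A, lam1, lam2
##   biexp4  : A(t) = A1 exp(-lam1 t) + A2 exp(-lam2 t)   params A1, A2, lam1, lam2
## biexp3 is exactly zero at t = 0 (one fewer free amplitude); lam2 is the
## uptake rate and must exceed the washout rate lam1 for a non-negative curve.

MODEL_FAMILIES <- c("monoexp", "biexp3", "biexp4")

# relative closeness below which biexp3 switches to its lam1 == lam2 limit
.BIEXP3_DEGENERATE_TOL <- 1e-9

.check_family <- function(model_family) {
  if (!is.character(model_family) || length(model_family) != 1L ||
      !model_family %in% MODEL_FAMILIES) {
    stop("unknown model family: ", paste(model_family, collapse = ", "),
         " (must be one of ", paste(MODEL_FAMILIES, collapse = ", "), ")")
  }
  model_family
}

.n_params <- function(model_family) {
  switch(.check_family(model_family), monoexp = 2L, biexp3 = 3L, biexp4 = 4L)
}

.param_names <- function(model_family) {
  switch(.check_family(model_family),
         monoexp = c("A", "lam"),
         biexp3  = c("A", "lam1", "lam2"),
         biexp4  = c("A1", "A2", "lam1", "lam2"))
}

.check_params <- function(model_family, params, strict = TRUE) {
  nm <- .param_names(model_family)
  if (!is.numeric(params) || length(params) != length(nm)) {
    stop(sprintf("'%s' requires %d numeric parameters (%s)", model_family,
                 length(nm), paste(nm, collapse = ", ")))
  }
  if (is.null(names(params)) || !all(nm %in% names(params))) {
    names(params) <- nm
  }
  params <- params[nm]
  if (any(!is.finite(params))) stop("non-finite model parameters")
  if (strict) {
    if (model_family == "monoexp" && params[["A"]] < 0) {
      stop("monoexp amplitude A must be >= 0")
    }
    if (model_family == "biexp3") {
      if (params[["A"]] < 0) stop("biexp3 amplitude A must be >= 0")
      if (params[["lam2"]] < params[["lam1"]]) {
        stop("biexp3 requires lam2 >= lam1 (uptake faster than washout)")
      }
    }
  }
  params
}

.biexp3_degenerate <- function(lam1, lam2) {
  lam1 != 0 && abs(lam1 - lam2) / abs(lam1) < .BIEXP3_DEGENERATE_TOL
}

#' Evaluate a time-activity model
#'
#' Computes the activity predicted by one of the model families at times
#' `t` (hours post-injection).
#'
#' @param model_family one of `"monoexp"`, `"biexp3"`, `"biexp4"`
#' @param params named numeric vector of parameters: `A`, `lam` for
#'   `monoexp`; `A`, `lam1`, `lam2` for `biexp3` (`lam2 >= lam1`);
#'   `A1`, `A2`, `lam1`, `lam2` for `biexp4`
#' @param t numeric vector of times in hours, `t >= 0`
#' @return numeric vector of activities (MBq)
#' @details For `biexp3`, when `lam1` and `lam2` coincide to within 1e-9
#'   relative the analytic limit `A * lam * t * exp(-lam * t)` is used.
#' @examples
#' eval_model("monoexp", c(A = 100, lam = 0.1), c(0, log(2) / 0.1))
#' eval_model("biexp3", c(A = 100, lam1 = 0.02, lam2 = 0.2), 0)  # exactly 0
#' @export
eval_model <- function(model_family, params, t) {
  params <- .check_params(model_family, params)
  if (any(t < 0)) stop("'t' must be >= 0 (hours post-injection)")
  switch(model_family,
    monoexp = params[["A"]] * exp(-params[["lam"]] * t),
    biexp3 = {
      A <- params[["A"]]; l1 <- params[["lam1"]]; l2 <- params[["lam2"]]
      if (.biexp3_degenerate(l1, l2)) {
        A * l1 * t * exp(-l1 * t)
      } else {
        A * (exp(-l1 * t) - exp(-l2 * t))
      }
    },
    biexp4 = params[["A1"]] * exp(-params[["lam1"]] * t) +
             params[["A2"]] * exp(-params[["lam2"]] * t)
  )
}

# integral of A exp(-lam t) over [a, b]; b may be Inf (requires lam > 0)
.int_exp_term <- function(A, lam, a, b) {
  if (A == 0) return(0)
  if (is.infinite(b)) {
    if (lam <= 0) {
      stop(structure(
        class = c("tiadose_divergent_integral", "error", "condition"),
        list(message = sprintf(
               "improper integral diverges: decay constant %g <= 0", lam),
             call = sys.call(-1))))
    }
    return(A / lam * exp(-lam * a))
  }
  if (lam == 0) return(A * (b - a))
  A / lam * (exp(-lam * a) - exp(-lam * b))
}

#' Closed-form definite integral of a time-activity model
#'
#' Exact antiderivative evaluation of the model over `[a, b]`, returning a
#' TIA segment in MBq.h.  `b` may be `Inf`, in which case every decay
#' constant entering the integrand must be strictly positive; otherwise a
#' condition of class `tiadose_divergent_integral` is signalled.
#'
#' @inheritParams eval_model
#' @param a,b integration limits in hours, `0 <= a <= b`; `b` may be `Inf`
#' @return TIA segment (MBq.h)
#' @examples
#' integral_closed_form("monoexp", c(A = 100, lam = 0.1), 0, Inf)  # 1000
#' integral_closed_form("biexp3", c(A = 100, lam1 = 0.02, lam2 = 0.2),
#'                      0, Inf)  # 4500
#' @export
integral_closed_form <- function(model_family, params, a, b) {
  params <- .check_params(model_family, params)
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L) {
    stop("'a' and 'b' must be single numbers")
  }
  if (a < 0 || b < a) stop("integration limits must satisfy 0 <= a <= b")
  switch(model_family,
    monoexp = .int_exp_term(params[["A"]], params[["lam"]], a, b),
    biexp3 = {
      A <- params[["A"]]; l1 <- params[["lam1"]]; l2 <- params[["lam2"]]
      if (.biexp3_degenerate(l1, l2)) {
        # integral of A l t e^(-l t): antiderivative -A e^(-l t) (t + 1/l)
        if (is.infinite(b)) {
          if (l1 <= 0) stop(structure(
            class = c("tiadose_divergent_integral", "error", "condition"),
            list(message = "improper integral diverges: decay constant <= 0",
                 call = sys.call())))
          A * exp(-l1 * a) * (a + 1 / l1)
        } else {
          A * (exp(-l1 * a) * (a + 1 / l1) - exp(-l1 * b) * (b + 1 / l1))
        }
      } else {
        .int_exp_term(A, l1, a, b) - .int_exp_term(A, l2, a, b)
      }
    },
    biexp4 = .int_exp_term(params[["A1"]], params[["lam1"]], a, b) +
             .int_exp_term(params[["A2"]], params[["lam2"]], a, b)
  )
}

#' Physical-decay tail integral
#'
#' TIA contributed by assuming pure physical decay of the radionuclide after
#' the last imaging time point: the integral of
#' `A_p4 * exp(-lam_physical * (t - t_p4))` from `t_p4` to infinity, which is
#' `A_p4 / lam_physical`.
#'
#' @param A_p4 activity at the last time point (MBq, >= 0)
#' @param lam_physical physical decay constant (1/h, > 0)
#' @return tail TIA segment (MBq.h)
#' @examples
#' physical_tail_integral(50, nuclide_constants()$lam_physical)
#' @export
physical_tail_integral <- function(A_p4, lam_physical) {
  if (A_p4 < 0) stop("'A_p4' must be >= 0")
  if (lam_physical <= 0) stop("'lam_physical' must be > 0")
  A_p4 / lam_physical
}
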