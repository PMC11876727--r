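# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: quadrature instead of antiderivatives, the direct
# sorted-order-statistic formula instead of stats::quantile, and a
# profiled grid search instead of Levenberg-Marquardt.

# adaptive quadrature of a model curve
quad_integral <- function(family, params, a, b) {
  stats::integrate(function(tt) eval_model(family, params, tt), a, b,
                   rel.tol = 1e-10, abs.tol = 0,
                   subdivisions = 2000L)$value
}

# improper integral approximated by truncating at 20 half-lives of the
# slowest decay constant in the integrand
quad_integral_improper <- function(family, params, a) {
  lams <- params[grep("^lam", names(params))]
  t_max <- a + 20 * log(2) / min(lams)
  quad_integral(family, params, a, t_max)
}

# random valid parameter draws per family (uses the current RNG stream)
draw_params <- function(family) {
  switch(family,
    monoexp = c(A = stats::runif(1, 1, 200),
                lam = stats::runif(1, 0.002, 0.3)),
    biexp3 = {
      l1 <- stats::runif(1, 0.002, 0.1)
      c(A = stats::runif(1, 1, 200), lam1 = l1,
        lam2 = l1 * stats::runif(1, 1.5, 20))
    },
    biexp4 = c(A1 = stats::runif(1, 1, 100), A2 = stats::runif(1, 1, 100),
               lam1 = stats::runif(1, 0.002, 0.1),
               lam2 = stats::runif(1, 0.05, 0.5)))
}

# type-7 quantile from first principles: sort, then linear interpolation
# between order statistics at h = (n-1) p + 1
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1L] - x[lo])
}

qcd_oracle <- function(x) {
  q1 <- quantile7_oracle(x, 0.25)
  q3 <- quantile7_oracle(x, 0.75)
  (q3 - q1) / (q3 + q1)
}

outlier_oracle <- function(x) {
  q1 <- quantile7_oracle(x, 0.25)
  q3 <- quantile7_oracle(x, 0.75)
  iqr <- q3 - q1
  x < q1 - 1.5 * iqr | x > q3 + 1.5 * iqr
}

# independent monoexponential least squares: the amplitude is profiled out
# analytically (A(lam) = sum(y w) / sum(w^2), w = exp(-lam t)) and the decay
# constant found by iteratively refined grid search
grid_ls_monoexp <- function(t, y, lam_range = c(1e-4, 1), stages = 6,
                            n_grid = 41) {
  rss_of <- function(lam) {
    w <- exp(-lam * t)
    A <- sum(y * w) / sum(w * w)
    sum((y - A * w)^2)
  }
  lo <- lam_range[1]; hi <- lam_range[2]
  for (s in seq_len(stages)) {
    grid <- seq(lo, hi, length.out = n_grid)
    rss <- vapply(grid, rss_of, numeric(1))
    i <- which.min(rss)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, n_grid)]
  }
  lam <- (lo + hi) / 2
  w <- exp(-lam * t)
  c(A = sum(y * w) / sum(w * w), lam = lam)
}

# a decaying noisy series suitable for every catalog method (last two
# points strictly decreasing so the line-to-zero tail is defined)
random_washout_series <- function(schedule = patient_schedules()$patientA,
                                  noise_sd = 0.05,
                                  lam_mult_range = c(2, 12)) {
  lamp <- nuclide_constants()$lam_physical
  repeat {
    p <- c(A = stats::runif(1, 5, 100),
           lam = stats::runif(1, lam_mult_range[1] * lamp,
                              lam_mult_range[2] * lamp))
    y <- eval_model("monoexp", p, schedule) *
      (1 + stats::rnorm(length(schedule), 0, noise_sd))
    y <- pmax(y, 0)
    n <- length(y)
    if (all(y > 0) && y[n] < y[n - 1L]) {
      return(list(series = ta_series("sim", schedule, y), params = p))
    }
  }
}

# bare tia_result constructor for boundary tests of the QC checks
fake_tia_result <- function(i1, i2, i3) {
  total <- i1 + i2 + i3
  structure(list(total = total, i1 = i1, i2 = i2, i3 = i3,
                 tail_fraction = i3 / total, qc_flags = character(),
                 method_id = "fake", fit = NULL),
            class = "tia_result")
}
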