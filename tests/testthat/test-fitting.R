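schedules <- patient_schedules()

test_that("noiseless data at both patient schedules is recovered exactly", {
  true_params <- list(
    monoexp = c(A = 100, lam = 0.012),
    biexp3 = c(A = 80, lam1 = 0.015, lam2 = 0.2),
    biexp4 = c(A1 = 50, A2 = 80, lam1 = 0.01, lam2 = 0.15))
  for (sched in schedules) {
    for (fam in names(true_params)) {
      p <- true_params[[fam]]
      s <- ta_series("r", sched, eval_model(fam, p, sched))
      fit <- fit_curve(s, fit_spec(fam))
      expect_true(fit$converged)
      expect_equal(fit$params[names(p)], p, tolerance = 1e-6)
      expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    }
  }
})

test_that("the physical decay-rate constraint binds at the bound", {
  lamp <- nuclide_constants()$lam_physical
  sched <- schedules$patientA
  s <- ta_series("r", sched,
                 eval_model("monoexp", c(A = 100, lam = 0.5 * lamp), sched))
  fit <- fit_curve(s, fit_spec("monoexp", constrain_lambda_physical = TRUE))
  expect_true(fit$converged)
  expect_equal(fit$params[["lam"]], lamp, tolerance = 1e-12)
  # unconstrained fit recovers the sub-physical rate instead
  fit_u <- fit_curve(s, fit_spec("monoexp"))
  expect_equal(fit_u$params[["lam"]], 0.5 * lamp, tolerance = 1e-6)
})

test_that("biexp4 on exactly 4 points is flagged ill-conditioned", {
  sched <- schedules$patientA
  s <- ta_series("r", sched,
                 eval_model("biexp4",
                            c(A1 = 50, A2 = 80, lam1 = 0.01, lam2 = 0.15),
                            sched))
  fit <- fit_curve(s, fit_spec("biexp4"))
  expect_true("ill_conditioned_4param" %in% fit$warnings)
})

test_that("initial guesses are deterministic and sensible", {
  sched <- schedules$patientA
  # log-linear regression is exact on exact monoexponential data
  s <- ta_series("r", sched, eval_model("monoexp", c(A = 42, lam = 0.03),
                                        sched))
  g <- initial_guess(s, "monoexp")
  expect_equal(g[["lam"]], 0.03, tolerance = 1e-9)
  expect_equal(g[["A"]], 42, tolerance = 1e-9)
  # flat series: decay guess clipped to a small positive floor
  flat <- ta_series("r", sched, rep(5, 4))
  expect_gt(initial_guess(flat, "monoexp")[["lam"]], 0)
  # interior peak: biexponential guess with uptake faster than washout
  s_pk <- ta_series("r", sched, c(30, 60, 20, 15))
  g3 <- initial_guess(s_pk, "biexp3")
  expect_gt(g3[["lam2"]], g3[["lam1"]])
  expect_error(initial_guess(ta_series("r", c(1, 2), c(0, 0)), "monoexp"),
               "positive")
})

test_that("fitting is equivariant under uniform activity rescaling", {
  set.seed(11)
  sched <- schedules$patientB
  y <- eval_model("monoexp", c(A = 60, lam = 0.02), sched) *
    (1 + rnorm(4, 0, 0.05))
  f1 <- fit_curve(ta_series("r", sched, y), fit_spec("monoexp"))
  f2 <- fit_curve(ta_series("r", sched, 3.5 * y), fit_spec("monoexp"))
  expect_equal(f2$params[["A"]] / f1$params[["A"]], 3.5, tolerance = 1e-9)
  expect_equal(f2$params[["lam"]], f1$params[["lam"]], tolerance = 1e-9)
})

test_that("weighted fits accept relative and user-supplied sigma", {
  set.seed(3)
  sched <- schedules$patientA
  y <- eval_model("monoexp", c(A = 90, lam = 0.02), sched) *
    (1 + rnorm(4, 0, 0.05))
  s <- ta_series("r", sched, y)
  f_rel <- fit_curve(s, fit_spec("monoexp", weighting = "relative"))
  f_usr <- fit_curve(s, fit_spec("monoexp", weighting = "user_supplied",
                                 sigma = pmax(y, 0.01 * max(y))))
  expect_true(f_rel$converged && f_usr$converged)
  # identical sigma definitions give identical fits
  expect_equal(f_rel$params, f_usr$params, tolerance = 1e-9)
  expect_error(fit_spec("monoexp", weighting = "user_supplied"), "sigma")
})

test_that("monoexp fitted TIA tracks an independent grid-search oracle", {
  set.seed(99)
  sched <- schedules$patientA
  p <- c(A = 100, lam = 0.015)
  n_rep <- 300
  tia_lm <- tia_grid <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    y <- pmax(eval_model("monoexp", p, sched) * (1 + rnorm(4, 0, 0.05)), 0)
    fit <- fit_curve(ta_series("r", sched, y), fit_spec("monoexp"))
    tia_lm[i] <- fit$params[["A"]] / fit$params[["lam"]]
    g <- grid_ls_monoexp(sched, y)
    tia_grid[i] <- g[["A"]] / g[["lam"]]
  }
  expect_equal(median(tia_lm), median(tia_grid), tolerance = 0.005)
})

test_that("diagnostics report fit quality and physiological sanity", {
  sched <- schedules$patientA
  s <- ta_series("r", sched, eval_model("monoexp", c(A = 50, lam = 0.02),
                                        sched),
                 injected_activity = 7210)
  fit <- fit_curve(s, fit_spec("monoexp"))
  d <- fit_diagnostics(fit, s)
  expect_equal(d$r_squared, 1, tolerance = 1e-9)
  expect_false("nonphysiological_t0_activity" %in% d$warnings)
  expect_equal(nrow(d$residual_table), 4L)
  # n = 4, k = 4: corrected AIC undefined
  s4 <- ta_series("r", sched,
                  eval_model("biexp4",
                             c(A1 = 40, A2 = 60, lam1 = 0.01, lam2 = 0.2),
                             sched),
                  injected_activity = 7210)
  f4 <- fit_curve(s4, fit_spec("biexp4"))
  expect_false(f4$aicc_defined)
  expect_true(is.na(f4$aicc))
  # a fit whose back-extrapolated activity at t = 0 exceeds the injection
  s_bad <- ta_series("r", sched,
                     eval_model("monoexp", c(A = 9000, lam = 0.05), sched),
                     injected_activity = 7210)
  d_bad <- fit_diagnostics(fit_curve(s_bad, fit_spec("monoexp")), s_bad)
  expect_true("nonphysiological_t0_activity" %in% d_bad$warnings)
})

test_that("point selectors subset the series as documented", {
  sched <- schedules$patientA
  y <- c(10, 50, 30, 20)
  s <- ta_series("r", sched, y)
  f_l3 <- fit_curve(s, fit_spec("monoexp", points_used = "last3"))
  expect_equal(f_l3$times_used, sched[2:4])
  f_24 <- fit_curve(s, fit_spec("monoexp", points_used = "pts2to4"))
  expect_equal(f_24$times_used, sched[2:4])
  expect_error(fit_curve(ta_series("r", c(1, 5), c(3, 2)),
                         fit_spec("monoexp", points_used = "last3")),
               "last3")
})
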