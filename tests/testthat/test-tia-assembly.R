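sched_A <- patient_schedules()$patientA
catalog <- default_method_catalog()

test_that("trapezoid area matches hand summation", {
  s <- ta_series("r", c(1, 2), c(0, 2))
  expect_equal(trapezoid_area(s, 1, 2), 1.0)
  s2 <- ta_series("r", c(2, 4), c(5, 5))
  expect_equal(trapezoid_area(s2, 2, 4), 10)
  y <- c(12.3, 8.1, 2.4, 1.9)
  s3 <- ta_series("r", sched_A, y)
  hand <- sum(diff(sched_A) * (y[-4] + y[-1]) / 2)
  expect_equal(trapezoid_area(s3, sched_A[1], sched_A[4]), hand)
  # partial segments interpolate linearly
  expect_equal(trapezoid_area(s2, 2.5, 3.5), 5)
  expect_error(trapezoid_area(s3, 0, 10), "limits")
})

test_that("fully model-based TIA reproduces the generating closed form", {
  p <- c(A = 100, lam = 0.012)
  s <- ta_series("r", sched_A, eval_model("monoexp", p, sched_A))
  res <- compute_tia(s, catalog$mono_constr)
  expect_equal(res$total, 100 / 0.012, tolerance = 1e-6)
  expect_equal(res$i1 + res$i2 + res$i3, res$total, tolerance = 1e-12)
})

test_that("physical-decay tail is the last activity over lambda_physical", {
  lamp <- nuclide_constants()$lam_physical
  y <- c(20, 15, 6, 5)
  s <- ta_series("r", sched_A, y)
  res <- compute_tia(s, catalog$trap_phys)
  expect_equal(res$i3, y[4] / lamp)
  # and the head is the triangle from the origin to the first point
  expect_equal(res$i1, y[1] * sched_A[1] / 2)
})

test_that("constant-head methods follow the I1 reporting convention", {
  y <- c(20, 18, 6, 5)
  s <- ta_series("r", sched_A, y)
  res <- compute_tia(s, catalog$const_trap_phys)
  # reported I1 is the rectangle area only up to the FIRST time point
  expect_equal(res$i1, y[2] * sched_A[1])
  # the remainder of the rectangle (up to t2) is reported under I2
  expect_equal(res$i2,
               y[2] * (sched_A[2] - sched_A[1]) +
                 trapezoid_area(s, sched_A[2], sched_A[4]))
  expect_equal(res$i1 + res$i2 + res$i3, res$total, tolerance = 1e-12)
  # model-body variant excludes the first point from the fit
  res_m <- compute_tia(s, catalog$mono_const_head)
  expect_equal(res_m$fit$times_used, sched_A[2:4])
})

test_that("linear-to-zero tail integrates the terminal triangle", {
  y <- c(20, 15, 6, 5)
  s <- ta_series("r", sched_A, y)
  res <- compute_tia(s, catalog$trap_linzero)
  slope <- (y[4] - y[3]) / (sched_A[4] - sched_A[3])
  expect_equal(res$i3, y[4]^2 / (2 * (-slope)))
  # a non-decaying terminal segment cannot be extrapolated to zero
  s_up <- ta_series("r", sched_A, c(20, 15, 5, 6))
  res_up <- compute_tia(s_up, catalog$trap_linzero)
  expect_true("nondecaying_tail" %in% res_up$qc_flags)
  expect_true(is.na(res_up$total))
})

test_that("interval additivity holds for every catalog method", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_washout_series()$series
    for (m in catalog) {
      res <- compute_tia(s, m)
      if (!is.na(res$total)) {
        expect_equal(res$i1 + res$i2 + res$i3, res$total,
                     tolerance = 1e-12)
        expect_true(all(c(res$i1, res$i2, res$i3) >= 0))
      }
    }
  }
})

test_that("TIA is linear in the activities", {
  set.seed(8)
  s <- random_washout_series()$series
  s_scaled <- ta_series(s$region_id, s$times, 2.5 * s$activities)
  for (mid in c("trap_phys", "trap_linzero", "mono_constr",
                "const_trap_efftail")) {
    r1 <- compute_tia(s, catalog[[mid]])
    r2 <- compute_tia(s_scaled, catalog[[mid]])
    expect_equal(r2$total, 2.5 * r1$total, tolerance = 1e-9)
    expect_equal(r2$i3, 2.5 * r1$i3, tolerance = 1e-9)
  }
})

test_that("physical-decay tails dominate fitted effective tails on washout data", {
  lamp <- nuclide_constants()$lam_physical
  set.seed(21)
  n_kept <- 0
  for (i in 1:60) {
    s <- random_washout_series()$series
    eff <- compute_tia(s, catalog$trap_efftail)
    lam_fit <- eff$fit
    last3 <- fit_curve(s, fit_spec("monoexp", points_used = "last3"))
    if (!last3$converged || last3$params[["lam"]] < lamp) next
    n_kept <- n_kept + 1
    phys <- compute_tia(s, catalog$trap_phys)
    expect_gte(phys$i3, eff$i3)
    expect_gte(phys$total, eff$total)
  }
  expect_gt(n_kept, 40)
})

test_that("model and trapezoid bodies agree closely on matched monoexp data", {
  # trapezoid overshoot on a convex exponential grows with lam * (gap
  # between scans); in the organ washout regime (effective half-life within
  # ~3x of physical) the two routes agree within 2%
  set.seed(31)
  for (i in 1:10) {
    gen <- random_washout_series(noise_sd = 0, lam_mult_range = c(1, 3))
    model_tia <- compute_tia(gen$series, catalog$mono_constr)$total
    trap_tia <- compute_tia(gen$series, catalog$trap_efftail)$total
    expect_equal(trap_tia / model_tia, 1, tolerance = 0.02)
  }
})

test_that("tail fraction check uses a strict 20% threshold", {
  expect_false(tail_fraction_check(fake_tia_result(10, 71, 19)))
  expect_false(tail_fraction_check(fake_tia_result(10, 70, 20)))  # boundary
  expect_true(tail_fraction_check(fake_tia_result(10, 69, 21)))
  expect_true(tail_fraction_check(fake_tia_result(5, 70, 25),
                                  threshold = 0.25) == FALSE)
})

test_that("method construction rejects inconsistent rule combinations", {
  expect_error(tia_method("x", "model_extension", "trapezoid",
                          "physical_decay"), "model body")
  expect_error(tia_method("x", "linear_from_origin", "trapezoid",
                          "model_extension"), "explicit tail")
  expect_error(tia_method("x", "linear_from_origin", "model",
                          "model_extension"), "fit_spec")
})

test_that("contribution report returns one row per method, failures flagged", {
  y <- c(20, 15, 6, 5)
  s <- ta_series("k", sched_A, y)
  tab <- report_interval_contributions(s, catalog)
  expect_equal(nrow(tab), length(catalog))
  expect_equal(tab$method_id, names(catalog))
  single <- report_interval_contributions(s, catalog["trap_phys"])
  expect_equal(nrow(single), 1L)
  res <- compute_tia(s, catalog$trap_phys)
  expect_equal(single$total, res$total)
  # the extrapolated interval carries the largest across-method spread
  spread <- apply(tab[, c("i1", "i2", "i3")], 2,
                  function(v) diff(range(v, na.rm = TRUE)))
  expect_equal(names(which.max(spread)), "i3")
})
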