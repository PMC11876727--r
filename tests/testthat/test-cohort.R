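test_that("region specs enforce the kinetic invariants", {
  lamp <- nuclide_constants()$lam_physical
  expect_error(region_spec("k", "organ_instant_uptake",
                           c(A = 10, lam = 0.5 * lamp)),
               "lam >= lam_physical")
  expect_error(region_spec("l", "lesion",
                           c(A = 10, lam1 = 0.2, lam2 = 0.02)),
               "lam2 >= lam1")
  expect_error(region_spec("l", "lesion",
                           c(A = 10, lam1 = 0.02, lam2 = 0.02)),
               "exceed")
  s <- region_spec("k", "organ_instant_uptake", c(A = 10, lam = 0.01),
                   schedule = "patientB")
  expect_equal(s$schedule, c(3.7, 32.6, 99.6, 193.3))
})

test_that("truth TIA is the closed-form integral of the generating curve", {
  t1 <- make_truth(region_spec("k", "organ_instant_uptake",
                               c(A = 100, lam = 0.01)))
  expect_equal(t1$tia, 10000)
  t2 <- make_truth(region_spec("l", "lesion",
                               c(A = 100, lam1 = 0.02, lam2 = 0.2)))
  expect_equal(t2$tia, 4500)
})

test_that("series sampling is seeded, noise-scaled, and convention-aware", {
  spec <- region_spec("k", "organ_instant_uptake", c(A = 50, lam = 0.012),
                      noise_sd = 0.05, decay_convention = "none")
  s1 <- sample_series(spec, 123)
  s2 <- sample_series(spec, 123)
  s3 <- sample_series(spec, 124)
  expect_identical(s1$activities, s2$activities)
  expect_false(identical(s1$activities, s3$activities))
  expect_equal(s1$times, c(3.7, 27.7, 103.1, 124.0))
  # zero noise lies exactly on the model
  spec0 <- region_spec("k", "organ_instant_uptake", c(A = 50, lam = 0.012),
                       noise_sd = 0)
  expect_equal(sample_series(spec0, 1)$activities,
               eval_model("monoexp", c(A = 50, lam = 0.012), spec0$schedule))
  # injection-corrected emission carries the exp(+lam_physical t) factor
  nc <- nuclide_constants()
  spec_inj <- region_spec("k", "organ_instant_uptake",
                          c(A = 50, lam = 0.012), noise_sd = 0,
                          decay_convention = "corrected_to_injection")
  expect_equal(sample_series(spec_inj, 1)$activities,
               sample_series(spec0, 1)$activities *
                 exp(nc$lam_physical * spec0$schedule))
})

test_that("default region sets encode the intended study conditions", {
  ra <- default_region_set("A")
  rb <- default_region_set("B")
  expect_true(all(vapply(ra, `[[`, "", "decay_convention") ==
                    "corrected_to_injection"))
  expect_true(all(vapply(rb, `[[`, "", "decay_convention") ==
                    "corrected_to_scan_start"))
  # patient A liver lesions carry ~48% of whole-liver TIA (-> ~93%
  # healthy-liver inflation); patient B lesions ~6% inflation
  tia_of <- function(set, reg) make_truth(set[[reg]])$tia
  infl_A <- (tia_of(ra, "lesion1") + tia_of(ra, "lesion2")) /
    tia_of(ra, "liver")
  expect_equal(infl_A, 0.934, tolerance = 0.01)
  infl_B <- (tia_of(rb, "lesion1") + tia_of(rb, "lesion2")) /
    tia_of(rb, "liver")
  expect_equal(infl_B, 0.06, tolerance = 0.005)
  # patient B kidneys have an uptake phase
  expect_equal(rb$kidney_left$model_family, "biexp3")
})

test_that("cohorts are pure functions of configuration and seed", {
  regions <- default_region_set("A", noise_sd = 0.05)
  cfg <- cohort_config(n_participants = 6, seed = 42)
  sim1 <- simulate_cohort(regions, cfg)
  sim2 <- simulate_cohort(regions, cfg)
  expect_identical(sim1$cohort, sim2$cohort)
  expect_identical(sim1$participants, sim2$participants)
  sim3 <- simulate_cohort(regions, cohort_config(n_participants = 6,
                                                 seed = 43))
  expect_false(identical(sim1$cohort$ad, sim3$cohort$ad))
})

test_that("noiseless matched-model pipeline recovers truth exactly", {
  regions <- default_region_set("A", noise_sd = 0)
  catalog <- default_method_catalog()
  cfg <- cohort_config(n_participants = 3,
                       method_freq = c(mono_constr = 1), seed = 1)
  sim <- simulate_cohort(regions, cfg, catalog)
  t4 <- sim$cohort[sim$cohort$task == "task4", ]
  for (reg in c("kidney_left", "kidney_right", "spleen", "liver")) {
    truth_ad <- sim$truth$ad_reference[sim$truth$region == reg]
    expect_equal(t4$ad[t4$region == reg], rep(truth_ad, 3),
                 tolerance = 1e-6)
  }
})

test_that("error modes move doses in the documented directions", {
  regions <- default_region_set("A", noise_sd = 0)
  catalog <- default_method_catalog()
  base_cfg <- function(...) cohort_config(
    n_participants = 2, method_freq = c(mono_constr = 1),
    error_rates = list(...), seed = 5)
  clean <- simulate_cohort(regions, base_cfg())
  ad_of <- function(sim, reg)
    sim$cohort$ad[sim$cohort$task == "task4" & sim$cohort$region == reg][1]

  # skipped decay un-correction inflates every activity and hence the dose
  skip <- simulate_cohort(regions, base_cfg(skip_decay_uncorrection = 1))
  for (reg in unique(clean$cohort$region))
    expect_gt(ad_of(skip, reg), ad_of(clean, reg))

  # lesions wrongly left inside the liver VOI inflate the liver dose only
  les <- simulate_cohort(regions, base_cfg(include_lesions_in_liver = 1))
  expect_gt(ad_of(les, "liver"), ad_of(clean, "liver"))
  expect_equal(ad_of(les, "kidney_left"), ad_of(clean, "kidney_left"))
  # on the shared reference TIA (task 5) the inflation is exactly the
  # designed ~93% lesion share of the whole-liver TIA
  ad5_of <- function(sim, reg)
    sim$cohort$ad[sim$cohort$task == "task5" & sim$cohort$region == reg][1]
  expect_equal(ad5_of(les, "liver") / ad5_of(clean, "liver") - 1, 0.934,
               tolerance = 0.01)

  # unweighted kidney summation exceeds the mass-weighted average
  sk <- simulate_cohort(regions, base_cfg(sum_kidneys_unweighted = 1))
  expect_gt(ad_of(sk, "kidney_total"), ad_of(clean, "kidney_total"))
  expect_equal(ad_of(sk, "kidney_total"),
               ad_of(sk, "kidney_left") + ad_of(sk, "kidney_right"))
})

test_that("mismatched monoexp fits biexponential lesions with larger bias", {
  regions <- default_region_set("A", noise_sd = 0.05)["lesion1"]
  catalog <- default_method_catalog()[c("mono_constr", "biexp3_model")]
  rec <- recovery_suite(regions, catalog, n_rep = 60, seed = 9)
  s <- rec$summary
  bias_mono <- abs(s$median_rel_err[s$method_id == "mono_constr"])
  bias_bi <- abs(s$median_rel_err[s$method_id == "biexp3_model"])
  expect_gt(bias_mono, bias_bi)
})
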