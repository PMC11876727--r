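## Synthetic ground-truth kinetics and virtual multi-participant cohorts.
##
## Ground truth is a continuous model curve per region (so the exact TIA is
## known in closed form); sampling emulates 4-time-point SPECT quantification
## with multiplicative Gaussian noise; a virtual cohort sends every
## participant through fit -> TIA -> dose with a method drawn from a
## frequency table and independently drawn analysis errors (skipped decay
## un-correction, lesions left inside the healthy liver, unweighted kidney
## summation).  A cohort is a pure function of (configuration, seed).

REGION_CLASSES <- c("organ_instant_uptake", "organ_slow_uptake", "lesion")

#' Region kinetics specification
#'
#' Ground-truth kinetics for one region.  Instant-uptake organs follow a
#' monoexponential washout; slow-uptake organs and lesions follow the
#' zero-at-origin biexponential (uptake phase, then washout).
#'
#' @param region region label
#' @param class one of `"organ_instant_uptake"`, `"organ_slow_uptake"`,
#'   `"lesion"`
#' @param params true model parameters (`A`, `lam` for instant uptake;
#'   `A`, `lam1`, `lam2` otherwise, with `lam2 > lam1 >= lam_physical`)
#' @param schedule `"patientA"`, `"patientB"`, or a numeric vector of
#'   imaging times (hours)
#' @param noise_sd multiplicative Gaussian noise standard deviation
#'   (fraction of the true activity; default 0.05)
#' @param decay_convention convention the emitted series is expressed in
#' @param lesion_of for lesions contained in an organ, that organ's region
#'   label (drives the lesion-in-liver error mode); `NA` otherwise
#' @param constants a [nuclide_constants()] (for invariant checks)
#' @return object of class `region_spec`
#' @export
region_spec <- function(region, class, params, schedule = "patientA",
                        noise_sd = 0.05, decay_convention = "none",
                        lesion_of = NA_character_,
                        constants = nuclide_constants()) {
  class <- match.arg(class, REGION_CLASSES)
  family <- if (class == "organ_instant_uptake") "monoexp" else "biexp3"
  params <- .check_params(family, params)
  lamp <- constants$lam_physical
  if (family == "monoexp" && params[["lam"]] < lamp)
    stop("instant-uptake organ washout must satisfy lam >= lam_physical")
  if (family == "biexp3") {
    if (params[["lam1"]] < lamp)
      stop("washout rate lam1 must be >= lam_physical")
    if (params[["lam2"]] <= params[["lam1"]])
      stop("uptake rate lam2 must exceed washout rate lam1")
  }
  if (is.character(schedule)) {
    schedule <- patient_schedules()[[match.arg(schedule,
                                               names(patient_schedules()))]]
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(
    list(region = region, class = class, model_family = family,
         params = params, schedule = as.numeric(schedule),
         noise_sd = noise_sd,
         decay_convention = match.arg(decay_convention, DECAY_CONVENTIONS),
         lesion_of = lesion_of),
    class = "region_spec")
}

#' Ground truth for a region
#'
#' Returns the generating parameters together with the exact TIA (the
#' closed-form integral of the true curve over `[0, Inf)`).
#'
#' @param spec a [region_spec()]
#' @return list with `spec`, `params`, `tia`
#' @export
make_truth <- function(spec) {
  stopifnot(inherits(spec, "region_spec"))
  list(spec = spec, params = spec$params,
       tia = integral_closed_form(spec$model_family, spec$params, 0, Inf))
}

# draw one noisy series using the CURRENT RNG state (stream-style, so a
# cohort is reproducible from a single seed)
.sample_series_stream <- function(spec, constants) {
  t <- spec$schedule
  true_act <- eval_model(spec$model_family, spec$params, t)
  eps <- stats::rnorm(length(t), 0, spec$noise_sd)
  act <- pmax(true_act * (1 + eps), 0)
  if (spec$decay_convention == "corrected_to_injection")
    act <- act * exp(constants$lam_physical * t)
  ta_series(spec$region, t, act, spec$decay_convention)
}

#' Sample a noisy time-activity series from a region's truth
#'
#' Activities are `model(t_i) * (1 + eps_i)` with
#' `eps_i ~ N(0, noise_sd^2)`, truncated so activities stay non-negative,
#' then expressed in the spec's decay-correction convention.
#'
#' @param spec a [region_spec()]
#' @param seed integer seed (the draw is a pure function of spec and seed)
#' @param constants a [nuclide_constants()]
#' @return a [ta_series()]
#' @export
sample_series <- function(spec, seed, constants = nuclide_constants()) {
  stopifnot(inherits(spec, "region_spec"))
  set.seed(seed)
  .sample_series_stream(spec, constants)
}

#' Default synthetic region sets for the two virtual patients
#'
#' Patient A: instant-uptake kidneys, spleen and healthy liver
#' (monoexponential), plus two liver-contained lesions sized so that the
#' lesions carry roughly 48% of the whole-liver TIA; series emitted
#' decay-corrected to the injection time.  Patient B: slow-uptake kidneys
#' (biexponential), healthy liver with two small contained lesions (about
#' 6% of whole-liver TIA), and two further lesions; series emitted
#' corrected to the scan start.  All washout rate constants exceed the
#' physical decay constant of Lu-177, so effective half-lives are shorter
#' than the physical half-life.
#'
#' @param patient `"A"` or `"B"`
#' @param noise_sd multiplicative noise level applied to every region
#' @param constants a [nuclide_constants()]
#' @return named list of [region_spec()]
#' @export
default_region_set <- function(patient = c("A", "B"), noise_sd = 0.05,
                               constants = nuclide_constants()) {
  patient <- match.arg(patient)
  if (patient == "A") {
    conv <- "corrected_to_injection"
    sched <- "patientA"
    specs <- list(
      region_spec("kidney_left", "organ_instant_uptake",
                  c(A = 18, lam = 0.0139), sched, noise_sd, conv,
                  constants = constants),
      region_spec("kidney_right", "organ_instant_uptake",
                  c(A = 16, lam = 0.0145), sched, noise_sd, conv,
                  constants = constants),
      region_spec("spleen", "organ_instant_uptake",
                  c(A = 15, lam = 0.010), sched, noise_sd, conv,
                  constants = constants),
      region_spec("liver", "organ_instant_uptake",
                  c(A = 40, lam = 0.009), sched, noise_sd, conv,
                  constants = constants),
      region_spec("lesion1", "lesion",
                  c(A = 46.1, lam1 = 0.020, lam2 = 0.20), sched, noise_sd,
                  conv, lesion_of = "liver", constants = constants),
      region_spec("lesion2", "lesion",
                  c(A = 65.6, lam1 = 0.025, lam2 = 0.12), sched, noise_sd,
                  conv, lesion_of = "liver", constants = constants))
  } else {
    conv <- "corrected_to_scan_start"
    sched <- "patientB"
    specs <- list(
      region_spec("kidney_left", "organ_slow_uptake",
                  c(A = 22, lam1 = 0.012, lam2 = 0.35), sched, noise_sd,
                  conv, constants = constants),
      region_spec("kidney_right", "organ_slow_uptake",
                  c(A = 20, lam1 = 0.0125, lam2 = 0.30), sched, noise_sd,
                  conv, constants = constants),
      region_spec("liver", "organ_instant_uptake",
                  c(A = 45, lam = 0.0095), sched, noise_sd, conv,
                  constants = constants),
      region_spec("lesion1", "lesion",
                  c(A = 3.16, lam1 = 0.020, lam2 = 0.20), sched, noise_sd,
                  conv, lesion_of = "liver", constants = constants),
      region_spec("lesion2", "lesion",
                  c(A = 4.49, lam1 = 0.025, lam2 = 0.12), sched, noise_sd,
                  conv, lesion_of = "liver", constants = constants),
      region_spec("lesion3", "lesion",
                  c(A = 30, lam1 = 0.018, lam2 = 0.15), sched, noise_sd,
                  conv, constants = constants),
      region_spec("lesion4", "lesion",
                  c(A = 12, lam1 = 0.030, lam2 = 0.25), sched, noise_sd,
                  conv, constants = constants))
  }
  stats::setNames(specs, vapply(specs, `[[`, "", "region"))
}

#' Cohort configuration
#'
#' @param n_participants number of virtual participants
#' @param method_freq named probability vector over catalog method ids
#'   (default: uniform over the catalog in use); must sum to 1
#' @param error_rates named list of per-participant error probabilities:
#'   `skip_decay_uncorrection`, `include_lesions_in_liver`,
#'   `sum_kidneys_unweighted` (all default 0)
#' @param software_mix named probability vector over
#'   `c("in_house", "commercial")`
#' @param seed integer seed; the cohort is a pure function of (config, seed)
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_participants = 24,
                          method_freq = NULL,
                          error_rates = list(),
                          software_mix = c(in_house = 0.5, commercial = 0.5),
                          seed = 1L) {
  defaults <- list(skip_decay_uncorrection = 0,
                   include_lesions_in_liver = 0,
                   sum_kidneys_unweighted = 0)
  unknown <- setdiff(names(error_rates), names(defaults))
  if (length(unknown))
    stop("unknown error modes: ", paste(unknown, collapse = ", "))
  defaults[names(error_rates)] <- error_rates
  if (any(unlist(defaults) < 0 | unlist(defaults) > 1))
    stop("error rates must lie in [0, 1]")
  if (!is.null(method_freq)) {
    if (abs(sum(method_freq) - 1) > 1e-8)
      stop("method frequencies must sum to 1")
  }
  if (abs(sum(software_mix) - 1) > 1e-8)
    stop("software mix must sum to 1")
  structure(
    list(n_participants = as.integer(n_participants),
         method_freq = method_freq, error_rates = defaults,
         software_mix = software_mix, seed = as.integer(seed)),
    class = "cohort_config")
}

# one participant's task-4 pipeline on one region series
.participant_tia <- function(series, method, skip_decay, constants) {
  if (!skip_decay) {
    series <- apply_decay_correction(series, "none", constants)
  } else {
    # the participant (wrongly) treats the reported values as activities
    # present at scan time
    series <- ta_series(series$region_id, series$times, series$activities,
                        "none", series$injected_activity)
  }
  compute_tia(series, method, constants)$total
}

#' Simulate a virtual dosimetry-challenge cohort
#'
#' Each virtual participant draws a fitting/integration method from the
#' frequency distribution and, independently, a set of analysis errors,
#' then produces per-region absorbed doses two ways: task 4 (their own
#' fit -> TIA -> dose on their own noisy measurement of the shared images)
#' and task 5 (a shared reference TIA per region -- the ground truth --
#' pushed through their dose-conversion step).  A combined `kidney_total`
#' region is derived from the two kidneys: mass-weighted average normally,
#' plain summation when the `sum_kidneys_unweighted` error is drawn.
#'
#' @param regions named list of [region_spec()] (one schedule per cohort)
#' @param config a [cohort_config()]
#' @param catalog method catalog (default [default_method_catalog()])
#' @param dose_table a [dose_factor_table()] covering every region (and
#'   `kidney_total` when both kidneys are present)
#' @param constants a [nuclide_constants()]
#' @return list with `cohort` (data.frame: `participant_id`, `task`,
#'   `region`, `ad`, `method_id`, `software_class`), `truth` (per-region
#'   true TIA and reference AD), and `participants` (drawn methods and
#'   error modes per participant)
#' @export
simulate_cohort <- function(regions, config,
                            catalog = default_method_catalog(),
                            dose_table = default_dose_factors(),
                            constants = nuclide_constants()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  freq <- config$method_freq
  if (is.null(freq))
    freq <- stats::setNames(rep(1 / length(catalog), length(catalog)),
                            names(catalog))
  if (!all(names(freq) %in% names(catalog)))
    stop("method_freq names must match the catalog")

  truths <- lapply(regions, make_truth)
  region_names <- names(regions)
  have_kidneys <- all(c("kidney_left", "kidney_right") %in% region_names)
  err <- config$error_rates

  # participant-level draws
  pid <- sprintf("P%02d", seq_len(config$n_participants))
  method_of <- sample(names(freq), config$n_participants, replace = TRUE,
                      prob = freq)
  software_of <- sample(names(config$software_mix), config$n_participants,
                        replace = TRUE, prob = config$software_mix)
  e_decay <- stats::runif(config$n_participants) < err$skip_decay_uncorrection
  e_lesion <- stats::runif(config$n_participants) <
    err$include_lesions_in_liver
  e_kidney <- stats::runif(config$n_participants) <
    err$sum_kidneys_unweighted

  rows <- list()
  add_row <- function(p, task, region, ad, method_id, software) {
    rows[[length(rows) + 1L]] <<- data.frame(
      participant_id = p, task = task, region = region, ad = ad,
      method_id = method_id, software_class = software,
      stringsAsFactors = FALSE)
  }

  masses <- stats::setNames(dose_table$mass_g, dose_table$region)
  lesion_regions <- region_names[!is.na(
    vapply(regions, `[[`, "", "lesion_of"))]

  for (i in seq_len(config$n_participants)) {
    method <- catalog[[method_of[i]]]
    tias <- numeric(0)
    for (reg in region_names) {
      series <- .sample_series_stream(regions[[reg]], constants)
      tias[reg] <- .participant_tia(series, method, e_decay[i], constants)
    }
    # lesion-in-liver error: the participant's liver VOI swallowed the lesions
    liver_lesions <- lesion_regions[
      vapply(regions[lesion_regions], `[[`, "", "lesion_of") == "liver"]
    tia4 <- tias
    if (e_lesion[i] && "liver" %in% region_names &&
        length(liver_lesions)) {
      tia4["liver"] <- tia4["liver"] + sum(tia4[liver_lesions])
    }
    ad4 <- vapply(region_names, function(reg)
      tia_to_ad(tia4[[reg]], reg, dose_table), numeric(1))
    # task 5: shared reference TIA through the participant's dose step
    tia5 <- vapply(truths, `[[`, numeric(1), "tia")
    if (e_lesion[i] && "liver" %in% region_names &&
        length(liver_lesions)) {
      tia5["liver"] <- tia5["liver"] + sum(tia5[liver_lesions])
    }
    ad5 <- vapply(region_names, function(reg)
      tia_to_ad(tia5[[reg]], reg, dose_table), numeric(1))

    for (reg in region_names) {
      # an infeasible method/series combination (e.g. a noise-inverted
      # terminal segment under a line-to-zero tail) yields no task-4
      # submission for that region; task 5 does not involve the fit
      if (!is.na(ad4[[reg]]))
        add_row(pid[i], "task4", reg, ad4[[reg]], method_of[i],
                software_of[i])
      add_row(pid[i], "task5", reg, ad5[[reg]], "reference", software_of[i])
    }
    if (have_kidneys) {
      comb <- function(l, r) {
        if (e_kidney[i]) l + r
        else combine_kidneys(l, masses[["kidney_left"]],
                             r, masses[["kidney_right"]])
      }
      if (!is.na(ad4[["kidney_left"]]) && !is.na(ad4[["kidney_right"]]))
        add_row(pid[i], "task4", "kidney_total",
                comb(ad4[["kidney_left"]], ad4[["kidney_right"]]),
                method_of[i], software_of[i])
      add_row(pid[i], "task5", "kidney_total",
              comb(ad5[["kidney_left"]], ad5[["kidney_right"]]),
              "reference", software_of[i])
    }
  }

  truth_df <- data.frame(
    region = region_names,
    model_family = vapply(regions, `[[`, "", "model_family"),
    tia_truth = vapply(truths, `[[`, numeric(1), "tia"),
    ad_reference = vapply(region_names, function(reg)
      tia_to_ad(truths[[reg]]$tia, reg, dose_table), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(truth_df) <- NULL

  list(
    cohort = do.call(rbind, rows),
    truth = truth_df,
    participants = data.frame(
      participant_id = pid, method_id = method_of,
      software_class = software_of,
      skip_decay_uncorrection = e_decay,
      include_lesions_in_liver = e_lesion,
      sum_kidneys_unweighted = e_kidney,
      stringsAsFactors = FALSE))
}

#' TIA recovery study across regions and methods
#'
#' Repeatedly samples noisy series from each region's truth, runs each
#' catalog method, and summarizes the relative TIA error against the exact
#' closed-form truth: the harness behind bias/spread comparisons such as
#' matched vs mismatched model families.
#'
#' @param regions named list of [region_spec()]
#' @param catalog list of [tia_method()]
#' @param n_rep replicates per region x method
#' @param seed integer seed
#' @param constants a [nuclide_constants()]
#' @return list with `detail` (one row per replicate) and `summary`
#'   (median/mean/sd of relative error per region x method)
#' @export
recovery_suite <- function(regions, catalog, n_rep = 100, seed = 1L,
                           constants = nuclide_constants()) {
  set.seed(seed)
  detail <- list()
  for (reg in names(regions)) {
    truth <- make_truth(regions[[reg]])
    for (mid in names(catalog)) {
      for (r in seq_len(n_rep)) {
        series <- .sample_series_stream(regions[[reg]], constants)
        series <- apply_decay_correction(series, "none", constants)
        tia <- tryCatch(compute_tia(series, catalog[[mid]], constants)$total,
                        error = function(e) NA_real_)
        detail[[length(detail) + 1L]] <- data.frame(
          region = reg, method_id = mid, rep = r, tia = tia,
          tia_truth = truth$tia, rel_err = (tia - truth$tia) / truth$tia,
          stringsAsFactors = FALSE)
      }
    }
  }
  detail <- do.call(rbind, detail)
  agg <- do.call(rbind, lapply(
    split(detail, list(detail$region, detail$method_id), drop = TRUE),
    function(d) data.frame(
      region = d$region[1L], method_id = d$method_id[1L],
      n = sum(!is.na(d$rel_err)),
      median_rel_err = stats::median(d$rel_err, na.rm = TRUE),
      mean_rel_err = mean(d$rel_err, na.rm = TRUE),
      sd_rel_err = stats::sd(d$rel_err, na.rm = TRUE),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  list(detail = detail, summary = agg)
}
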