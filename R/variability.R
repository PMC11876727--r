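## Robust variability statistics for multi-center dose comparisons: the
## quartile coefficient of dispersion (QCD), interquartile-range outlier
## fences, and the paired task-4/task-5 analysis that isolates the fitting
## step's contribution to absorbed-dose spread.

#' Quartiles
#'
#' First quartile, median, and third quartile under a configurable quantile
#' convention (passed to [stats::quantile()]; the default, type 7, is
#' linear interpolation between order statistics).
#'
#' @param values numeric vector, `n >= 1`
#' @param type quantile convention, 1-9 (default 7)
#' @return named numeric vector `c(q1, median, q3)`
#' @examples
#' quartiles(c(1, 2, 3, 4))  # q1 = 1.75, median = 2.5, q3 = 3.25
#' @export
quartiles <- function(values, type = 7) {
  if (length(values) == 0L) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  c(q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1)`: a robust relative-spread measure, preferred
#' over the coefficient of variation when outliers are expected.  It is
#' invariant under positive rescaling and lies in `[0, 1]` for positive
#' data.
#'
#' @inheritParams quartiles
#' @return dimensionless QCD (fraction, not percent)
#' @examples
#' qcd(c(1, 2, 3, 4))  # 0.30
#' @export
qcd <- function(values, type = 7) {
  q <- quartiles(values, type = type)
  s <- q[["q3"]] + q[["q1"]]
  if (s == 0) stop("QCD undefined: Q1 + Q3 == 0")
  (q[["q3"]] - q[["q1"]]) / s
}

#' IQR outlier fences
#'
#' Flags values lying strictly outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#' Values exactly on a fence are not outliers.
#'
#' @inheritParams quartiles
#' @return list with `iqr`, `lower`, `upper`, `outlier` (logical vector),
#'   `n_outliers`, `outlier_fraction`
#' @export
iqr_outliers <- function(values, type = 7) {
  q <- quartiles(values, type = type)
  iqr <- q[["q3"]] - q[["q1"]]
  lower <- q[["q1"]] - 1.5 * iqr
  upper <- q[["q3"]] + 1.5 * iqr
  out <- values < lower | values > upper
  list(iqr = iqr, lower = lower, upper = upper, outlier = out,
       n_outliers = sum(out), outlier_fraction = mean(out))
}

#' Variability report for one set of values
#'
#' One-row summary combining quartiles, QCD, IQR, and outlier flags.
#'
#' @inheritParams quartiles
#' @param region region label for the report row
#' @param ids optional identifiers parallel to `values`, used to name
#'   outliers
#' @return one-row data.frame: `region`, `n`, `median`, `q1`, `q3`, `qcd`,
#'   `qcd_pct`, `iqr`, `n_outliers`, `outlier_fraction`, `outlier_ids`
#' @export
variability_report <- function(values, region = "all", ids = NULL,
                               type = 7) {
  q <- quartiles(values, type = type)
  fl <- iqr_outliers(values, type = type)
  qcd_val <- if (q[["q3"]] + q[["q1"]] != 0) qcd(values, type) else NA_real_
  out_ids <- if (is.null(ids)) which(fl$outlier) else ids[fl$outlier]
  data.frame(
    region = region, n = length(values),
    median = q[["median"]], q1 = q[["q1"]], q3 = q[["q3"]],
    qcd = qcd_val, qcd_pct = round(100 * qcd_val, 1),
    iqr = fl$iqr, n_outliers = fl$n_outliers,
    outlier_fraction = fl$outlier_fraction,
    outlier_ids = paste(out_ids, collapse = ";"),
    stringsAsFactors = FALSE)
}

.check_cohort <- function(cohort) {
  need <- c("participant_id", "task", "region", "ad")
  missing <- setdiff(need, names(cohort))
  if (length(missing))
    stop("cohort table missing columns: ", paste(missing, collapse = ", "))
  if (!all(cohort$task %in% c("task4", "task5")))
    stop("'task' must be 'task4' or 'task5'")
  key <- paste(cohort$participant_id, cohort$task, cohort$region)
  if (anyDuplicated(key))
    stop("cohort has duplicate (participant, task, region) entries")
  cohort
}

#' Paired task-4 vs task-5 dose comparison
#'
#' For each region, restricts to participants present in BOTH tasks and
#' computes each participant's normalized dose difference
#' `(AD_task4 - AD_task5) / mean(AD_task5)`, where the normalizing mean is
#' taken over ALL included participants' task-5 doses for that region (not
#' the participant's own).  Task 5 shares a single reference TIA across
#' participants, so this difference isolates what the participant's own
#' fitting and integration added.  Outliers are flagged with 1.5 x IQR
#' fences and labeled with method and software class when available.
#'
#' @param cohort data.frame with columns `participant_id`, `task`
#'   (`"task4"`/`"task5"`), `region`, `ad`, and optionally `method_id`,
#'   `software_class`
#' @param type quantile convention
#' @return list with `deltas` (per participant x region) and `report` (per
#'   region: n paired, median, IQR, outlier labels); regions with fewer
#'   than 2 paired participants appear in `skipped`
#' @export
paired_delta_analysis <- function(cohort, type = 7) {
  cohort <- .check_cohort(cohort)
  deltas <- NULL
  reports <- NULL
  skipped <- character()
  for (reg in unique(cohort$region)) {
    sub <- cohort[cohort$region == reg, , drop = FALSE]
    t4 <- sub[sub$task == "task4", , drop = FALSE]
    t5 <- sub[sub$task == "task5", , drop = FALSE]
    paired <- intersect(t4$participant_id, t5$participant_id)
    if (length(paired) < 2L) {
      skipped <- c(skipped, reg)
      next
    }
    t4 <- t4[match(paired, t4$participant_id), , drop = FALSE]
    t5 <- t5[match(paired, t5$participant_id), , drop = FALSE]
    mean_t5 <- mean(t5$ad)
    delta <- (t4$ad - t5$ad) / mean_t5
    fl <- iqr_outliers(delta, type = type)
    d <- data.frame(
      region = reg, participant_id = paired, delta = delta,
      method_id = if ("method_id" %in% names(t4)) t4$method_id else NA,
      software_class = if ("software_class" %in% names(t4))
        t4$software_class else NA,
      outlier = fl$outlier, stringsAsFactors = FALSE)
    deltas <- rbind(deltas, d)
    rep_row <- variability_report(delta, region = reg, ids = paired,
                                  type = type)
    rep_row$outlier_methods <- paste(unique(d$method_id[d$outlier]),
                                     collapse = ";")
    rep_row$outlier_software <- paste(unique(d$software_class[d$outlier]),
                                      collapse = ";")
    reports <- rbind(reports, rep_row)
  }
  rownames(deltas) <- rownames(reports) <- NULL
  list(deltas = deltas, report = reports, skipped = skipped)
}

#' Per-region QCD difference between tasks
#'
#' `QCD(task 4) - QCD(task 5)` for each region: the spread added by
#' participant-performed fitting and integration on top of the shared-TIA
#' task.  Reported both as a fraction and in percentage points.
#'
#' @inheritParams paired_delta_analysis
#' @param paired_only restrict both tasks to participants present in both
#'   (default `TRUE`, matching the paired analysis)
#' @return data.frame: `region`, `n`, `qcd_task4`, `qcd_task5`, `qcd_diff`,
#'   `qcd_diff_pct_points`
#' @export
qcd_difference <- function(cohort, type = 7, paired_only = TRUE) {
  cohort <- .check_cohort(cohort)
  rows <- lapply(unique(cohort$region), function(reg) {
    sub <- cohort[cohort$region == reg, , drop = FALSE]
    t4 <- sub[sub$task == "task4", , drop = FALSE]
    t5 <- sub[sub$task == "task5", , drop = FALSE]
    if (paired_only) {
      paired <- intersect(t4$participant_id, t5$participant_id)
      t4 <- t4[t4$participant_id %in% paired, , drop = FALSE]
      t5 <- t5[t5$participant_id %in% paired, , drop = FALSE]
    }
    if (nrow(t4) == 0L || nrow(t5) == 0L)
      stop("region '", reg, "' missing one of the tasks")
    q4 <- qcd(t4$ad, type); q5 <- qcd(t5$ad, type)
    data.frame(region = reg, n = nrow(t4), qcd_task4 = q4, qcd_task5 = q5,
               qcd_diff = q4 - q5,
               qcd_diff_pct_points = round(100 * (q4 - q5), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
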