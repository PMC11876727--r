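## TimeActivitySeries: one region's sampled time-activity data.

DECAY_CONVENTIONS <- c("corrected_to_injection", "corrected_to_scan_start",
                       "none")

#' Time-activity series for one region
#'
#' Container for one region's sampled activities at the imaging time points,
#' together with the decay-correction convention the activities are
#' expressed in.
#'
#' @param region_id character label for the region (e.g. `"kidney_left"`)
#' @param times imaging times in hours post-injection; strictly increasing,
#'   all > 0; at least 2 points
#' @param activities measured activities in MBq, same length as `times`,
#'   all >= 0
#' @param decay_convention one of `"corrected_to_injection"`,
#'   `"corrected_to_scan_start"`, `"none"`.  `"none"` means the activity
#'   actually present at each imaging time; `"corrected_to_injection"` means
#'   each value has been scaled by `exp(+lam_physical * t)` back to the
#'   injection time.
#' @param injected_activity optionally, the injected activity (MBq), used by
#'   physiological sanity checks on fits
#' @return object of class `ta_series`
#' @examples
#' ta_series("kidney_left", c(3.7, 27.7, 103.1, 124.0),
#'           c(18.1, 13.2, 4.9, 3.8))
#' @export
ta_series <- function(region_id, times, activities,
                      decay_convention = "none",
                      injected_activity = NA_real_) {
  if (!is.character(region_id) || length(region_id) != 1L || !nzchar(region_id))
    stop("'region_id' must be a non-empty string")
  if (length(times) != length(activities))
    stop(sprintf("region '%s': times and activities differ in length",
                 region_id))
  if (length(times) < 2L)
    stop(sprintf("region '%s': at least 2 time points required", region_id))
  if (any(!is.finite(times)) || any(times <= 0))
    stop(sprintf("region '%s': times must be finite and > 0", region_id))
  if (any(diff(times) <= 0))
    stop(sprintf("region '%s': times must be strictly increasing", region_id))
  if (any(!is.finite(activities)) || any(activities < 0))
    stop(sprintf("region '%s': activities must be finite and >= 0", region_id))
  decay_convention <- match.arg(decay_convention, DECAY_CONVENTIONS)
  structure(
    list(region_id = region_id,
         times = as.numeric(times),
         activities = as.numeric(activities),
         decay_convention = decay_convention,
         injected_activity = as.numeric(injected_activity)),
    class = "ta_series"
  )
}

#' @export
print.ta_series <- function(x, ...) {
  cat(sprintf("Time-activity series '%s' (%d points, convention: %s)\n",
              x$region_id, length(x$times), x$decay_convention))
  print(data.frame(time_h = x$times, activity_MBq = x$activities),
        row.names = FALSE)
  invisible(x)
}

#' Imaging schedules of the two challenge patients
#'
#' Four-time-point SPECT imaging schedules (hours post-injection): patient A
#' at 3.7, 27.7, 103.1 and 124.0 h; patient B at 3.7, 32.6, 99.6 and
#' 193.3 h.
#'
#' @return named list of numeric vectors `patientA` and `patientB`
#' @export
patient_schedules <- function() {
  list(patientA = c(3.7, 27.7, 103.1, 124.0),
       patientB = c(3.7, 32.6, 99.6, 193.3))
}
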