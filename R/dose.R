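## Organ-level conversion of TIA to absorbed dose via self-dose factors,
## plus the decay-correction and kidney-combination handling whose misuse
## drives much of the between-center dose spread.

#' Dose-factor table
#'
#' Region-wise self-dose factors (Gy per MBq.h) and masses.  The shipped
#' default (`inst/extdata/dose_factors_synthetic.csv`) carries synthetic
#' placeholder factors for the standard region set; real analyses should
#' substitute factors from their dosimetry software of choice.
#'
#' @param region character vector of region labels
#' @param factor_Gy_per_MBq_h self-dose factor per region (> 0)
#' @param mass_g region mass in grams (> 0)
#' @param reference_mass_g optional reference (phantom) mass per region,
#'   used when mass scaling is requested; defaults to `mass_g`
#' @return data.frame of class `dose_factor_table`
#' @export
dose_factor_table <- function(region, factor_Gy_per_MBq_h, mass_g,
                              reference_mass_g = mass_g) {
  if (any(factor_Gy_per_MBq_h <= 0)) stop("dose factors must be > 0")
  if (any(mass_g <= 0) || any(reference_mass_g <= 0))
    stop("masses must be > 0")
  if (anyDuplicated(region)) stop("duplicated region in dose-factor table")
  out <- data.frame(region = as.character(region),
                    factor_Gy_per_MBq_h = factor_Gy_per_MBq_h,
                    mass_g = mass_g,
                    reference_mass_g = reference_mass_g,
                    stringsAsFactors = FALSE)
  class(out) <- c("dose_factor_table", "data.frame")
  out
}

#' Read / write a dose-factor CSV
#'
#' Columns: `region`, `factor_Gy_per_MBq_h`, `mass_g`,
#' `reference_mass_g` (optional).
#'
#' @param path file path
#' @return a [dose_factor_table()]
#' @export
read_dose_factors_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "factor_Gy_per_MBq_h", "mass_g")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("dose-factor CSV missing columns: ", paste(missing, collapse = ", "))
  if (!"reference_mass_g" %in% names(df)) df$reference_mass_g <- df$mass_g
  dose_factor_table(df$region, df$factor_Gy_per_MBq_h, df$mass_g,
                    df$reference_mass_g)
}

#' @rdname read_dose_factors_csv
#' @param table a [dose_factor_table()]
#' @export
write_dose_factors_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Default synthetic dose-factor table
#'
#' The placeholder self-dose factors shipped with the package (synthetic
#' values of realistic magnitude, not from any phantom library).
#'
#' @return a [dose_factor_table()]
#' @export
default_dose_factors <- function() {
  read_dose_factors_csv(system.file("extdata", "dose_factors_synthetic.csv",
                                    package = "tiadose", mustWork = TRUE))
}

#' Convert TIA to absorbed dose
#'
#' Organ-level self-dose conversion: `AD = TIA x S`, with the self-dose
#' factor optionally rescaled by `reference_mass / mass` (the standard
#' inverse-mass approximation for adapting a phantom factor to a
#' patient-specific mass).
#'
#' @param tia time-integrated activity (MBq.h, >= 0)
#' @param region region label present in `table`
#' @param table a [dose_factor_table()]
#' @param mass_scaling apply the inverse-mass rescaling? (default `FALSE`)
#' @return absorbed dose (Gy)
#' @export
tia_to_ad <- function(tia, region, table, mass_scaling = FALSE) {
  i <- match(region, table$region)
  if (is.na(i)) stop("region not in dose-factor table: ", region)
  scale <- if (mass_scaling) table$reference_mass_g[i] / table$mass_g[i] else 1
  tia * table$factor_Gy_per_MBq_h[i] * scale
}

#' Mass-weighted combination of the two kidney doses
#'
#' The correct way to report a single "total kidney" absorbed dose from
#' separately computed left and right kidney doses: the mass-weighted
#' average `(m_L d_L + m_R d_R) / (m_L + m_R)`.  Plain summation of the two
#' doses (a common error) always exceeds this value when both doses are
#' positive.
#'
#' @param ad_left,ad_right per-kidney absorbed doses (Gy)
#' @param mass_left,mass_right kidney masses (g, > 0)
#' @return combined absorbed dose (Gy)
#' @export
combine_kidneys <- function(ad_left, mass_left, ad_right, mass_right) {
  if (mass_left <= 0 || mass_right <= 0) stop("kidney masses must be > 0")
  (mass_left * ad_left + mass_right * ad_right) / (mass_left + mass_right)
}

# exponent sign of each convention relative to the raw ("none") activity:
# corrected-to-injection activities carry a factor exp(+lam * t)
.convention_exponent <- function(convention) {
  switch(match.arg(convention, DECAY_CONVENTIONS),
         corrected_to_injection = 1,
         corrected_to_scan_start = 0,  # acquisition-time reference
         none = 0)
}

#' Convert a series between decay-correction conventions
#'
#' Activities decay-corrected to the injection time carry a factor
#' `exp(+lam_physical * t_i)` relative to the activity actually present at
#' the scan; converting between conventions multiplies each point by the
#' appropriate exponential ratio.  Correction to the start of each SPECT
#' scan is treated as numerically identical to the uncorrected activity at
#' the acquisition time (per-scan duration offsets are not modeled).
#' The operation is idempotent when the series is already in the target
#' convention, and round trips are exact.
#'
#' @param series a [ta_series()]
#' @param target_convention the convention to convert to
#' @param constants a [nuclide_constants()]
#' @return a [ta_series()] in the target convention
#' @export
apply_decay_correction <- function(series, target_convention,
                                   constants = nuclide_constants()) {
  stopifnot(inherits(series, "ta_series"))
  e_from <- .convention_exponent(series$decay_convention)
  e_to <- .convention_exponent(target_convention)
  fac <- exp((e_to - e_from) * constants$lam_physical * series$times)
  ta_series(series$region_id, series$times, series$activities * fac,
            match.arg(target_convention, DECAY_CONVENTIONS),
            series$injected_activity)
}

#' Healthy-tissue TIA with contained lesions removed
#'
#' The TIA of lesions located inside an organ must not be counted towards
#' the healthy-tissue TIA of that organ; including it inflates the
#' healthy-organ dose.
#'
#' @param organ_tia whole-organ TIA (MBq.h)
#' @param lesion_tias TIAs of lesions contained in the organ (MBq.h)
#' @param lesions_inside are the lesion volumes inside the organ volume?
#'   If `FALSE` the organ TIA is returned unchanged.
#' @return healthy-tissue TIA (MBq.h)
#' @export
healthy_organ_tia <- function(organ_tia, lesion_tias = numeric(),
                              lesions_inside = TRUE) {
  if (!lesions_inside || length(lesion_tias) == 0L) return(organ_tia)
  out <- organ_tia - sum(lesion_tias)
  if (out < 0)
    stop("lesion TIA exceeds whole-organ TIA; inconsistent inputs")
  out
}
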