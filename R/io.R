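## CSV readers/writers for the package's interchange schemas.  CSV is the
## interchange format throughout: UTF-8, comma-separated, '.' decimal,
## header row mandatory.

#' Read time-activity series from CSV
#'
#' Expects columns `region`, `time_h`, `activity_MBq`, `decay_convention`
#' (one convention per region), and optionally `injected_activity_MBq`.
#' Rows are grouped by region into one [ta_series()] each; validation
#' errors name the offending region.
#'
#' @param path CSV file path
#' @return named list of [ta_series()]
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("region", "time_h", "activity_MBq", "decay_convention")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("series CSV missing columns: ", paste(missing, collapse = ", "))
  out <- lapply(split(df, df$region), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    if (anyDuplicated(d$time_h))
      stop("region '", d$region[1L], "': duplicated time points")
    conv <- unique(d$decay_convention)
    if (length(conv) != 1L)
      stop("region '", d$region[1L], "': mixed decay conventions")
    inj <- if ("injected_activity_MBq" %in% names(d))
      d$injected_activity_MBq[1L] else NA_real_
    ta_series(d$region[1L], d$time_h, d$activity_MBq, conv, inj)
  })
  out[unique(df$region)]
}

#' @rdname read_series_csv
#' @param series_list named list of [ta_series()]
#' @export
write_series_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) data.frame(
    region = s$region_id, time_h = s$times, activity_MBq = s$activities,
    decay_convention = s$decay_convention,
    injected_activity_MBq = s$injected_activity,
    stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read / write a cohort submission CSV
#'
#' Columns: `participant_id`, `task`, `region`, `ad` (Gy), and optionally
#' `method_id`, `software_class`.
#'
#' @param path CSV file path
#' @return cohort data.frame
#' @export
read_cohort_csv <- function(path) {
  .check_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_csv
#' @param cohort cohort data.frame
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(.check_cohort(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Compare two result CSVs field by field
#'
#' Intended for validating an in-house reimplementation against a reference
#' result table: numeric columns are compared with a relative tolerance,
#' everything else exactly.  Returns the mismatching cells rather than
#' raising.
#'
#' @param path_reference,path_candidate CSV files with identical schemas
#' @param rel_tol relative tolerance for numeric columns (default 1e-6)
#' @return list with `pass` (logical) and `diffs` (data.frame of
#'   mismatching cells: row, column, reference, candidate)
#' @export
validate_against_reference <- function(path_reference, path_candidate,
                                       rel_tol = 1e-6) {
  ref <- utils::read.csv(path_reference, stringsAsFactors = FALSE)
  cand <- utils::read.csv(path_candidate, stringsAsFactors = FALSE)
  if (!identical(names(ref), names(cand)))
    stop("schema mismatch: column names differ")
  if (nrow(ref) != nrow(cand))
    stop("schema mismatch: row counts differ")
  diffs <- NULL
  for (col in names(ref)) {
    a <- ref[[col]]; b <- cand[[col]]
    if (is.numeric(a) && is.numeric(b)) {
      denom <- pmax(abs(a), abs(b), 1e-300)
      bad <- which(!(is.na(a) & is.na(b)) &
                     (is.na(a) != is.na(b) |
                        abs(a - b) / denom > rel_tol))
    } else {
      bad <- which(!(is.na(a) & is.na(b)) & !(a %in% NA) & a != b)
    }
    if (length(bad)) {
      diffs <- rbind(diffs, data.frame(
        row = bad, column = col,
        reference = as.character(a[bad]),
        candidate = as.character(b[bad]), stringsAsFactors = FALSE))
    }
  }
  list(pass = is.null(diffs),
       diffs = if (is.null(diffs))
         data.frame(row = integer(), column = character(),
                    reference = character(), candidate = character())
       else diffs)
}

# small deterministic content hash (Horner scheme mod 2^31 - 1) used to
# stamp report summaries with the configuration they came from
.config_hash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(txt))
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}
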