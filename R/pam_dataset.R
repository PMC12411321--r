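#' Quality-flag reason codes
#'
#' Reason codes carried per record in the `flags` column of a
#' [pam_dataset]. An empty flag string means the record is accepted.
#' `RECOVERED_NOTE` is informational: it marks the record at which an
#' artifact event closed and may coexist with an accepted record.
#'
#' @format Character vector of the recognised codes.
#' @export
FLAG_CODES <- c(
  "MISSING",            # mandatory field missing in the source file
  "RANGE",              # non-positive, F' > Fm', or detector saturation
  "LOW_SIGNAL",         # Fm' below the low-signal floor
  "NIGHT_JUMP",         # rapid nighttime Fm' step (rain/dew/snow onset)
  "PROPORTIONAL_DROP",  # co-drop of F' and Fm' with stable PhiP (optical)
  "DRIFT",              # slow Fm decline with stable Fv/Fm (sample moving)
  "YII_OUT",            # PhiP outside plausible bounds
  "TEMP_RANGE",         # temperature outside the ML correction model range
  "RECOVERED_NOTE"      # event closed at this record (informational)
)

# event codes: presence of any of these means "rejected"
.EVENT_CODES <- setdiff(FLAG_CODES, "RECOVERED_NOTE")

#' Test and manipulate per-record flag strings
#'
#' Flags are stored as semicolon-joined reason codes, `""` when empty.
#'
#' @param flags character vector of flag strings.
#' @param code a single reason code from [FLAG_CODES].
#' @return `flag_has()` a logical vector; `flag_add()`, `flag_drop()` the
#'   modified flag strings; `is_accepted()` logical, `TRUE` where no
#'   rejecting code is present.
#' @export
flag_has <- function(flags, code) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(x) code %in% x, logical(1))
}

#' @rdname flag_has
#' @export
flag_add <- function(flags, code) {
  stopifnot(code %in% FLAG_CODES)
  vapply(strsplit(flags, ";", fixed = TRUE), function(parts) {
    paste(union(parts[nzchar(parts)], code), collapse = ";")
  }, character(1))
}

#' @rdname flag_has
#' @export
flag_drop <- function(flags, code) {
  vapply(strsplit(flags, ";", fixed = TRUE), function(x) {
    paste(setdiff(x[nzchar(x)], code), collapse = ";")
  }, character(1))
}

#' @rdname flag_has
#' @export
is_accepted <- function(flags) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(x) !any(x %in% .EVENT_CODES), logical(1))
}

#' Construct a monitoring-PAM dataset
#'
#' The container consumed by every processing stage: an ordered table of
#' point records (one saturating-pulse event per fluorometer head) plus the
#' protocol constants needed downstream.
#'
#' @param records data.frame with columns `timestamp` (POSIXct), `head_id`
#'   (character), `par` (umol m-2 s-1), `temp_c` (deg C), `f_prime` (mV, F'),
#'   `fm_prime` (mV, Fm'), optionally `y_ii` (instrument-reported quantum
#'   yield of photochemistry) and `flags`. Missing optional columns are
#'   added (`y_ii = NA`, `flags = ""`).
#' @param interval_minutes nominal saturating-pulse interval (minutes).
#' @param detector_range_mv detector maximum (mV); signals at or above this
#'   are saturated.
#' @param metadata free-form named list (site, species, instrument, ...).
#' @return An object of class `pam_dataset`: a list with elements
#'   `records`, `interval_minutes`, `detector_range_mv`, `metadata`.
#'   Records are sorted by (`head_id`, `timestamp`).
#' @export
pam_dataset <- function(records, interval_minutes = 30,
                        detector_range_mv = 4000, metadata = list()) {
  stopifnot(is.data.frame(records), detector_range_mv > 0,
            interval_minutes > 0)
  needed <- c("timestamp", "head_id", "par", "temp_c", "f_prime", "fm_prime")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0)
    stop("records is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (!inherits(records$timestamp, "POSIXct"))
    stop("records$timestamp must be POSIXct")
  if (is.null(records$y_ii)) records$y_ii <- NA_real_
  if (is.null(records$flags)) records$flags <- ""
  records$head_id <- as.character(records$head_id)
  records <- records[order(records$head_id, records$timestamp), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records,
                 interval_minutes = interval_minutes,
                 detector_range_mv = detector_range_mv,
                 metadata = metadata),
            class = "pam_dataset")
}

#' @export
print.pam_dataset <- function(x, ...) {
  r <- x$records
  heads <- unique(r$head_id)
  cat("<pam_dataset> ", nrow(r), " records, ", length(heads), " head(s): ",
      paste(heads, collapse = ", "), "\n", sep = "")
  if (nrow(r) > 0)
    cat("  span: ", format(min(r$timestamp)), " .. ",
        format(max(r$timestamp)), "\n", sep = "")
  cat("  interval ", x$interval_minutes, " min, detector range ",
      x$detector_range_mv, " mV\n", sep = "")
  nfl <- sum(!is_accepted(r$flags))
  cat("  flagged: ", nfl, " (",
      if (nrow(r) > 0) round(100 * nfl / nrow(r), 1) else 0, "%)\n", sep = "")
  if (isTRUE(x$metadata$ml_temp_corrected))
    cat("  ML temperature correction applied\n")
  invisible(x)
}

#' @export
summary.pam_dataset <- function(object, ...) {
  r <- object$records
  by_head <- table(r$head_id)
  fl <- sum(!is_accepted(r$flags))
  out <- list(n = nrow(r), heads = by_head, flagged = fl)
  class(out) <- "summary.pam_dataset"
  out
}

#' @export
print.summary.pam_dataset <- function(x, ...) {
  cat("pam_dataset:", x$n, "records,", x$flagged, "flagged\n")
  print(x$heads)
  invisible(x)
}

#' Number of records in a pam_dataset
#' @param x a [pam_dataset].
#' @return integer record count.
#' @export
n_records <- function(x) nrow(x$records)
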