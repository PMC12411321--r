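#' Describe the layout of a delimited monitoring-PAM export
#'
#' Monitoring fluorometer loggers write delimited text but the byte layout
#' differs between firmware versions and sites, so parsing is driven by a
#' dialect descriptor: delimiter, decimal mark, missing-value tokens, the
#' timestamp format, and a column map from the standard field names to the
#' source column names. Real exports may need a custom column map.
#'
#' @param sep field delimiter (default `";"`, mirroring a semicolon-delimited
#'   logger export with one row per head per saturating-pulse event).
#' @param dec decimal mark.
#' @param na_tokens strings treated as missing.
#' @param time_format `strptime` format of the timestamp column.
#' @param tz_offset fixed UTC offset applied when the file carries no zone,
#'   e.g. `"+0200"`. Field data loggers run on a fixed clock (no DST), so a
#'   single offset is assumed for the whole file.
#' @param columns named character vector mapping standard names
#'   (`timestamp`, `head_id`, `par`, `temp_c`, `f_prime`, `fm_prime`, and
#'   optionally `y_ii`, `flags`) to source column names.
#' @return A list of class `pam_dialect`.
#' @export
pam_dialect <- function(sep = ";", dec = ".",
                        na_tokens = c("NA", "NaN", ""),
                        time_format = "%Y-%m-%d %H:%M:%S",
                        tz_offset = "+0000",
                        columns = c(timestamp = "timestamp",
                                    head_id = "head_id",
                                    par = "par",
                                    temp_c = "temp_c",
                                    f_prime = "f_prime",
                                    fm_prime = "fm_prime",
                                    y_ii = "y_ii",
                                    flags = "flags")) {
  mandatory <- c("timestamp", "head_id", "par", "temp_c",
                 "f_prime", "fm_prime")
  miss <- setdiff(mandatory, names(columns))
  if (length(miss) > 0)
    stop("dialect column map missing: ", paste(miss, collapse = ", "))
  structure(list(sep = sep, dec = dec, na_tokens = na_tokens,
                 time_format = time_format, tz_offset = tz_offset,
                 columns = columns),
            class = "pam_dialect")
}

.parse_offset_secs <- function(tz_offset) {
  m <- regmatches(tz_offset, regexec("^([+-])(\\d{2}):?(\\d{2})$", tz_offset))[[1]]
  if (length(m) != 4) stop("invalid tz_offset: ", tz_offset)
  sgn <- if (m[2] == "-") -1 else 1
  sgn * (as.numeric(m[3]) * 3600 + as.numeric(m[4]) * 60)
}

#' Read a delimited monitoring-PAM file
#'
#' Parses one delimited export into a validated, per-head, time-ordered
#' [pam_dataset]. Rows with an unparseable timestamp or empty head id are
#' dropped (count reported via message); rows with a missing mandatory
#' numeric field are kept and flagged `MISSING` so that gap statistics stay
#' honest. Duplicate (head, timestamp) pairs keep the first occurrence
#' (logger restarts duplicate the boundary record).
#'
#' @param path path to the file.
#' @param dialect a [pam_dialect] describing the layout.
#' @param interval_minutes,detector_range_mv,metadata passed to
#'   [pam_dataset()].
#' @return A [pam_dataset]. The parse report (dropped rows, duplicates)
#'   is attached as attribute `"read_report"`.
#' @export
read_pam <- function(path, dialect = pam_dialect(),
                     interval_minutes = 30, detector_range_mv = 4000,
                     metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           dec = dialect$dec, na.strings = dialect$na_tokens,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character",
                           quote = "\"", comment.char = "")
  cols <- dialect$columns
  mandatory <- c("timestamp", "head_id", "par", "temp_c",
                 "f_prime", "fm_prime")
  for (std in mandatory) {
    if (!(cols[[std]] %in% names(raw)))
      stop("format error: source column '", cols[[std]],
           "' (", std, ") not found in ", path)
  }
  get_col <- function(std) {
    if (!(std %in% names(cols))) return(NULL)
    src <- cols[[std]]
    if (!is.na(src) && src %in% names(raw)) raw[[src]] else NULL
  }
  num <- function(x) {
    x[x %in% dialect$na_tokens] <- NA
    if (dialect$dec != ".") x <- gsub(dialect$dec, ".", x, fixed = TRUE)
    suppressWarnings(as.numeric(x))
  }
  ts_chr <- get_col("timestamp")
  ts <- as.POSIXct(ts_chr, format = dialect$time_format, tz = "UTC")
  # stored internally in UTC; the declared fixed offset is removed
  ts <- ts - .parse_offset_secs(dialect$tz_offset)
  head_id <- get_col("head_id")
  df <- data.frame(timestamp = ts,
                   head_id = as.character(head_id),
                   par = num(get_col("par")),
                   temp_c = num(get_col("temp_c")),
                   f_prime = num(get_col("f_prime")),
                   fm_prime = num(get_col("fm_prime")),
                   stringsAsFactors = FALSE)
  y <- get_col("y_ii")
  df$y_ii <- if (is.null(y)) NA_real_ else num(y)
  fl <- get_col("flags")
  df$flags <- if (is.null(fl)) "" else ifelse(is.na(fl), "", fl)

  bad <- is.na(df$timestamp) | is.na(df$head_id) | !nzchar(df$head_id)
  n_dropped <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  if (nrow(df) == 0) stop("empty input: no parseable rows in ", path)

  df <- df[order(df$head_id, df$timestamp), , drop = FALSE]
  dup <- duplicated(df[, c("head_id", "timestamp")])
  n_dup <- sum(dup)
  if (n_dup > 0) {
    warning(n_dup, " duplicate (head, timestamp) record(s); keeping first")
    df <- df[!dup, , drop = FALSE]
  }
  missing_core <- is.na(df$par) | is.na(df$temp_c) |
    is.na(df$f_prime) | is.na(df$fm_prime)
  df$flags[missing_core] <- flag_add(df$flags[missing_core], "MISSING")

  if (n_dropped > 0)
    message(n_dropped, " unparseable row(s) dropped from ", path)
  ds <- pam_dataset(df, interval_minutes = interval_minutes,
                    detector_range_mv = detector_range_mv,
                    metadata = metadata)
  attr(ds, "read_report") <- list(n_read = length(ts), n_dropped = n_dropped,
                                  n_duplicates = n_dup)
  ds
}

#' Write a pam_dataset as delimited text
#'
#' Emits the standard column layout (`timestamp`, `head_id`, `par`,
#' `temp_c`, `f_prime`, `fm_prime`, `y_ii`, `flags`), with flags as
#' semicolon-joined reason codes. `read_pam(write_pam(x))` round-trips all
#' fields; no numeric value is altered.
#'
#' @param dataset a [pam_dataset].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_pam <- function(dataset, path, sep = ";") {
  stopifnot(inherits(dataset, "pam_dataset"))
  r <- dataset$records
  out <- data.frame(
    timestamp = format(r$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    head_id = r$head_id,
    par = format(r$par, digits = 15, trim = TRUE, scientific = FALSE),
    temp_c = format(r$temp_c, digits = 15, trim = TRUE, scientific = FALSE),
    f_prime = format(r$f_prime, digits = 15, trim = TRUE, scientific = FALSE),
    fm_prime = format(r$fm_prime, digits = 15, trim = TRUE, scientific = FALSE),
    y_ii = ifelse(is.na(r$y_ii), "NA",
                  format(r$y_ii, digits = 15, trim = TRUE, scientific = FALSE)),
    flags = r$flags,
    stringsAsFactors = FALSE)
  out[] <- lapply(out, function(x) { x[x == "NA"] <- "NA"; x })
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Validate a pam_dataset
#'
#' Report-only check: per-head record counts, time-gap anomalies (gaps
#' longer than twice the nominal interval), and invariant violations
#' (F' > Fm' on accepted records, negative PAR, non-positive signals,
#' detector saturation, non-increasing timestamps). Never mutates data.
#'
#' @param dataset a [pam_dataset].
#' @return A list of class `pam_validation` with elements `head_counts`,
#'   `gaps` (data.frame), `violations` (data.frame), `n_violations`.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "pam_dataset"))
  r <- dataset$records
  viol <- list()
  add_viol <- function(idx, what) {
    if (any(idx)) viol[[length(viol) + 1]] <<-
        data.frame(row = which(idx), issue = what, stringsAsFactors = FALSE)
  }
  acc <- is_accepted(r$flags)
  fin <- !is.na(r$f_prime) & !is.na(r$fm_prime)
  add_viol(acc & fin & r$f_prime > r$fm_prime, "f_prime > fm_prime")
  add_viol(acc & fin & (r$f_prime <= 0 | r$fm_prime <= 0),
           "non-positive signal")
  add_viol(!is.na(r$par) & r$par < 0, "negative PAR")
  add_viol(acc & !is.na(r$fm_prime) &
             r$fm_prime >= dataset$detector_range_mv, "detector saturation")

  gaps <- do.call(rbind, lapply(split(seq_len(nrow(r)), r$head_id),
    function(ii) {
      if (length(ii) < 2) return(NULL)
      ts <- r$timestamp[ii]
      d <- as.numeric(diff(ts), units = "mins")
      big <- which(d > 2 * dataset$interval_minutes)
      if (length(big) == 0) return(NULL)
      data.frame(head_id = r$head_id[ii[1]],
                 after = ts[big], gap_minutes = d[big],
                 stringsAsFactors = FALSE)
    }))
  if (is.null(gaps))
    gaps <- data.frame(head_id = character(), after = as.POSIXct(character()),
                       gap_minutes = numeric())
  violations <- if (length(viol) > 0) do.call(rbind, viol) else
    data.frame(row = integer(), issue = character())
  out <- list(head_counts = table(r$head_id), gaps = gaps,
              violations = violations, n_violations = nrow(violations))
  class(out) <- "pam_validation"
  out
}

#' @export
print.pam_validation <- function(x, ...) {
  cat("pam_dataset validation\n  records per head:\n")
  print(x$head_counts)
  cat("  gap anomalies: ", nrow(x$gaps), "\n", sep = "")
  cat("  invariant violations: ", x$n_violations, "\n", sep = "")
  if (x$n_violations > 0) print(utils::head(x$violations, 10))
  invisible(x)
}
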