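#' Classify records into day and night and find night windows
#'
#' A night window is a maximal run of records with measured PAR at or below
#' `dark_par_threshold` lasting at least `min_dark_hours`. Shorter dark
#' runs (dusk gaps, heavy cloud) stay DAY. Night is defined from the
#' colocated PAR sensor rather than solar geometry, so only in-file data is
#' used. Under dark acclimation all reversible NPQ can be assumed relaxed
#' and all PSII centers open, so F' and Fm' within these windows are read
#' as F0 and Fm.
#'
#' @param dataset a [pam_dataset], records time-ordered per head.
#' @param dark_par_threshold PAR at or below which a record counts as dark
#'   (umol m-2 s-1).
#' @param min_dark_hours minimum window duration (hours). The duration of a
#'   run is measured from first to last record plus one nominal interval,
#'   since each point record stands for its sampling interval.
#' @return A list with `dataset` (records gain a `day_night` column) and
#'   `windows`, a data.frame with one row per night window: `head_id`,
#'   `night_date` (the window is labelled by the morning of its end, so the
#'   "preceding night" of day D is the window dated D), `start`, `end`,
#'   `n_records`. Heads with no qualifying window contribute zero rows.
#' @export
classify_day_night <- function(dataset, dark_par_threshold = 1,
                               min_dark_hours = 2) {
  stopifnot(inherits(dataset, "pam_dataset"))
  r <- dataset$records
  r$day_night <- "DAY"
  windows <- list()
  for (h in unique(r$head_id)) {
    ii <- which(r$head_id == h)
    dark <- !is.na(r$par[ii]) & r$par[ii] <= dark_par_threshold
    rl <- rle(dark)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (k in which(rl$values)) {
      idx <- ii[starts[k]:ends[k]]
      span_h <- as.numeric(difftime(r$timestamp[idx[length(idx)]],
                                    r$timestamp[idx[1]], units = "hours")) +
        dataset$interval_minutes / 60
      if (span_h >= min_dark_hours) {
        r$day_night[idx] <- "NIGHT"
        windows[[length(windows) + 1]] <- data.frame(
          head_id = h,
          night_date = as.Date(r$timestamp[idx[length(idx)]], tz = "UTC"),
          start = r$timestamp[idx[1]],
          end = r$timestamp[idx[length(idx)]],
          n_records = length(idx),
          stringsAsFactors = FALSE)
      }
    }
  }
  windows <- if (length(windows) > 0) do.call(rbind, windows) else
    data.frame(head_id = character(), night_date = as.Date(character()),
               start = as.POSIXct(character()), end = as.POSIXct(character()),
               n_records = integer())
  windows <- windows[order(windows$head_id, windows$start), , drop = FALSE]
  rownames(windows) <- NULL
  dataset$records <- r
  list(dataset = dataset, windows = windows)
}

#' Aggregate accepted nighttime records into per-night summaries
#'
#' For each night window, aggregates F' of accepted (unflagged) records
#' into a nightly F0 and Fm' into a nightly Fm, and derives
#' Fv/Fm = 1 - F0/Fm. The default aggregate is the median, robust to
#' residual artifacts the filter missed; `"predawn"` uses the last quarter
#' of the window, when dark acclimation is deepest.
#'
#' @param labelled result of [classify_day_night()], or a [pam_dataset]
#'   whose records already carry `day_night`.
#' @param windows night-window table (taken from `labelled` when omitted).
#' @param aggregate one of `"median"`, `"mean"`, `"predawn"`.
#' @param n_min minimum accepted records for a usable night.
#' @return data.frame of class `night_summary` with columns `night_date`,
#'   `head_id`, `f0`, `fm`, `fvfm`, `n_used`, `qc_ok`. `qc_ok` is FALSE
#'   when fewer than `n_min` records were usable or f0 >= fm.
#' @export
nightly_summary <- function(labelled, windows = NULL,
                            aggregate = c("median", "mean", "predawn"),
                            n_min = 4) {
  aggregate <- match.arg(aggregate)
  if (is.list(labelled) && !inherits(labelled, "pam_dataset")) {
    if (is.null(windows)) windows <- labelled$windows
    dataset <- labelled$dataset
  } else dataset <- labelled
  stopifnot(inherits(dataset, "pam_dataset"), is.data.frame(windows))
  r <- dataset$records
  out <- lapply(seq_len(nrow(windows)), function(k) {
    w <- windows[k, ]
    sel <- r$head_id == w$head_id &
      r$timestamp >= w$start & r$timestamp <= w$end
    if (aggregate == "predawn") {
      idx <- which(sel)
      keep <- idx[idx > idx[1] + floor(0.75 * (length(idx) - 1)) - 1e-9]
      q3 <- ceiling(0.75 * length(idx))
      keep <- idx[seq.int(max(1L, q3), length(idx))]
      sel <- rep(FALSE, length(sel)); sel[keep] <- TRUE
    }
    use <- sel & is_accepted(r$flags) &
      !is.na(r$f_prime) & !is.na(r$fm_prime)
    agg <- if (aggregate == "mean") mean else stats::median
    f0 <- if (any(use)) agg(r$f_prime[use]) else NA_real_
    fm <- if (any(use)) agg(r$fm_prime[use]) else NA_real_
    n_used <- sum(use)
    qc_ok <- n_used >= n_min && !is.na(f0) && !is.na(fm) &&
      f0 > 0 && f0 < fm
    data.frame(night_date = w$night_date, head_id = w$head_id,
               f0 = f0, fm = fm,
               fvfm = if (!is.na(f0) && !is.na(fm) && fm > 0)
                 1 - f0 / fm else NA_real_,
               n_used = n_used, qc_ok = qc_ok,
               stringsAsFactors = FALSE)
  })
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(night_date = as.Date(character()), head_id = character(),
               f0 = numeric(), fm = numeric(), fvfm = numeric(),
               n_used = integer(), qc_ok = logical())
  class(res) <- c("night_summary", class(res))
  res
}
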