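#' Filter configuration
#'
#' Threshold set governing the artifact-flagging cascade. Each default maps
#' to a stated detection mechanism: optical disturbances (dew, rain, snow,
#' insects, leaf movement) attenuate the measuring light or the sampled
#' area, so they depress F' and Fm' proportionally while leaving the
#' quantum yield of photochemistry almost unchanged; nighttime Fm is
#' otherwise quasi-stable, so fast nocturnal steps indicate condensation or
#' precipitation; a slow Fm decline with stable Fv/Fm indicates the sample
#' drifting out of the sensor frame rather than physiology. All values are
#' config-overridable.
#'
#' @param f_min_mv low-signal floor for Fm' (mV); default
#'   `detector_range_mv / 100`, resolved when the cascade runs.
#' @param night_jump_rel max tolerated relative step of Fm' between
#'   consecutive night records.
#' @param prop_window sliding window (records) for co-drop detection.
#' @param prop_drop_rel minimum common relative decrease of F' and Fm'.
#' @param phi_stable_tol max |change in PhiP| for a drop to count as
#'   optical rather than physiological.
#' @param drift_days nightly-summary window (nights) for the slow-drift
#'   test.
#' @param drift_rel minimum cumulative relative Fm decline over
#'   `drift_days` to call DRIFT.
#' @param fvfm_stable_tol max Fv/Fm range over the drift window for the
#'   decline to count as non-physiological. Under the lake model a
#'   sustained-NPQ-driven relative Fm decline of x shifts Fv/Fm by about
#'   x (Fv/Fm)(1 - Fv/Fm), i.e. 0.035-0.06 at `drift_rel = 0.25`, while
#'   true optical drift leaves Fv/Fm within nightly noise (~0.01); the
#'   default 0.02 sits between the two.
#' @param yii_min,yii_max plausible bounds on PhiP.
#' @param recovery_tol_rel relative band around the pre-event baseline
#'   within which an event closes (unflagging).
#' @param dark_par_threshold,min_dark_hours,n_min night-classification and
#'   summary settings used when the cascade derives windows itself.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(f_min_mv = NULL,
                          night_jump_rel = 0.30,
                          prop_window = 5,
                          prop_drop_rel = 0.30,
                          phi_stable_tol = 0.05,
                          drift_days = 14,
                          drift_rel = 0.25,
                          fvfm_stable_tol = 0.02,
                          yii_min = 0,
                          yii_max = 0.85,
                          recovery_tol_rel = 0.10,
                          dark_par_threshold = 1,
                          min_dark_hours = 2,
                          n_min = 4) {
  rel <- c(night_jump_rel = night_jump_rel, prop_drop_rel = prop_drop_rel,
           drift_rel = drift_rel, recovery_tol_rel = recovery_tol_rel)
  if (any(rel <= 0 | rel >= 1))
    stop("relative thresholds must lie in (0, 1)")
  if (prop_window < 2 || drift_days < 2)
    stop("windows must span at least 2 records/nights")
  structure(list(f_min_mv = f_min_mv, night_jump_rel = night_jump_rel,
                 prop_window = prop_window, prop_drop_rel = prop_drop_rel,
                 phi_stable_tol = phi_stable_tol, drift_days = drift_days,
                 drift_rel = drift_rel, fvfm_stable_tol = fvfm_stable_tol,
                 yii_min = yii_min, yii_max = yii_max,
                 recovery_tol_rel = recovery_tol_rel,
                 dark_par_threshold = dark_par_threshold,
                 min_dark_hours = min_dark_hours, n_min = n_min),
            class = "filter_config")
}

#' Read / write a filter configuration as key=value text
#' @param path file path.
#' @param config a [filter_config].
#' @return `read_filter_config()` a [filter_config];
#'   `write_filter_config()` `path`, invisibly.
#' @export
read_filter_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !grepl("^\\s*#", ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) as.numeric(trimws(x[2]))),
    vapply(kv, function(x) trimws(x[1]), character(1)))
  do.call(filter_config, vals)
}

#' @rdname read_filter_config
#' @export
write_filter_config <- function(config, path) {
  u <- unclass(config)
  u <- u[!vapply(u, is.null, logical(1))]
  writeLines(paste0(names(u), "=", vapply(u, format, character(1))), path)
  invisible(path)
}

.resolve_f_min <- function(config, dataset) {
  if (is.null(config$f_min_mv)) dataset$detector_range_mv / 100
  else config$f_min_mv
}

# usable for event logic: accepted so far, with finite signals
.usable <- function(r) {
  is_accepted(r$flags) & !is.na(r$f_prime) & !is.na(r$fm_prime)
}

.get_events <- function(dataset) {
  ev <- attr(dataset, "pam_events")
  if (is.null(ev))
    ev <- data.frame(type = character(), head_id = character(),
                     onset = integer(), end = integer(),
                     base_f = numeric(), base_fm = numeric(),
                     open = logical(), stringsAsFactors = FALSE)
  ev
}

#' Range and saturation filter
#'
#' Flags `RANGE` on records with non-positive F' or Fm', F' > Fm'
#' (ordering violation), or Fm' at/above the detector maximum (the signal
#' may exceed the dynamic range of the detector during a saturating
#' pulse).
#'
#' @param dataset a [pam_dataset].
#' @param detector_range_mv detector maximum; defaults to the dataset's.
#' @return The flagged dataset.
#' @export
filter_range <- function(dataset, detector_range_mv = NULL) {
  stopifnot(inherits(dataset, "pam_dataset"))
  if (is.null(detector_range_mv))
    detector_range_mv <- dataset$detector_range_mv
  r <- dataset$records
  fin <- !is.na(r$f_prime) & !is.na(r$fm_prime)
  bad <- fin & (r$f_prime <= 0 | r$fm_prime <= 0 |
                  r$f_prime > r$fm_prime |
                  r$fm_prime >= detector_range_mv)
  r$flags[bad] <- flag_add(r$flags[bad], "RANGE")
  dataset$records <- r
  dataset
}

#' Low-signal filter
#'
#' Disturbances also corrupt PhiP through falling signal-to-noise ratio
#' when absolute F' and Fm' are very low; records with Fm' strictly below
#' the floor are flagged `LOW_SIGNAL`.
#'
#' @param dataset a [pam_dataset].
#' @param config a [filter_config].
#' @return The flagged dataset.
#' @export
filter_low_signal <- function(dataset, config = filter_config()) {
  r <- dataset$records
  fmin <- .resolve_f_min(config, dataset)
  bad <- !is.na(r$fm_prime) & r$fm_prime < fmin
  r$flags[bad] <- flag_add(r$flags[bad], "LOW_SIGNAL")
  dataset$records <- r
  dataset
}

#' Nighttime rapid-change filter
#'
#' Rapid changes of Fm (nighttime Fm') typically indicate rainfall, dew
#' formation or snowfall. Within each night window, a consecutive-record
#' relative Fm' step exceeding `night_jump_rel` opens an event: the record
#' and all subsequent records of the window stay flagged `NIGHT_JUMP`
#' until recovery (see [unflag_recovery()]). The rule never touches
#' daytime records, where fast Fm' changes are a physiological response to
#' fluctuating illumination. The pre-event baseline (median of the last 3
#' accepted records before onset) is stored with the event.
#'
#' @param dataset a [pam_dataset].
#' @param windows night-window table from [classify_day_night()].
#' @param config a [filter_config].
#' @return The flagged dataset; open/closed events are carried in the
#'   `"pam_events"` attribute for the recovery pass.
#' @export
filter_night_jump <- function(dataset, windows, config = filter_config()) {
  r <- dataset$records
  events <- .get_events(dataset)
  usable0 <- .usable(r)
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    idx <- which(r$head_id == w$head_id &
                   r$timestamp >= w$start & r$timestamp <= w$end &
                   usable0)
    if (length(idx) < 2) next
    hist_f <- numeric(0); hist_fm <- numeric(0)
    open <- FALSE; onset <- NA_integer_
    prev_fm <- NA_real_
    for (i in idx) {
      if (!open) {
        if (!is.na(prev_fm) &&
            abs(r$fm_prime[i] - prev_fm) / prev_fm > config$night_jump_rel &&
            length(hist_fm) > 0) {
          open <- TRUE; onset <- i
          base_f <- stats::median(utils::tail(hist_f, 3))
          base_fm <- stats::median(utils::tail(hist_fm, 3))
          r$flags[i] <- flag_add(r$flags[i], "NIGHT_JUMP")
        } else {
          hist_f <- c(hist_f, r$f_prime[i])
          hist_fm <- c(hist_fm, r$fm_prime[i])
          prev_fm <- r$fm_prime[i]
        }
      } else {
        r$flags[i] <- flag_add(r$flags[i], "NIGHT_JUMP")
      }
    }
    if (open) {
      events <- rbind(events, data.frame(
        type = "NIGHT_JUMP", head_id = w$head_id,
        onset = onset, end = idx[length(idx)],
        base_f = base_f, base_fm = base_fm, open = TRUE,
        stringsAsFactors = FALSE))
    }
  }
  dataset$records <- r
  attr(dataset, "pam_events") <- events
  dataset
}

#' Proportional co-drop filter
#'
#' Dew, snow, rain films and wind-induced leaf movement attenuate the
#' measuring light or the sampled area, depressing F' and Fm' by the same
#' factor while PhiP = 1 - F'/Fm' stays nearly unchanged. Within a sliding
#' window of `prop_window` records, if both channels fall by at least
#' `prop_drop_rel` relative to the window-entry record while |change in
#' PhiP| stays within `phi_stable_tol`, an event opens at the drop and
#' subsequent records stay flagged `PROPORTIONAL_DROP` until recovery.
#' A genuine NPQ event depresses Fm' but moves PhiP, so it is not flagged.
#'
#' @inheritParams filter_night_jump
#' @return The flagged dataset with events recorded for the recovery pass.
#' @export
filter_proportional <- function(dataset, config = filter_config()) {
  r <- dataset$records
  events <- .get_events(dataset)
  for (h in unique(r$head_id)) {
    idx <- which(r$head_id == h & .usable(r))
    if (length(idx) < 2) next
    phi <- 1 - r$f_prime[idx] / r$fm_prime[idx]
    open <- FALSE
    for (p in seq_along(idx)) {
      i <- idx[p]
      if (!open) {
        back <- seq.int(max(1, p - config$prop_window + 1), p - 1)
        if (length(back) == 0 || back[1] > p - 1) next
        for (b in back) {
          j <- idx[b]
          if (r$f_prime[i] <= (1 - config$prop_drop_rel) * r$f_prime[j] &&
              r$fm_prime[i] <= (1 - config$prop_drop_rel) * r$fm_prime[j] &&
              abs(phi[p] - phi[b]) <= config$phi_stable_tol) {
            open <- TRUE; onset <- i
            pre <- idx[seq_len(p - 1)]
            base_f <- stats::median(utils::tail(r$f_prime[pre], 3))
            base_fm <- stats::median(utils::tail(r$fm_prime[pre], 3))
            r$flags[i] <- flag_add(r$flags[i], "PROPORTIONAL_DROP")
            break
          }
        }
      } else {
        r$flags[i] <- flag_add(r$flags[i], "PROPORTIONAL_DROP")
      }
    }
    if (open) {
      events <- rbind(events, data.frame(
        type = "PROPORTIONAL_DROP", head_id = h,
        onset = onset, end = idx[length(idx)],
        base_f = base_f, base_fm = base_fm, open = TRUE,
        stringsAsFactors = FALSE))
    }
  }
  dataset$records <- r
  attr(dataset, "pam_events") <- events
  dataset
}

#' Slow-drift filter
#'
#' A gradual day-to-day decline in nightly Fm with stable Fv/Fm points to
#' a leaf sample slowly moving out of the sensor frame (an optical change,
#' not physiology: seasonal downregulation depresses Fm and Fv/Fm
#' together). Over every run of `drift_days` consecutive usable nightly
#' summaries, a robust linear trend ([MASS::rlm]) of Fm versus night is
#' fitted; if the fitted cumulative relative decline reaches `drift_rel`
#' while the Fv/Fm range stays within `fvfm_stable_tol`, all records of
#' the affected nights' dates are flagged `DRIFT`.
#'
#' @param dataset a [pam_dataset].
#' @param summaries a [nightly_summary()] table.
#' @param config a [filter_config].
#' @return list with `dataset` (DRIFT flags added), `summaries` (gains a
#'   logical `drift` column), `drift_nights` (data.frame head_id,
#'   night_date).
#' @export
filter_drift <- function(dataset, summaries, config = filter_config()) {
  r <- dataset$records
  summaries$drift <- FALSE
  hits <- list()
  for (h in unique(summaries$head_id)) {
    s <- summaries[summaries$head_id == h & summaries$qc_ok, , drop = FALSE]
    s <- s[order(s$night_date), , drop = FALSE]
    if (nrow(s) < config$drift_days) {
      message("filter_drift: fewer than ", config$drift_days,
              " usable nights for head ", h, "; skipped")
      next
    }
    nwin <- nrow(s) - config$drift_days + 1
    flag_nights <- rep(FALSE, nrow(s))
    for (a in seq_len(nwin)) {
      sel <- a:(a + config$drift_days - 1)
      day <- as.numeric(s$night_date[sel] - s$night_date[sel[1]])
      # windows broken by long gaps are not comparable
      if (max(day) > 2 * config$drift_days) next
      fm <- s$fm[sel]
      fit <- stats::lm(fm ~ day)
      # rlm's MAD scale degenerates on (near-)exact trends; only go robust
      # when there is residual scatter for it to work with
      if (stats::mad(stats::resid(fit)) > 1e-8 * abs(mean(fm)))
        fit <- tryCatch(MASS::rlm(fm ~ day, maxit = 50),
                        error = function(e) fit)
      pr <- stats::predict(fit, data.frame(day = range(day)))
      if (pr[1] <= 0) next
      decline <- (pr[1] - pr[2]) / pr[1]
      if (decline >= config$drift_rel &&
          diff(range(s$fvfm[sel])) <= config$fvfm_stable_tol)
        flag_nights[sel] <- TRUE
    }
    if (any(flag_nights)) {
      nights <- s$night_date[flag_nights]
      summaries$drift[summaries$head_id == h &
                        summaries$night_date %in% nights] <- TRUE
      hits[[length(hits) + 1]] <- data.frame(head_id = h,
                                             night_date = nights)
      sel_rec <- r$head_id == h &
        as.Date(r$timestamp, tz = "UTC") %in% nights
      r$flags[sel_rec] <- flag_add(r$flags[sel_rec], "DRIFT")
    }
  }
  dataset$records <- r
  list(dataset = dataset, summaries = summaries,
       drift_nights = if (length(hits) > 0) do.call(rbind, hits) else
         data.frame(head_id = character(), night_date = as.Date(character())))
}

#' Close artifact events whose signals have recovered
#'
#' Levels are un-flagged once they return to the expected range: an open
#' `NIGHT_JUMP` or `PROPORTIONAL_DROP` event closes at the first record in
#' its span whose F' AND Fm' both lie within `recovery_tol_rel` of the
#' pre-event baseline. The closing record and everything after it in the
#' event span are accepted again; the closing record carries
#' `RECOVERED_NOTE`. Re-entry of one channel alone does not close the
#' event. Events never recovering stay fully flagged and are reported
#' open.
#'
#' @param dataset a [pam_dataset] carrying events from the jump/co-drop
#'   filters.
#' @param config a [filter_config].
#' @return The dataset with closed events unflagged; the `"pam_events"`
#'   attribute is updated (`open` column).
#' @export
unflag_recovery <- function(dataset, config = filter_config()) {
  r <- dataset$records
  events <- .get_events(dataset)
  if (nrow(events) == 0) return(dataset)
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    span <- ev$onset:ev$end
    span <- span[r$head_id[span] == ev$head_id &
                   flag_has(r$flags[span], ev$type)]
    if (length(span) == 0) next
    ok <- !is.na(r$f_prime[span]) & !is.na(r$fm_prime[span]) &
      abs(r$f_prime[span] - ev$base_f) / ev$base_f <= config$recovery_tol_rel &
      abs(r$fm_prime[span] - ev$base_fm) / ev$base_fm <= config$recovery_tol_rel
    if (any(ok)) {
      close_at <- span[which(ok)[1]]
      clear <- span[span >= close_at]
      r$flags[clear] <- flag_drop(r$flags[clear], ev$type)
      r$flags[close_at] <- flag_add(r$flags[close_at], "RECOVERED_NOTE")
      events$open[e] <- FALSE
    }
  }
  dataset$records <- r
  attr(dataset, "pam_events") <- events
  dataset
}

#' PhiP plausibility filter
#'
#' Flags `YII_OUT` on accepted records whose quantum yield of
#' photochemistry (1 - F'/Fm') falls outside `[yii_min, yii_max]`.
#'
#' @inheritParams filter_low_signal
#' @return The flagged dataset.
#' @export
filter_yii <- function(dataset, config = filter_config()) {
  r <- dataset$records
  use <- .usable(r)
  phi <- 1 - r$f_prime / r$fm_prime
  bad <- use & (phi < config$yii_min | phi > config$yii_max)
  r$flags[bad] <- flag_add(r$flags[bad], "YII_OUT")
  dataset$records <- r
  dataset
}

#' Run the full artifact-flagging cascade
#'
#' Deterministic order: RANGE, LOW_SIGNAL, NIGHT_JUMP, PROPORTIONAL_DROP,
#' DRIFT, recovery pass, YII_OUT. Values are never mutated and flagged
#' records are never deleted: downstream consumers choose exclusion. The
#' cascade first clears every flag it manages (all codes except `MISSING`
#' and `TEMP_RANGE`), so re-applying it yields identical flags
#' (idempotence).
#'
#' @param dataset a [pam_dataset] (optionally temperature-corrected).
#' @param config a [filter_config].
#' @param windows optional night-window table; derived with
#'   [classify_day_night()] (using the config's night settings) when
#'   omitted.
#' @return list with `dataset` (flagged; records gain `day_night`),
#'   `report` (class `pam_filter_report`: per-reason counts, retained
#'   fraction, open events), `windows`, `summaries` (post-event nightly
#'   summaries used by the drift stage, with its `drift` column).
#' @export
apply_filters <- function(dataset, config = filter_config(),
                          windows = NULL) {
  stopifnot(inherits(dataset, "pam_dataset"),
            inherits(config, "filter_config"))
  r <- dataset$records
  managed <- setdiff(FLAG_CODES, c("MISSING", "TEMP_RANGE"))
  for (code in managed) r$flags <- flag_drop(r$flags, code)
  dataset$records <- r
  attr(dataset, "pam_events") <- NULL

  dataset <- filter_range(dataset)
  dataset <- filter_low_signal(dataset, config)
  if (is.null(windows)) {
    cl <- classify_day_night(dataset,
                             dark_par_threshold = config$dark_par_threshold,
                             min_dark_hours = config$min_dark_hours)
    dataset <- cl$dataset
    windows <- cl$windows
  }
  dataset <- filter_night_jump(dataset, windows, config)
  dataset <- filter_proportional(dataset, config)
  summaries <- nightly_summary(dataset, windows, n_min = config$n_min)
  dr <- filter_drift(dataset, summaries, config)
  dataset <- dr$dataset
  summaries <- dr$summaries
  dataset <- unflag_recovery(dataset, config)
  dataset <- filter_yii(dataset, config)

  fl <- dataset$records$flags
  counts <- vapply(FLAG_CODES, function(cd) sum(flag_has(fl, cd)), integer(1))
  events <- .get_events(dataset)
  report <- structure(list(
    n_records = length(fl),
    counts = counts,
    retained_fraction = mean(is_accepted(fl)),
    open_events = sum(events$open)),
    class = "pam_filter_report")
  list(dataset = dataset, report = report, windows = windows,
       summaries = summaries)
}

#' @export
print.pam_filter_report <- function(x, ...) {
  cat("artifact filter report: ", x$n_records, " records, retained ",
      round(100 * x$retained_fraction, 1), "%\n", sep = "")
  nz <- x$counts[x$counts > 0]
  if (length(nz) > 0)
    for (i in seq_along(nz))
      cat(sprintf("  %-18s %d\n", names(nz)[i], nz[i]))
  if (x$open_events > 0)
    cat("  events still open at series end: ", x$open_events, "\n", sep = "")
  invisible(x)
}

#' Score the cascade against simulated ground truth
#'
#' Sensitivity is the fraction of artifact-bearing records (truth label not
#' `NONE`) that carry at least one rejecting flag; specificity the fraction
#' of clean records left unflagged.
#'
#' @param dataset a flagged [pam_dataset].
#' @param truth a ground-truth table with `head_id`, `timestamp`, `label`
#'   (see [simulate_pam_season()]).
#' @return list with `sensitivity`, `specificity`, `n_artifact`, `n_clean`,
#'   and the confusion counts.
#' @export
filter_score <- function(dataset, truth) {
  r <- dataset$records
  key <- function(d) paste(d$head_id, format(d$timestamp, "%Y%m%d%H%M%S"))
  m <- match(key(r), key(truth))
  stopifnot(!anyNA(m))
  lab <- truth$label[m]
  flagged <- !is_accepted(r$flags)
  art <- lab != "NONE"
  list(sensitivity = mean(flagged[art]),
       specificity = mean(!flagged[!art]),
       n_artifact = sum(art), n_clean = sum(!art),
       tp = sum(flagged & art), fp = sum(flagged & !art),
       fn = sum(!flagged & art), tn = sum(!flagged & !art))
}
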