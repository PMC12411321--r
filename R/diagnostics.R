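#' Protocol settings of a monitoring campaign
#'
#' @param detector_range_mv detector maximum (mV).
#' @param fvfm_ref reference Fv/Fm.
#' @param interval_minutes saturating-pulse interval; under uniform
#'   scheduling there are `1440/interval_minutes` pulse events per day.
#' @param sp_duration_s,sp_par saturating-pulse duration (s) and intensity
#'   (umol m-2 s-1).
#' @return list of class `protocol_settings` with the above plus
#'   `sp_per_day`.
#' @export
protocol_settings <- function(detector_range_mv = 4000, fvfm_ref = 0.83,
                              interval_minutes = 30, sp_duration_s = 0.8,
                              sp_par = 8000) {
  stopifnot(interval_minutes > 0)
  structure(list(detector_range_mv = detector_range_mv,
                 fvfm_ref = fvfm_ref,
                 interval_minutes = interval_minutes,
                 sp_per_day = 1440 / interval_minutes,
                 sp_duration_s = sp_duration_s, sp_par = sp_par),
            class = "protocol_settings")
}

#' Maximum F0 compatible with the detector range
#'
#' The measuring-light intensity must be set so that F0 stays low enough
#' for the saturating-pulse signal not to clip: from F0 = (1 - Fv/Fm) Fm
#' at the reference Fv/Fm, the headroom is
#' `(1 - fvfm_ref) x detector_range_mv` — 680 mV for a 4000 mV detector
#' at reference 0.83.
#'
#' @param detector_range_mv detector maximum (mV).
#' @param fvfm_ref reference Fv/Fm in (0, 1).
#' @return F0 ceiling (mV).
#' @export
f0_headroom <- function(detector_range_mv, fvfm_ref) {
  if (any(detector_range_mv <= 0)) stop("detector_range_mv must be positive")
  if (any(fvfm_ref <= 0 | fvfm_ref >= 1))
    stop("fvfm_ref must lie strictly in (0, 1)")
  (1 - fvfm_ref) * detector_range_mv
}

#' Daily PAR dose contributed by the saturating pulses
#'
#' `sp_per_day x sp_duration_s x sp_par / 1000` mmol m-2: at 48 pulses of
#' 0.8 s and 8000 umol m-2 s-1 this is 307.2 mmol m-2 — negligible beside
#' a sunny summer day, but a relevant addition in winter.
#'
#' @param sp_per_day pulses per day.
#' @param sp_duration_s pulse duration (s).
#' @param sp_par pulse intensity (umol m-2 s-1).
#' @return daily dose (mmol m-2).
#' @export
sp_daily_dose <- function(sp_per_day, sp_duration_s, sp_par) {
  if (any(sp_duration_s < 0) || any(sp_par < 0) || any(sp_per_day < 0))
    stop("inputs must be non-negative")
  sp_per_day * sp_duration_s * sp_par / 1000
}

#' Goodness-of-fit diagnostics
#'
#' The statistics reported with every reference fit: R2 (squared Pearson
#' correlation of observed vs fitted), N, and RRMSE (root mean squared
#' error divided by the mean of the observed values, scale-invariant).
#' When the observations have zero variance the correlation is undefined
#' and R2 is reported as NA.
#'
#' @param observed,fitted equal-length numeric vectors (length >= 2).
#' @return list with `r2`, `n`, `rrmse`.
#' @export
diagnostic_stats <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2)
  n <- length(observed)
  r2 <- if (stats::sd(observed) == 0) NA_real_     # undefined: no signal
  else if (stats::sd(fitted) == 0) 0               # constant fit explains none
  else stats::cor(observed, fitted)^2
  rrmse <- sqrt(mean((observed - fitted)^2)) / mean(observed)
  list(r2 = r2, n = n, rrmse = rrmse)
}

#' Run the full processing pipeline
#'
#' Read (or accept) a dataset, optionally temperature-correct it, classify
#' day/night, run the artifact filter cascade, fit the seasonal
#' references, and compute the diurnal and seasonal parameter tables plus
#' per-day phase labels. Optionally writes every table to a directory
#' along with a run log, so each figure and number is regenerable from
#' exported text.
#'
#' @param input a [pam_dataset], or a file path read with `dialect`.
#' @param dialect a [pam_dialect] (when `input` is a path).
#' @param temp_model optional [ml_temp_model][fit_temperature_model]; the
#'   default applies no correction.
#' @param config a [filter_config()].
#' @param ref_form `"hyperbolic"` or `"linear"` reference regression.
#' @param fvfm_ref reference Fv/Fm.
#' @param breakpoints optional Date vector for segmented references.
#' @param c_psi PSI contribution used in PhiP.
#' @param out_dir optional output directory for the exported tables.
#' @return list of class `pam_pipeline` with `dataset`, `windows`,
#'   `summaries`, `filter_report`, `reference`, `diurnal`, `seasonal`,
#'   `phases` (per head x date segment labels), `log` (character).
#' @export
run_pipeline <- function(input, dialect = pam_dialect(),
                         temp_model = NULL,
                         config = filter_config(),
                         ref_form = c("hyperbolic", "linear"),
                         fvfm_ref = 0.83,
                         breakpoints = NULL,
                         c_psi = 0, out_dir = NULL) {
  ref_form <- match.arg(ref_form)
  log <- character(0)
  say <- function(...) log <<- c(log, paste0(...))
  dataset <- if (inherits(input, "pam_dataset")) input
  else read_pam(input, dialect)
  say("records read: ", n_records(dataset))
  if (!is.null(temp_model)) {
    dataset <- correct_f(dataset, temp_model)
    say("ML temperature correction applied (ref ",
        temp_model$ref_temp_c, " C)")
  } else say("no ML temperature correction (identity)")

  fl <- apply_filters(dataset, config)
  dataset <- fl$dataset
  say("filter retained fraction: ",
      sprintf("%.4f", fl$report$retained_fraction))
  for (cd in names(fl$report$counts))
    if (fl$report$counts[[cd]] > 0)
      say("  flag ", cd, ": ", fl$report$counts[[cd]])

  summaries <- nightly_summary(dataset, fl$windows, n_min = config$n_min)
  say("night windows: ", nrow(fl$windows), "; usable nights: ",
      sum(summaries$qc_ok))

  ref <- if (!is.null(breakpoints) && length(breakpoints) > 0) {
    segment_references(summaries, as.Date(breakpoints),
                       form = ref_form, fvfm_ref = fvfm_ref)
  } else {
    fits <- lapply(split(summaries, summaries$head_id), function(s) {
      tryCatch(fit_fm_vs_fvfm(s, form = ref_form, fvfm_ref = fvfm_ref),
               error = function(e) {
                 say("reference fit fell back to max_observed: ",
                     conditionMessage(e))
                 max_observed_reference(s, fvfm_ref = fvfm_ref)
               })
    })
    if (length(fits) == 1) fits[[1]] else {
      rows <- do.call(rbind, lapply(names(fits), function(h) {
        f <- fits[[h]]
        data.frame(head_id = h,
                   start = min(summaries$night_date),
                   end = max(summaries$night_date),
                   form = f$form, fmr = f$fmr, f0r = f$f0r,
                   r2 = f$r2, n = f$n, rrmse = f$rrmse,
                   stringsAsFactors = FALSE)
      }))
      attr(rows, "fits") <- stats::setNames(fits, paste0(names(fits), "/1"))
      class(rows) <- c("reference_periods", class(rows))
      rows
    }
  }
  if (inherits(ref, "fmr_fit"))
    say(sprintf("reference fit (%s): FmR = %.1f mV, R2 = %.3f, N = %d, RRMSE = %.3f",
                ref$form, ref$fmr, ref$r2, ref$n, ref$rrmse))

  diurnal <- diurnal_params(dataset, summaries, ref, c_psi = c_psi)
  seasonal <- seasonal_params(summaries, ref)
  say("diurnal records: ", nrow(diurnal),
      "; seasonal nights: ", nrow(seasonal))

  phases <- do.call(rbind, lapply(
    split(diurnal, list(diurnal$head_id,
                        as.Date(diurnal$timestamp, tz = "UTC")),
          drop = TRUE),
    function(dd) {
      dd <- dd[stats::complete.cases(dd[, c("pq_t", "npq_t")]), ]
      if (nrow(dd) < 3) return(NULL)
      ph <- suppressMessages(classify_phases(dd))
      if (nrow(ph) == 0) return(NULL)
      data.frame(head_id = dd$head_id[1],
                 date = as.Date(dd$timestamp[1], tz = "UTC"),
                 sequence = paste(phase_sequence(ph), collapse = ">"),
                 stringsAsFactors = FALSE)
    }))

  out <- structure(list(dataset = dataset, windows = fl$windows,
                        summaries = summaries,
                        filter_report = fl$report, reference = ref,
                        diurnal = diurnal, seasonal = seasonal,
                        phases = phases, log = log),
                   class = "pam_pipeline")
  if (!is.null(out_dir)) export_pipeline(out, out_dir)
  out
}

#' @export
print.pam_pipeline <- function(x, ...) {
  cat("<pam_pipeline>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Export every pipeline table as delimited text
#'
#' @param pipeline a [run_pipeline()] result.
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
export_pipeline <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (is.null(df) || nrow(df) == 0) return(invisible(NULL))
    df <- as.data.frame(df)
    if ("timestamp" %in% names(df))
      df$timestamp <- format(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_pam(pipeline$dataset, file.path(out_dir, "records_flagged.csv"))
  wt(pipeline$windows, "night_windows")
  wt(as.data.frame(pipeline$summaries), "night_summaries")
  wt(pipeline$diurnal, "diurnal_params")
  wt(pipeline$seasonal, "seasonal_params")
  wt(pipeline$phases, "phase_labels")
  if (inherits(pipeline$reference, "fmr_fit")) {
    wt(fmr_fit_table(pipeline$reference), "reference_fit")
  } else wt(as.data.frame(pipeline$reference), "reference_fit")
  rep <- pipeline$filter_report
  writeLines(c(paste0("retained_fraction=", rep$retained_fraction),
               paste0(names(rep$counts), "=", rep$counts),
               pipeline$log),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
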