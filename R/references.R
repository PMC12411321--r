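#' Estimate seasonal reference fluorescence levels from nightly summaries
#'
#' The seasonal references FmR and F0R are the Fm and F0 expected in the
#' absence of sustained NPQ and photoinhibition; every seasonal quenching
#' parameter is expressed against them. They are estimated by regressing
#' nightly Fm on nightly Fv/Fm and evaluating the fit at a reference
#' Fv/Fm (default 0.83, after Bjorkman and Demmig).
#'
#' Two forms are offered. The default `"hyperbolic"`, Fm = a x/(1 - x)
#' with x = Fv/Fm, is what the lake model implies at constant
#' photochemical capacity: with Fm proportional to 1/(1 + NPQ) and
#' x = PQ/(1 + PQ + NPQ), eliminating NPQ at fixed PQ gives
#' Fm proportional to x/(1 - x). `"linear"` (Fm = a + b x) is kept as the
#' simpler alternative. Only `qc_ok` nights enter the fit.
#'
#' @param summaries a [nightly_summary()] table (one head).
#' @param form `"hyperbolic"` or `"linear"`.
#' @param fvfm_ref reference Fv/Fm at which FmR is read off the fit.
#' @param min_n minimum number of usable nights.
#' @return An object of class `fmr_fit` with fields `form`, `params`,
#'   `r2` (squared Pearson correlation of observed vs fitted Fm), `n`,
#'   `rrmse` (RMSE / mean observed Fm), `fvfm_ref`, `fmr` (mV),
#'   `f0r = fmr (1 - fvfm_ref)` (mV), plus the underlying `lm` fit and the
#'   points used. Standard methods (`print`, `summary`, `coef`, `predict`,
#'   `fitted`, `residuals`, `plot`) apply.
#' @export
fit_fm_vs_fvfm <- function(summaries, form = c("hyperbolic", "linear"),
                           fvfm_ref = 0.83, min_n = 5) {
  form <- match.arg(form)
  stopifnot(fvfm_ref > 0, fvfm_ref < 1)
  s <- summaries[summaries$qc_ok & !is.na(summaries$fvfm), , drop = FALSE]
  if (nrow(s) < min_n)
    stop("fit error: only ", nrow(s), " usable nights (need ", min_n, ")")
  if (any(s$fvfm <= 0 | s$fvfm >= 1))
    stop("fit error: fvfm values outside (0, 1)")
  if (diff(range(s$fvfm)) < 0.02)
    stop("fit error: degenerate Fv/Fm spread (range < 0.02); ",
         "consider max_observed_reference() instead")
  x <- s$fvfm; y <- s$fm
  if (form == "hyperbolic") {
    tt <- x / (1 - x)
    fit <- stats::lm(y ~ 0 + tt)
    fmr <- unname(stats::coef(fit)[1]) * fvfm_ref / (1 - fvfm_ref)
    params <- c(a = unname(stats::coef(fit)[1]))
  } else {
    fit <- stats::lm(y ~ x)
    fmr <- unname(stats::predict(fit, data.frame(x = fvfm_ref)))
    params <- c(a = unname(stats::coef(fit)[1]),
                b = unname(stats::coef(fit)[2]))
  }
  fitted_y <- unname(stats::fitted(fit))
  stats_ <- diagnostic_stats(y, fitted_y)
  if (fmr <= 0) stop("fit error: non-positive FmR")
  structure(list(form = form, params = params,
                 r2 = stats_$r2, n = stats_$n, rrmse = stats_$rrmse,
                 fvfm_ref = fvfm_ref, fmr = fmr,
                 f0r = fmr * (1 - fvfm_ref),
                 model = fit,
                 data = data.frame(fvfm = x, fm = y,
                                   night_date = s$night_date)),
            class = "fmr_fit")
}

#' Fallback reference from the highest observed nights
#'
#' When the Fv/Fm spread is too narrow for a regression, FmR can be taken
#' as the mean of the `top_k` highest nightly Fm values — the nights
#' closest to the unquenched state.
#'
#' @param summaries a [nightly_summary()] table.
#' @param top_k number of top nights to average.
#' @param fvfm_ref reference Fv/Fm used to derive F0R.
#' @return An `fmr_fit` with `form = "max_observed"` (no regression
#'   diagnostics).
#' @export
max_observed_reference <- function(summaries, top_k = 5, fvfm_ref = 0.83) {
  s <- summaries[summaries$qc_ok, , drop = FALSE]
  if (nrow(s) < top_k)
    stop("need at least top_k = ", top_k, " usable nights")
  fmr <- mean(utils::head(sort(s$fm, decreasing = TRUE), top_k))
  structure(list(form = "max_observed", params = c(top_k = top_k),
                 r2 = NA_real_, n = top_k, rrmse = NA_real_,
                 fvfm_ref = fvfm_ref, fmr = fmr,
                 f0r = fmr * (1 - fvfm_ref),
                 model = NULL,
                 data = data.frame(fvfm = s$fvfm, fm = s$fm,
                                   night_date = s$night_date)),
            class = "fmr_fit")
}

#' Construct a reference from externally known levels
#'
#' Wraps a known FmR (e.g. from a previous campaign, or a simulator's
#' generating value) in the reference-fit container so it can drive the
#' parameter computations; `f0r = fmr (1 - fvfm_ref)`.
#'
#' @param fmr reference maximal fluorescence (mV).
#' @param fvfm_ref reference Fv/Fm.
#' @return An `fmr_fit` with `form = "manual"`.
#' @export
manual_reference <- function(fmr, fvfm_ref = 0.83) {
  stopifnot(fmr > 0, fvfm_ref > 0, fvfm_ref < 1)
  structure(list(form = "manual", params = c(fmr = fmr),
                 r2 = NA_real_, n = 0L, rrmse = NA_real_,
                 fvfm_ref = fvfm_ref, fmr = fmr,
                 f0r = fmr * (1 - fvfm_ref), model = NULL,
                 data = data.frame(fvfm = numeric(), fm = numeric(),
                                   night_date = as.Date(character()))),
            class = "fmr_fit")
}

#' @export
print.fmr_fit <- function(x, ...) {
  cat("<fmr_fit> form = ", x$form, ", n = ", x$n, "\n", sep = "")
  cat(sprintf("  FmR = %.2f mV at Fv/Fm_ref = %.2f;  F0R = %.2f mV\n",
              x$fmr, x$fvfm_ref, x$f0r))
  if (!is.na(x$r2))
    cat(sprintf("  R2 = %.4f, RRMSE = %.4f\n", x$r2, x$rrmse))
  invisible(x)
}

#' @export
summary.fmr_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$model)) {
    cat("underlying regression:\n")
    print(summary(object$model))
  }
  invisible(object)
}

#' @export
coef.fmr_fit <- function(object, ...) object$params

#' Predict nightly Fm at given Fv/Fm from a reference fit
#' @param object an `fmr_fit`.
#' @param newdata numeric vector of Fv/Fm values, or a data.frame with a
#'   `fvfm` column; defaults to the fitted points.
#' @param ... unused.
#' @return predicted Fm (mV).
#' @export
predict.fmr_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$fvfm
  else if (is.data.frame(newdata)) newdata$fvfm
  else as.numeric(newdata)
  switch(object$form,
         hyperbolic = object$params[["a"]] * x / (1 - x),
         linear = object$params[["a"]] + object$params[["b"]] * x,
         max_observed = rep(object$fmr, length(x)),
         manual = rep(object$fmr, length(x)))
}

#' @export
fitted.fmr_fit <- function(object, ...) predict(object)

#' @export
residuals.fmr_fit <- function(object, ...)
  object$data$fm - predict(object)

#' Diagnostic plot of a reference fit
#'
#' Nightly Fm against Fv/Fm with the fitted curve, plus dashed lines at
#' the reference Fv/Fm (vertical) and the estimated FmR (horizontal).
#'
#' @param x an `fmr_fit`.
#' @param ... passed to [graphics::plot].
#' @export
plot.fmr_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$fvfm, d$fm, xlab = "Fv/Fm", ylab = "Fm (mV)",
                 main = sprintf("FmR fit (%s): FmR = %.0f mV", x$form, x$fmr),
                 ...)
  xx <- seq(min(d$fvfm), max(x$fvfm_ref, max(d$fvfm)), length.out = 200)
  graphics::lines(xx, predict(x, xx))
  graphics::abline(v = x$fvfm_ref, lty = 2)
  graphics::abline(h = x$fmr, lty = 2)
  invisible(x)
}

#' Table export of a reference fit (plot-data parity)
#'
#' @param x an `fmr_fit`.
#' @return data.frame with the observed points and fitted values, so the
#'   diagnostic figure can be regenerated outside R graphics.
#' @export
fmr_fit_table <- function(x) {
  data.frame(night_date = x$data$night_date, fvfm = x$data$fvfm,
             fm = x$data$fm, fitted = predict(x),
             fvfm_ref = x$fvfm_ref, fmr = x$fmr, f0r = x$f0r,
             form = x$form)
}

#' Fit per-segment references over user-chosen breakpoints
#'
#' When sample geometry, absorption or PSI contribution shift during a
#' campaign, a single FmR is no longer valid; the dataset can be divided
#' at explicit breakpoints, each segment getting its own reference fit.
#' Segmentation is deliberately user-driven (no automatic changepoint
#' search): subsets without a clear rationale obscure real regulatory
#' dynamics, so a warning is issued when adjacent FmR levels differ by
#' less than 5%.
#'
#' @param summaries a [nightly_summary()] table.
#' @param breakpoints sorted Date vector strictly inside the data span;
#'   each breakpoint starts a new segment.
#' @param form,fvfm_ref,min_n passed to [fit_fm_vs_fvfm()].
#' @return data.frame of class `reference_periods` with one row per
#'   head x segment: `head_id`, `start`, `end`, `form`, `fmr`, `f0r`,
#'   `r2`, `n`, `rrmse`; the `fmr_fit` objects are attached as the
#'   `"fits"` attribute (list keyed `head/segment`).
#' @export
segment_references <- function(summaries, breakpoints = as.Date(character()),
                               form = c("hyperbolic", "linear"),
                               fvfm_ref = 0.83, min_n = 5) {
  form <- match.arg(form)
  breakpoints <- sort(as.Date(breakpoints))
  span <- range(summaries$night_date)
  if (length(breakpoints) > 0 &&
      (any(breakpoints <= span[1]) || any(breakpoints > span[2])))
    stop("breakpoint(s) outside the data span ", span[1], " .. ", span[2])
  edges <- c(span[1], breakpoints, span[2] + 1)
  rows <- list(); fits <- list()
  for (h in unique(summaries$head_id)) {
    sh <- summaries[summaries$head_id == h, , drop = FALSE]
    for (g in seq_len(length(edges) - 1)) {
      seg <- sh[sh$night_date >= edges[g] & sh$night_date < edges[g + 1], ,
                drop = FALSE]
      fit <- tryCatch(
        fit_fm_vs_fvfm(seg, form = form, fvfm_ref = fvfm_ref, min_n = min_n),
        error = function(e)
          stop("segment ", g, " (", edges[g], " .. ", edges[g + 1] - 1,
               "), head ", h, ": ", conditionMessage(e), call. = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        head_id = h, start = edges[g], end = edges[g + 1] - 1,
        form = fit$form, fmr = fit$fmr, f0r = fit$f0r,
        r2 = fit$r2, n = fit$n, rrmse = fit$rrmse,
        stringsAsFactors = FALSE)
      fits[[paste0(h, "/", g)]] <- fit
    }
    fmrs <- vapply(rows[vapply(rows, function(x) x$head_id == h, logical(1))],
                   function(x) x$fmr, numeric(1))
    if (length(fmrs) > 1 &&
        any(abs(diff(fmrs)) / utils::head(fmrs, -1) < 0.05))
      warning("adjacent FmR levels for head ", h,
              " differ by < 5%; consider fewer segments")
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("reference_periods", class(out))
  out
}

#' Look up the reference covering each date
#'
#' @param ref an `fmr_fit` (single period) or a
#'   [segment_references()] table.
#' @param head_id,dates record head and dates to resolve.
#' @return data.frame with `fmr`, `f0r`, `fvfm_ref` per date (NA when no
#'   period covers a date).
#' @export
reference_for <- function(ref, head_id, dates) {
  n <- length(dates)
  if (inherits(ref, "fmr_fit"))
    return(data.frame(fmr = rep(ref$fmr, n), f0r = rep(ref$f0r, n),
                      fvfm_ref = rep(ref$fvfm_ref, n)))
  stopifnot(inherits(ref, "reference_periods"))
  fits <- attr(ref, "fits")
  fmr <- f0r <- fvr <- rep(NA_real_, n)
  for (k in seq_len(nrow(ref))) {
    sel <- head_id == ref$head_id[k] &
      dates >= ref$start[k] & dates <= ref$end[k]
    fmr[sel] <- ref$fmr[k]; f0r[sel] <- ref$f0r[k]
    key <- names(fits)[startsWith(names(fits), paste0(ref$head_id[k], "/"))][1]
    fvr[sel] <- if (!is.null(fits[[key]])) fits[[key]]$fvfm_ref else 0.83
  }
  data.frame(fmr = fmr, f0r = f0r, fvfm_ref = fvr)
}
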