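#' Fit a measuring-light temperature-response model
#'
#' LED output is temperature dependent (blue LEDs change by roughly 2%
#' between 20 and -20 deg C; red/amber LEDs by far more), which propagates
#' multiplicatively into recorded F' and Fm'. Given climate-chamber
#' calibration readings on a physiologically stable target, this fits a
#' low-order polynomial to the relative ML-output factor c(T) per channel,
#' renormalised so c(`ref_temp_c`) = 1 exactly. The temperature response of
#' the F' and Fm' channels may differ slightly, so each is fitted
#' separately.
#'
#' @param temp_c calibration temperatures (deg C); at least `degree + 2`
#'   distinct values.
#' @param f_prime,fm_prime signals (mV) recorded at `temp_c`.
#' @param ref_temp_c temperature to which signals are normalised.
#' @param degree polynomial degree (1 or 2; default 1).
#' @return An object of class `ml_temp_model`: `ref_temp_c`, `coeffs_f`,
#'   `coeffs_fm` (ascending-power polynomial coefficients of c(T)),
#'   `degree`, `valid_range` (range of calibration temperatures) and
#'   `residuals` (per-channel RMS of the relative-signal fit).
#' @export
fit_temperature_model <- function(temp_c, f_prime, fm_prime,
                                  ref_temp_c = 20, degree = 1) {
  stopifnot(degree %in% c(0, 1, 2),
            length(temp_c) == length(f_prime),
            length(temp_c) == length(fm_prime))
  if (length(unique(temp_c)) < degree + 2)
    stop("fit error: need at least ", degree + 2,
         " distinct calibration temperatures")
  if (any(f_prime <= 0) || any(fm_prime <= 0))
    stop("calibration signals must be positive")
  fit_channel <- function(sig) {
    X <- outer(temp_c, 0:degree, `^`)
    co <- stats::lm.fit(X, sig)$coefficients
    co[is.na(co)] <- 0
    at_ref <- sum(co * ref_temp_c^(0:degree))
    if (at_ref <= 0) stop("fit error: fitted signal non-positive at ref_temp_c")
    co_rel <- co / at_ref            # c(ref_temp_c) = 1 exactly
    fitted <- as.numeric(X %*% co)
    list(coeffs = unname(co_rel),
         rms = sqrt(mean((sig / at_ref - fitted / at_ref)^2)))
  }
  chf <- fit_channel(f_prime)
  chfm <- fit_channel(fm_prime)
  m <- structure(list(ref_temp_c = ref_temp_c,
                      coeffs_f = chf$coeffs, coeffs_fm = chfm$coeffs,
                      degree = degree,
                      valid_range = range(temp_c),
                      residuals = c(f = chf$rms, fm = chfm$rms)),
                 class = "ml_temp_model")
  rng <- ml_temp_factor(m, seq(m$valid_range[1], m$valid_range[2],
                               length.out = 50))
  if (any(rng$c_f <= 0) || any(rng$c_fm <= 0))
    stop("fit error: correction factor non-positive inside valid range")
  m
}

#' Identity measuring-light temperature model
#'
#' c(T) = 1 for both channels over any temperature: correction with this
#' model leaves the data unchanged. ML fluctuations below 1% are generally
#' considered acceptable, so no correction is the default posture unless a
#' fitted model is supplied.
#'
#' @param valid_range temperatures accepted by [correct_f()].
#' @return An `ml_temp_model`.
#' @export
ml_temp_identity <- function(valid_range = c(-50, 50)) {
  structure(list(ref_temp_c = 20, coeffs_f = 1, coeffs_fm = 1,
                 degree = 0, valid_range = valid_range,
                 residuals = c(f = 0, fm = 0)),
            class = "ml_temp_model")
}

#' Evaluate the relative ML-output factors of a temperature model
#'
#' @param model an `ml_temp_model`.
#' @param temp_c temperatures (deg C).
#' @return data.frame with columns `c_f`, `c_fm`.
#' @export
ml_temp_factor <- function(model, temp_c) {
  ev <- function(co) {
    p <- seq_along(co) - 1
    as.numeric(outer(temp_c, p, `^`) %*% co)
  }
  data.frame(c_f = ev(model$coeffs_f), c_fm = ev(model$coeffs_fm))
}

#' @export
print.ml_temp_model <- function(x, ...) {
  cat("<ml_temp_model> degree ", x$degree, ", c(", x$ref_temp_c,
      " C) = 1, valid ", x$valid_range[1], "..", x$valid_range[2], " C\n",
      sep = "")
  cat("  c_F(T) coeffs: ", paste(signif(x$coeffs_f, 6), collapse = ", "),
      "\n  c_FM(T) coeffs: ", paste(signif(x$coeffs_fm, 6), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Temperature-correct F' and Fm' for measuring-light output
#'
#' Divides each record's F' and Fm' by the model's relative ML-output
#' factor at the record temperature, so signals recorded at different
#' temperatures are comparable. Division (not subtraction) because the ML
#' effect is multiplicative on the emitted/returned signal. Raw values are
#' retained in `f_prime_raw` / `fm_prime_raw`; the correction is recorded
#' in the dataset metadata and refuses to run twice. Records whose
#' temperature is missing or outside the model's valid range are flagged
#' `TEMP_RANGE` and left uncorrected. With identical per-channel factors
#' the quantum yield of photochemistry (1 - F'/Fm') is unchanged by the
#' correction.
#'
#' @param dataset a [pam_dataset].
#' @param model an [ml_temp_model][fit_temperature_model].
#' @return The corrected [pam_dataset].
#' @export
correct_f <- function(dataset, model) {
  stopifnot(inherits(dataset, "pam_dataset"),
            inherits(model, "ml_temp_model"))
  if (isTRUE(dataset$metadata$ml_temp_corrected))
    stop("refusal: dataset is already ML-temperature corrected")
  r <- dataset$records
  r$f_prime_raw <- r$f_prime
  r$fm_prime_raw <- r$fm_prime
  out_of_range <- is.na(r$temp_c) |
    r$temp_c < model$valid_range[1] | r$temp_c > model$valid_range[2]
  ok <- !out_of_range
  fac <- ml_temp_factor(model, r$temp_c[ok])
  r$f_prime[ok] <- r$f_prime[ok] / fac$c_f
  r$fm_prime[ok] <- r$fm_prime[ok] / fac$c_fm
  r$flags[out_of_range] <- flag_add(r$flags[out_of_range], "TEMP_RANGE")
  dataset$records <- r
  dataset$metadata$ml_temp_corrected <- TRUE
  dataset$metadata$ml_temp_model <- list(ref_temp_c = model$ref_temp_c,
                                         coeffs_f = model$coeffs_f,
                                         coeffs_fm = model$coeffs_fm)
  dataset
}

#' Serialise / restore an ML temperature model
#'
#' The model is stored as a small JSON block (reference temperature,
#' per-channel coefficients, valid range) so a correction fitted once in a
#' climate chamber can be reused across campaigns.
#'
#' @param model an `ml_temp_model`.
#' @param path file path.
#' @return `ml_temp_model_write()` returns `path` invisibly;
#'   `ml_temp_model_read()` returns the model.
#' @export
ml_temp_model_write <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ml_temp_model_write
#' @export
ml_temp_model_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(ref_temp_c = x$ref_temp_c,
                 coeffs_f = as.numeric(x$coeffs_f),
                 coeffs_fm = as.numeric(x$coeffs_fm),
                 degree = x$degree,
                 valid_range = as.numeric(x$valid_range),
                 residuals = unlist(x$residuals)),
            class = "ml_temp_model")
}
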