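#' Maximum photochemical quenching
#'
#' PQ_max is the intrinsic rate constant of photochemistry in open,
#' functional PSII centers relative to the sum of the fluorescence and
#' constitutive-dissipation rate constants. It is fixed by the reference
#' maximum photochemical yield:
#' PQ_max = (Fv/Fm)_R / (1 - (Fv/Fm)_R) = FmR/F0R - 1. For the widely used
#' reference Fv/Fm = 0.83 it equals 4.88.
#'
#' @param fvfm_ref reference Fv/Fm in (0, 1).
#' @return PQ_max (dimensionless).
#' @export
pq_max <- function(fvfm_ref) {
  if (any(fvfm_ref <= 0 | fvfm_ref >= 1))
    stop("fvfm_ref must lie strictly in (0, 1)")
  fvfm_ref / (1 - fvfm_ref)
}

#' Quantum yield of photochemistry
#'
#' PhiP = (Fm' - F') / (Fm' - C_PSI). With the PSI contribution C_PSI = 0
#' (the default; no practical field protocol exists to estimate it) this
#' reduces to 1 - F'/Fm'.
#'
#' @param f F' (mV).
#' @param fm Fm' (mV), `fm >= f`.
#' @param c_psi PSI contribution to the signal (mV), `c_psi < fm`.
#' @return PhiP (dimensionless).
#' @export
phi_p <- function(f, fm, c_psi = 0) {
  if (any(fm <= c_psi)) stop("domain error: fm must exceed c_psi")
  if (any(fm < f)) stop("domain error: fm must be >= f")
  (fm - f) / (fm - c_psi)
}

#' Quantum yield of sustained NPQ from a daytime record
#'
#' PhiNPQ_s is normally a nighttime quantity (F0/Fm - F0/FmR) but can be
#' evaluated in daytime by substituting the prevailing F':
#' F'/Fm - F'/FmR, with Fm the preceding night's maximal fluorescence.
#'
#' @param f prevailing F' (mV).
#' @param fm_night preceding-night Fm (mV), `fm_night <= fmr`.
#' @param fmr seasonal reference FmR (mV).
#' @return PhiNPQ_s (dimensionless).
#' @export
phi_npq_s_daytime <- function(f, fm_night, fmr) {
  if (any(f <= 0 | fm_night <= 0 | fmr <= 0))
    stop("domain error: inputs must be positive")
  if (any(fm_night > fmr))
    stop("domain error: fm_night must not exceed fmr")
  f / fm_night - f / fmr
}

#' Diurnal quenching arithmetic (vectorised core)
#'
#' The raw parameter algebra applied by [diurnal_params()], exposed for
#' direct use on vectors of fluorescence levels. All parameters are
#' dimensionless ratios of PAM levels, so they are invariant under a
#' common rescaling of every input, and they satisfy the exact identities
#' `phi_p + phi_npq_t + phi_fd = 1` (with `c_psi = 0`),
#' `npq_t = npq_r + npq_s` and `pq_t = ql_t x pq_max` (when
#' `f0r = fmr (1 - fvfm_ref)`).
#'
#' @param f,fm_prime record F' and Fm' (mV).
#' @param fm_night preceding-night Fm (mV).
#' @param fmr,f0r seasonal references (mV).
#' @param c_psi PSI contribution (mV), used in `phi_p` only.
#' @param phi_f_max theoretical maximal PSII fluorescence yield.
#' @return data.frame of the diurnal parameters (see [diurnal_params()]).
#' @export
diurnal_quench <- function(f, fm_prime, fm_night, fmr, f0r,
                           c_psi = 0, phi_f_max = 0.1) {
  out <- data.frame(
    phi_p = (fm_prime - f) / (fm_prime - c_psi),
    pq_t = fmr / f - fmr / fm_prime,
    ql_t = (1 / f - 1 / fm_prime) / (1 / f0r - 1 / fmr),
    npq_t = fmr / fm_prime - 1,
    npq_r = fmr / fm_prime - fmr / fm_night,
    phi_npq_t = f / fm_prime - f / fmr,
    phi_npq_r = f / fm_prime - f / fm_night,
    phi_fd = f / fmr)
  out$phi_f_est <- phi_f_max * out$phi_fd
  out
}

#' Seasonal quenching arithmetic (vectorised core)
#'
#' The nightly parameter algebra applied by [seasonal_params()]: exact
#' identities `phi_p_max + phi_npq_s + phi_fd_s = 1` and
#' `pq_s = ql_s x pq_max` (when `f0r = fmr (1 - fvfm_ref)`).
#'
#' @param f0,fm nightly minimal and maximal fluorescence (mV).
#' @param fmr,f0r seasonal references (mV).
#' @return data.frame of the seasonal parameters (see
#'   [seasonal_params()]).
#' @export
seasonal_quench <- function(f0, fm, fmr, f0r) {
  data.frame(
    phi_p_max = 1 - f0 / fm,
    pq_s = fmr / f0 - fmr / fm,
    ql_s = (1 / f0 - 1 / fm) / (1 / f0r - 1 / fmr),
    npq_s = fmr / fm - 1,
    phi_npq_s = f0 / fm - f0 / fmr,
    phi_fd_s = f0 / fmr)
}

# bind each record to the most recent night window that ended before it
.preceding_night <- function(records, summaries) {
  m <- rep(NA_integer_, nrow(records))
  for (h in unique(records$head_id)) {
    ri <- which(records$head_id == h)
    sh <- which(summaries$head_id == h)
    if (length(sh) == 0) next
    sdates <- summaries$night_date[sh]
    o <- order(sdates)
    sh <- sh[o]; sdates <- sdates[o]
    rd <- as.Date(records$timestamp[ri], tz = "UTC")
    pos <- findInterval(as.numeric(rd), as.numeric(sdates))
    ok <- pos >= 1
    m[ri[ok]] <- sh[pos[ok]]
  }
  m
}

#' Diurnal quenching and yield parameters
#'
#' Computes, per accepted record, the full diurnal parameter set against
#' the preceding night's Fm and the seasonal references FmR / F0R:
#' \describe{
#'   \item{phi_p}{PhiP = 1 - F'/Fm' (C_PSI = 0 by default)}
#'   \item{pq_t}{total photochemical quenching, FmR/F' - FmR/Fm'}
#'   \item{ql_t}{total open-and-functional PSII fraction,
#'     (1/F' - 1/Fm') / (1/F0R - 1/FmR)}
#'   \item{npq_t}{total non-photochemical quenching, FmR/Fm' - 1}
#'   \item{npq_r}{reversible NPQ, FmR/Fm' - FmR/Fm}
#'   \item{phi_npq_t}{F'/Fm' - F'/FmR}
#'   \item{phi_npq_r}{F'/Fm' - F'/Fm}
#'   \item{phi_fd}{yield of fluorescence plus constitutive dissipation,
#'     F'/FmR}
#'   \item{phi_f_est}{PhiF estimate, 0.1 x phi_fd, assuming a theoretical
#'     maximal PSII fluorescence yield of 10%}
#' }
#' The algebra guarantees phi_p + phi_npq_t + phi_fd = 1,
#' npq_t = npq_r + npq_s (of the governing night) and
#' pq_t = ql_t x pq_max. A record whose preceding night is missing or
#' failed QC gets NA parameters (never fabricated). The "preceding night"
#' of a record is the night window that ended most recently before it.
#'
#' @param dataset a filtered [pam_dataset].
#' @param summaries a [nightly_summary()] table.
#' @param ref an `fmr_fit` or [segment_references()] table.
#' @param c_psi PSI signal contribution (mV) used in `phi_p` only.
#' @param phi_f_max theoretical maximal PSII fluorescence yield.
#' @return data.frame with `timestamp`, `head_id`, `par`, `day_night`
#'   (when present), the parameters above, and `y_ii` as an alias of
#'   `phi_p` for instrument-output consistency.
#' @export
diurnal_params <- function(dataset, summaries, ref, c_psi = 0,
                           phi_f_max = 0.1) {
  r <- dataset$records
  keep <- is_accepted(r$flags) & !is.na(r$f_prime) & !is.na(r$fm_prime)
  r <- r[keep, , drop = FALSE]
  ni <- .preceding_night(r, summaries)
  ok_night <- !is.na(ni) & summaries$qc_ok[ifelse(is.na(ni), 1L, ni)]
  fm_night <- ifelse(ok_night, summaries$fm[ni], NA_real_)
  refs <- reference_for(ref, r$head_id, as.Date(r$timestamp, tz = "UTC"))
  fmr <- refs$fmr; f0r <- refs$f0r
  q <- diurnal_quench(r$f_prime, r$fm_prime, fm_night, fmr, f0r,
                      c_psi = c_psi, phi_f_max = phi_f_max)
  out <- cbind(data.frame(timestamp = r$timestamp, head_id = r$head_id,
                          par = r$par, stringsAsFactors = FALSE), q)
  if (!is.null(r$day_night)) out$day_night <- r$day_night
  out$y_ii <- out$phi_p
  out
}

#' Seasonal quenching and yield parameters
#'
#' Computes, per usable night, the seasonal parameter set against the
#' references FmR / F0R:
#' \describe{
#'   \item{phi_p_max}{Fv/Fm = 1 - F0/Fm}
#'   \item{pq_s}{sustained photochemical quenching, FmR/F0 - FmR/Fm}
#'   \item{ql_s}{fraction of functional PSII centers,
#'     (1/F0 - 1/Fm) / (1/F0R - 1/FmR)}
#'   \item{npq_s}{sustained NPQ, FmR/Fm - 1}
#'   \item{phi_npq_s}{F0/Fm - F0/FmR}
#'   \item{phi_fd_s}{F0/FmR}
#' }
#' At night the yields close exactly: phi_p_max + phi_npq_s + phi_fd_s = 1.
#'
#' @param summaries a [nightly_summary()] table.
#' @param ref an `fmr_fit` or [segment_references()] table.
#' @return data.frame with `night_date`, `head_id` and the parameters
#'   above; nights failing QC are omitted.
#' @export
seasonal_params <- function(summaries, ref) {
  s <- summaries[summaries$qc_ok, , drop = FALSE]
  refs <- reference_for(ref, s$head_id, s$night_date)
  cbind(data.frame(night_date = s$night_date, head_id = s$head_id,
                   f0 = s$f0, fm = s$fm, stringsAsFactors = FALSE),
        seasonal_quench(s$f0, s$fm, refs$fmr, refs$f0r))
}
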