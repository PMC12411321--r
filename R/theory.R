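#' Instrument and leaf optical constants of the fluorescence forward model
#'
#' The constants of the forward equations for F' and Fm': the measuring
#' light PAR at the leaf (`par_ml`), leaf absorptance (`a_leaf`), fraction
#' of absorbed light reaching PSII (`alpha_ii`), the escape x area x
#' sensitivity clump `beta` (mV m2 umol-1 s), the PSI signal contribution
#' `c_psi` (mV, pulse-insensitive), and the first-order rate constants
#' (s-1) for fluorescence (`k_f`), constitutive thermal dissipation
#' (`k_d`), sustained and reversible NPQ (`k_npqs`, `k_npqr`) and intrinsic
#' photochemistry in open functional centers (`k_psii`). These constants
#' are never individually identifiable from monitoring data; the forward
#' model exists for simulation and testing, while inversion works in
#' (pq, npq) space only.
#'
#' @param par_ml,a_leaf,alpha_ii,beta,c_psi,k_f,k_d,k_npqs,k_npqr,k_psii
#'   see description. Defaults give k_f/(k_f + k_d) = 0.1 (a theoretical
#'   maximal PSII fluorescence yield of 10%) and k_psii/(k_f + k_d) = 4.88
#'   (PQ_max at reference Fv/Fm 0.83).
#' @return list of class `optical_constants`.
#' @export
optical_constants <- function(par_ml = 1, a_leaf = 0.84, alpha_ii = 0.5,
                              beta = 11904.76190476190, c_psi = 0,
                              k_f = 0.1, k_d = 0.9,
                              k_npqs = 0, k_npqr = 0, k_psii = 4.88) {
  stopifnot(par_ml > 0, beta > 0, a_leaf >= 0, a_leaf <= 1,
            alpha_ii >= 0, alpha_ii <= 1, k_f > 0,
            k_d >= 0, k_npqs >= 0, k_npqr >= 0, k_psii >= 0, c_psi >= 0)
  structure(list(par_ml = par_ml, a_leaf = a_leaf, alpha_ii = alpha_ii,
                 beta = beta, c_psi = c_psi, k_f = k_f, k_d = k_d,
                 k_npqs = k_npqs, k_npqr = k_npqr, k_psii = k_psii),
            class = "optical_constants")
}

#' Quenching state of a leaf
#'
#' PQ and NPQ expressed as rate constants relative to (k_f + k_d), the
#' Stern-Volmer framing: pq = ql_s ql_r k_psii / (k_f + k_d) and
#' npq = (k_npqs + k_npqr) / (k_f + k_d). When constructed from openness /
#' functionality fractions and constants, pq is derived; otherwise it can
#' be given directly.
#'
#' @param pq,npq relative rate constants (>= 0). `pq` may be omitted when
#'   `ql_r`, `ql_s` and `constants` are supplied.
#' @param ql_r,ql_s reversible (openness) and sustained (functionality)
#'   fractions of PSII centers in `[0, 1]`.
#' @param phi_f_max theoretical maximal PSII fluorescence yield.
#' @param constants an [optical_constants()] used to derive `pq`/`npq`
#'   from the k's when not given.
#' @return list of class `quench_state`.
#' @export
quench_state <- function(pq = NULL, npq = NULL, ql_r = NA_real_,
                         ql_s = NA_real_, phi_f_max = 0.1,
                         constants = NULL) {
  if (!is.null(constants)) {
    base <- constants$k_f + constants$k_d
    if (is.null(pq)) {
      stopifnot(!is.na(ql_r), !is.na(ql_s))
      pq <- ql_s * ql_r * constants$k_psii / base
    }
    if (is.null(npq)) npq <- (constants$k_npqs + constants$k_npqr) / base
  }
  stopifnot(!is.null(pq), !is.null(npq), all(pq >= 0), all(npq >= 0))
  if (any(!is.na(ql_r) & (ql_r < 0 | ql_r > 1)) ||
      any(!is.na(ql_s) & (ql_s < 0 | ql_s > 1)))
    stop("ql fractions must lie in [0, 1]")
  structure(list(pq = pq, npq = npq, ql_r = ql_r, ql_s = ql_s,
                 phi_f_max = phi_f_max),
            class = "quench_state")
}

#' Lake-model quantum yields from a quenching state
#'
#' Under the lake (connected-antenna) model the three yields are
#' PhiF = phi_f_max / (1 + NPQ + PQ), PhiFm = phi_f_max / (1 + NPQ),
#' PhiP = PQ / (1 + PQ + NPQ), with phi_f_max the theoretical maximal
#' PSII fluorescence yield (default 0.1).
#'
#' @param pq,npq relative rate constants, or a single [quench_state()] as
#'   `pq` with `npq` missing.
#' @param phi_f_max maximal fluorescence yield.
#' @return data.frame with `phi_f`, `phi_fm`, `phi_p` (vectorised).
#' @export
yields <- function(pq, npq = NULL, phi_f_max = 0.1) {
  if (inherits(pq, "quench_state")) {
    st <- pq; pq <- st$pq; npq <- st$npq; phi_f_max <- st$phi_f_max
  }
  data.frame(phi_f = phi_f_max / (1 + npq + pq),
             phi_fm = phi_f_max / (1 + npq),
             phi_p = pq / (1 + pq + npq))
}

#' Forward fluorescence signals from a quenching state
#'
#' The forward equations give the recorded PAM signals:
#' F'  = PAR_ML A alpha_II beta k_F /
#'       (k_F + k_D + k_NPQs + k_NPQr + qLs qLr k_PSII) + C_PSI
#' Fm' = PAR_ML A alpha_II beta k_F /
#'       (k_F + k_D + k_NPQs + k_NPQr) + C_PSI
#' where the NPQ rate constants are taken from the state's `npq` (only
#' their sum enters) and the photochemical sink from the state's openness
#' and functionality fractions with the constants' `k_psii`. With
#' `c_psi = 0` the ratio f/fm equals PhiF/PhiFm of [yields()].
#'
#' @param state a [quench_state()] with `ql_r`, `ql_s` set.
#' @param constants an [optical_constants()].
#' @return list with `f_prime`, `fm_prime` (mV).
#' @export
forward_f <- function(state, constants) {
  stopifnot(inherits(state, "quench_state"),
            inherits(constants, "optical_constants"))
  scale <- constants$par_ml * constants$a_leaf * constants$alpha_ii *
    constants$beta
  base <- constants$k_f + constants$k_d
  k_npq <- state$npq * base
  k_pq <- if (!anyNA(state$ql_r) && !anyNA(state$ql_s))
    state$ql_s * state$ql_r * constants$k_psii
  else state$pq * base
  list(f_prime = scale * constants$k_f / (base + k_npq + k_pq) +
         constants$c_psi,
       fm_prime = scale * constants$k_f / (base + k_npq) + constants$c_psi)
}

#' Invert measured PAM levels to quenching parameters
#'
#' Given a record's F' and Fm' and the seasonal references, the relative
#' rate constants follow directly from the quenching definitions:
#' npq = FmR/Fm' - 1 and pq = FmR/F' - FmR/Fm'. Feeding the result back
#' through [yields()] reproduces f/FmR x phi_f_max and fm/FmR x phi_f_max
#' (the consistency contract, exact at c_psi = 0).
#'
#' @param f,fm measured F' and Fm' (mV), `0 < f < fm`.
#' @param fmr seasonal reference FmR (mV). `fm` above `fmr` (beyond
#'   `tol`) is an error: the reference likely needs re-estimation, as
#'   signals may increase later in the season.
#' @param f0r optional F0R, only checked for ordering.
#' @param tol relative tolerance on the `fm <= fmr` check.
#' @return a [quench_state()] with `pq`, `npq` (fractions NA).
#' @export
invert_to_quench <- function(f, fm, fmr, f0r = NULL, tol = 1e-9) {
  if (any(f <= 0) || any(fm <= f))
    stop("domain error: need 0 < f < fm")
  if (any(fm > fmr * (1 + tol)))
    stop("fm exceeds the reference FmR: re-estimate the reference ",
         "(signals may increase later in the season, risking saturation)")
  if (!is.null(f0r) && any(f0r >= fmr))
    stop("domain error: f0r must be below fmr")
  quench_state(pq = fmr / f - fmr / fm, npq = fmr / fm - 1)
}

#' Iso-line grid of the yield space (plot data)
#'
#' Evaluates the lake-model yields over a PQ x NPQ grid, the backing table
#' for theoretical-domain figures.
#'
#' @param pq,npq numeric grids of relative rate constants.
#' @param phi_f_max maximal fluorescence yield.
#' @return data.frame over the full grid with `pq`, `npq`, `phi_f`,
#'   `phi_fm`, `phi_p`.
#' @export
yield_grid <- function(pq = seq(0, 5, by = 0.25),
                       npq = seq(0, 5, by = 0.25), phi_f_max = 0.1) {
  g <- expand.grid(pq = pq, npq = npq)
  cbind(g, yields(g$pq, g$npq, phi_f_max))
}

#' Classify the phases of a diurnal fluorescence-yield trajectory
#'
#' Diurnal PhiF-PhiP trajectories typically traverse up to three phases:
#' an initial photochemical phase (PQ1) where decreasing PQ dominates, an
#' NPQ phase where rising NPQ dominates, and a second photochemical phase
#' (PQ2) once NPQ capacity is saturated or inhibited. The labelling here
#' operationalises that taxonomy: for each consecutive segment the
#' relative changes d(pq)/(1 + pq) and d(npq)/(1 + npq) are compared; NPQ
#' is assigned when the npq term dominates by at least `dominance_ratio`,
#' otherwise PQ (PQ2 when an NPQ segment has already occurred or when
#' npq_t has reached `npq_saturation`); FLAT when both terms are below
#' `noise_floor`. Contiguous same-label segments merge. The labels are
#' invariant to uniform scaling of all fluorescence inputs, because pq_t
#' and npq_t are.
#'
#' @param trajectory data.frame for one day, time-ordered, with columns
#'   `pq_t` and `npq_t` (e.g. from [diurnal_params()]); at least 3 rows.
#' @param dominance_ratio factor by which the npq term must exceed the pq
#'   term to label a segment NPQ.
#' @param noise_floor relative change below which a segment is FLAT.
#' @param npq_saturation npq_t level above which a pq-dominated segment is
#'   the photoinhibitory PQ2 even without a preceding NPQ segment.
#' @return data.frame with one row per merged segment: `from`, `to` (row
#'   indices into `trajectory`), `label`. The per-step labels are attached
#'   as attribute `"steps"`. Use [phase_sequence()] for the condensed
#'   non-FLAT label sequence.
#' @export
classify_phases <- function(trajectory, dominance_ratio = 2,
                            noise_floor = 0.02, npq_saturation = 3) {
  tr <- trajectory
  ok <- stats::complete.cases(tr[, c("pq_t", "npq_t")])
  if (sum(ok) < 3) {
    message("classify_phases: fewer than 3 usable points; nothing labelled")
    return(structure(data.frame(from = integer(), to = integer(),
                                label = character()),
                     steps = character(0)))
  }
  idx <- which(ok)
  pq <- tr$pq_t[idx]; npq <- tr$npq_t[idx]
  dpq <- diff(pq) / (1 + pq[-length(pq)])
  dnpq <- diff(npq) / (1 + npq[-length(npq)])
  seen_npq <- FALSE
  lab <- character(length(dpq))
  for (i in seq_along(dpq)) {
    a <- abs(dpq[i]); b <- abs(dnpq[i])
    if (a < noise_floor && b < noise_floor) {
      lab[i] <- "FLAT"
    } else if (b >= dominance_ratio * a) {
      lab[i] <- "NPQ"; seen_npq <- TRUE
    } else {
      lab[i] <- if (seen_npq || npq[i + 1] >= npq_saturation) "PQ2" else "PQ1"
    }
  }
  rl <- rle(lab)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  segs <- data.frame(from = idx[starts], to = idx[ends + 1],
                     label = rl$values, stringsAsFactors = FALSE)
  attr(segs, "steps") <- lab
  segs
}

#' Condensed phase sequence of a classified trajectory
#'
#' @param phases result of [classify_phases()].
#' @param drop_flat drop FLAT segments before condensing.
#' @return character vector of successive distinct phase labels.
#' @export
phase_sequence <- function(phases, drop_flat = TRUE) {
  lab <- phases$label
  if (drop_flat) lab <- lab[lab != "FLAT"]
  rle(lab)$values
}
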