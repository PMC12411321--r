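---
title: "Processing long-term field PAM fluorescence: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing long-term field PAM fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldpam)
```

## The measurement and its assumptions

A monitoring PAM (pulse-amplitude-modulated) fluorometer excites chlorophyll
fluorescence with microsecond pulses of constant measuring light (ML) and
records, at a fixed interval (here 30 min, 48 observations per day), the
prevailing fluorescence F′ and the pulse-maximal fluorescence F_M′ obtained
during a short saturating pulse (SP), together with PAR and air temperature.
Because the ML is constant, variations in the recorded millivolt signal track
the quantum yield of fluorescence (Assumption 1), and because the SP
transiently closes all PSII centers, photochemical quenching vanishes during
the pulse (Assumption 2). At night, reversible NPQ relaxes and all centers
reopen, so F′ and F_M′ become the dark-acclimated F₀ and F_M.

Everything in this package rests on the lake-model (connected antenna) yield
algebra. With PQ and NPQ expressed as rate constants relative to
k_F + k_D:

* ΦF = ΦF_max / (1 + NPQ + PQ)
* ΦF_M = ΦF_max / (1 + NPQ)
* ΦP = PQ / (1 + PQ + NPQ)

with ΦF_max = 0.1, the theoretical maximal fluorescence yield of PSII.
`yields()`, `forward_f()` and `invert_to_quench()` implement this triplet,
its signal-level forward form

F′ = PAR_ML · A · α_II · β · k_F / (k_F + k_D + k_NPQs + k_NPQr + qLs·qLr·k_PSII) + C_PSI

and its inversion. The Eq-level constants are never individually
identifiable from monitoring data; the forward model exists for simulation
and testing, and inversion works only in (PQ, NPQ) space.

## The parameter set

`diurnal_quench()` / `seasonal_quench()` (and their dataset-level wrappers
`diurnal_params()` / `seasonal_params()`) compute the full diurnal and
seasonal parameter families against the preceding night's F_M and the
seasonal references F_MR / F_0R: PQ_T, qL_T, NPQ_T, NPQ_r, ΦP, ΦNPQ_T,
ΦNPQ_r, ΦF+D (diurnal) and PQ_s, qL_s, NPQ_s, ΦP_max = F_V/F_M, ΦNPQ_s,
ΦF+D (seasonal). Three families of exact identities hold by construction
and are enforced in the test suite at 1e-12 relative error:

* additivity: NPQ_T = NPQ_r + NPQ_s;
* factorisation: PQ_T = qL_T · PQ_max and PQ_s = qL_s · PQ_max, with
  PQ_max = (F_V/F_M)_R / (1 − (F_V/F_M)_R) = F_MR/F_0R − 1 (4.88 at the
  reference 0.83);
* yield closure: ΦP + ΦNPQ_T + ΦF+D = 1, and at night
  ΦP_max + ΦNPQ_s + ΦF+D = 1.

Every parameter is a ratio of PAM levels, hence invariant under a common
rescaling of all signals — the property that makes long-term records
interpretable at all, and the one the artifact filters exploit.

One notational caveat: NPQ_r is defined here as F_MR/F_M′ − F_MR/F_M.
A shorthand F_M/F_M′ − 1 is sometimes seen; the two differ by the factor
F_MR/F_M and only the first makes NPQ_T = NPQ_r + NPQ_s exact, so the first
is canonical throughout this package.

C_PSI, the PSI contribution to the signal, defaults to 0: no practical field
protocol exists to estimate it. It is exposed as a constant applied in ΦP
only. A property test characterises the consequence of ignoring a genuine
PSI pedestal: inverted NPQ is biased low, npq_est = S·npq / (S + C_PSI(1+npq)),
with the bias growing as quenching deepens and the signal shrinks.

## Seasonal references

F_MR and F_0R are the F_M and F₀ expected in the absence of sustained NPQ
and photoinhibition. `fit_fm_vs_fvfm()` estimates them by regressing nightly
F_M on nightly F_V/F_M and evaluating the fit at a reference F_V/F_M
(default 0.83, config-overridable), returning a classed model object with
the usual `print`/`summary`/`coef`/`predict`/`plot` methods plus R², N and
RRMSE (RMSE / mean observed F_M).

The functional form was a genuinely open choice. We default to the
hyperbolic form F_M = a·x/(1−x) because the lake model implies it: at fixed
PQ, F_M ∝ 1/(1+NPQ) and x = F_V/F_M = PQ/(1+PQ+NPQ), so eliminating NPQ
gives F_M ∝ x/(1−x). A linear form is kept as the simpler alternative, and
`max_observed_reference()` (mean of the top-k nightly F_M) is the fallback
when the F_V/F_M spread is too narrow to support a regression (< 0.02).
When sample geometry, absorption or the PSI contribution shift during a
campaign, `segment_references()` fits one reference per user-chosen
segment. Segmentation is deliberately user-driven — no automatic
changepoint search — because unprincipled subsetting absorbs real
regulatory dynamics into the references; a warning is issued when adjacent
F_MR levels differ by less than 5%.

Only QC-passing, unflagged nights enter reference fits. On data generated
by the lake model at constant PQ the hyperbolic fit recovers the generating
F_MR to better than 0.1% noise-free, and to ~0.5% RMSE with 2%
multiplicative channel noise over 60 nights (both verified in the suite).
When PQ is *not* constant across the season (winter photoinhibition lowers
qL_s), the fitted F_MR acquires an upward bias of a few percent — the test
suite bounds the resulting NPQ_s trajectory error at 5%.

## Artifact filtering

Dew, rain, snow, ice, insects and wind-induced leaf movement attenuate the
ML or the viewed sample area. Because such optical disturbances scale both
F′ and F_M′ by a common factor, they depress the signals while leaving
ΦP = 1 − F′/F_M′ nearly unchanged — the *differential response* criterion.
The second criterion is *rate of change*: nighttime F_M is quasi-stable, so
fast nocturnal steps mean condensation or precipitation, while gradual
day-to-day declines with stable F_V/F_M mean the sample is sliding out of
the frame. `apply_filters()` runs a deterministic cascade:

1. `RANGE` — non-positive signals, F′ > F_M′, detector saturation;
2. `LOW_SIGNAL` — F_M′ below a floor (default detector range / 100), where
   signal-to-noise corrupts even ratio parameters;
3. `NIGHT_JUMP` — consecutive-record relative F_M′ steps above
   `night_jump_rel` (default 0.30) inside a night window open an event;
4. `PROPORTIONAL_DROP` — co-drops of both channels ≥ `prop_drop_rel`
   (default 0.30) within a sliding window while |ΔΦP| ≤ 0.05;
5. `DRIFT` — a robust (M-estimator) trend of nightly F_M over 14-night
   windows declining ≥ 25% while F_V/F_M stays within `fvfm_stable_tol`;
6. a recovery pass that closes events when both channels return within 10%
   of the pre-event baseline (median of the last 3 accepted records before
   onset), marking the closing record `RECOVERED_NOTE`;
7. `YII_OUT` — ΦP outside [0, 0.85].

Records are flagged, never deleted or altered; the cascade clears its own
flags before running, so it is idempotent, and downstream consumers decide
about exclusion. Day-time F_M′ jumps are never flagged by rule 3 — fast
daytime changes are a physiological response to fluctuating light — and an
event still open when its night window ends closes with the window, because
after sunrise the nocturnal baseline is no longer a meaningful recovery
target; persistent daytime attenuation is rule 4's job. Recovery requires
*both* channels in band: one channel alone re-entering is not recovery.

Two defaults deserve justification beyond "it works". First, the
night-jump/co-drop thresholds (0.30) sit far above the 2% measurement noise
and well below the ~2-fold signal changes typical of condensation events.
Second, the drift guard `fvfm_stable_tol` is 0.02, derived from the lake
model: an NPQ_s-driven relative F_M decline of x moves F_V/F_M by
approximately x·(F_V/F_M)(1 − F_V/F_M), which at the 25% decline threshold
is 0.035–0.06 across the physiological F_V/F_M range, whereas true optical
drift leaves nightly F_V/F_M within measurement noise (~0.01). A guard at
0.05 would swallow the sustained-NPQ autumn transition into the drift flag;
0.02 sits between the two regimes. All thresholds live in
`filter_config()` and a key=value config file, and the trade-off between
filter intensity and data loss remains the user's to tune with the
diagnostic plots.

## The season simulator

`simulate_pam_season()` generates a full artifact-bearing boreal-evergreen
monitoring season with per-record ground truth, so every processing stage
is testable without field data. Its defaults are the study conditions used
throughout the test suite: 365 days from June 1 at 30-min intervals
(17,520 records, one head); a boreal photoperiod (day length 5–19 h) and
temperature cycle (seasonal sinusoid −9 to +17 °C plus diurnal harmonic
and noise); reversible NPQ with a saturating light response
(npq_r_max = 2.5, half-saturation 400 µmol m⁻² s⁻¹) relaxing fully at
night; sustained NPQ as a logistic in the 10-day trailing mean temperature
(cap 5, midpoint 2 °C), putting midwinter F_V/F_M near 0.4; a
photoinhibition state (qL_s) eroded by cold-bright exposure and floored at
0.75; and an optical gain of 2400 mV, placing summer F₀ near 10% of a
4000 mV detector range — the recommended operating point. The daily
sustained-pool update takes effect at solar noon so that a single state
governs each night; this choice (the day boundary is arbitrary for pools
that move on day timescales) is also what lets the test suite demand exact
(1e-6) recovery of the simulated NPQ_s from the pipeline's nightly medians
when noise and artifacts are off.

Artifacts are multiplicative on both channels, which is their stated
physical mechanism (they act on PAR_ML or β), so simulated ΦP is preserved
by construction: dew on 15% of nights (attenuation drawn from 0.3–0.7,
condensing within one interval and evaporating at dawn), two winter snow
burials at 2% residual signal, and a drift episode (2.5%/day from day 35,
restored at a maintenance visit on day 75 — field stations service their
mounts). Overlaps resolve with precedence SNOW > DEW > DRIFT. Multiplicative
lognormal noise (CV 2%) preserves positivity. Against this truth the default
cascade reaches ≥ 0.80 sensitivity and ≥ 0.95 specificity (verified in the
suite across seeds).

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: pigment-pool and absorptance changes (Assumption 1
violations other than the simulated optical artifacts), PSI variable
fluorescence, within-shoot heterogeneity, rain events at daytime, partial
snow, sub-saturating pulses under strong NPQ, and sensor calibration error.
Response shapes are qualitative emulators, not mechanistic claims.

## Phase classification

Diurnal ΦF–ΦP trajectories traverse up to three regimes: an initial
photochemical phase (falling PQ dominates), an NPQ phase (rising NPQ
dominates), and a second photochemical — photoinhibitory — phase once NPQ
capacity is saturated or inhibited. The literature describes this taxonomy
qualitatively; `classify_phases()` operationalises it, and the rule is ours:
per consecutive segment, compare |Δpq/(1+pq)| against |Δnpq/(1+npq)|; label
NPQ when the npq term dominates by ≥ `dominance_ratio` (2), otherwise PQ
(PQ2 when an NPQ segment has occurred or npq_t ≥ `npq_saturation` = 3), and
FLAT when both terms are under `noise_floor` (0.02). When neither term
dominates, the segment stays PQ — NPQ must earn dominance, PQ is the default
carrier. Labels depend only on pq_t/npq_t, so they inherit the scale
invariance of the quenching parameters. `phase_fixture_day()` provides the
three canonical regimes (cloudy PQ1-only; summer PQ1→NPQ; frozen winter
PQ1→PQ2 with no NPQ phase) used in the acceptance tests.

## Numerical and procedural choices

* Nightly aggregation: median (robust to residual artifacts); `"predawn"`
  (last quarter of the window) and mean are available because the field
  convention varies. A night needs ≥ 4 accepted records and F₀ < F_M to
  pass QC.
* Night definition: measured PAR ≤ 1 µmol m⁻² s⁻¹ for ≥ 2 h, from the
  colocated PAR sensor — no solar geometry, only in-file data. A run's
  duration counts one nominal interval per record. Windows are labelled by
  the date of their end, so "the preceding night" of day D is night D.
* ML temperature correction: per-channel low-order polynomial of the
  relative LED output, normalised to 1 at the reference temperature,
  *dividing* the signals (the effect is multiplicative). Default is no
  correction — sub-1% ML variation is conventionally acceptable — and the
  correction refuses to run twice; raw values are always retained.
* Timestamps are stored in UTC after removing a declared fixed logger
  offset (field loggers do not observe DST).
* Duplicate (head, timestamp) records keep the first occurrence (logger
  restarts duplicate the boundary record); missing mandatory fields flag
  `MISSING` rather than dropping the row, keeping gap statistics honest.
* Degenerate inputs: reference fits refuse < 5 usable nights or an F_V/F_M
  spread < 0.02 (advising the max-observed fallback); `invert_to_quench()`
  rejects F_M′ above F_MR beyond tolerance, advising reference
  re-estimation; zero-variance observations make R² NA (undefined) while a
  constant fit against varying observations scores R² 0.
* Problem sizes in the shipped tests — a 365-day season for filter scoring
  and end-to-end recovery, 12–30-day seasons for unit properties, 200
  replicates for the noisy reference-recovery estimate, 50×50 grids for the
  forward/inverse oracle — were chosen to exercise every seasonal regime
  while keeping the default suite fast.

## Known limitations

Filter thresholds were set from stated mechanisms and validated against the
simulator, not against instrument-specific field data; real deployments
should start from the diagnostic plots and tune `filter_config()`. The
drift filter needs 14 usable nights and cannot see drift faster than the
reference window or slower than ~1.8%/day at its default decline threshold.
F_MR estimation assumes the optical chain (geometry, absorptance, PSI
share) is constant within a segment; violations masquerade as quenching.
The parameter algebra inherits both PAM assumptions: ML-proportionality and
complete pulse saturation — neither is corrected for here (no multiphase
pulse correction), and C_PSI = 0 understates NPQ when PSI contributes
appreciably to the signal.
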