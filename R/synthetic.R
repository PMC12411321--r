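#' Configuration of the boreal-season forward simulator
#'
#' Defines the study conditions the simulator emulates: a full year of
#' 30-minute monitoring on boreal evergreen foliage, with a seasonal
#' photoperiod and temperature cycle driving reversible NPQ induction,
#' sustained (overwintering) NPQ with a multi-day temperature memory,
#' photoinhibitory loss of functional PSII centers, and weather/instrument
#' artifacts (nocturnal dew films, snow burial, slow mounting drift)
#' injected on top of the clean signal with per-record ground truth.
#' Response shapes are emulators of the qualitative seasonal patterns of
#' such data — test scaffolding, not mechanistic claims.
#'
#' @param start_date first day (Date or string); default June 1, so the
#'   record starts in the favourable season as deployment guidance
#'   recommends.
#' @param n_days season length (days).
#' @param interval_minutes saturating-pulse interval.
#' @param head_id fluorometer head label.
#' @param daylen_mean,daylen_amp photoperiod driver: day length (h) is
#'   `daylen_mean + daylen_amp cos(2 pi (doy - 172)/365)` (boreal-latitude
#'   amplitude).
#' @param par_peak clear-sky midsummer noon PAR (umol m-2 s-1); daily peaks
#'   scale with relative day length.
#' @param cloud_min daily stochastic cloud transmission is drawn in
#'   `[cloud_min, 1]` (Beta(2,1)-shaped toward clear).
#' @param temp_mean,temp_seasonal_amp seasonal air-temperature sinusoid
#'   (deg C), minimum in late January.
#' @param temp_diurnal_amp,temp_noise_sd diurnal harmonic and white noise.
#' @param fvfm_ref_gen the generator's reference Fv/Fm: PQ_max of the
#'   unquenched state is `fvfm_ref_gen/(1 - fvfm_ref_gen)`.
#' @param npq_r_max,par_half saturating light response of reversible NPQ:
#'   `npq_r = npq_r_max PAR/(PAR + par_half)` (relaxes to 0 at night).
#' @param ql_r_min,par_half_ql openness declines with light:
#'   `ql_r = ql_r_min + (1 - ql_r_min)/(1 + PAR/par_half_ql)`.
#' @param npq_s_max,npq_s_t0,npq_s_tw,temp_memory_days sustained NPQ is a
#'   logistic in the trailing `temp_memory_days`-day mean temperature,
#'   `npq_s = npq_s_max plogis((npq_s_t0 - Tmem)/npq_s_tw)`, updated once
#'   per day (sustained pools move on day timescales); the daily state
#'   takes effect at solar noon, so a single state governs each night.
#' @param ql_s_min,photoinh_gain,ql_recovery_rate functional-center
#'   fraction: declines with daily cold-bright exposure, recovers in
#'   warmth, floored at `ql_s_min`; updated once per day.
#' @param scale_mv lumped optical gain PAR_ML A alpha_II beta
#'   k_F/(k_F + k_D) (mV): the unquenched Fm. Default 2400 puts summer F0
#'   near 10% of a 4000 mV detector range, the recommended operating
#'   point.
#' @param c_psi PSI signal contribution (mV).
#' @param led_temp_coeffs optional ascending-power polynomial of the LED
#'   output factor c(T) applied to both channels (e.g.
#'   `c(1.01, -5e-4)` emulates a blue LED gaining ~2% from 20 to -20 C);
#'   `NULL` for a temperature-stable ML.
#' @param noise_cv multiplicative lognormal measurement noise CV (per
#'   channel, independent; positivity preserved).
#' @param dew_prob_per_night,dew_atten nightly dew probability and the
#'   range the attenuation multiplier is drawn from. Dew condenses within
#'   one interval, persists to the end of the dark period and evaporates
#'   at dawn.
#' @param snow_blocks list of `c(first_day, last_day)` season-day ranges
#'   during which snow buries the head; signal multiplied to
#'   `snow_residual` (plus `snow_floor` mV of scattering).
#' @param snow_residual,snow_floor see above.
#' @param drift_onset_day,drift_rate,drift_end_day slow mounting drift:
#'   from `drift_onset_day` the signal decays by `drift_rate` per day
#'   (sample sliding out of the frame) until a maintenance visit restores
#'   alignment on `drift_end_day` (`NULL` = never).
#' @param seed integer seed; identical configs and seeds give identical
#'   output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(start_date = "2014-06-01", n_days = 365,
                       interval_minutes = 30, head_id = "H1",
                       daylen_mean = 12, daylen_amp = 7,
                       par_peak = 1600, cloud_min = 0.25,
                       temp_mean = 4, temp_seasonal_amp = 13,
                       temp_diurnal_amp = 4, temp_noise_sd = 1.5,
                       fvfm_ref_gen = 0.83,
                       npq_r_max = 2.5, par_half = 400,
                       ql_r_min = 0.25, par_half_ql = 300,
                       npq_s_max = 5, npq_s_t0 = 2, npq_s_tw = 3,
                       temp_memory_days = 10,
                       ql_s_min = 0.75, photoinh_gain = 0.01,
                       ql_recovery_rate = 0.05,
                       scale_mv = 2400, c_psi = 0,
                       led_temp_coeffs = NULL,
                       noise_cv = 0.02,
                       dew_prob_per_night = 0.15, dew_atten = c(0.3, 0.7),
                       snow_blocks = list(c(170, 180), c(205, 218)),
                       snow_residual = 0.02, snow_floor = 0,
                       drift_onset_day = 35, drift_rate = 0.025,
                       drift_end_day = 75,
                       seed = 1) {
  stopifnot(dew_prob_per_night >= 0, dew_prob_per_night <= 1,
            noise_cv >= 0, n_days >= 1, scale_mv > 0)
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  structure(cfg, class = "sim_config")
}

#' Simulate the environmental drivers
#'
#' Per-record timestamp, PAR and air temperature: PAR is a clear-sky
#' half-sinusoid over the photoperiod times a daily stochastic cloud
#' factor; temperature a seasonal sinusoid plus a diurnal harmonic and
#' white noise. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return data.frame with `timestamp`, `day` (season day, 1-based),
#'   `par`, `temp_c`.
#' @export
simulate_environment <- function(config) {
  set.seed(config$seed %% 2147483647L)
  per_day <- as.integer(1440 / config$interval_minutes)
  n <- config$n_days * per_day
  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  ts <- t0 + (seq_len(n) - 1) * config$interval_minutes * 60
  day <- rep(seq_len(config$n_days), each = per_day)
  hour <- (as.numeric(ts - t0, units = "hours")) %% 24
  doy <- as.integer(format(as.Date(ts, tz = "UTC"), "%j"))
  daylen <- config$daylen_mean +
    config$daylen_amp * cos(2 * pi * (doy - 172) / 365)
  sunrise <- 12 - daylen / 2
  frac <- (hour - sunrise) / daylen
  elev <- ifelse(frac > 0 & frac < 1, sin(pi * frac), 0)
  cloud <- config$cloud_min +
    (1 - config$cloud_min) * stats::rbeta(config$n_days, 2, 1)
  par <- config$par_peak *
    (daylen / (config$daylen_mean + config$daylen_amp)) * elev * cloud[day]
  temp <- config$temp_mean +
    config$temp_seasonal_amp * cos(2 * pi * (doy - 202) / 365) +
    config$temp_diurnal_amp * elev +
    stats::rnorm(n, sd = config$temp_noise_sd)
  data.frame(timestamp = ts, day = day, par = par, temp_c = temp)
}

#' Simulate the quenching physiology along an environment
#'
#' Reversible NPQ follows a saturating response to instantaneous PAR and
#' relaxes fully at night; PSII openness (ql_r) declines with light from 1
#' toward its floor; sustained NPQ follows a logistic in the trailing
#' multi-day temperature mean; the functional-center fraction (ql_s)
#' erodes with cold-bright exposure and recovers in warmth. The sustained
#' pools update once per day. pq = ql_s ql_r PQ_max.
#'
#' @param environment output of [simulate_environment()].
#' @param config a [sim_config()].
#' @return data.frame per record: `pq`, `npq_r`, `npq_s`, `ql_r`, `ql_s`.
#' @export
simulate_physiology <- function(environment, config) {
  env <- environment
  pqmax <- config$fvfm_ref_gen / (1 - config$fvfm_ref_gen)
  tday <- tapply(env$temp_c, env$day, mean)
  par_day <- tapply(env$par, env$day, mean)
  nd <- length(tday)
  tmem <- vapply(seq_len(nd), function(d) {
    mean(tday[max(1, d - config$temp_memory_days + 1):d])
  }, numeric(1))
  npq_s_day <- config$npq_s_max *
    stats::plogis((config$npq_s_t0 - tmem) / config$npq_s_tw)
  ql_s_day <- numeric(nd)
  q <- 1
  for (d in seq_len(nd)) {
    cold <- max(0, 5 - tmem[d]) / 5
    warm <- max(0, tmem[d] - 5) / 5
    q <- q - config$photoinh_gain * (par_day[d] / 1000) * cold +
      config$ql_recovery_rate * warm * (1 - q)
    q <- min(1, max(config$ql_s_min, q))
    ql_s_day[d] <- q
  }
  npq_r <- config$npq_r_max * env$par / (env$par + config$par_half)
  ql_r <- config$ql_r_min +
    (1 - config$ql_r_min) / (1 + env$par / config$par_half_ql)
  # sustained pools switch at solar noon, so one state governs each night
  hour <- as.numeric(format(env$timestamp, "%H")) +
    as.numeric(format(env$timestamp, "%M")) / 60
  eff_day <- pmax(1L, env$day - as.integer(hour < 12))
  ql_s <- ql_s_day[eff_day]
  data.frame(pq = ql_s * ql_r * pqmax,
             npq_r = npq_r,
             npq_s = npq_s_day[eff_day],
             ql_r = ql_r, ql_s = ql_s)
}

.led_factor <- function(coeffs, temp_c) {
  if (is.null(coeffs)) return(rep(1, length(temp_c)))
  p <- seq_along(coeffs) - 1
  as.numeric(outer(temp_c, p, `^`) %*% coeffs)
}

#' Render fluorescence signals from simulated states
#'
#' Clean F' and Fm' follow the lake-model forward equations with the
#' lumped optical gain `scale_mv`:
#' F' = scale_mv/(1 + pq + npq) + c_psi, Fm' = scale_mv/(1 + npq) + c_psi,
#' multiplied by the LED temperature factor and independent multiplicative
#' lognormal noise per channel. Ground truth stores the pre-artifact,
#' pre-noise signals and the quenching components.
#'
#' @param states output of [simulate_physiology()].
#' @param environment output of [simulate_environment()].
#' @param config a [sim_config()].
#' @return list with `dataset` (a [pam_dataset]) and `truth` (data.frame
#'   per record: quenching components, `f_clean`, `fm_clean`,
#'   `label = "NONE"`).
#' @export
render_fluorescence <- function(states, environment, config) {
  set.seed((config$seed + 1L) %% 2147483647L)
  env <- environment
  npq <- states$npq_r + states$npq_s
  f_clean <- config$scale_mv / (1 + states$pq + npq) + config$c_psi
  fm_clean <- config$scale_mv / (1 + npq) + config$c_psi
  led <- .led_factor(config$led_temp_coeffs, env$temp_c)
  sdlog <- if (config$noise_cv > 0) sqrt(log(1 + config$noise_cv^2)) else 0
  n <- nrow(env)
  ef <- if (sdlog > 0) exp(stats::rnorm(n, 0, sdlog)) else rep(1, n)
  em <- if (sdlog > 0) exp(stats::rnorm(n, 0, sdlog)) else rep(1, n)
  f_obs <- f_clean * led * ef
  fm_obs <- fm_clean * led * em
  rec <- data.frame(timestamp = env$timestamp,
                    head_id = config$head_id,
                    par = env$par, temp_c = env$temp_c,
                    f_prime = f_obs, fm_prime = fm_obs,
                    y_ii = 1 - f_obs / fm_obs,
                    flags = "",
                    stringsAsFactors = FALSE)
  ds <- pam_dataset(rec, interval_minutes = config$interval_minutes,
                    metadata = list(source = "fieldpam simulator",
                                    seed = config$seed))
  truth <- data.frame(timestamp = env$timestamp, head_id = config$head_id,
                      day = env$day,
                      pq = states$pq, npq_r = states$npq_r,
                      npq_s = states$npq_s,
                      ql_r = states$ql_r, ql_s = states$ql_s,
                      f_clean = f_clean, fm_clean = fm_clean,
                      label = "NONE", stringsAsFactors = FALSE)
  list(dataset = ds, truth = truth)
}

#' Inject weather and instrument artifacts
#'
#' Applies, with precedence SNOW > DEW > DRIFT, the configured artifacts
#' to the rendered signals. All artifacts are multiplicative on both
#' channels (they attenuate the measuring light or the viewed area), so
#' the per-record PhiP is preserved by construction; snow may additionally
#' add a small constant scattering floor. Truth labels record which
#' artifact governs each record.
#'
#' @param dataset,truth output of [render_fluorescence()].
#' @param config a [sim_config()].
#' @return list with the modified `dataset` and `truth`.
#' @export
inject_artifacts <- function(dataset, truth, config) {
  set.seed((config$seed + 2L) %% 2147483647L)
  r <- dataset$records
  n <- nrow(r)
  factor <- rep(1, n)
  floor_mv <- rep(0, n)
  label <- truth$label
  day <- truth$day

  # DRIFT: exponential decay from onset until the maintenance visit
  if (!is.null(config$drift_onset_day) && config$drift_rate > 0) {
    dend <- if (is.null(config$drift_end_day)) Inf else config$drift_end_day
    sel <- day >= config$drift_onset_day & day <= dend
    dt <- day[sel] - config$drift_onset_day +
      (as.numeric(r$timestamp[sel]) %% 86400) / 86400
    factor[sel] <- factor[sel] * (1 - config$drift_rate)^dt
    label[sel] <- "DRIFT"
  }

  # DEW on sampled nights: maximal dark runs of >= 4 records
  dark <- r$par <= 1
  rl <- rle(dark)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
  for (k in which(rl$values & rl$lengths >= 4)) {
    if (stats::runif(1) < config$dew_prob_per_night) {
      len <- rl$lengths[k]
      onset <- starts[k] + sample.int(len - 2, 1)   # not the first record
      atten <- stats::runif(1, config$dew_atten[1], config$dew_atten[2])
      sel <- onset:ends[k]
      factor[sel] <- factor[sel] * atten
      label[sel] <- "DEW"
    }
  }

  # SNOW blocks override everything: burial leaves only a residual signal
  for (b in config$snow_blocks) {
    sel <- day >= b[1] & day <= b[2]
    factor[sel] <- config$snow_residual
    floor_mv[sel] <- config$snow_floor
    label[sel] <- "SNOW"
  }

  r$f_prime <- r$f_prime * factor + floor_mv
  r$fm_prime <- r$fm_prime * factor + floor_mv
  r$y_ii <- 1 - r$f_prime / r$fm_prime
  dataset$records <- r
  truth$label <- label
  list(dataset = dataset, truth = truth)
}

#' Simulate a full artifact-bearing monitoring season
#'
#' Runs environment, physiology, rendering and artifact injection in
#' sequence. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `dataset`, `truth`, `config`.
#' @export
simulate_pam_season <- function(config = sim_config()) {
  env <- simulate_environment(config)
  st <- simulate_physiology(env, config)
  rd <- render_fluorescence(st, env, config)
  ia <- inject_artifacts(rd$dataset, rd$truth, config)
  list(dataset = ia$dataset, truth = ia$truth, config = config)
}

#' Write a simulated season plus its ground truth
#'
#' Emits the standard delimited record file and a parallel ground-truth
#' file sharing the (head, timestamp) keys.
#'
#' @param sim output of [simulate_pam_season()].
#' @param path record-file path; truth is written next to it with suffix
#'   `"_truth"`.
#' @return paths, invisibly.
#' @export
write_simulation <- function(sim, path) {
  write_pam(sim$dataset, path)
  tpath <- sub("(\\.[^.]*)?$", "_truth\\1", path)
  tr <- sim$truth
  tr$timestamp <- format(tr$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.table(tr, tpath, sep = ";", row.names = FALSE, quote = FALSE)
  invisible(c(path, tpath))
}

#' Canonical single-day quenching trajectories
#'
#' Builds idealised one-day (pq_t, npq_t) trajectories for the three
#' canonical diurnal regimes, for exercising [classify_phases()]:
#' `"cloudy"` (NPQ stays minimal, PQ declines: photochemical phase only),
#' `"summer"` (morning PQ decline, then a dominant midday NPQ rise),
#' `"winter"` (frozen day: NPQ induction inhibited, sustained NPQ creeping
#' past saturation while PQ collapses — the photoinhibitory regime).
#' Yield columns are derived with [yields()].
#'
#' @param regime one of `"cloudy"`, `"summer"`, `"winter"`.
#' @return data.frame with `pq_t`, `npq_t`, `phi_fd`, `phi_p`, `par`.
#' @export
phase_fixture_day <- function(regime = c("cloudy", "summer", "winter")) {
  regime <- match.arg(regime)
  tr <- switch(regime,
    cloudy = data.frame(pq_t = seq(4.8, 2.0, length.out = 15),
                        npq_t = rep(0.05, 15),
                        par = seq(20, 220, length.out = 15)),
    summer = data.frame(pq_t = c(seq(4.8, 2.4, length.out = 10),
                                 seq(2.38, 2.2, length.out = 10)),
                        npq_t = c(seq(0, 0.3, length.out = 10),
                                  seq(0.55, 2.7, length.out = 10)),
                        par = c(seq(30, 700, length.out = 10),
                                seq(780, 1500, length.out = 10))),
    winter = data.frame(pq_t = seq(3.5, 1.1, length.out = 17),
                        npq_t = seq(2.6, 3.4, length.out = 17),
                        par = seq(10, 400, length.out = 17)))
  y <- yields(tr$pq_t, tr$npq_t)
  tr$phi_fd <- y$phi_f / 0.1
  tr$phi_p <- y$phi_p
  tr
}
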