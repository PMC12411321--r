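# Fixture builders shared across the suite. Everything is generated in
# code; no stored data files.

ts_seq <- function(n, start = "2014-06-01 00:00:00", by_min = 30) {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * by_min * 60
}

make_ds <- function(n = 5, par = 0, temp = 15, f = 200, fm = 600,
                    head = "H1", start = "2014-06-01 00:00:00",
                    by_min = 30, ...) {
  rec <- data.frame(timestamp = ts_seq(n, start, by_min),
                    head_id = head,
                    par = rep_len(par, n), temp_c = rep_len(temp, n),
                    f_prime = rep_len(f, n), fm_prime = rep_len(fm, n),
                    stringsAsFactors = FALSE)
  pam_dataset(rec, interval_minutes = by_min, ...)
}

# one clear 24 h day: PAR half-sinusoid 06:00-18:00, dark otherwise
make_day_ds <- function(peak = 1200, by_min = 30, f = 200, fm = 600,
                        start = "2014-06-01 00:00:00") {
  n <- 24 * 60 / by_min
  ts <- ts_seq(n, start, by_min)
  hour <- (as.numeric(ts - ts[1], units = "hours")) %% 24
  par <- ifelse(hour >= 6 & hour < 18, peak * sin(pi * (hour - 6) / 12), 0)
  rec <- data.frame(timestamp = ts, head_id = "H1", par = par,
                    temp_c = 15, f_prime = f, fm_prime = fm,
                    stringsAsFactors = FALSE)
  pam_dataset(rec, interval_minutes = by_min)
}

# nightly summaries generated from the lake model at constant PQ:
# fm = fmr/(1 + npq), f0 = fmr/(1 + pq + npq)
lake_summaries <- function(fmr = 2400, npq = seq(0.05, 4, length.out = 40),
                           pq = pq_max(0.83), head = "H1",
                           start = as.Date("2014-06-01")) {
  fm <- fmr / (1 + npq)
  f0 <- fmr / (1 + pq + npq)
  data.frame(night_date = start + seq_along(npq), head_id = head,
             f0 = f0, fm = fm, fvfm = 1 - f0 / fm,
             n_used = 10L, qc_ok = TRUE, stringsAsFactors = FALSE)
}

# season cache: the expensive simulations are shared between tests
.season_env <- new.env(parent = emptyenv())
cached_season <- function(key, cfg) {
  if (is.null(.season_env[[key]]))
    .season_env[[key]] <- simulate_pam_season(cfg)
  .season_env[[key]]
}

clean_short_season <- function(seed = 11, n_days = 12) {
  cached_season(paste0("clean", seed, "_", n_days),
                sim_config(seed = seed, n_days = n_days, noise_cv = 0,
                           dew_prob_per_night = 0, snow_blocks = list(),
                           drift_onset_day = NULL))
}
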