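test_that("the simulator is deterministic under its seed", {
  cfg <- sim_config(seed = 17, n_days = 4)
  a <- simulate_pam_season(cfg)
  b <- simulate_pam_season(cfg)
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_pam_season(sim_config(seed = 18, n_days = 4))
  expect_false(identical(a$dataset$records$fm_prime,
                         c2$dataset$records$fm_prime))
})

test_that("clear-sky PAR is symmetric about solar noon and dark at night", {
  cfg <- sim_config(seed = 1, n_days = 1, cloud_min = 1)  # no clouds
  env <- simulate_environment(cfg)
  expect_equal(sum(env$par == 0), sum(env$par <= 0))
  # records at 11:30 and 12:30, 10:30 and 13:30 ... pair up
  hour <- as.numeric(format(env$timestamp, "%H")) +
    as.numeric(format(env$timestamp, "%M")) / 60
  for (off in c(0.5, 1.5, 2.5)) {
    expect_equal(env$par[hour == 12 - off], env$par[hour == 12 + off],
                 tolerance = 1e-9)
  }
})

test_that("winter days are shorter than summer days", {
  summer <- simulate_environment(sim_config(seed = 1, n_days = 2,
                                            start_date = "2014-06-20"))
  winter <- simulate_environment(sim_config(seed = 1, n_days = 2,
                                            start_date = "2014-12-20"))
  expect_gt(sum(summer$par > 1), 1.5 * sum(winter$par > 1))
})

test_that("midsummer midnight has fully relaxed reversible quenching", {
  sim <- clean_short_season()
  tr <- sim$truth
  night <- sim$dataset$records$par == 0
  expect_equal(unique(tr$npq_r[night]), 0)
  expect_equal(unique(tr$ql_r[night]), 1)
})

test_that("deep-winter nights approach the configured sustained-NPQ cap", {
  cfg <- sim_config(seed = 2, n_days = 240, noise_cv = 0,
                    dew_prob_per_night = 0, snow_blocks = list(),
                    drift_onset_day = NULL)
  env <- simulate_environment(cfg)
  st <- simulate_physiology(env, cfg)
  jan <- format(env$timestamp, "%m") == "01"
  expect_gt(min(st$npq_s[jan]), 0.9 * cfg$npq_s_max)
})

test_that("a cold-bright week erodes the functional-center fraction daily", {
  cfg <- sim_config(seed = 3, n_days = 8, temp_mean = -5,
                    temp_seasonal_amp = 0, temp_diurnal_amp = 0,
                    temp_noise_sd = 0, cloud_min = 1, ql_s_min = 0.1)
  env <- simulate_environment(cfg)
  st <- simulate_physiology(env, cfg)
  # one value per simulated day, read at local noon
  noon <- format(env$timestamp, "%H:%M") == "12:00"
  qls <- st$ql_s[noon]
  expect_true(all(diff(qls) < 0))
})

test_that("rendered signals invert exactly back to the generator state", {
  sim <- clean_short_season()
  r <- sim$dataset$records
  tr <- sim$truth
  phi <- 1 - r$f_prime / r$fm_prime
  expect_lt(max(abs(phi - tr$pq / (1 + tr$pq + tr$npq_r + tr$npq_s))), 1e-9)
})

test_that("doubling the optical gain doubles signals, not parameters", {
  base <- sim_config(seed = 19, n_days = 3, noise_cv = 0,
                     dew_prob_per_night = 0, snow_blocks = list(),
                     drift_onset_day = NULL)
  big <- base; big$scale_mv <- 2 * base$scale_mv
  s1 <- simulate_pam_season(base)
  s2 <- simulate_pam_season(big)
  expect_equal(s2$dataset$records$fm_prime,
               2 * s1$dataset$records$fm_prime, tolerance = 1e-12)
  q1 <- seasonal_quench(200, 600, base$scale_mv, base$scale_mv * 0.17)
  q2 <- seasonal_quench(400, 1200, big$scale_mv, big$scale_mv * 0.17)
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("dew halves both channels and leaves nightly fvfm untouched", {
  cfg <- sim_config(seed = 23, n_days = 6, noise_cv = 0,
                    dew_prob_per_night = 1, dew_atten = c(0.5, 0.5),
                    snow_blocks = list(), drift_onset_day = NULL)
  dewy <- simulate_pam_season(cfg)
  cfg2 <- cfg; cfg2$dew_prob_per_night <- 0
  clean <- simulate_pam_season(cfg2)
  dew <- dewy$truth$label == "DEW"
  expect_gt(sum(dew), 0)
  expect_equal(dewy$dataset$records$f_prime[dew],
               0.5 * clean$dataset$records$f_prime[dew], tolerance = 1e-12)
  cl_d <- classify_day_night(dewy$dataset)
  cl_c <- classify_day_night(clean$dataset)
  s_d <- nightly_summary(cl_d)
  s_c <- nightly_summary(cl_c)
  expect_equal(s_d$fvfm, s_c$fvfm, tolerance = 1e-12)
})

test_that("snow burial drops the signal below the low-signal floor", {
  art <- cached_season("art1", sim_config(seed = 1))
  snow <- art$truth$label == "SNOW"
  expect_gt(sum(snow), 0)
  expect_true(all(art$dataset$records$fm_prime[snow] <
                    art$dataset$detector_range_mv / 100))
})

test_that("zero artifact rates leave every truth label NONE", {
  sim <- clean_short_season()
  expect_equal(unique(sim$truth$label), "NONE")
})

test_that("blue-LED coefficients inflate cold readings by the set factor", {
  cfg <- sim_config(seed = 29, n_days = 2, noise_cv = 0,
                    temp_mean = -20, temp_seasonal_amp = 0,
                    temp_diurnal_amp = 0, temp_noise_sd = 0,
                    dew_prob_per_night = 0, snow_blocks = list(),
                    drift_onset_day = NULL,
                    led_temp_coeffs = c(1.01, -5e-4))
  cfg0 <- cfg; cfg0$led_temp_coeffs <- NULL
  led <- simulate_pam_season(cfg)
  plain <- simulate_pam_season(cfg0)
  ratio <- led$dataset$records$fm_prime / plain$dataset$records$fm_prime
  expect_equal(ratio, 1.01 - 5e-4 * led$dataset$records$temp_c,
               tolerance = 1e-12)
  expect_equal(unique(round(ratio, 6)), 1.02)  # -20 C: +2%
})

test_that("simulation files round-trip with their ground truth", {
  sim <- clean_short_season()
  path <- withr::local_tempfile(fileext = ".csv")
  paths <- write_simulation(sim, path)
  back <- read_pam(path)
  expect_equal(n_records(back), n_records(sim$dataset))
  tr <- utils::read.table(sub("\\.csv$", "_truth.csv", path), header = TRUE,
                          sep = ";", stringsAsFactors = FALSE)
  expect_equal(nrow(tr), nrow(sim$truth))
  expect_equal(sort(unique(tr$label)), sort(unique(sim$truth$label)))
})
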