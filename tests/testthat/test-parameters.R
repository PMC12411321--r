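test_that("pq_max reproduces the reference points", {
  expect_equal(round(pq_max(0.83), 2), 4.88)
  expect_equal(pq_max(0.5), 1.0)
  expect_equal(pq_max(0.9), 9.0, tolerance = 1e-12)
  expect_error(pq_max(1), "0, 1")
  expect_error(pq_max(0), "0, 1")
})

test_that("phi_p follows (Fm' - F')/(Fm' - C_PSI)", {
  expect_equal(phi_p(300, 1000), 0.7)
  expect_equal(phi_p(300, 1000, c_psi = 100), 700 / 900, tolerance = 1e-15)
  expect_equal(phi_p(250, 250), 0)  # closed-centers limit
  expect_error(phi_p(300, 200), "fm")
  expect_error(phi_p(50, 100, c_psi = 150), "c_psi")
})

test_that("the worked diurnal record reproduces every hand value", {
  q <- diurnal_quench(f = 250, fm_prime = 500, fm_night = 800,
                      fmr = 1000, f0r = 170)
  expect_equal(q$phi_p, 0.5)
  expect_equal(q$npq_t, 1.0)
  expect_equal(q$npq_r, 1000 / 500 - 1000 / 800)  # 0.75
  expect_equal(q$phi_fd, 0.25)
  expect_equal(q$phi_npq_t, 0.25)
  expect_equal(q$phi_p + q$phi_npq_t + q$phi_fd, 1, tolerance = 1e-15)
  expect_equal(q$phi_f_est, 0.1 * 0.25)
  # PQ_T = qL_T x PQ_max when f0r = fmr (1 - fvfm_ref)
  expect_equal(q$pq_t / q$ql_t, pq_max(0.83), tolerance = 1e-12)
})

test_that("with Fm = FmR the reversible component carries all of NPQ_T", {
  q <- diurnal_quench(f = 250, fm_prime = 500, fm_night = 1000,
                      fmr = 1000, f0r = 170)
  expect_equal(q$npq_r, q$npq_t, tolerance = 1e-15)
})

test_that("seasonal parameters at the reference state and off it", {
  ref_state <- seasonal_quench(f0 = 170, fm = 1000, fmr = 1000, f0r = 170)
  expect_equal(ref_state$npq_s, 0)
  expect_equal(ref_state$ql_s, 1)
  expect_equal(ref_state$pq_s, pq_max(0.83), tolerance = 1e-12)
  expect_equal(ref_state$phi_p_max, 0.83)

  q <- seasonal_quench(f0 = 200, fm = 500, fmr = 1000, f0r = 170)
  expect_equal(q$npq_s, 1.0)
  expect_equal(q$phi_npq_s, 200 / 500 - 200 / 1000)  # 0.2
  expect_equal(q$phi_p_max + q$phi_npq_s + q$phi_fd_s, 1, tolerance = 1e-15)
})

test_that("phi_npq_s_daytime matches its definition and limits", {
  expect_equal(phi_npq_s_daytime(300, 800, 1000), 0.375 - 0.3)
  expect_equal(phi_npq_s_daytime(300, 1000, 1000), 0)
  # at night with f = F0 it reproduces the seasonal value
  q <- seasonal_quench(f0 = 200, fm = 500, fmr = 1000, f0r = 170)
  expect_equal(phi_npq_s_daytime(200, 500, 1000), q$phi_npq_s)
  expect_error(phi_npq_s_daytime(300, 1100, 1000), "exceed")
})

test_that("Table-1 identities hold on random valid tuples", {
  set.seed(4)
  n <- 2000
  fmr <- runif(n, 300, 3000)
  fvfm_ref <- 0.83
  f0r <- fmr * (1 - fvfm_ref)
  fm_night <- fmr * runif(n, 0.3, 1)
  fm_prime <- fm_night * runif(n, 0.3, 1)
  f <- fm_prime * runif(n, 0.2, 0.95)
  f0 <- fm_night * runif(n, 0.17, 0.9)
  q <- diurnal_quench(f, fm_prime, fm_night, fmr, f0r)
  s <- seasonal_quench(f0, fm_night, fmr, f0r)
  npq_s <- fmr / fm_night - 1
  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
  expect_lt(max(rel(q$npq_t, q$npq_r + npq_s)), 1e-12)
  expect_lt(max(rel(q$pq_t, q$ql_t * pq_max(fvfm_ref))), 1e-12)
  expect_lt(max(rel(s$pq_s, s$ql_s * pq_max(fvfm_ref))), 1e-12)
  expect_lt(max(abs(q$phi_p + q$phi_npq_t + q$phi_fd - 1)), 1e-12)
  expect_lt(max(abs(s$phi_p_max + s$phi_npq_s + s$phi_fd_s - 1)), 1e-12)
  # nighttime partition: with F' = F0 the sustained + reversible yields
  # recompose the total
  qn <- diurnal_quench(f0, fm_night, fm_night, fmr, f0r)
  expect_lt(max(abs(qn$phi_npq_r + s$phi_npq_s - qn$phi_npq_t)), 1e-12)
})

test_that("every parameter is scale-free and monotone where stated", {
  q1 <- diurnal_quench(250, 500, 800, 1000, 170)
  q2 <- diurnal_quench(250 * 13, 500 * 13, 800 * 13, 1000 * 13, 170 * 13)
  expect_equal(q1, q2, tolerance = 1e-12)
  # NPQ_T strictly decreasing in Fm'
  fmp <- seq(400, 900, by = 100)
  npq_t <- diurnal_quench(200, fmp, 950, 1000, 170)$npq_t
  expect_true(all(diff(npq_t) < 0))
  # PhiP strictly decreasing in F' at fixed Fm'
  fv <- seq(100, 450, by = 50)
  phi <- diurnal_quench(fv, 500, 800, 1000, 170)$phi_p
  expect_true(all(diff(phi) < 0))
})

test_that("diurnal_params binds records to the preceding night and ref", {
  # two nights around one day; record mid-day must use the morning window
  n <- 96  # two days
  ts <- ts_seq(n)
  hour <- (as.numeric(ts - ts[1], units = "hours")) %% 24
  par <- ifelse(hour >= 6 & hour < 18, 800, 0)
  f <- ifelse(par > 0, 250, 200)
  fm <- ifelse(par > 0, 500, 800)
  rec <- data.frame(timestamp = ts, head_id = "H1", par = par,
                    temp_c = 15, f_prime = f, fm_prime = fm,
                    stringsAsFactors = FALSE)
  ds <- pam_dataset(rec)
  cl <- classify_day_night(ds)
  summ <- nightly_summary(cl)
  ref <- manual_reference(1000, 0.83)
  dp <- diurnal_params(cl$dataset, summ, ref)
  day1 <- dp[dp$par > 0 & as.Date(dp$timestamp, tz = "UTC") ==
               as.Date("2014-06-01"), ]
  expect_equal(unique(day1$npq_r), 1000 / 500 - 1000 / 800,
               tolerance = 1e-12)
  expect_equal(unique(day1$phi_p), 0.5)
  expect_equal(unique(round(day1$y_ii - day1$phi_p, 12)), 0)

  sp <- seasonal_params(summ, ref)
  expect_equal(unique(sp$npq_s), 1000 / 800 - 1, tolerance = 1e-12)
  expect_equal(unique(sp$phi_p_max), 1 - 200 / 800, tolerance = 1e-12)
})

test_that("records without a usable preceding night get NA, not numbers", {
  ds <- make_ds(n = 4, par = 500, f = 250, fm = 500,
                start = "2014-06-01 10:00:00")
  summ <- data.frame(night_date = as.Date("2014-06-01"), head_id = "H1",
                     f0 = 200, fm = 800, fvfm = 0.75, n_used = 2,
                     qc_ok = FALSE)
  dp <- diurnal_params(ds, summ, manual_reference(1000))
  expect_true(all(is.na(dp$npq_r)))
  expect_true(all(is.na(dp$phi_npq_r)))
  # reference-independent columns still computed
  expect_equal(unique(dp$phi_p), 0.5)
})
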