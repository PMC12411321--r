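test_that("range filter flags saturation, ordering and sign violations", {
  ds <- make_ds(n = 4, f = c(250, 500, 250, -5),
                fm = c(4000, 450, 500, 600), detector_range_mv = 4000)
  out <- filter_range(ds)
  fl <- out$records$flags
  expect_true(flag_has(fl[1], "RANGE"))   # at detector range (saturated)
  expect_true(flag_has(fl[2], "RANGE"))   # F' > Fm'
  expect_false(flag_has(fl[3], "RANGE"))  # clean
  expect_true(flag_has(fl[4], "RANGE"))   # non-positive
})

test_that("low-signal floor is strict and scale-aware", {
  cfg <- filter_config(f_min_mv = 50)
  ds <- make_ds(n = 3, f = c(5, 12, 60), fm = c(20, 50, 240))
  out <- filter_low_signal(ds, cfg)
  fl <- out$records$flags
  expect_true(flag_has(fl[1], "LOW_SIGNAL"))
  expect_false(flag_has(fl[2], "LOW_SIGNAL"))  # boundary: strict <
  expect_false(flag_has(fl[3], "LOW_SIGNAL"))
  # a winter series at 10% of summer level but above the floor passes
  winter <- make_ds(n = 5, f = 20, fm = 60)
  expect_true(all(is_accepted(
    filter_low_signal(winter, cfg)$records$flags)))
})

night_jump_fixture <- function() {
  make_ds(n = 5, par = 0,
          f = c(200, 198, 103, 100, 197),
          fm = c(600, 595, 310, 300, 590))
}

test_that("a nocturnal Fm step opens an event that closes on recovery", {
  ds <- night_jump_fixture()
  cl <- classify_day_night(ds)
  out <- filter_night_jump(cl$dataset, cl$windows)
  expect_equal(which(flag_has(out$records$flags, "NIGHT_JUMP")), 3:5)
  rec <- unflag_recovery(out)
  fl <- rec$records$flags
  expect_equal(which(flag_has(fl, "NIGHT_JUMP")), 3:4)
  expect_true(flag_has(fl[5], "RECOVERED_NOTE"))
  expect_true(is_accepted(fl[5]))
})

test_that("gentle nocturnal variation is never flagged", {
  ds <- make_ds(n = 6, par = 0, fm = 600 * cumprod(c(1, rep(0.95, 5))),
                f = 200 * cumprod(c(1, rep(0.95, 5))))
  cl <- classify_day_night(ds)
  out <- filter_night_jump(cl$dataset, cl$windows)
  expect_true(all(is_accepted(out$records$flags)))
})

test_that("the identical jump at noon is not a night jump", {
  ds <- make_ds(n = 5, par = 800,
                f = c(200, 198, 103, 100, 197),
                fm = c(600, 595, 310, 300, 590))
  cl <- classify_day_night(ds)
  out <- filter_night_jump(cl$dataset, cl$windows)
  expect_true(all(is_accepted(out$records$flags)))
})

test_that("unrecovered events stay flagged; one channel back is not enough", {
  # no return to baseline at all
  ds <- make_ds(n = 5, par = 0,
                f = c(200, 198, 103, 100, 101),
                fm = c(600, 595, 310, 300, 305))
  cl <- classify_day_night(ds)
  out <- unflag_recovery(filter_night_jump(cl$dataset, cl$windows))
  expect_equal(which(flag_has(out$records$flags, "NIGHT_JUMP")), 3:5)
  # Fm back in band but F' still depressed: event stays open
  ds2 <- make_ds(n = 5, par = 0,
                 f = c(200, 198, 103, 100, 101),
                 fm = c(600, 595, 310, 300, 590))
  cl2 <- classify_day_night(ds2)
  out2 <- unflag_recovery(filter_night_jump(cl2$dataset, cl2$windows))
  expect_equal(which(flag_has(out2$records$flags, "NIGHT_JUMP")), 3:5)
})

test_that("proportional co-drop with stable PhiP is flagged; NPQ is not", {
  # both channels halve, PhiP steady: optical artifact
  ds <- make_ds(n = 6, par = 400,
                f = c(200, 201, 199, 100, 100, 200),
                fm = c(600, 602, 598, 300, 299, 600))
  out <- unflag_recovery(filter_proportional(ds))
  fl <- out$records$flags
  expect_equal(which(flag_has(fl, "PROPORTIONAL_DROP")), 4:5)
  expect_true(flag_has(fl[6], "RECOVERED_NOTE"))
  # Fm' halves while F' holds (true NPQ induction; PhiP moves): untouched
  ds2 <- make_ds(n = 4, par = 400,
                 f = c(200, 200, 200, 200),
                 fm = c(600, 600, 300, 300))
  out2 <- filter_proportional(ds2)
  expect_true(all(is_accepted(out2$records$flags)))
  # both rising is not a drop
  ds3 <- make_ds(n = 4, par = 400,
                 f = c(200, 200, 400, 400),
                 fm = c(600, 600, 1200, 1200))
  out3 <- filter_proportional(ds3)
  expect_true(all(is_accepted(out3$records$flags)))
})

drift_summaries <- function(fm_start = 1000, decline = 0.4, n = 16,
                            fvfm = 0.82) {
  fm <- fm_start * seq(1, 1 - decline, length.out = n)
  fv <- rep_len(fvfm, n)
  data.frame(night_date = as.Date("2014-06-01") + seq_len(n) - 1,
             head_id = "H1", f0 = fm * (1 - fv), fm = fm, fvfm = fv,
             n_used = 10L, qc_ok = TRUE, stringsAsFactors = FALSE)
}

drift_records <- function(summ) {
  n <- nrow(summ)
  rec <- data.frame(timestamp = as.POSIXct(paste(summ$night_date, "12:00:00"),
                                           tz = "UTC"),
                    head_id = "H1", par = 500, temp_c = 10,
                    f_prime = summ$f0, fm_prime = summ$fm,
                    stringsAsFactors = FALSE)
  pam_dataset(rec)
}

test_that("a 40% Fm slide with constant Fv/Fm is drift; downregulation is not", {
  s <- drift_summaries()
  out <- filter_drift(drift_records(s), s)
  expect_true(any(out$summaries$drift))
  expect_gt(sum(flag_has(out$dataset$records$flags, "DRIFT")), 0)

  # same Fm decline but Fv/Fm falling 0.83 -> 0.55: winter downregulation
  s2 <- drift_summaries()
  s2$fvfm <- seq(0.83, 0.55, length.out = nrow(s2))
  s2$f0 <- s2$fm * (1 - s2$fvfm)
  out2 <- filter_drift(drift_records(s2), s2)
  expect_false(any(out2$summaries$drift))

  # flat Fm: nothing to flag
  s3 <- drift_summaries(decline = 0)
  out3 <- filter_drift(drift_records(s3), s3)
  expect_false(any(out3$summaries$drift))
})

test_that("too few usable nights makes the drift filter a no-op", {
  s <- drift_summaries(n = 5)
  expect_message(out <- filter_drift(drift_records(s), s), "fewer than")
  expect_false(any(out$summaries$drift))
})

test_that("implausible PhiP is flagged YII_OUT", {
  ds <- make_ds(n = 3, f = c(5, 30, 100), fm = c(100, 100, 120))
  out <- filter_yii(ds)  # phi = 0.95, 0.70, 0.167
  fl <- out$records$flags
  expect_true(flag_has(fl[1], "YII_OUT"))
  expect_false(flag_has(fl[2], "YII_OUT"))
  expect_false(flag_has(fl[3], "YII_OUT"))
})

test_that("a stricter jump threshold flags a superset (per-rule monotonicity)", {
  ds <- make_ds(n = 5, par = 0,
                f = c(200, 153, 100, 97, 98),
                fm = c(600, 460, 300, 290, 295))
  cl <- classify_day_night(ds)
  strict <- filter_night_jump(cl$dataset, cl$windows,
                              filter_config(night_jump_rel = 0.20))
  weak <- filter_night_jump(cl$dataset, cl$windows,
                            filter_config(night_jump_rel = 0.40))
  s_idx <- which(flag_has(strict$records$flags, "NIGHT_JUMP"))
  w_idx <- which(flag_has(weak$records$flags, "NIGHT_JUMP"))
  expect_true(all(w_idx %in% s_idx))
  expect_gt(length(s_idx), length(w_idx))
})

test_that("the cascade preserves values, is idempotent, and passes clean data", {
  sim <- clean_short_season()
  fl1 <- apply_filters(sim$dataset)
  expect_equal(fl1$report$retained_fraction, 1.0)
  expect_identical(fl1$dataset$records$f_prime, sim$dataset$records$f_prime)
  expect_identical(fl1$dataset$records$fm_prime, sim$dataset$records$fm_prime)

  art <- cached_season("art_small",
                       sim_config(seed = 5, n_days = 30,
                                  dew_prob_per_night = 0.4,
                                  drift_onset_day = 40))
  fa1 <- apply_filters(art$dataset)
  fa2 <- apply_filters(fa1$dataset)
  expect_identical(fa2$dataset$records$flags, fa1$dataset$records$flags)
  expect_identical(fa1$dataset$records$fm_prime, art$dataset$records$fm_prime)
  expect_lt(fa1$report$retained_fraction, 1.0)
})

test_that("filter configs survive the key=value round trip", {
  cfg <- filter_config(f_min_mv = 35, night_jump_rel = 0.25, drift_days = 10)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_filter_config(cfg, path)
  back <- read_filter_config(path)
  expect_equal(back$f_min_mv, 35)
  expect_equal(back$night_jump_rel, 0.25)
  expect_equal(back$drift_days, 10)
  expect_error(filter_config(night_jump_rel = 1.2), "thresholds")
})
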