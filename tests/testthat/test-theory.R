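test_that("lake-model yields at the origin, the reference point, and limits", {
  y0 <- yields(0, 0)
  expect_equal(y0$phi_f, 0.1)
  expect_equal(y0$phi_fm, 0.1)
  expect_equal(y0$phi_p, 0)
  # pq at PQ_max(0.83): phi_p equals the reference Fv/Fm
  yr <- yields(pq_max(0.83), 0)
  expect_equal(yr$phi_p, 0.83, tolerance = 1e-12)
  expect_equal(yields(4.88, 0)$phi_p, 4.88 / 5.88, tolerance = 1e-12)
  # strong NPQ quenches every yield monotonically toward zero
  npq <- c(1, 10, 100, 1e4)
  yy <- yields(2, npq)
  expect_true(all(diff(yy$phi_f) < 0) && all(diff(yy$phi_fm) < 0) &&
                all(diff(yy$phi_p) < 0))
  expect_lt(yields(2, 1e9)$phi_fm, 1e-8)
})

test_that("yields satisfy the exact closure identities", {
  set.seed(8)
  pq <- runif(200, 0, 6); npq <- runif(200, 0, 6)
  y <- yields(pq, npq)
  expect_equal(y$phi_p, pq / (1 + pq + npq), tolerance = 1e-15)
  expect_equal(y$phi_f * (1 + pq + npq), rep(0.1, 200), tolerance = 1e-15)
})

test_that("forward model reproduces the direct-substitution example", {
  # all quenching zero, k_f/(k_f+k_d) = 0.1, PAR_ML A alpha_II beta = 5000
  cst <- optical_constants(par_ml = 1, a_leaf = 1, alpha_ii = 1,
                           beta = 5000, k_f = 0.1, k_d = 0.9)
  st <- quench_state(pq = 0, npq = 0)
  fw <- forward_f(st, cst)
  expect_equal(fw$f_prime, 500)
  expect_equal(fw$fm_prime, 500)
  # closed centers: ql_r = 0 makes the pulse invisible
  st2 <- quench_state(npq = 0.7, ql_r = 0, ql_s = 1, constants = cst)
  fw2 <- forward_f(st2, cst)
  expect_equal(fw2$f_prime, fw2$fm_prime)
})

test_that("forward signals and yields tell one consistent story", {
  cst <- optical_constants(par_ml = 1, a_leaf = 0.84, alpha_ii = 0.5,
                           beta = 12000, k_f = 0.1, k_d = 0.9,
                           k_npqs = 0.4, k_npqr = 0.8, k_psii = 4.88)
  for (qlr in c(0.3, 0.7, 1)) for (qls in c(0.8, 1)) {
    st <- quench_state(ql_r = qlr, ql_s = qls, constants = cst)
    fw <- forward_f(st, cst)
    y <- yields(st)
    expect_equal(1 - fw$f_prime / fw$fm_prime, y$phi_p, tolerance = 1e-12)
    expect_equal(fw$f_prime / fw$fm_prime, y$phi_f / y$phi_fm,
                 tolerance = 1e-12)
  }
})

test_that("inversion matches the direct arithmetic and reference state", {
  iv <- invert_to_quench(250, 500, 1000)
  expect_equal(iv$npq, 1.0)
  expect_equal(iv$pq, 2.0)
  ref <- invert_to_quench(170, 1000, 1000, f0r = 170)
  expect_equal(ref$npq, 0)
  expect_equal(ref$pq, pq_max(0.83), tolerance = 1e-12)
  expect_error(invert_to_quench(300, 1100, 1000), "re-estimate")
  expect_error(invert_to_quench(600, 500, 1000), "0 < f < fm")
})

test_that("forward then invert is the identity on a 50 x 50 grid", {
  cst <- optical_constants(par_ml = 1, a_leaf = 1, alpha_ii = 1,
                           beta = 5000, k_f = 0.1, k_d = 0.9)
  fmr <- 5000 * 0.1  # signal with no quenching
  g <- expand.grid(pq = seq(0.01, 6, length.out = 50),
                   npq = seq(0, 6, length.out = 50))
  st <- quench_state(pq = g$pq, npq = g$npq)
  fw <- forward_f(st, cst)
  iv <- invert_to_quench(fw$f_prime, fw$fm_prime, fmr)
  expect_lt(max(abs(iv$pq - g$pq) / g$pq), 1e-12)
  expect_lt(max(abs(iv$npq - g$npq) / pmax(g$npq, 1)), 1e-12)
  # consistency contract: yields of the inverted state reproduce the
  # normalised signals
  y <- yields(iv$pq, iv$npq)
  expect_equal(y$phi_f, 0.1 * fw$f_prime / fmr, tolerance = 1e-12)
  expect_equal(y$phi_fm, 0.1 * fw$fm_prime / fmr, tolerance = 1e-12)
})

test_that("a PSI offset biases inverted npq downward, worst at low signal", {
  # C_PSI adds a pulse-insensitive pedestal; inverting while ignoring it
  # compresses the apparent quenching: npq_est = S npq / (S + c (1+npq))
  c_psi <- 25
  cst <- optical_constants(par_ml = 1, a_leaf = 1, alpha_ii = 1,
                           beta = 5000, k_f = 0.1, k_d = 0.9,
                           c_psi = c_psi)
  fmr_obs <- 5000 * 0.1 + c_psi
  npq <- seq(0.5, 6, length.out = 20)
  st <- quench_state(pq = rep(2, 20), npq = npq)
  fw <- forward_f(st, cst)
  iv <- invert_to_quench(fw$f_prime, fw$fm_prime, fmr_obs)
  bias <- iv$npq - npq
  expect_true(all(bias < 0))
  expect_true(all(diff(bias) < 0))  # grows with quenching (lower signal)
})

test_that("the three canonical day regimes classify to their taxonomy", {
  expect_equal(phase_sequence(classify_phases(phase_fixture_day("cloudy"))),
               "PQ1")
  expect_equal(phase_sequence(classify_phases(phase_fixture_day("summer"))),
               c("PQ1", "NPQ"))
  expect_equal(phase_sequence(classify_phases(phase_fixture_day("winter"))),
               c("PQ1", "PQ2"))
})

test_that("phase labels ignore uniform rescaling of the fluorescence", {
  # two datasets differing by a gain factor produce identical pq/npq
  # trajectories, hence identical labels
  fmr <- 1000
  npq <- c(0.1, 0.12, 0.5, 1.2, 2.2, 2.5, 2.6)
  pq <- c(4.5, 3.4, 3.1, 3.0, 2.9, 2.1, 1.4)
  for (gain in c(1, 0.2, 12)) {
    f <- gain * fmr / (1 + pq + npq)
    fm <- gain * fmr / (1 + npq)
    iv <- invert_to_quench(f, fm, gain * fmr)
    tr <- data.frame(pq_t = iv$pq, npq_t = iv$npq)
    if (gain == 1) base_seq <- phase_sequence(classify_phases(tr))
    expect_equal(phase_sequence(classify_phases(tr)), base_seq)
  }
})

test_that("too few points yields an empty labelling with a notice", {
  expect_message(out <- classify_phases(data.frame(pq_t = 1, npq_t = 1)),
                 "fewer than 3")
  expect_equal(nrow(out), 0)
})

test_that("yield_grid tabulates the iso-line surface consistently", {
  g <- yield_grid(pq = c(0, 2), npq = c(0, 1))
  expect_equal(nrow(g), 4)
  at <- g[g$pq == 2 & g$npq == 1, ]
  expect_equal(at$phi_p, 0.5)
  expect_equal(at$phi_fm, 0.05)
})
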