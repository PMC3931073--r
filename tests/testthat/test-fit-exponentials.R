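test_that("a pure single exponential is recovered exactly", {
  tr <- make_biexp_trace(a1 = 17, k1 = 69)
  f <- fit_exponentials(tr, 1)
  expect_true(f$converged)
  expect_equal(f$phases$kobs, 69, tolerance = 1e-7)
  expect_equal(f$phases$amplitude, 17, tolerance = 1e-7)
  expect_equal(f$baseline, 1.17, tolerance = 1e-9)
})

test_that("noiseless in-family data is recovered to 0.1% with signed amplitudes", {
  # includes a quench (negative amplitude) case
  cases <- list(c(29, 265, 4.7, 34), c(-12, 150, -3, 8), c(40, 500, 5, 20))
  for (cs in cases) {
    tr <- make_biexp_trace(cs[1], cs[2], cs[3], cs[4])
    f <- fit_exponentials(tr, 2)
    expect_true(f$converged)
    expect_equal(f$phases$kobs, c(cs[2], cs[4]), tolerance = 1e-3)
    expect_equal(f$phases$amplitude, c(cs[1], cs[3]), tolerance = 1e-3)
  }
})

test_that("the printed biphasic dissociation example is recovered within 3 SE", {
  tr <- make_biexp_trace(29, 265, 4.7, 34, noise_sd = 0.5, seed = 42, n = 600)
  f <- fit_exponentials(tr, 2)
  expect_true(f$converged)
  expect_lt(abs(f$phases$kobs[1] - 265), 3 * f$phases$kobs_se[1])
  expect_lt(abs(f$phases$kobs[2] - 34), 3 * f$phases$kobs_se[2])
  expect_lt(abs(f$phases$amplitude[1] - 29), 3 * f$phases$amplitude_se[1])
  expect_lt(abs(f$phases$amplitude[2] - 4.7), 3 * f$phases$amplitude_se[2])
})

test_that("closely spaced rates are poorly identified and selection prefers one phase", {
  # identifiability sweep at fixed noise: relative SE of the fast rate
  # explodes as the rate ratio approaches 1
  worst_rel_se <- sapply(c(1.1, 1.3, 2, 5, 10), function(r) {
    tr <- make_biexp_trace(15, 50 * r, 15, 50, noise_sd = 0.3, seed = 7, n = 500)
    f <- fit_exponentials(tr, 2)
    max(f$phases$kobs_se / f$phases$kobs)
  })
  expect_gt(worst_rel_se[1], 10 * worst_rel_se[5])
  expect_gt(worst_rel_se[2], 10 * worst_rel_se[5])
  expect_lt(worst_rel_se[5], 0.05)
  tr_close <- make_biexp_trace(15, 60, 15, 50, noise_sd = 0.3, seed = 7, n = 500)
  expect_identical(as.integer(select_phase_count(tr_close)), 1L)
  tr_far <- make_biexp_trace(15, 250, 15, 50, noise_sd = 0.3, seed = 7, n = 500)
  expect_identical(as.integer(select_phase_count(tr_far)), 2L)
})

test_that("phase-count selection behaves at the boundaries", {
  # single-exponential truth plus noise
  tr1 <- make_biexp_trace(20, 80, noise_sd = 0.4, seed = 3)
  expect_identical(as.integer(select_phase_count(tr1)), 1L)
  # displacement-like truth: well separated phases
  tr2 <- make_biexp_trace(38, 60.4, 4, 0.78, noise_sd = 0.4, seed = 5, n = 700)
  expect_identical(as.integer(select_phase_count(tr2)), 2L)
  # second amplitude exactly zero
  tr3 <- make_biexp_trace(20, 80, 0, 5)
  expect_identical(as.integer(select_phase_count(tr3)), 1L)
})

test_that("fits compose with simulation: fit(simulate(theta)) = theta", {
  # acto-S1 dissociation has exactly two observable modes: agreement to 1%
  p2 <- mut_fig()$scheme2
  tr2 <- simulate_transient(p2, atp = 500, n_points = 500)
  ph2 <- eigen_phases(p2, atp = 500)
  f2 <- fit_exponentials(tr2, 2)
  expect_equal(f2$phases$kobs, ph2$rate[1:2], tolerance = 0.01)
  expect_equal(f2$phases$amplitude, ph2$amplitude[1:2], tolerance = 0.01)
  # the S1 scheme carries a third, tiny product-release mode; the fast phase
  # is still exact and the slow phase accurate to a few percent
  p1 <- mut_fig()$scheme1
  tr1 <- simulate_transient(p1, atp = 250, n_points = 500)
  ph1 <- eigen_phases(p1, atp = 250)
  f1 <- fit_exponentials(tr1, 2)
  expect_equal(f1$phases$kobs[1], ph1$rate[1], tolerance = 1e-3)
  expect_equal(f1$phases$kobs[2], ph1$rate[2], tolerance = 0.04)
})

test_that("parameter standard errors scale linearly with noise", {
  noise <- c(0.1, 0.5, 1, 2)
  se <- sapply(noise, function(s) {
    f <- fit_exponentials(make_biexp_trace(25, 100, noise_sd = s, seed = 11,
                                           n = 500), 1)
    f$phases$kobs_se
  })
  slope <- stats::coef(lm(se ~ 0 + noise))[[1]]
  expect_lt(max(abs(se - slope * noise) / (slope * noise)), 0.2)
})

test_that("discarding the dead time barely moves moderate rates", {
  tr <- make_biexp_trace(25, 300, noise_sd = 0.05, seed = 9, n = 1500,
                         dead_time = 1e-4, t_max = 0.2)
  f_full <- fit_exponentials(tr, 1)
  f_cut <- fit_exponentials(tr[tr$time >= 0.0015, ], 1)
  expect_lt(abs(f_cut$phases$kobs - f_full$phases$kobs) / f_full$phases$kobs,
            0.01)
})

test_that("tidy and glance expose the fit in broom shape", {
  f <- fit_exponentials(make_biexp_trace(29, 265, 4.7, 34), 2)
  td <- tidy(f)
  expect_identical(td$phase, c("fast", "slow"))
  expect_named(td, c("phase", "kobs", "kobs_se", "amplitude", "amplitude_se"))
  gl <- glance(f)
  expect_identical(gl$n_phases, 2L)
  expect_true(gl$converged)
})

test_that("traces that are too short are rejected", {
  tr <- make_biexp_trace(17, 69, n = 10)
  expect_error(fit_exponentials(tr, 1), "50 samples")
})
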