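test_that("derived constants are exact ratios of their stored inputs", {
  d_wt <- derive_constants(list(K1k2 = 1.5, k_plus2 = 160, k_slow = 14))
  expect_equal(d_wt$value[d_wt$quantity == "one_over_K1"], 160 / 1.5,
               tolerance = 1e-12)
  expect_equal(d_wt$value[d_wt$quantity == "detached_lifetime"], 1000 / 14,
               tolerance = 1e-12)
  d_mut <- derive_constants(list(k_slow = 4, K_DA = 470, K_A = 24,
                                 K_AD = 18, K_D = 0.7))
  expect_equal(d_mut$value[d_mut$quantity == "detached_lifetime"], 250)
  expect_equal(d_mut$value[d_mut$quantity == "K_DA_over_K_A"], 470 / 24,
               tolerance = 1e-12)
  expect_equal(d_mut$value[d_mut$quantity == "K_AD_over_K_D"], 18 / 0.7,
               tolerance = 1e-12)
  # missing primaries drop their rows (with a message), never error
  expect_message(d_min <- derive_constants(list(k_slow = 14)), "skipped")
  expect_identical(d_min$quantity, "detached_lifetime")
})

test_that("the half-saturation diagnostic discriminates binding from hydrolysis", {
  # independent slope measurement close to k_max / K_half: binding control
  out <- assign_fast_phase(k_max = 102, K_half = 93, K1k2 = 1.1)
  expect_identical(out$diagnosis, "binding-limited")
  expect_equal(out$k_half_rate, 51)
  expect_equal(out$half_conc_hydrolysis, 102 / 2.2, tolerance = 1e-12)
  expect_equal(out$ratio, 93 / (102 / 2.2), tolerance = 1e-12)
  expect_false(out$degenerate)
  # slope derived from the same fit: flagged degenerate by identity
  out_d <- assign_fast_phase(k_max = 88, K_half = 93, K1k2 = 0.946)
  expect_true(out_d$degenerate)
  # observed half-max equidistant from both predictions: indeterminate
  out_i <- assign_fast_phase(k_max = 100, K_half = 100 / sqrt(2), K1k2 = 1)
  expect_identical(out_i$diagnosis, "indeterminate")
  # hydrolysis-controlled case
  out_h <- assign_fast_phase(k_max = 100, K_half = 50, K1k2 = 1)
  expect_identical(out_h$diagnosis, "hydrolysis-limited")
})

test_that("construct comparison reports ratios, Welch tests and flags", {
  ref <- tibble::tibble(parameter = "K_alphaD", prep = 1:3,
                        value = c(3.5, 3.7, 3.9))
  alt <- tibble::tibble(parameter = "K_alphaD", prep = 1:3,
                        value = c(7.6, 8.0, 8.4))
  out <- compare_constructs(ref, alt)
  expect_equal(out$ratio, 8 / 3.7, tolerance = 1e-12)
  expect_true(out$significant)
  # identical replicate sets: ratio 1, p = 1
  same <- compare_constructs(ref, ref)
  expect_equal(same$ratio, 1)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # single replicate: ratio only, no test
  out1 <- compare_constructs(ref[1, ], alt[1, ])
  expect_true(is.na(out1$p_value))
  expect_equal(out1$ratio, 7.6 / 3.5, tolerance = 1e-12)
})

test_that("three preparations give good power to detect the ATP-binding change", {
  # Monte-Carlo power of the Welch test for 160 +/- 23 vs 102 +/- 14, n = 3
  hits <- withr::with_seed(99, {
    sapply(1:400, function(i) {
      x <- rnorm(3, 160, 23)
      y <- rnorm(3, 102, 14)
      stats::t.test(x, y)$p.value < 0.05
    })
  })
  expect_gt(mean(hits), 0.6)
})
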