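adp_grid <- c(0, 5, 10, 15, 20, 30, 50, 75, 100)

test_that("competitive ADP inhibition recovers the apparent affinity", {
  s <- tibble::tibble(conc = adp_grid, kobs = 28 / (1 + adp_grid / 13))
  fit <- fit_adp_competition(s, atp_conc = 20)
  expect_equal(fit$K_AD, 13, tolerance = 1e-6)
  expect_equal(fit$kobs0, 28, tolerance = 1e-6)
  # direct half-point identity of the competition form
  expect_equal(fit$kobs0 / (1 + fit$K_AD / fit$K_AD), fit$kobs0 / 2,
               tolerance = 1e-12)
})

test_that("competition fit rejects uninformative or contradictory series", {
  expect_error(fit_adp_competition(tibble::tibble(conc = c(0, 0, 0),
                                                  kobs = c(28, 28.1, 27.9))),
               "no inhibition")
  rising <- tibble::tibble(conc = adp_grid, kobs = 10 + 0.5 * adp_grid)
  expect_error(fit_adp_competition(rising), "model violation")
})

test_that("amplitude ratios define the conformational equilibrium", {
  out <- k_minus_alpha_from_amplitudes(29, 4.7, 85)
  expect_equal(out$K_alpha, 29 / 4.7, tolerance = 1e-12)
  expect_equal(out$k_minus_alpha, 85 / (29 / 4.7), tolerance = 1e-12)
  eq <- k_minus_alpha_from_amplitudes(12, 12, 49)
  expect_equal(eq$K_alpha, 1)
  expect_equal(eq$k_minus_alpha, 49)
  # fast-myosin limit: vanished slow phase
  sen <- k_minus_alpha_from_amplitudes(30, 0, 85)
  expect_identical(sen$K_alpha, Inf)
  expect_identical(sen$k_minus_alpha, 0)
})

test_that("overall ADP affinity conventions are exact inverses", {
  for (conv in c("partition", "reciprocal")) {
    K <- overall_KAD(implied_KADP(10, 3.7, conv), 3.7, conv)
    expect_equal(K, 10, tolerance = 1e-12)
  }
  # the primed state vanishes: overall equals elementary
  expect_equal(overall_KAD(12.7, Inf), 12.7)
  expect_equal(implied_KADP(10, Inf), 10)
  # summary-table pair under both candidate algebraic forms
  expect_equal(implied_KADP(10, 3.7, "partition"), 10 * 4.7 / 3.7,
               tolerance = 1e-12)
  expect_equal(implied_KADP(10, 3.7, "reciprocal"), 10 * 3.7 / 4.7,
               tolerance = 1e-12)
  # default convention: partitioning tightens the overall affinity
  expect_lt(overall_KAD(12.7, 3.7), 12.7)
})

titration_grid <- c(0, 5, 10, 15, 20, 25, 30, 35, 45, 60, 90, 120, 160,
                    300, 600, 1000, 1600)

test_that("quadratic titration recovers K_D across three decades", {
  for (K in c(1, 10, 100, 1000)) {
    amp <- 30 * quadratic_bound(titration_grid, 30, K) / 30
    fit <- fit_quadratic_titration(
      tibble::tibble(s1_total = titration_grid, amplitude = amp), A0 = 30)
    expect_lt(abs(fit$K_D - K) / K, 0.01)
    expect_false(fit$tight_binding)
  }
})

test_that("the stoichiometric limit is flagged and the root stays physical", {
  amp <- 25 * quadratic_bound(titration_grid, 30, 0.2) / 30
  expect_warning(
    fit <- fit_quadratic_titration(
      tibble::tibble(s1_total = titration_grid, amplitude = amp), A0 = 30),
    "tight-binding")
  expect_true(fit$tight_binding)
  # K_D -> 0: the isotherm is piecewise linear in min(M, A0)
  expect_equal(quadratic_bound(titration_grid, 30, 1e-9),
               pmin(titration_grid, 30), tolerance = 1e-4)
  b <- quadratic_bound(titration_grid, 30, 50)
  expect_true(all(b >= 0 & b <= pmin(titration_grid, 30) + 1e-12))
})

test_that("the quadratic reduces to a hyperbola when actin is dilute", {
  K <- 200
  M <- seq(10, 2000, length.out = 40)
  b_quad <- quadratic_bound(M, K / 100, K)
  b_hyp <- (K / 100) * M / (M + K)
  expect_lt(max(abs(b_quad - b_hyp) / b_hyp), 0.01)
})

test_that("titration inputs are validated", {
  curve <- tibble::tibble(s1_total = titration_grid,
                          amplitude = 30 * quadratic_bound(titration_grid, 30, 100) / 30)
  expect_error(fit_quadratic_titration(curve), "A0")
  expect_error(fit_quadratic_titration(dplyr::mutate(curve, amplitude = -amplitude),
                                       A0 = 30), ">= 0")
})
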