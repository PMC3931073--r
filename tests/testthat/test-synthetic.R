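test_that("identical seeds give bit-identical experiments", {
  des <- experiment_design("trp_atp_titration")
  inst <- instrument_model(noise_sd = 0.5, n_points = 200)
  e1 <- generate_experiment(des, mut_fig(), inst, seed = 77)
  e2 <- generate_experiment(des, mut_fig(), inst, seed = 77)
  for (i in seq_along(e1$conditions$trace)) {
    expect_identical(e1$conditions$trace[[i]]$signal,
                     e2$conditions$trace[[i]]$signal)
  }
  e3 <- generate_experiment(des, mut_fig(), inst, seed = 78)
  expect_false(identical(e1$conditions$trace[[1]]$signal,
                         e3$conditions$trace[[1]]$signal))
})

test_that("zero noise leaves fit residuals at machine precision", {
  des <- experiment_design("pyrene_atp_dissociation")
  e <- generate_experiment(des, mut_fig(), quiet_instrument(300), seed = 1)
  f <- fit_exponentials(e$conditions$trace[[8]], 2)
  expect_lt(glance(f)$sigma, 1e-7)
})

test_that("generated amplitude structure matches the calibrated observables", {
  # tryptophan: ~17% fast / ~1% slow rise at saturating ATP
  e <- generate_experiment(experiment_design("trp_atp_titration"), mut_fig(),
                           quiet_instrument(400), seed = 1)
  f <- fit_exponentials(e$conditions$trace[[8]], 2)
  expect_equal(f$phases$amplitude[1], 17, tolerance = 0.05)
  expect_equal(f$phases$amplitude[2], 1, tolerance = 0.3)
  # pyrene-actin: total dissociation amplitude ~30-34% of pre-mix
  e2 <- generate_experiment(experiment_design("pyrene_atp_dissociation"),
                            mut_fig(), quiet_instrument(400), seed = 1)
  f2 <- fit_exponentials(e2$conditions$trace[[8]], 2)
  expect_gt(sum(f2$phases$amplitude), 30)
  expect_lt(sum(f2$phases$amplitude), 35)
})

test_that("the full chain recovers the generating constants", {
  inst <- quiet_instrument(700)
  ref <- mut_fig()
  # tryptophan ATP titration -> scheme-1 binding constants
  r1 <- analyze_experiment(generate_experiment(
    experiment_design("trp_atp_titration"), ref, inst, seed = 2))
  est1 <- setNames(r1$estimates$value, r1$estimates$parameter)
  p1 <- ref$scheme1
  expect_equal(est1[["k_plus2"]], p1$k_plus2, tolerance = 0.02)
  expect_equal(est1[["one_over_K1"]], 1 / p1$K1, tolerance = 0.02)
  expect_equal(est1[["k_slow"]], p1$k_plus3 + p1$k_minus3, tolerance = 0.05)
  # pyrene dissociation -> scheme-2 binding constants
  r2 <- analyze_experiment(generate_experiment(
    experiment_design("pyrene_atp_dissociation"), ref, inst, seed = 2))
  est2 <- setNames(r2$estimates$value, r2$estimates$parameter)
  p2 <- ref$scheme2
  expect_equal(est2[["k_plus2_prime"]], p2$k_plus2_prime, tolerance = 0.02)
  expect_equal(est2[["one_over_K1_prime"]], 1 / p2$K1_prime, tolerance = 0.02)
  expect_equal(est2[["k_plus_alpha"]], p2$k_plus_alpha, tolerance = 0.02)
  # the amplitude-ratio estimate of K_alpha carries an O(k_plus_alpha/kobs)
  # truncation bias; it is only accurate to ~15% on this grid
  expect_equal(est2[["K_alpha"]], K_alpha(p2), tolerance = 0.15)
  # ADP competition -> overall ADP affinity (finite-exchange bias < 5%)
  r3 <- analyze_experiment(generate_experiment(
    experiment_design("adp_competition"), ref, inst, seed = 2))
  expect_equal(r3$estimates$value[1], p2$K_AD, tolerance = 0.05)
  # ADP displacement -> release rate and primed-state isomerization
  r4 <- analyze_experiment(generate_experiment(
    experiment_design("adp_displacement"), ref, inst, seed = 2))
  est4 <- setNames(r4$estimates$value, r4$estimates$parameter)
  expect_equal(est4[["k_minusAD"]], p2$k_minusAD, tolerance = 0.02)
  expect_equal(est4[["k_plus_alphaD"]], p2$k_plus_alphaD, tolerance = 0.06)
  # actin titrations -> affinities in the absence and presence of ADP
  r5 <- analyze_experiment(generate_experiment(
    experiment_design("actin_titration"), ref, inst, seed = 2))
  est5 <- setNames(r5$estimates$value, r5$estimates$parameter)
  expect_equal(est5[["K_A"]], p2$K_A, tolerance = 0.01)
  expect_equal(est5[["K_DA"]], p2$K_DA, tolerance = 0.01)
})

test_that("noisy full-chain recovery lands within 2 SE of the generating rate", {
  e <- generate_experiment(experiment_design("trp_atp_titration"), wt_tab(),
                           instrument_model(noise_sd = 0.5, n_points = 500),
                           seed = 1)
  hyper <- analyze_experiment(e)$fits$hyperbola
  expect_lt(abs(hyper$k_max - wt_tab()$scheme1$k_plus2),
            2 * max(hyper$k_max_se, 0.02 * hyper$k_max))
})

test_that("zero inter-preparation CV collapses replicates", {
  cv0 <- setNames(rep(0, length(myokin:::default_prep_cv)),
                  names(myokin:::default_prep_cv))
  b <- battery(wt_fig(), mut_fig(), seed = 5, n_prep = 2,
               instrument = quiet_instrument(300),
               designs = "trp_atp_titration", prep_cv = cv0)
  wide <- tidyr::pivot_wider(b$fits, id_cols = c("construct", "parameter"),
                             names_from = "prep", values_from = "value")
  expect_equal(wide$`1`, wide$`2`, tolerance = 1e-9)
})

test_that("swapping construct labels inverts the comparison ratios", {
  b <- battery(wt_fig(), mut_fig(), seed = 6, n_prep = 2,
               instrument = instrument_model(noise_sd = 0.2, n_points = 300),
               designs = "trp_atp_titration")
  tbl <- function(cn) {
    f <- dplyr::filter(b$fits, construct == cn)
    tibble::tibble(parameter = f$parameter, prep = f$prep, value = f$value)
  }
  fwd <- compare_constructs(tbl("ref"), tbl("alt"))
  rev <- compare_constructs(tbl("alt"), tbl("ref"))
  j <- dplyr::inner_join(fwd, rev, by = "parameter", suffix = c("_f", "_r"))
  expect_equal(j$ratio_f, 1 / j$ratio_r, tolerance = 1e-12)
  expect_equal(j$p_value_f, j$p_value_r, tolerance = 1e-12)
})
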