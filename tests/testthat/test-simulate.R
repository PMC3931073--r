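test_that("state occupancies are conserved at every time point", {
  p <- mut_tab()$scheme2
  Q <- build_rate_matrix(p, atp = 250, adp = 25)
  p0 <- initial_state(p, rownames(Q), adp_premix = 50)
  sys <- myokin:::eigen_system(Q, p0)
  occ <- myokin:::propagate_states(sys, exp(seq(log(1e-4), log(10), length.out = 200)))
  expect_lt(max(abs(rowSums(occ) - 1)), 1e-9)
  expect_gt(min(occ), -1e-9)
})

test_that("analytic propagation agrees with brute-force matrix exponentials", {
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    Q <- matrix(runif(16, 0, 50), 4, 4)
    diag(Q) <- 0
    diag(Q) <- -colSums(Q)
    p0 <- as.numeric(stats::rmultinom(1, 1, rep(1, 4)))
    sys <- myokin:::eigen_system(Q, p0)
    tt <- c(1e-3, 1e-2, 0.1, 1)
    P1 <- myokin:::propagate_states(sys, tt)
    P2 <- t(sapply(tt, function(s) as.numeric(Matrix::expm(Q * s) %*% p0)))
    worst <- max(worst, max(abs(P1 - P2)))
  }
  expect_lt(worst, 1e-8)
})

test_that("analytic path matches a stiff ODE integration", {
  p <- mut_fig()$scheme2
  Q <- build_rate_matrix(p, atp = 500)
  p0 <- initial_state(p, rownames(Q))
  tt <- exp(seq(log(0.0015), log(0.3), length.out = 80))
  sol <- deSolve::lsoda(p0, c(0, tt), function(t, y, parms) list(as.numeric(Q %*% y)),
                        rtol = 1e-10, atol = 1e-12)
  sys <- myokin:::eigen_system(Q, p0)
  expect_lt(max(abs(myokin:::propagate_states(sys, tt) - sol[-1, -1])), 1e-8)
})

test_that("a two-state system relaxes with exactly its single rate", {
  k <- 37.5
  Q <- matrix(c(-k, k, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sys <- myokin:::eigen_system(Q, c(a = 1, b = 0))
  expect_equal(sort(sys$rates), c(0, k), tolerance = 1e-12)
})

test_that("eigen phases reconstruct the simulated signal", {
  p <- mut_fig()$scheme1
  tr <- simulate_transient(p, atp = 250, n_points = 300)
  ph <- eigen_phases(p, atp = 250, drop_null = FALSE)
  base <- attr(ph, "baseline")
  recon <- base - colSums(ph$amplitude / 100 * exp(-outer(ph$rate, tr$time)))
  expect_lt(max(abs(recon - tr$signal)) / diff(range(tr$signal)), 1e-6)
  expect_true(all(diff(ph$rate) <= 0))
})

test_that("with ADP present the slowest observable acto-S1 phase is ADP release limited", {
  p <- wt_tab()$scheme2
  ph <- eigen_phases(p, atp = 2000, adp_premix = 50, adp = 25)
  dominant <- ph$rate[which.max(abs(ph$amplitude))]
  # the dominant displacement phase is capped by ADP release from A.M.D
  expect_lt(abs(dominant - p$k_minusAD) / p$k_minusAD, 0.15)
})

test_that("saturating ATP drives scheme-1 fast phase to the isomerization rate", {
  p <- wt_fig()$scheme1
  ph <- eigen_phases(p, atp = 1e7)
  expect_equal(ph$rate[1], p$k_plus2, tolerance = 1e-4)
})

test_that("explicit two-step binding converges to the rapid-equilibrium collapse", {
  p <- mut_fig()$scheme1
  p$k_minus1 <- 1e4
  t_grid <- exp(seq(log(0.0015), log(1.5), length.out = 250))
  tr_c <- simulate_transient(p, atp = 250, t_grid = t_grid)
  tr_e <- simulate_transient(p, atp = 250, t_grid = t_grid,
                             explicit_binding = TRUE)
  dev <- max(abs(tr_e$signal - tr_c$signal)) / diff(range(tr_c$signal))
  expect_lt(dev, 0.02)
})

test_that("complete dissociation ends at the free-actin fluorescence level", {
  p <- mut_fig()$scheme2
  obs <- observable_map("pyrene-actin")
  tr <- simulate_transient(p, atp = 4000, n_points = 200)
  expect_equal(tail(tr$signal, 1), obs[["A.free"]] / obs[["AM"]],
               tolerance = 1e-4)
})

test_that("traces survive the delimited-text round trip with metadata", {
  p <- wt_fig()$scheme1
  tr <- simulate_transient(p, atp = 100, n_points = 120)
  f <- withr::local_tempfile(fileext = ".txt")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_lt(max(abs(tr2$signal - tr$signal)), 1e-8)
  expect_identical(trace_meta(tr2)$atp, 100)
  expect_identical(trace_meta(tr2)$probe, "tryptophan")
})

test_that("malformed trace files fail with a line-located parse error", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# probe: x", "time_s\trel_fluorescence", "0.001\t1.0",
               "0.002\t1.0\t9"), f)
  expect_error(read_trace(f), "line 4")
  writeLines(c("just text"), f)
  expect_error(read_trace(f), "malformed")
})

test_that("custom initial occupancies are validated", {
  p <- mut_fig()$scheme2
  expect_error(simulate_transient(p, atp = 250, initial = c(bogus = 1)),
               "states")
  expect_error(simulate_transient(p, atp = 250, initial = c(AM = 0.5)),
               "sum to 1")
})
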