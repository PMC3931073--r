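# shared fixtures: reference constants and a noiseless instrument

wt_fig <- function() reference_params("WT", "figures")
mut_fig <- function() reference_params("R453C", "figures")
wt_tab <- function() reference_params("WT", "table")
mut_tab <- function() reference_params("R453C", "table")

quiet_instrument <- function(n_points = 600) {
  instrument_model(noise_sd = 0, n_points = n_points)
}

# analytic biexponential trace builder (pre-mix level 1, amplitudes in %)
make_biexp_trace <- function(a1, k1, a2 = 0, k2 = 1, baseline = NULL,
                             noise_sd = 0, seed = 1, n = 400,
                             t_max = NULL, dead_time = 0.0015) {
  if (is.null(baseline)) baseline <- 1 + (a1 + a2) / 100
  if (is.null(t_max)) t_max <- 20 / min(c(k1, if (a2 != 0) k2))
  t <- exp(seq(log(dead_time), log(t_max), length.out = n))
  y <- baseline - a1 / 100 * exp(-k1 * t) - a2 / 100 * exp(-k2 * t)
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd / 100))
  }
  structure(tibble::tibble(time = t, signal = y),
            meta = list(probe = "synthetic"),
            class = c("myokin_trace", class(tibble::tibble())))
}
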