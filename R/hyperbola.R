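#' Hyperbolic fit of observed rate versus substrate concentration
#'
#' For two-step nucleotide binding with a rapid pre-equilibrium followed by
#' an effectively irreversible isomerization, the observed fast-phase rate
#' is hyperbolic in substrate:
#' `kobs = k_max * [S] / (K_half + [S])`,
#' with `k_max` the isomerization rate, `K_half` the half-saturating
#' concentration (the reciprocal of the binding equilibrium constant), and
#' initial slope `k_max / K_half` the apparent second-order binding constant.
#' The initial slope is reported as the derived ratio (with a delta-method
#' standard error), never fitted independently.
#'
#' @param series a data frame with columns `conc` (uM) and `kobs` (s^-1); if
#'   a `phase` column is present only `phase == "fast"` rows are used. At
#'   least 5 concentrations are required.
#' @return an object of class `hyperbola_fit` with elements `k_max`,
#'   `K_half`, `initial_slope` (each with `_se`), the underlying `nls` fit
#'   and the data; supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' s <- tibble::tibble(conc = c(10, 25, 50, 100, 250, 400),
#'                     kobs = 88 * conc / (81.5 + conc))
#' fit_hyperbola(s)
#' @export
fit_hyperbola <- function(series) {
  series <- as_tibble(series)
  if ("phase" %in% names(series)) series <- filter(series, .data$phase == "fast")
  require_columns(series, c("conc", "kobs"), "a kobs series")
  series <- filter(series, is.finite(.data$kobs))
  series <- arrange(series, .data$conc)
  if (any(diff(series$conc) <= 0)) abort("concentrations must be strictly increasing.")
  if (nrow(series) < 5) abort(">= 5 concentrations are required for a hyperbolic fit.")
  if (var(series$kobs) < 1e-20 * max(1, mean(series$kobs)^2)) {
    abort("degenerate series: kobs shows no concentration dependence.")
  }
  kmax0 <- 1.05 * max(series$kobs)
  khalf0 <- series$conc[which.min(abs(series$kobs - kmax0 / 2))]
  fit <- nlslm_fit(
    function(p) series$kobs - p[["k_max"]] * series$conc / (p[["K_half"]] + series$conc),
    start = c(k_max = kmax0, K_half = max(khalf0, min(series$conc))),
    lower = c(1e-9, 1e-9))
  cf <- fit$par
  if (max(series$conc) < 0.3 * cf[["K_half"]]) {
    abort("saturation not reached: the highest concentration is below 0.3 x K_half.")
  }
  V <- fit$vcov
  se <- sqrt(diag(V))
  slope <- cf[["k_max"]] / cf[["K_half"]]
  # delta method for k_max / K_half
  g <- c(1 / cf[["K_half"]], -cf[["k_max"]] / cf[["K_half"]]^2)
  slope_se <- sqrt(drop(t(g) %*% V %*% g))
  structure(
    list(k_max = cf[["k_max"]], k_max_se = se[[1]],
         K_half = cf[["K_half"]], K_half_se = se[[2]],
         initial_slope = slope, initial_slope_se = slope_se,
         fit = fit, data = series),
    class = "hyperbola_fit")
}

#' @describeIn fit_hyperbola one row per parameter (`k_max`, `K_half`,
#'   `initial_slope`) with estimate and standard error.
#' @param x a `hyperbola_fit`.
#' @param ... unused.
#' @export
tidy.hyperbola_fit <- function(x, ...) {
  tibble(term = c("k_max", "K_half", "initial_slope"),
         estimate = c(x$k_max, x$K_half, x$initial_slope),
         std.error = c(x$k_max_se, x$K_half_se, x$initial_slope_se),
         unit = c("s^-1", "uM", "uM^-1 s^-1"))
}

#' @describeIn fit_hyperbola one-row fit summary.
#' @export
glance.hyperbola_fit <- function(x, ...) {
  r <- x$fit$residuals
  tibble(rss = sum(r^2), sigma = sqrt(sum(r^2) / max(length(r) - 2, 1)),
         n = length(r), converged = x$fit$converged)
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  cat("<hyperbola_fit>  kobs = k_max [S] / (K_half + [S])\n")
  cat(sprintf("  k_max        : %.4g +/- %.2g s^-1\n", x$k_max, x$k_max_se))
  cat(sprintf("  K_half       : %.4g +/- %.2g uM\n", x$K_half, x$K_half_se))
  cat(sprintf("  initial slope: %.4g +/- %.2g uM^-1 s^-1 (= k_max / K_half)\n",
              x$initial_slope, x$initial_slope_se))
  invisible(x)
}

#' Second-order binding constant from the linear low-concentration regime
#'
#' Restricts a kobs series to concentrations at most `frac * K_half` (the
#' regime where the hyperbola is linear) and fits a straight line through
#' the origin (default) or with a free intercept. The slope is the apparent
#' second-order binding constant (uM^-1 s^-1).
#'
#' @inheritParams fit_hyperbola
#' @param K_half the half-saturating concentration delimiting the linear
#'   regime; if `NULL` it is estimated by a preliminary hyperbolic fit.
#' @param frac linear-regime cutoff as a fraction of `K_half` (default 0.2).
#' @param through_origin force the intercept to zero (default TRUE).
#' @return a tibble with `slope`, `slope_se`, `intercept`, `n_used`.
#' @export
fit_linear_low_conc <- function(series, K_half = NULL, frac = 0.2,
                                through_origin = TRUE) {
  series <- as_tibble(series)
  if ("phase" %in% names(series)) series <- filter(series, .data$phase == "fast")
  require_columns(series, c("conc", "kobs"), "a kobs series")
  if (is.null(K_half)) K_half <- fit_hyperbola(series)$K_half
  sub <- filter(series, .data$conc <= frac * K_half)
  if (nrow(sub) < 3) {
    abort(sprintf("fewer than 3 points at concentrations <= %.3g uM (0.%d x K_half).",
                  frac * K_half, round(frac * 10)))
  }
  fm <- if (through_origin) lm(kobs ~ 0 + conc, data = sub) else lm(kobs ~ conc, data = sub)
  sm <- suppressWarnings(summary(fm))$coefficients
  tibble(slope = sm["conc", "Estimate"], slope_se = sm["conc", "Std. Error"],
         intercept = if (through_origin) 0 else unname(coef(fm)[1]),
         n_used = nrow(sub))
}
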