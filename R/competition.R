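#' Competitive ADP-inhibition fit of ATP-induced dissociation rates
#'
#' At low ATP, ATP-induced dissociation of acto-S1 is a single exponential
#' and ADP acts as a rapid-equilibrium competitive inhibitor of the ATP
#' binding site, so the observed rate falls with ADP as
#' `kobs([ADP]) = kobs(0) / (1 + [ADP] / K_AD)`.
#' Both `kobs(0)` and the apparent ADP affinity `K_AD` are estimated jointly
#' (fixing `kobs(0)` to the zero-ADP measurement would propagate its single
#' measurement error into `K_AD`).
#'
#' @param series a data frame with columns `conc` (ADP, uM) and `kobs`
#'   (s^-1); an `[ADP] = 0` point is allowed and used.
#' @param atp_conc the fixed ATP concentration (uM), stored for provenance.
#' @return an object of class `adp_competition_fit` with `K_AD`, `K_AD_se`,
#'   `kobs0`, `kobs0_se`; supports [tidy()] and [glance()].
#' @examples
#' s <- tibble::tibble(conc = c(0, 5, 10, 20, 50, 100),
#'                     kobs = 28 / (1 + conc / 13))
#' fit_adp_competition(s, atp_conc = 20)
#' @export
fit_adp_competition <- function(series, atp_conc = NA) {
  series <- as_tibble(series)
  require_columns(series, c("conc", "kobs"), "an ADP competition series")
  series <- arrange(series, .data$conc)
  if (all(series$conc == 0)) {
    abort("no inhibition information: the series only contains [ADP] = 0.")
  }
  if (nrow(series) < 4) abort(">= 4 ADP concentrations are required.")
  # the competitive model requires kobs to decrease with ADP
  fm <- lm(kobs ~ conc, data = series)
  sl <- suppressWarnings(summary(fm))$coefficients["conc", ]
  if (sl[["Estimate"]] > 0 && sl[["Estimate"]] > 2 * sl[["Std. Error"]]) {
    abort("model violation: kobs increases with [ADP]; competitive inhibition cannot hold.")
  }
  k0_0 <- max(series$kobs)
  half <- series$conc[which.min(abs(series$kobs - k0_0 / 2))]
  fit <- nlslm_fit(
    function(p) series$kobs - p[["kobs0"]] / (1 + series$conc / p[["K_AD"]]),
    start = c(kobs0 = k0_0, K_AD = max(half, 1e-3)),
    lower = c(1e-9, 1e-9))
  cf <- fit$par
  se <- sqrt(diag(fit$vcov))
  structure(
    list(K_AD = cf[["K_AD"]], K_AD_se = se[[2]],
         kobs0 = cf[["kobs0"]], kobs0_se = se[[1]],
         atp_conc = atp_conc, fit = fit, data = series),
    class = "adp_competition_fit")
}

#' @describeIn fit_adp_competition parameter table (`K_AD`, `kobs0`).
#' @param x an `adp_competition_fit`.
#' @param ... unused.
#' @export
tidy.adp_competition_fit <- function(x, ...) {
  tibble(term = c("K_AD", "kobs0"),
         estimate = c(x$K_AD, x$kobs0),
         std.error = c(x$K_AD_se, x$kobs0_se),
         unit = c("uM", "s^-1"))
}

#' @describeIn fit_adp_competition one-row fit summary.
#' @export
glance.adp_competition_fit <- function(x, ...) {
  tibble(rss = x$fit$rss, n = x$fit$n, atp_conc = x$atp_conc,
         converged = x$fit$converged)
}

#' @export
print.adp_competition_fit <- function(x, ...) {
  cat("<adp_competition_fit>  kobs = kobs(0) / (1 + [ADP]/K_AD)\n")
  cat(sprintf("  K_AD   : %.4g +/- %.2g uM\n", x$K_AD, x$K_AD_se))
  cat(sprintf("  kobs(0): %.4g +/- %.2g s^-1", x$kobs0, x$kobs0_se))
  if (is.finite(x$atp_conc)) cat(sprintf("  (at %.3g uM ATP)", x$atp_conc))
  cat("\n")
  invisible(x)
}
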