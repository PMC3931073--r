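#' Tight-binding (quadratic) titration fit of actin affinity
#'
#' In an active-site titration the fixed partner (actin at `A0`) is
#' comparable in concentration to the dissociation constant, so the bound
#' fraction follows the physically significant root of the binding
#' quadratic rather than a hyperbola. With `M` the total S1 added,
#' `bound(M) = ((M + A0 + K_D) - sqrt((M + A0 + K_D)^2 - 4 M A0)) / 2`,
#' the root that lies in `[0, min(A0, M)]`. The transient amplitude is
#' assumed proportional to the actin.S1 complex, so the model fitted is
#' `amplitude = scale * bound(M) / A0` with free `K_D` and `scale`.
#'
#' A best-fit `K_D` below `A0 / 50` is in the stoichiometric (tight-binding)
#' limit where the curve is the piecewise-linear `scale * min(M, A0) / A0`;
#' the fit then only bounds `K_D` from above and a warning is raised.
#'
#' @param curve a data frame with columns `s1_total` (nM) and `amplitude`
#'   (%); should bracket `A0` from below and above.
#' @param A0 fixed actin concentration (nM); taken from
#'   `attr(curve, "A0")` when missing.
#' @return an object of class `titration_fit` with `K_D` (nM), `K_D_se`,
#'   `scale`, `scale_se`, `tight_binding` flag; supports [tidy()] /
#'   [glance()].
#' @examples
#' M <- c(0, 10, 20, 30, 45, 60, 90, 120, 160)
#' amp <- 34 * quadratic_bound(M, A0 = 30, K_D = 11) / 30
#' fit_quadratic_titration(tibble::tibble(s1_total = M, amplitude = amp), A0 = 30)
#' @export
fit_quadratic_titration <- function(curve, A0 = NULL) {
  curve <- as_tibble(curve)
  require_columns(curve, c("s1_total", "amplitude"), "a titration curve")
  A0 <- A0 %||% attr(curve, "A0")
  if (is.null(A0)) abort("`A0` (fixed actin concentration, nM) must be supplied.")
  assert_number(A0, "A0", min = 1e-9)
  if (any(curve$amplitude < -1e-8)) abort("amplitudes must be >= 0.")
  if (nrow(curve) < 5) abort(">= 5 titration points are required.")
  if (!any(curve$s1_total < A0) || !any(curve$s1_total > A0)) {
    warn("titration grid does not bracket A0; K_D may be poorly constrained.")
  }
  amax <- max(curve$amplitude)
  half <- curve$s1_total[which.min(abs(curve$amplitude - amax / 2))]
  K0 <- max(half - A0 / 2, A0 / 20, 1e-3)
  fit <- nlslm_fit(
    function(p) curve$amplitude -
      p[["scale"]] * quadratic_bound(curve$s1_total, A0, p[["K_D"]]) / A0,
    start = c(scale = amax, K_D = K0),
    lower = c(1e-9, 1e-9))
  cf <- fit$par
  se <- sqrt(diag(fit$vcov))
  tight <- cf[["K_D"]] < A0 / 50
  if (tight) {
    warn(sprintf("tight-binding limit: best-fit K_D = %.3g nM < A0/50 = %.3g nM; treat as an upper bound only.",
                 cf[["K_D"]], A0 / 50))
  }
  structure(
    list(K_D = cf[["K_D"]], K_D_se = se[[2]],
         scale = cf[["scale"]], scale_se = se[[1]],
         A0 = A0, tight_binding = tight, fit = fit, data = curve),
    class = "titration_fit")
}

#' Bound complex concentration from the binding quadratic
#'
#' Physically significant root of `x^2 - (M + A0 + K_D) x + M A0 = 0`; the
#' returned concentration always lies in `[0, min(M, A0)]` and reduces to
#' the hyperbola `A0 * M / (M + K_D)` when `A0 << K_D` and to
#' `min(M, A0)` as `K_D -> 0`.
#'
#' @param M total titrant concentration(s) (same units as `A0`).
#' @param A0 fixed partner concentration.
#' @param K_D dissociation constant.
#' @return bound-complex concentration, same length as `M`.
#' @export
quadratic_bound <- function(M, A0, K_D) {
  b <- M + A0 + K_D
  disc <- pmax(b^2 - 4 * M * A0, 0)
  (b - sqrt(disc)) / 2
}

#' @describeIn fit_quadratic_titration parameter table.
#' @param x a `titration_fit`.
#' @param ... unused.
#' @export
tidy.titration_fit <- function(x, ...) {
  tibble(term = c("K_D", "scale"),
         estimate = c(x$K_D, x$scale),
         std.error = c(x$K_D_se, x$scale_se),
         unit = c("nM", "%"))
}

#' @describeIn fit_quadratic_titration one-row fit summary.
#' @export
glance.titration_fit <- function(x, ...) {
  tibble(rss = x$fit$rss, n = x$fit$n, A0 = x$A0,
         tight_binding = x$tight_binding, converged = x$fit$converged)
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit>  amplitude = scale * bound(M; A0, K_D) / A0\n")
  cat(sprintf("  K_D  : %.4g +/- %.2g nM (A0 = %.3g nM)%s\n", x$K_D, x$K_D_se,
              x$A0, if (x$tight_binding) "  [tight-binding: upper bound]" else ""))
  cat(sprintf("  scale: %.4g +/- %.2g %%\n", x$scale, x$scale_se))
  invisible(x)
}
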