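# internal helpers

#' Logarithmically spaced grid
#'
#' @param from,to positive endpoints.
#' @param n number of points.
#' @return numeric vector of length `n`, log-spaced and including both endpoints.
#' @keywords internal
#' @noRd
logspace <- function(from, to, n) {
  stopifnot(from > 0, to > from, n >= 2)
  exp(seq(log(from), log(to), length.out = n))
}

# scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_number <- function(x, name, min = -Inf, allow_na = FALSE) {
  if (allow_na && (is.null(x) || (length(x) == 1L && is.na(x)))) return(invisible(NA_real_))
  if (!is_number(x)) abort(sprintf("`%s` must be a single finite number.", name))
  if (x < min) abort(sprintf("`%s` must be >= %g (got %g).", name, min, x))
  invisible(as.numeric(x))
}

# deterministic splitting of a master seed into per-task sub-seeds; documented
# rule: sub_seed(seed, i) = (seed + 1000003 * i) mod (2^31 - 1), kept positive.
sub_seed <- function(seed, index) {
  s <- (as.numeric(seed) + 1000003 * as.numeric(index)) %% 2147483647
  as.integer(s + (s == 0))
}

# right-pad or recycle column checks for user-supplied tables
require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s must have column(s): %s", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# robust Levenberg-Marquardt least squares on a residual function; avoids the
# nls-model construction that can fail for boundary or near-degenerate
# solutions.  Returns coefficient vector, covariance (sigma^2 (J'J)^-1),
# residuals and a convergence flag.
nlslm_fit <- function(resid_fn, start, lower = NULL) {
  out <- minpack.lm::nls.lm(
    par = start, lower = lower, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  r <- out$fvec
  p <- length(out$par)
  sigma2 <- sum(r^2) / max(length(r) - p, 1)
  V <- tryCatch(sigma2 * solve(out$hessian),
                error = function(e) matrix(NA_real_, p, p,
                                           dimnames = list(names(out$par),
                                                           names(out$par))))
  dimnames(V) <- list(names(out$par), names(out$par))
  list(par = out$par, vcov = V, residuals = r, rss = sum(r^2),
       converged = out$info %in% 1:4, n = length(r))
}
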