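# analytic propagation of dP/dt = Q P via eigen-decomposition

# decompose Q; returns list(rates, modes, coefs) such that
# P(t) = sum_i coefs_i * exp(lambda_i t) * v_i.  Near-degenerate eigenvalues
# are separated by a 1e-9 s^-1 diagonal jitter (logged warning) so the
# eigenvector basis stays well conditioned.
eigen_system <- function(Q, p0) {
  ev <- eigen(Q)
  lam <- ev$values
  if (nrow(Q) > 1 && min(dist(cbind(Re(lam), Im(lam)))) < 1e-9) {
    warn("near-degenerate eigenvalues; applying 1e-9 s^-1 diagonal jitter.")
    Qj <- Q + diag(seq_len(nrow(Q)) * 1e-9, nrow(Q))
    ev <- eigen(Qj)
    lam <- ev$values
  }
  complex_modes <- any(abs(Im(lam)) > 1e-10 * (1 + abs(Re(lam))))
  V <- ev$vectors
  if (!complex_modes) {
    lam <- Re(lam)
    V <- Re(V)
  }
  coefs <- tryCatch(solve(V, p0), error = function(e) {
    warn("defective rate matrix; falling back to least-squares mode coefficients.")
    qr.solve(V, p0)
  })
  list(rates = -Re(lam), lambda = lam, V = V, coefs = coefs,
       complex_modes = complex_modes)
}

propagate_states <- function(sys, t) {
  # occupancy matrix: length(t) x n_states; complex conjugate mode pairs
  # (possible for irreversible cycles) recombine to a real trajectory
  E <- exp(outer(t, sys$lambda))        # e^{lambda t}
  out <- E %*% t(sys$V * rep(sys$coefs, each = nrow(sys$V)))
  if (sys$complex_modes) Re(out) else out
}

default_time_grid <- function(sys, yields, dead_time = 0.0015, n = 1000) {
  # log-spaced from the dead time to 20 / (slowest observable phase); a phase
  # counts as observable when it carries at least 2% of the total transient
  # amplitude, so vanishing slow tails (e.g. basal product release) do not
  # stretch the recorded window
  amp <- Mod(drop(yields %*% sys$V) * sys$coefs)
  transient <- sys$rates > 1e-9
  total <- sum(amp[transient])
  live <- transient & amp > 0.02 * max(total, 1e-300)
  slowest <- if (any(live)) min(sys$rates[live]) else 1
  logspace(dead_time, max(20 / slowest, dead_time * 10), n)
}

#' Simulate a stopped-flow fluorescence transient
#'
#' Builds the rate matrix for the given scheme and concentrations, propagates
#' the pre-mix equilibrium analytically through the eigen-decomposition of
#' the rate matrix, and projects the state occupancies onto per-state
#' fluorescence yields. The returned signal is normalized so the pre-mix
#' level is 1 (set `normalize = "none"` to keep raw yield units, e.g. for
#' titration series that share a common fluorescence scale).
#'
#' @param params a [scheme1_params()] or [scheme2_params()] object.
#' @param atp,adp post-mix nucleotide concentrations (uM).
#' @param observables an [observable_map()]; defaults to tryptophan for
#'   scheme 1 and pyrene-actin for scheme 2.
#' @param t_grid time points (s); default log-spaced `n_points` from
#'   `dead_time` to 20 over the slowest signal-carrying rate.
#' @param dead_time instrument dead time (s); the trace starts there.
#' @param n_points number of samples for the default grid.
#' @param adp_premix ADP (uM) present in the protein syringe before mixing
#'   (sets the initial equilibrium, e.g. ADP-displacement experiments).
#' @param bound_fraction acto-S1 only: fraction of actin with S1 bound at
#'   time zero (titration experiments).
#' @param normalize `"premix"` (default) or `"none"`.
#' @param protein tracked-species concentration (uM), for the
#'   pseudo-first-order check.
#' @param explicit_binding scheme 1 only, see [build_rate_matrix()].
#' @param initial optional named occupancy vector overriding the pre-mix
#'   equilibrium (must be named by rate-matrix states and sum to 1).
#' @return a `myokin_trace`: a tibble with columns `time` (s) and `signal`
#'   (relative fluorescence), carrying a `meta` attribute (probe,
#'   concentrations, scheme, normalization).
#' @examples
#' p <- reference_params("R453C", "figures")$scheme1
#' tr <- simulate_transient(p, atp = 250)
#' head(tr)
#' @export
simulate_transient <- function(params, atp = 0, adp = 0, observables = NULL,
                               t_grid = NULL, dead_time = 0.0015,
                               n_points = 1000, adp_premix = 0,
                               bound_fraction = 1,
                               normalize = c("premix", "none"),
                               protein = 0.01, explicit_binding = FALSE,
                               initial = NULL) {
  normalize <- match.arg(normalize)
  if (is.null(observables)) {
    observables <- if (inherits(params, "scheme1_params")) {
      observable_map("tryptophan")
    } else {
      observable_map("pyrene-actin")
    }
  }
  Q <- build_rate_matrix(params, atp = atp, adp = adp, protein = protein,
                         explicit_binding = explicit_binding)
  states <- rownames(Q)
  y <- yields_for(observables, states, explicit_binding)
  p0 <- resolve_initial(initial, params, states, adp_premix, bound_fraction)
  sys <- eigen_system(Q, p0)
  if (is.null(t_grid)) {
    t_grid <- default_time_grid(sys, y, dead_time = dead_time, n = n_points)
  } else {
    if (any(diff(t_grid) <= 0)) abort("`t_grid` must be strictly increasing.")
    if (t_grid[1] < dead_time) abort("`t_grid` must start at or after the dead time.")
  }
  occ <- propagate_states(sys, t_grid)
  signal <- drop(occ %*% y)
  premix <- drop(p0 %*% y)
  if (normalize == "premix") signal <- signal / premix
  new_trace(
    time = t_grid, signal = signal,
    meta = list(
      probe = attr(observables, "probe"),
      scheme = attr(Q, "scheme"),
      atp = atp, adp = adp, adp_premix = adp_premix,
      protein = protein, bound_fraction = bound_fraction,
      dead_time = dead_time, normalize = normalize,
      premix_level = premix, noise_sd = 0, seed = NA_integer_
    )
  )
}

resolve_initial <- function(initial, params, states, adp_premix, bound_fraction) {
  if (is.null(initial)) {
    return(initial_state(params, states, adp_premix = adp_premix,
                         bound_fraction = bound_fraction))
  }
  if (is.null(names(initial)) || !all(names(initial) %in% states)) {
    abort("`initial` must be named by rate-matrix states.")
  }
  if (abs(sum(initial) - 1) > 1e-9) abort("`initial` occupancies must sum to 1.")
  p0 <- setNames(numeric(length(states)), states)
  p0[names(initial)] <- initial
  p0
}

yields_for <- function(observables, states, explicit_binding = FALSE) {
  y <- unclass(observables)
  if (explicit_binding && !"M.T" %in% names(y)) y <- c(y, M.T = unname(y["M"]))
  missing <- setdiff(states, names(y))
  if (length(missing)) {
    abort(sprintf("observable map lacks yields for state(s): %s",
                  paste(missing, collapse = ", ")))
  }
  y[states]
}

#' Analytic relaxation phases of a scheme
#'
#' Eigen-decomposes the rate matrix and reports each observable phase as a
#' rate (s^-1) and a signed amplitude (% of the pre-mix fluorescence,
#' positive for a rise). This is the analytic oracle against which the
#' exponential fits and the simulated traces are validated: the simulated
#' signal equals `baseline - sum(amplitude_i / 100 * exp(-rate_i * t))` in
#' pre-mix units.
#'
#' @inheritParams simulate_transient
#' @param drop_null drop phases with negligible amplitude (default TRUE).
#' @return a tibble with columns `rate` (s^-1, sorted fast to slow) and
#'   `amplitude` (%), plus attribute `baseline` (the end level).
#' @examples
#' p <- reference_params("R453C", "figures")$scheme1
#' eigen_phases(p, atp = 250)
#' @export
eigen_phases <- function(params, atp = 0, adp = 0, observables = NULL,
                         adp_premix = 0, bound_fraction = 1,
                         protein = 0.01, explicit_binding = FALSE,
                         drop_null = TRUE, initial = NULL) {
  if (is.null(observables)) {
    observables <- if (inherits(params, "scheme1_params")) {
      observable_map("tryptophan")
    } else {
      observable_map("pyrene-actin")
    }
  }
  Q <- build_rate_matrix(params, atp = atp, adp = adp, protein = protein,
                         explicit_binding = explicit_binding)
  states <- rownames(Q)
  y <- yields_for(observables, states, explicit_binding)
  p0 <- resolve_initial(initial, params, states, adp_premix, bound_fraction)
  sys <- eigen_system(Q, p0)
  if (sys$complex_modes) {
    abort("rate matrix has oscillatory (complex) modes; phases are not defined.")
  }
  premix <- drop(p0 %*% y)
  coef_sig <- drop(y %*% sys$V) * sys$coefs / premix   # signal = sum c_i e^{-r_i t}
  keep <- sys$rates > 1e-9
  if (drop_null) keep <- keep & abs(coef_sig) > 1e-12 * max(abs(coef_sig), 1e-300)
  out <- tibble(rate = sys$rates[keep], amplitude = -100 * coef_sig[keep]) |>
    arrange(desc(.data$rate))
  attr(out, "baseline") <- sum(coef_sig[sys$rates <= 1e-9])
  out
}

# ---- trace container -------------------------------------------------------

new_trace <- function(time, signal, meta) {
  out <- tibble(time = as.numeric(time), signal = as.numeric(signal))
  attr(out, "meta") <- meta
  class(out) <- c("myokin_trace", class(out))
  out
}

#' Trace metadata
#'
#' @param trace a `myokin_trace`.
#' @return the metadata list attached to a trace (probe, concentrations,
#'   seed, ...).
#' @export
trace_meta <- function(trace) attr(trace, "meta")

validate_trace <- function(trace, min_points = 50) {
  require_columns(trace, c("time", "signal"), "a fluorescence trace")
  if (nrow(trace) < min_points) {
    abort(sprintf(">= %d samples required (got %d).", min_points, nrow(trace)))
  }
  if (anyNA(trace$time) || anyNA(trace$signal)) abort("trace contains NA values.")
  if (any(diff(trace$time) <= 0)) abort("trace time must be strictly increasing.")
  invisible(trace)
}

#' Write or read a trace as delimited text
#'
#' Traces are stored as two-column tab-separated text (`time_s`,
#' `rel_fluorescence`) preceded by a `#`-prefixed header block carrying the
#' metadata as `# key: value` lines.
#'
#' @param trace a `myokin_trace`.
#' @param path file path.
#' @return `read_trace()` returns a `myokin_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- trace_meta(trace) %||% list()
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15), collapse = ","))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s\trel_fluorescence", con)
  writeLines(sprintf("%.10g\t%.10g", trace$time, trace$signal), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[trimws(key)]] <- if (is.na(num) && val != "NA") val else num
  }
  body <- lines[!is_meta]
  if (length(body) < 2 || !grepl("^time_s\t", body[1])) {
    abort(sprintf("malformed trace file '%s': expected 'time_s\\trel_fluorescence' header at line %d.",
                  path, sum(is_meta) + 1L))
  }
  fields <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    abort(sprintf("malformed trace file '%s': expected 2 fields at line %d.",
                  path, sum(is_meta) + 1L + bad[1]))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 2, byrow = TRUE)
  new_trace(m[, 1], m[, 2], meta)
}
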