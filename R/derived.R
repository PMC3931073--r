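#' Diagnose whether the fast fluorescence phase reports binding or hydrolysis
#'
#' For two-step ATP binding with an irreversible second step, the observed
#' half-saturating ATP concentration discriminates between two assignments
#' of the saturating fast-phase rate `k_max`. If the fluorescence change
#' reports the binding isomerization (`k_max = k_plus2`), half saturation
#' occurs at `[ATP] = k_max / K1k2` (= 1/K1). If it reports the hydrolysis
#' step (`k_max = k_plus3 + k_minus3`), the observed rate equals
#' `K1k2 * [ATP]` until it saturates, so `kobs = k_max/2` already at
#' `[ATP] = k_max / (2 K1k2)` - a factor of two lower. The diagnosis is
#' whichever prediction is closer (on a log scale) to the observed
#' `K_half`; when the two predictions straddle the observation within 10%
#' of each other the call is `"indeterminate"`, and when the supplied
#' `K1k2` equals `k_max / K_half` the comparison is degenerate by
#' construction (the slope was derived from the same fit) and is flagged.
#'
#' @param k_max saturating fast-phase rate (s^-1).
#' @param K_half observed half-saturating ATP concentration (uM).
#' @param K1k2 independently measured apparent second-order binding
#'   constant (uM^-1 s^-1).
#' @return a one-row tibble: `diagnosis` ("binding-limited",
#'   "hydrolysis-limited" or "indeterminate"), the two predicted half-max
#'   concentrations `half_conc_binding` and `half_conc_hydrolysis` (uM),
#'   the rate at half saturation `k_half_rate = k_max/2` (s^-1), the
#'   discrimination `ratio` (observed/hydrolysis prediction), and a
#'   `degenerate` flag.
#' @examples
#' assign_fast_phase(k_max = 102, K_half = 93, K1k2 = 1.1)
#' @export
assign_fast_phase <- function(k_max, K_half, K1k2) {
  assert_number(k_max, "k_max", min = 1e-12)
  assert_number(K_half, "K_half", min = 1e-12)
  assert_number(K1k2, "K1k2", min = 1e-12)
  p_bind <- k_max / K1k2
  p_hyd <- k_max / (2 * K1k2)
  d_bind <- abs(log(p_bind / K_half))
  d_hyd <- abs(log(p_hyd / K_half))
  # if the supplied slope is k_max/K_half itself (to rounding), the observed
  # half-max reproduces the binding prediction by algebraic identity and the
  # comparison carries no information
  degenerate <- abs(K1k2 - k_max / K_half) < 1e-3 * K1k2
  diagnosis <- if (abs(d_bind - d_hyd) < 0.1 * max(d_bind, d_hyd, 1e-12)) {
    "indeterminate"
  } else if (d_bind < d_hyd) "binding-limited" else "hydrolysis-limited"
  tibble(diagnosis = diagnosis,
         half_conc_binding = p_bind,
         half_conc_hydrolysis = p_hyd,
         k_half_rate = k_max / 2,
         observed_K_half = K_half,
         ratio = K_half / p_hyd,
         degenerate = degenerate)
}

#' Derived kinetic constants from primary fitted values
#'
#' Computes the standard derived quantities of a transient-kinetic study
#' from the primary fitted constants of one construct. Every derived value
#' is a stored-input ratio computed at call time:
#' `one_over_K1 = k_plus2 / K1k2` (uM), the detached lifetime
#' `1000 / k_slow` (ms, with `k_slow = k_plus3 + k_minus3`),
#' `one_over_K1_prime = k_plus2_prime / K1k2_prime`, `K_DA / K_A`,
#' `K_AD / K_D`, and the amplitude-ratio pair `K_alpha`, `k_minus_alpha`
#' when amplitudes are supplied. Missing primaries simply drop the rows
#' that need them (with a message).
#'
#' @param primaries a named list or named numeric vector of primary
#'   constants; recognised names: `K1k2`, `k_plus2`, `k_slow`,
#'   `K1k2_prime`, `k_plus2_prime`, `K_A`, `K_DA`, `K_D`, `K_AD`,
#'   `k_plus_alpha`, `a_fast`, `a_slow`.
#' @return a tibble with columns `quantity`, `value`, `unit`.
#' @examples
#' derive_constants(list(K1k2 = 1.5, k_plus2 = 160, k_slow = 14))
#' @export
derive_constants <- function(primaries) {
  p <- as.list(primaries)
  has <- function(...) all(vapply(list(...), function(nm)
    !is.null(p[[nm]]) && is.finite(p[[nm]]), logical(1)))
  rows <- list()
  if (has("K1k2", "k_plus2")) {
    rows$one_over_K1 <- tibble(quantity = "one_over_K1",
                               value = p$k_plus2 / p$K1k2, unit = "uM")
  }
  if (has("K1k2_prime", "k_plus2_prime")) {
    rows$one_over_K1_prime <- tibble(quantity = "one_over_K1_prime",
                                     value = p$k_plus2_prime / p$K1k2_prime,
                                     unit = "uM")
  }
  if (has("k_slow")) {
    rows$lifetime <- tibble(quantity = "detached_lifetime",
                            value = 1000 / p$k_slow, unit = "ms")
  }
  if (has("K_DA", "K_A")) {
    rows$kda_ka <- tibble(quantity = "K_DA_over_K_A",
                          value = p$K_DA / p$K_A, unit = "")
  }
  if (has("K_AD", "K_D")) {
    rows$kad_kd <- tibble(quantity = "K_AD_over_K_D",
                          value = p$K_AD / p$K_D, unit = "")
  }
  if (has("a_fast", "a_slow", "k_plus_alpha") && p$a_slow > 0) {
    am <- k_minus_alpha_from_amplitudes(p$a_fast, p$a_slow, p$k_plus_alpha)
    rows$K_alpha <- tibble(quantity = "K_alpha", value = am$K_alpha, unit = "")
    rows$k_minus_alpha <- tibble(quantity = "k_minus_alpha",
                                 value = am$k_minus_alpha, unit = "s^-1")
  }
  known <- c("K1k2", "k_plus2", "k_slow", "K1k2_prime", "k_plus2_prime",
             "K_A", "K_DA", "K_D", "K_AD", "k_plus_alpha", "a_fast", "a_slow")
  absent <- setdiff(known, names(p)[vapply(p, function(v) length(v) == 1 && is.finite(v), logical(1))])
  if (length(absent)) {
    message("derive_constants: primaries absent, dependent rows skipped: ",
            paste(absent, collapse = ", "))
  }
  if (!length(rows)) return(tibble(quantity = character(), value = numeric(),
                                   unit = character()))
  list_rbind(unname(rows))
}

#' Compare fitted parameters between two constructs
#'
#' Joins per-preparation parameter estimates for two constructs (typically
#' wild type and a mutant), computes the ratio of means per parameter, and
#' tests for a difference with Welch's two-sample t-test (unequal
#' variances) when both constructs have at least two replicate
#' preparations. With a single replicate on either side only the ratio is
#' reported.
#'
#' @param ref,alt data frames with columns `parameter`, `prep`, `value`:
#'   one row per parameter per replicate preparation. `ref` is the
#'   denominator of the ratio (wild type by convention).
#' @param alpha significance level for flagging (default 0.05).
#' @return a tibble with one row per parameter: means and SDs for both
#'   constructs, `ratio` (alt/ref mean), `p_value`, `significant`,
#'   `n_ref`, `n_alt`.
#' @export
compare_constructs <- function(ref, alt, alpha = 0.05) {
  for (df in list(ref, alt)) require_columns(df, c("parameter", "prep", "value"),
                                             "a construct fit table")
  s_ref <- summarise(group_by(as_tibble(ref), .data$parameter),
                     ref_mean = mean(.data$value), ref_sd = sd(.data$value),
                     n_ref = sum(is.finite(.data$value)), .groups = "drop")
  s_alt <- summarise(group_by(as_tibble(alt), .data$parameter),
                     alt_mean = mean(.data$value), alt_sd = sd(.data$value),
                     n_alt = sum(is.finite(.data$value)), .groups = "drop")
  out <- left_join(s_ref, s_alt, by = "parameter")
  pvals <- map_dbl(out$parameter, function(par) {
    x <- ref$value[ref$parameter == par]
    y <- alt$value[alt$parameter == par]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (var(x) + var(y) < 1e-24 * (mean(x)^2 + mean(y)^2 + 1e-300)) {
      # identical replicate sets: no evidence of difference
      return(1)
    }
    t.test(y, x)$p.value
  })
  mutate(out,
         ratio = .data$alt_mean / .data$ref_mean,
         p_value = pvals,
         significant = is.finite(pvals) & pvals < alpha)
}
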