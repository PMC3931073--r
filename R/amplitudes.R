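#' Conformational equilibrium from the fast/slow amplitude ratio
#'
#' The ratio of the fast- to slow-phase amplitudes of ATP-induced acto-S1
#' dissociation equals the equilibrium constant between the
#' nucleotide-accessible and blocked rigor conformations,
#' `K_alpha = A_fast / A_slow`, and with the slow-phase saturating rate
#' `k_plus_alpha` the reverse isomerization follows as
#' `k_minus_alpha = k_plus_alpha / K_alpha`. A vanishing slow amplitude is
#' the fast-myosin limit: `K_alpha` is reported as `Inf` (only a single
#' phase is observable) and `k_minus_alpha` as 0.
#'
#' @param a_fast,a_slow phase amplitudes (% of pre-mix fluorescence, same
#'   sign convention); `a_slow` may be 0.
#' @param k_plus_alpha saturating slow-phase rate (s^-1).
#' @return a tibble with `K_alpha` and `k_minus_alpha` (s^-1).
#' @examples
#' k_minus_alpha_from_amplitudes(29, 4.7, 85)
#' @export
k_minus_alpha_from_amplitudes <- function(a_fast, a_slow, k_plus_alpha) {
  assert_number(a_fast, "a_fast")
  assert_number(a_slow, "a_slow", min = 0)
  assert_number(k_plus_alpha, "k_plus_alpha", min = 0)
  if (a_slow == 0) {
    return(tibble(K_alpha = Inf, k_minus_alpha = 0))
  }
  K <- a_fast / a_slow
  tibble(K_alpha = K, k_minus_alpha = k_plus_alpha / K)
}

#' Overall ADP affinity of acto-S1 from the elementary constants
#'
#' The measurable (overall) dissociation constant of ADP for acto-S1,
#' `K_AD`, combines the elementary A.M + D dissociation constant `K_ADP`
#' with the partitioning of the ADP-bound complex between its two
#' conformations, `K_alphaD = [A.M.D] / [A.M'.D]`. Under the default
#' `"partition"` convention the extra bound state tightens the overall
#' affinity:
#' `K_AD = K_ADP * K_alphaD / (1 + K_alphaD)`.
#' The `"reciprocal"` convention applies the factor the other way
#' (`K_AD = K_ADP * (1 + K_alphaD) / K_alphaD`) and is provided because the
#' algebraic form is a documented package convention, not an asserted fact.
#' In either convention `K_AD -> K_ADP` as `K_alphaD -> Inf` (the primed
#' ADP state vanishes). [implied_KADP()] is the exact inverse.
#'
#' @param K_ADP elementary A.M + D dissociation constant (uM).
#' @param K_alphaD A.M.D / A.M'.D equilibrium constant (may be `Inf`).
#' @param convention `"partition"` (default) or `"reciprocal"`.
#' @return the overall `K_AD` (uM).
#' @examples
#' overall_KAD(12.7, 3.7)
#' implied_KADP(10, 3.7)     # Table-style inputs: implied elementary constant
#' @export
overall_KAD <- function(K_ADP, K_alphaD,
                        convention = c("partition", "reciprocal")) {
  convention <- match.arg(convention)
  assert_number(K_ADP, "K_ADP", min = 1e-12)
  if (!is_number(K_alphaD) && !identical(K_alphaD, Inf)) {
    abort("`K_alphaD` must be a positive number (Inf allowed).")
  }
  if (K_alphaD <= 0) abort("`K_alphaD` must be > 0.")
  if (is.infinite(K_alphaD)) return(K_ADP)
  f <- K_alphaD / (1 + K_alphaD)
  switch(convention, partition = K_ADP * f, reciprocal = K_ADP / f)
}

#' @rdname overall_KAD
#' @param K_AD overall ADP affinity (uM).
#' @export
implied_KADP <- function(K_AD, K_alphaD,
                         convention = c("partition", "reciprocal")) {
  convention <- match.arg(convention)
  assert_number(K_AD, "K_AD", min = 1e-12)
  if (K_alphaD <= 0) abort("`K_alphaD` must be > 0.")
  if (is.infinite(K_alphaD)) return(K_AD)
  f <- K_alphaD / (1 + K_alphaD)
  switch(convention, partition = K_AD / f, reciprocal = K_AD * f)
}
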