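#' Build the first-order rate matrix for a kinetic scheme
#'
#' Encodes either scheme as a linear rate system `dP/dt = Q P` over the state
#' occupancy vector `P`, with nucleotide concentrations folded into
#' pseudo-first-order rates. Columns of `Q` sum to zero (mass conservation)
#' and off-diagonal entries are non-negative.
#'
#' For the S1 scheme the default states are the rapid-equilibrium binding
#' pool `M` (apo + collapsed M.T), the post-isomerization state `Mstar.T`,
#' the hydrolysis product state `Mss.DPi`, a lumped absorbing `products`
#' state, and (when ADP is present and the ADP constants are set) `M.D`.
#' With `explicit_binding = TRUE` (requires `k_minus1` in the parameters)
#' `M` and `M.T` are separate states with `k_plus1 = K1 * k_minus1`.
#'
#' For the acto-S1 scheme the states are `AMp` (blocked rigor conformer),
#' `AM` (nucleotide-accessible rigor, with the ATP binding step collapsed),
#' the absorbing dissociated state `A.free`, and, when ADP is present,
#' `AM.D` plus (if the primed-ADP rates are set) `AMp.D`. The elementary
#' A.M + D affinity used for the ADP on-rate is `K_AD` itself when the ADP
#' branch is lumped, or the partition-corrected
#' `K_ADP = K_AD (1 + K_alphaD) / K_alphaD` when `AMp.D` is explicit.
#'
#' @param params a [scheme1_params()] or [scheme2_params()] object.
#' @param atp,adp post-mix nucleotide concentrations (uM).
#' @param protein post-mix concentration (uM) of the tracked species (S1 or
#'   actin.S1); used only to enforce pseudo-first-order validity (each
#'   nucleotide must be in >= 10-fold excess, or zero).
#' @param explicit_binding scheme 1 only: model ATP binding as an explicit
#'   two-step process instead of a rapid equilibrium.
#' @param check_pseudo_first_order set `FALSE` to skip the excess check.
#' @return a square numeric matrix with state names on both dimensions and
#'   attributes `scheme` and `concs`.
#' @examples
#' p <- reference_params("R453C", "figures")$scheme2
#' Q <- build_rate_matrix(p, atp = 250)
#' colSums(Q)   # all (numerically) zero
#' @export
build_rate_matrix <- function(params, atp = 0, adp = 0, protein = 0.01,
                              explicit_binding = FALSE,
                              check_pseudo_first_order = TRUE) {
  assert_number(atp, "atp", min = 0)
  assert_number(adp, "adp", min = 0)
  assert_number(protein, "protein", min = 0)
  if (check_pseudo_first_order) {
    if (atp > 0 && atp < 10 * protein) {
      abort(sprintf(paste0(
        "pseudo-first-order violation: [ATP] = %g uM is less than 10 x ",
        "[protein] = %g uM"), atp, protein))
    }
    if (adp > 0 && adp < 10 * protein) {
      abort(sprintf(paste0(
        "pseudo-first-order violation: [ADP] = %g uM is less than 10 x ",
        "[protein] = %g uM"), adp, protein))
    }
  }
  build_rate_matrix_(params, atp = atp, adp = adp, protein = protein,
                     explicit_binding = explicit_binding)
}

build_rate_matrix_ <- function(params, ...) UseMethod("build_rate_matrix_")

#' @export
build_rate_matrix_.scheme1_params <- function(params, atp = 0, adp = 0,
                                              protein = 0.01,
                                              explicit_binding = FALSE, ...) {
  p <- params
  with_adp <- adp > 0 && !is.na(p$K_D) && !is.na(p$k_minusD)
  if (explicit_binding) {
    if (is.na(p$k_minus1)) {
      abort("explicit_binding requires `k_minus1` in the parameter set.")
    }
    states <- c("M", if (with_adp) "M.D", "M.T", "Mstar.T", "Mss.DPi", "products")
    Q <- empty_Q(states)
    Q <- add_rate(Q, "M", "M.T", p$K1 * p$k_minus1 * atp)
    Q <- add_rate(Q, "M.T", "M", p$k_minus1)
    Q <- add_rate(Q, "M.T", "Mstar.T", p$k_plus2)
    Q <- add_rate(Q, "Mstar.T", "M.T", p$k_minus2)
  } else {
    # rapid-equilibrium pool: fraction of the pool with ATP bound
    fT <- p$K1 * atp / (1 + p$K1 * atp)
    states <- c("M", if (with_adp) "M.D", "Mstar.T", "Mss.DPi", "products")
    Q <- empty_Q(states)
    Q <- add_rate(Q, "M", "Mstar.T", p$k_plus2 * fT)
    Q <- add_rate(Q, "Mstar.T", "M", p$k_minus2)
  }
  Q <- add_rate(Q, "Mstar.T", "Mss.DPi", p$k_plus3)
  Q <- add_rate(Q, "Mss.DPi", "Mstar.T", p$k_minus3)
  Q <- add_rate(Q, "Mss.DPi", "products", p$k_release)
  if (with_adp) {
    # ADP binds the free-M fraction of the pool
    f_free <- if (explicit_binding) 1 else 1 / (1 + p$K1 * atp)
    k_onD <- p$k_minusD / p$K_D
    Q <- add_rate(Q, "M", "M.D", k_onD * adp * f_free)
    Q <- add_rate(Q, "M.D", "M", p$k_minusD)
  }
  finish_Q(Q, scheme = "scheme1", atp = atp, adp = adp)
}

#' @export
build_rate_matrix_.scheme2_params <- function(params, atp = 0, adp = 0,
                                              protein = 0.01, ...) {
  p <- params
  with_adp <- adp > 0 && !is.na(p$K_AD) && !is.na(p$k_minusAD)
  with_primed_adp <- with_adp && !is.na(p$k_plus_alphaD) && !is.na(p$k_minus_alphaD)
  states <- c("AMp", "AM", if (with_adp) "AM.D", if (with_primed_adp) "AMp.D",
              "A.free")
  Q <- empty_Q(states)
  # `AM` is the rapid-equilibrium pool {A.M, A.M.T}; transitions available
  # only to the nucleotide-free conformer (isomerization to A.M', ADP
  # binding) are gated by the free fraction of the pool, since A.M' cannot
  # hold nucleotide and ADP competes with ATP for the same site
  fT <- p$K1_prime * atp / (1 + p$K1_prime * atp)
  f_free <- 1 - fT
  Q <- add_rate(Q, "AMp", "AM", p$k_plus_alpha)
  Q <- add_rate(Q, "AM", "AMp", p$k_minus_alpha * f_free)
  Q <- add_rate(Q, "AM", "A.free", p$k_plus2_prime * fT)
  if (with_adp) {
    K_branch <- elementary_KADP(p, with_primed_adp)
    Q <- add_rate(Q, "AM", "AM.D", p$k_minusAD / K_branch * adp * f_free)
    Q <- add_rate(Q, "AM.D", "AM", p$k_minusAD)
    if (with_primed_adp) {
      Q <- add_rate(Q, "AM.D", "AMp.D", p$k_minus_alphaD)
      Q <- add_rate(Q, "AMp.D", "AM.D", p$k_plus_alphaD)
    }
  }
  finish_Q(Q, scheme = "scheme2", atp = atp, adp = adp)
}

# elementary A.M + D dissociation constant implied by the stored overall
# affinity: the measured K_AD sees ADP competing against the whole apo
# conformer pool (A.M + A.M'), and - when the primed ADP state is modelled -
# the bound complex partitioned over A.M.D + A.M'.D, so both partition
# factors are unfolded before the constant is used as a branch Kd
elementary_KADP <- function(p, primed) {
  Ka <- K_alpha(p)
  apo <- if (is.infinite(Ka)) 1 else 1 + 1 / Ka
  K <- p$K_AD / apo
  if (primed) K <- implied_KADP(K, K_alphaD(p))
  K
}

empty_Q <- function(states) {
  matrix(0, length(states), length(states), dimnames = list(states, states))
}

add_rate <- function(Q, from, to, rate) {
  if (is.na(rate)) rate <- 0
  Q[to, from] <- Q[to, from] + rate
  Q
}

finish_Q <- function(Q, scheme, atp, adp) {
  diag(Q) <- 0
  diag(Q) <- -colSums(Q)
  attr(Q, "scheme") <- scheme
  attr(Q, "concs") <- c(atp = atp, adp = adp)
  Q
}

#' Pre-mix equilibrium occupancies
#'
#' Returns the equilibrium distribution of the tracked species before mixing
#' with ATP: for the S1 scheme the apo state (partitioned with `M.D` when ADP
#' was present in the pre-mix syringe); for the acto-S1 scheme the
#' A.M'/A.M conformational equilibrium, partitioned with the ADP-bound states
#' when ADP was pre-incubated. `bound_fraction` scales the actin-attached
#' states for titration experiments in which only part of the actin carries
#' S1; the remainder starts in the dissociated state.
#'
#' @param params a scheme parameter object.
#' @param states state names of the rate matrix the vector must match.
#' @param adp_premix ADP concentration (uM) in the pre-mix syringe.
#' @param bound_fraction fraction of actin with S1 bound at time zero
#'   (acto-S1 scheme only).
#' @return a named occupancy vector summing to 1.
#' @export
initial_state <- function(params, states, adp_premix = 0, bound_fraction = 1) {
  w <- setNames(numeric(length(states)), states)
  if (inherits(params, "scheme1_params")) {
    if (adp_premix > 0 && "M.D" %in% states) {
      fD <- (adp_premix / params$K_D) / (1 + adp_premix / params$K_D)
      w["M"] <- 1 - fD
      w["M.D"] <- fD
    } else {
      w["M"] <- 1
    }
  } else if (inherits(params, "scheme2_params")) {
    Ka <- K_alpha(params)
    rel <- c(AM = 1, AMp = if (is.infinite(Ka)) 0 else 1 / Ka)
    if (adp_premix > 0 && "AM.D" %in% states) {
      KaD <- K_alphaD(params)
      K_branch <- elementary_KADP(params, "AMp.D" %in% states)
      rel["AM.D"] <- adp_premix / K_branch
      if ("AMp.D" %in% states) rel["AMp.D"] <- rel[["AM.D"]] / KaD
    }
    rel <- rel[names(rel) %in% states]
    w[names(rel)] <- rel / sum(rel) * bound_fraction
    if ("A.free" %in% states) w["A.free"] <- 1 - bound_fraction
  } else {
    abort("`params` must be a scheme1_params or scheme2_params object.")
  }
  w
}
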