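#' Stopped-flow instrument model for synthetic experiments
#'
#' Describes the instrument features the synthetic transients carry: traces
#' start at the mixing dead time (points before it are simply not recorded,
#' no convolution), carry additive iid Gaussian noise expressed as percent
#' of the pre-mix fluorescence, and are sampled on a log- or linear-spaced
#' grid.
#'
#' @param dead_time mixing dead time (s), default 0.0015.
#' @param noise_sd noise standard deviation (% of pre-mix fluorescence),
#'   default 0.5.
#' @param n_points samples per trace, default 600.
#' @param spacing `"log"` (default) or `"linear"`.
#' @return an object of class `instrument_model`.
#' @export
instrument_model <- function(dead_time = 0.0015, noise_sd = 0.5,
                             n_points = 600, spacing = c("log", "linear")) {
  assert_number(dead_time, "dead_time", min = 0)
  assert_number(noise_sd, "noise_sd", min = 0)
  assert_number(n_points, "n_points", min = 50)
  spacing <- match.arg(spacing)
  structure(list(dead_time = dead_time, noise_sd = noise_sd,
                 n_points = as.integer(n_points), spacing = spacing),
            class = "instrument_model")
}

#' Stopped-flow experiment designs
#'
#' Describes one of the five experiment designs of the study, with
#' concentration grids defaulting to the published post-mix ranges:
#'
#' * `trp_atp_titration`: 0.2 uM S1 mixed with ATP, tryptophan signal; ATP
#'   grid log-spaced 10-400 uM (beyond 4x the half-saturating
#'   concentration).
#' * `pyrene_atp_dissociation`: 0.05 uM pyrene-actin.S1 mixed with ATP;
#'   ATP grid log-spaced 250-4000 uM (two dissociation phases resolve
#'   above ~200 uM; below that the transient is effectively single
#'   exponential).
#' * `adp_competition`: 0.1 uM pyrene-actin.S1 mixed with 20 uM ATP plus
#'   0-100 uM ADP; single-exponential regime.
#' * `adp_displacement`: 0.1 uM pyrene-actin.S1 pre-incubated with 50 uM
#'   ADP, mixed with 2 mM ATP (post-mix ADP 25 uM).
#' * `actin_titration`: 30 nM pyrene-actin titrated with S1 (0-160 nM
#'   without ADP, mixed with 20 uM ATP) and with S1 in the presence of
#'   100 uM ADP (0-1.6 uM S1, mixed with 500 uM ATP).
#'
#' @param kind design kind, one of the five above.
#' @param ... design fields to override (e.g. `atp_grid`, `adp_grid`,
#'   `s1_grid`, `atp`, `adp_premix`, `A0`, `protein`).
#' @return an object of class `experiment_design` (a list).
#' @export
experiment_design <- function(kind = c("trp_atp_titration",
                                       "pyrene_atp_dissociation",
                                       "adp_competition",
                                       "adp_displacement",
                                       "actin_titration"), ...) {
  kind <- match.arg(kind)
  base <- switch(kind,
    trp_atp_titration = list(
      atp_grid = logspace(10, 400, 8), protein = 0.2, probe = "tryptophan"),
    pyrene_atp_dissociation = list(
      atp_grid = logspace(250, 4000, 8), protein = 0.05, probe = "pyrene-actin",
      alpha_backflow = FALSE),
    adp_competition = list(
      atp = 20, adp_grid = c(0, 5, 10, 15, 20, 30, 50, 75, 100),
      protein = 0.1, probe = "pyrene-actin", adp_branch = "lumped"),
    adp_displacement = list(
      atp = 2000, adp_premix = 50, protein = 0.1, probe = "pyrene-actin",
      adp_branch = "explicit"),
    actin_titration = list(
      A0 = 30,
      s1_grid = c(0, 5, 10, 20, 30, 45, 60, 90, 120, 160),
      s1_grid_adp = c(0, 50, 100, 200, 300, 450, 700, 1000, 1300, 1600),
      atp = 20, atp_adp = 500, adp = 100, protein = 0.03,
      probe = "pyrene-actin")
  )
  over <- list(...)
  unknown <- setdiff(names(over), c(names(base), "atp", "adp_premix"))
  if (length(unknown)) {
    abort(sprintf("unknown design field(s): %s", paste(unknown, collapse = ", ")))
  }
  structure(c(list(kind = kind), modifyList(base, over)),
            class = "experiment_design")
}

pick_params <- function(design, params) {
  if (inherits(params, "scheme1_params") || inherits(params, "scheme2_params")) {
    return(params)
  }
  if (is.list(params) && all(c("scheme1", "scheme2") %in% names(params))) {
    return(if (design$kind == "trp_atp_titration") params$scheme1 else params$scheme2)
  }
  abort("`params` must be a scheme parameter object or a list with $scheme1 and $scheme2.")
}

lump_adp_branch <- function(p) {
  # collapse the primed ADP state into a single rapid-equilibrium branch of
  # overall affinity K_AD (used where the analysis assumes pure competition)
  p$k_plus_alphaD <- NA_real_
  p$k_minus_alphaD <- NA_real_
  p
}

add_noise <- function(trace, noise_sd, seed) {
  if (noise_sd <= 0) {
    meta <- attr(trace, "meta"); meta$noise_sd <- 0; meta$seed <- seed
    attr(trace, "meta") <- meta
    return(trace)
  }
  noisy <- withr::with_seed(seed, rnorm(nrow(trace), 0, noise_sd / 100))
  meta <- attr(trace, "meta"); meta$noise_sd <- noise_sd; meta$seed <- seed
  out <- new_trace(trace$time, trace$signal + noisy, meta)
  out
}

#' Generate one synthetic stopped-flow experiment
#'
#' Simulates the set of noiseless transients a design prescribes, adds
#' instrument noise, and returns the traces together with the generating
#' truth (for recovery scoring; [write_trace()] does not export the truth).
#' Identical seeds give bit-identical output; per-trace noise seeds are
#' split from the master seed by the documented rule
#' `sub_seed(seed, i) = (seed + 1000003 i) mod (2^31 - 1)`.
#'
#' @param design an [experiment_design()].
#' @param params a scheme parameter object, or a list with `$scheme1` and
#'   `$scheme2` (e.g. from [reference_params()]); the scheme the design
#'   needs is picked automatically.
#' @param instrument an [instrument_model()].
#' @param seed master seed (integer).
#' @return an object of class `myokin_experiment`: a list with `design`,
#'   `conditions` (a tibble with one row per trace: the condition columns
#'   and a `trace` list-column), and `truth`.
#' @examples
#' des <- experiment_design("trp_atp_titration")
#' exp <- generate_experiment(des, reference_params("R453C", "figures"),
#'                            instrument_model(noise_sd = 0), seed = 1)
#' exp$conditions
#' @export
generate_experiment <- function(design, params,
                                instrument = instrument_model(), seed = 1) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(instrument, "instrument_model"))
  p <- pick_params(design, params)
  conds <- design_conditions(design)
  sim1 <- function(i) {
    cond <- conds[i, ]
    pp <- p
    init <- NULL
    if (identical(design$adp_branch, "lumped")) pp <- lump_adp_branch(pp)
    bound_fraction <- 1
    normalize <- "premix"
    if (design$kind == "actin_titration") {
      K <- if (cond$adp > 0) pp$K_DA else pp$K_A
      bound_fraction <- quadratic_bound(cond$s1_total, design$A0, K) / design$A0
      normalize <- "none"   # titration traces share the free-actin scale
    }
    if (inherits(pp, "scheme2_params") && isFALSE(design$alpha_backflow)) {
      # irreversible-dissociation limit (the model behind the dissociation
      # analysis): the pre-mix A.M/A.M' split is set by K_alpha, but once
      # ATP floods the cell A.M is committed to dissociation and does not
      # return to A.M'
      Qs <- build_rate_matrix(pp, atp = cond$atp, adp = cond$adp,
                              protein = design$protein %||% 0.01,
                              check_pseudo_first_order = FALSE)
      init <- initial_state(pp, rownames(Qs), adp_premix = cond$adp_premix,
                            bound_fraction = bound_fraction)
      pp$k_minus_alpha <- 0
    }
    simulate1 <- function(t_grid = NULL) {
      simulate_transient(
        pp, atp = cond$atp, adp = cond$adp, adp_premix = cond$adp_premix,
        bound_fraction = bound_fraction, normalize = normalize,
        t_grid = t_grid, dead_time = instrument$dead_time,
        n_points = instrument$n_points,
        protein = design$protein %||% 0.01, initial = init)
    }
    tr <- simulate1()
    if (identical(instrument$spacing, "linear")) {
      tr <- simulate1(seq(instrument$dead_time, max(tr$time),
                          length.out = instrument$n_points))
    }
    add_noise(tr, instrument$noise_sd, sub_seed(seed, i))
  }
  conds$trace <- map(seq_len(nrow(conds)), sim1)
  structure(
    list(design = design, conditions = conds,
         truth = list(params = p, design = design, instrument = instrument,
                      seed = seed)),
    class = "myokin_experiment")
}

design_conditions <- function(design) {
  k <- design$kind
  if (k == "trp_atp_titration" || k == "pyrene_atp_dissociation") {
    tibble(atp = design$atp_grid, adp = 0, adp_premix = 0, s1_total = NA_real_)
  } else if (k == "adp_competition") {
    tibble(atp = design$atp, adp = design$adp_grid, adp_premix = 0,
           s1_total = NA_real_)
  } else if (k == "adp_displacement") {
    tibble(atp = design$atp, adp = design$adp_premix / 2,
           adp_premix = design$adp_premix, s1_total = NA_real_)
  } else {
    bind_rows(
      tibble(atp = design$atp, adp = 0, adp_premix = 0,
             s1_total = design$s1_grid),
      tibble(atp = design$atp_adp, adp = design$adp,
             adp_premix = design$adp, s1_total = design$s1_grid_adp))
  }
}

#' Analyze one synthetic (or imported) experiment
#'
#' Runs the fitting chain appropriate to the design: exponential phase fits
#' per trace, then the secondary analysis that yields the kinetic constants
#' the design measures. Returns the per-trace phase table, the secondary
#' fit object(s), and a tidy table of recovered constants named with the
#' package's parameter spellings (`K1k2`, `k_plus2`, `one_over_K1`,
#' `k_slow`, `K1k2_prime`, ..., `K_A`, `K_DA`).
#'
#' @param experiment a `myokin_experiment` from [generate_experiment()].
#' @return a list with `series` (tibble), `fits` (list), and `estimates`
#'   (tibble with columns `parameter`, `value`).
#' @export
analyze_experiment <- function(experiment) {
  stopifnot(inherits(experiment, "myokin_experiment"))
  k <- experiment$design$kind
  switch(k,
    trp_atp_titration = analyze_atp_titration(experiment, scheme1 = TRUE),
    pyrene_atp_dissociation = analyze_atp_titration(experiment, scheme1 = FALSE),
    adp_competition = analyze_adp_competition(experiment),
    adp_displacement = analyze_adp_displacement(experiment),
    actin_titration = analyze_actin_titration(experiment))
}

two_phase_series <- function(experiment) {
  conds <- experiment$conditions
  rows <- map(seq_len(nrow(conds)), function(i) {
    tr <- conds$trace[[i]]
    f2 <- fit_exponentials(tr, 2)
    ph <- f2$phases
    # a double exponential is only credible when the rates separate (ratio
    # >= 1.5) and each phase actually contributes to the recorded window:
    # after dead-time attenuation a phase must carry at least 2% of the
    # recorded signal change, otherwise it is a fitting artifact and the
    # dominant single-exponential rate is the honest observable
    rec_total <- 100 * diff(range(tr$signal))
    obs_amp <- abs(ph$amplitude) * exp(-ph$kobs * tr$time[1])
    ok <- f2$converged && all(is.finite(ph$kobs)) &&
      ph$kobs[1] / ph$kobs[2] >= 1.5 &&
      all(obs_amp >= 0.02 * rec_total)
    if (ok) {
      tibble(conc = conds$atp[i],
             kobs_fast = ph$kobs[1], kobs_slow = ph$kobs[2],
             a_fast = ph$amplitude[1], a_slow = ph$amplitude[2],
             n_phases = 2L, converged = TRUE)
    } else {
      f1 <- fit_exponentials(tr, 1)
      tibble(conc = conds$atp[i],
             kobs_fast = f1$phases$kobs[1], kobs_slow = NA_real_,
             a_fast = f1$phases$amplitude[1], a_slow = NA_real_,
             n_phases = 1L, converged = f1$converged)
    }
  })
  list_rbind(rows)
}

analyze_atp_titration <- function(experiment, scheme1) {
  series <- two_phase_series(experiment)
  hyper <- fit_hyperbola(tibble(conc = series$conc, kobs = series$kobs_fast))
  plateau <- filter(series, .data$conc > 2 * hyper$K_half,
                    is.finite(.data$kobs_slow))
  k_slow <- mean(plateau$kobs_slow)
  if (scheme1) {
    est <- tibble(
      parameter = c("K1k2", "k_plus2", "one_over_K1", "k_slow"),
      value = c(hyper$initial_slope, hyper$k_max, hyper$K_half, k_slow))
  } else {
    amp_ratio <- mean(plateau$a_fast / plateau$a_slow)   # Eq.-style K_alpha
    am <- k_minus_alpha_from_amplitudes(amp_ratio, 1, k_slow)
    est <- tibble(
      parameter = c("K1k2_prime", "k_plus2_prime", "one_over_K1_prime",
                    "k_plus_alpha", "K_alpha", "k_minus_alpha"),
      value = c(hyper$initial_slope, hyper$k_max, hyper$K_half, k_slow,
                am$K_alpha, am$k_minus_alpha))
  }
  list(series = series, fits = list(hyperbola = hyper), estimates = est)
}

analyze_adp_competition <- function(experiment) {
  conds <- experiment$conditions
  rows <- map(seq_len(nrow(conds)), function(i) {
    f <- fit_exponentials(conds$trace[[i]], 1)
    tibble(conc = conds$adp[i], kobs = f$phases$kobs[1],
           amplitude = f$phases$amplitude[1], converged = f$converged)
  })
  series <- list_rbind(rows)
  comp <- fit_adp_competition(series, atp_conc = experiment$design$atp)
  list(series = series, fits = list(competition = comp),
       estimates = tibble(parameter = "K_AD", value = comp$K_AD))
}

analyze_adp_displacement <- function(experiment) {
  series <- two_phase_series(experiment)
  est <- tibble(
    parameter = c("k_minusAD", "k_plus_alphaD", "K_alphaD"),
    value = c(mean(series$kobs_fast), mean(series$kobs_slow),
              mean(series$a_fast / series$a_slow)))
  list(series = series, fits = list(), estimates = est)
}

analyze_actin_titration <- function(experiment) {
  conds <- experiment$conditions
  amps <- map_dbl(seq_len(nrow(conds)), function(i) {
    tr <- conds$trace[[i]]
    if (diff(range(tr$signal)) < 1e-9) return(0)
    f <- fit_exponentials(tr, 1)
    f$phases$amplitude[1]
  })
  curve <- mutate(conds, amplitude = amps)
  A0 <- experiment$design$A0
  fit_one <- function(sub) {
    fit_quadratic_titration(
      tibble(s1_total = sub$s1_total, amplitude = pmax(sub$amplitude, 0)),
      A0 = A0)
  }
  apo <- fit_one(filter(curve, .data$adp == 0))
  with_adp <- filter(curve, .data$adp > 0)
  fits <- list(K_A = apo)
  est <- tibble(parameter = "K_A", value = apo$K_D)
  if (nrow(with_adp)) {
    fD <- fit_one(with_adp)
    fits$K_DA <- fD
    est <- bind_rows(est, tibble(parameter = "K_DA", value = fD$K_D))
  }
  list(series = select(curve, -"trace"), fits = fits, estimates = est)
}

# per-parameter inter-preparation coefficients of variation (SD/mean read
# from the replicate scatter of the summary table; 10% where no SD is given)
default_prep_cv <- c(
  K1 = 0.07, k_plus2 = 0.14, k_plus3 = 0.10, k_minus3 = 0.10,
  K_D = 0.10, k_minusD = 0.14,
  K1_prime = 0.19, k_plus2_prime = 0.046, k_plus_alpha = 0.24,
  k_minus_alpha = 0.17, K_AD = 0.30, k_minusAD = 0.047,
  k_plus_alphaD = 0.056, k_minus_alphaD = 0.11, K_A = 0.41, K_DA = 0.60)

perturb_params <- function(params, cv, seed) {
  vals <- unclass(params)
  nm <- intersect(names(vals), names(cv))
  factors <- withr::with_seed(seed, {
    sdlog <- sqrt(log(1 + cv[nm]^2))
    setNames(exp(rnorm(length(nm), -sdlog^2 / 2, sdlog)), nm)
  })
  for (n in nm) {
    if (!is.na(vals[[n]])) vals[[n]] <- vals[[n]] * factors[[n]]
  }
  ctor <- if (inherits(params, "scheme1_params")) scheme1_params else scheme2_params
  do.call(ctor, vals[names(formals(ctor))])
}

#' Generate and analyze a complete synthetic study
#'
#' Runs the full study battery: all five experiment designs for both
#' constructs, replicated over `n_prep` synthetic protein "preparations".
#' Inter-preparation variability is modelled as a lognormal multiplicative
#' perturbation of each rate/equilibrium constant with per-parameter
#' coefficients of variation taken from the replicate scatter of the
#' published summary values (see `default_prep_cv` in the package source),
#' mean-corrected so the expected value of each constant is unchanged.
#' Every preparation and trace receives a sub-seed split deterministically
#' from `seed`.
#'
#' @param params_ref,params_alt parameter lists (with `$scheme1`,
#'   `$scheme2`) for the reference (WT) and alternative (mutant) construct,
#'   e.g. from [reference_params()].
#' @param seed master seed.
#' @param n_prep synthetic preparations per construct (default 3).
#' @param instrument an [instrument_model()].
#' @param designs subset of design kinds to run (default all five).
#' @param prep_cv named CV overrides.
#' @return an object of class `myokin_battery`: list with `fits` (tibble:
#'   `construct`, `prep`, `parameter`, `value`), `experiments` (nested
#'   list), `report` (the [compare_constructs()] table with derived rows),
#'   and `seed`.
#' @seealso [run_battery()] for the file-based pipeline wrapper.
#' @export
battery <- function(params_ref, params_alt, seed = 42, n_prep = 3,
                    instrument = instrument_model(),
                    designs = c("trp_atp_titration", "pyrene_atp_dissociation",
                                "adp_competition", "adp_displacement",
                                "actin_titration"),
                    prep_cv = NULL) {
  cv <- default_prep_cv
  if (!is.null(prep_cv)) cv[names(prep_cv)] <- prep_cv
  constructs <- list(ref = params_ref, alt = params_alt)
  all_fits <- list()
  experiments <- list()
  idx <- 0
  for (cn in names(constructs)) {
    for (prep in seq_len(n_prep)) {
      idx <- idx + 1
      pseed <- sub_seed(seed, 10000 + idx)
      pars <- list(
        scheme1 = perturb_params(constructs[[cn]]$scheme1, cv, pseed),
        scheme2 = perturb_params(constructs[[cn]]$scheme2, cv, sub_seed(pseed, 1)))
      for (d in designs) {
        des <- experiment_design(d)
        eseed <- sub_seed(seed, 100 * idx + match(d, designs))
        exp <- generate_experiment(des, pars, instrument, seed = eseed)
        res <- analyze_experiment(exp)
        all_fits[[length(all_fits) + 1]] <-
          mutate(res$estimates, construct = cn, prep = prep, design = d,
                 .before = 1)
        experiments[[cn]][[paste0("prep", prep)]][[d]] <- res
      }
    }
  }
  fits <- list_rbind(all_fits)
  report <- battery_report(fits)
  structure(list(fits = fits, experiments = experiments, report = report,
                 seed = seed, n_prep = n_prep),
            class = "myokin_battery")
}

battery_report <- function(fits) {
  base <- function(cn) {
    f <- filter(fits, .data$construct == cn)
    tibble(parameter = f$parameter, prep = f$prep, value = f$value)
  }
  ref <- base("ref"); alt <- base("alt")
  # derived per-prep rows so they enter the comparison like primaries
  derived_rows <- function(tbl) {
    per_prep <- map(unique(tbl$prep), function(pp) {
      prim <- filter(tbl, .data$prep == pp)
      vals <- setNames(as.list(prim$value), prim$parameter)
      if (!is.null(vals$k_slow)) {
        tibble(parameter = "detached_lifetime_ms", prep = pp,
               value = 1000 / vals$k_slow)
      }
    })
    bind_rows(per_prep)
  }
  ref <- bind_rows(ref, derived_rows(ref))
  alt <- bind_rows(alt, derived_rows(alt))
  compare_constructs(ref, alt)
}

#' @export
print.myokin_battery <- function(x, ...) {
  cat(sprintf("<myokin_battery> %d preparations per construct, seed %d\n",
              x$n_prep, x$seed))
  print(x$report, n = Inf)
  invisible(x)
}
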