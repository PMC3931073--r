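#' Plot a fluorescence trace
#'
#' @param object a `myokin_trace`.
#' @param log_time show time on a log axis (default TRUE; stopped-flow
#'   transients span decades).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.myokin_trace <- function(object, log_time = TRUE, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "time (s)", y = "relative fluorescence")
  if (log_time) gg <- gg + ggplot2::scale_x_log10()
  gg
}

#' Plot an exponential fit with residuals
#'
#' @param object an `exp_fit`.
#' @param ... unused.
#' @return a ggplot object (data, fitted curve, residual panel).
#' @export
autoplot.exp_fit <- function(object, ...) {
  tr <- object$trace
  fitted_y <- if (!is.null(object$fit)) predict(object$fit) else rep(NA_real_, nrow(tr))
  d <- tibble(time = tr$time, signal = tr$signal, fitted = fitted_y) |>
    mutate(residual = .data$signal - .data$fitted)
  long <- tidyr::pivot_longer(
    mutate(d, fit_panel = "signal", res_panel = "residual"),
    cols = c("signal", "residual"), names_to = "panel", values_to = "y")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$y)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(
      data = tibble(time = d$time, y = d$fitted, panel = "signal"),
      colour = "firebrick") +
    ggplot2::facet_grid(rows = ggplot2::vars(factor(.data$panel,
                                                    c("signal", "residual"))),
                        scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%d-phase exponential fit", object$n_phases))
}

#' Plot a hyperbolic kobs fit
#'
#' @param object a `hyperbola_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.hyperbola_fit <- function(object, ...) {
  grid <- tibble(conc = seq(0, max(object$data$conc), length.out = 200))
  grid$kobs <- object$k_max * grid$conc / (object$K_half + grid$conc)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$kobs)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[substrate] (uM)", y = expression(k[obs] ~ (s^-1)),
                  subtitle = sprintf("k_max = %.3g s^-1, K_half = %.3g uM",
                                     object$k_max, object$K_half))
}

#' Plot an ADP-competition fit
#'
#' @param object an `adp_competition_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.adp_competition_fit <- function(object, ...) {
  grid <- tibble(conc = seq(0, max(object$data$conc), length.out = 200))
  grid$kobs <- object$kobs0 / (1 + grid$conc / object$K_AD)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$kobs)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[ADP] (uM)", y = expression(k[obs] ~ (s^-1)),
                  subtitle = sprintf("K_AD = %.3g uM", object$K_AD))
}

#' Plot a quadratic titration fit
#'
#' @param object a `titration_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.titration_fit <- function(object, ...) {
  grid <- tibble(s1_total = seq(0, max(object$data$s1_total), length.out = 300))
  grid$amplitude <- object$scale *
    quadratic_bound(grid$s1_total, object$A0, object$K_D) / object$A0
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$s1_total, y = .data$amplitude)) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[S1] total (nM)", y = "amplitude (%)",
                  subtitle = sprintf("K_D = %.3g nM (A0 = %.3g nM)",
                                     object$K_D, object$A0))
}

#' Plot a battery parameter report
#'
#' Dot-and-error plot of the mutant/wild-type ratio per parameter with
#' significance highlighting.
#'
#' @param object a `myokin_battery`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.myokin_battery <- function(object, ...) {
  rep <- filter(object$report, is.finite(.data$ratio))
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$ratio, y = .data$parameter,
                                    colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mutant / WT ratio of means", y = NULL,
                  colour = "p < 0.05")
}
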