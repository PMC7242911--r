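# diagnostic ggplot2 methods for fitted objects

#' Plot a binding fit
#'
#' Titration points and the fitted depletion-corrected isotherm on a
#' log10 concentration axis.
#'
#' @param object A `binding_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binding_fit
#' @export
autoplot.binding_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    conc_um = 10^seq(log10(min(d$conc_um)), log10(max(d$conc_um)),
                     length.out = 200)
  )
  grid$signal <- binding_signal(
    free_ligand(grid$conc_um, object$p_tot, object$kd),
    object$s1, object$s2, object$kd
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_um, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Total ligand (µM)", y = "Signal",
      title = sprintf("One-to-one binding fit: Kd = %.3g µM", object$kd)
    )
}

#' Plot a dose-response fit
#'
#' @param object A `dose_response_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(
    conc_um = 10^seq(log10(min(d$conc_um)), log10(max(d$conc_um)),
                     length.out = 200)
  )
  grid$signal <- dose_response_signal(log10(grid$conc_um), object$a1,
                                      object$a2, object$x0, object$p)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc_um, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Inhibitor (µM)", y = "Signal",
      title = sprintf("Dose-response fit: IC50 = %.3g µM", object$ic50)
    )
}

#' Plot a double-exponential shrinkage fit
#'
#' @param object A `double_exp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot double_exp_fit
#' @export
autoplot.double_exp_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble::tibble(time_s = seq(min(d$time_s), max(d$time_s),
                                      length.out = 400))
  grid$fluorescence <- object$baseline +
    object$a_fast * (1 - exp(-object$k_fast * grid$time_s)) +
    object$a_slow * (1 - exp(-object$k_slow * grid$time_s))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s,
                                  y = .data$fluorescence)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = "Time (s)", y = "Fluorescence (a.u.)",
      title = sprintf("Shrinkage fit: k = %.3g /s", object$k_selected)
    )
}

#' Plot a calcein-quench fit
#'
#' @param object A `quench_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot quench_fit
#' @export
autoplot.quench_fit <- function(object, ...) {
  d <- object$data
  post <- d$time_s >= object$injection_time
  grid <- tibble::tibble(time_s = seq(object$injection_time,
                                      max(d$time_s), length.out = 400))
  grid$fluorescence <- object$f_inf +
    (object$f0 - object$f_inf) *
    exp(-object$k * (grid$time_s - object$injection_time))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s,
                                  y = .data$fluorescence)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$injection_time,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Time (s)", y = "Fluorescence (a.u.)",
      title = sprintf("Calcein-quench fit: k = %.3g /s", object$k)
    )
}
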