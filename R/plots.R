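#' Plot a complex-stiffness spectrum
#'
#' Log-log plot of the elastic (\eqn{\kappa'}) and viscous (\eqn{\kappa''})
#' components against angular frequency; untrusted grid points are drawn
#' hollow.
#'
#' @param object A `stiffness_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stiffness_spectrum <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "omega", "kp", "kpp", "trusted"),
    cols = c("kp", "kpp"), names_to = "component", values_to = "kappa")
  dat$component <- factor(dat$component, c("kp", "kpp"),
                          c("elastic k'", "viscous k''"))
  ggplot2::ggplot(dat, ggplot2::aes(.data$omega, .data$kappa,
                                    colour = .data$component,
                                    shape = .data$trusted)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::scale_colour_manual(values = c("elastic k'" = "#c0392b",
                                            "viscous k''" = "#2980b9")) +
    ggplot2::labs(x = "angular frequency (rad/s)",
                  y = "complex stiffness (pN/nm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cohort spectrum with confidence bands
#'
#' Median (or mean) \eqn{\kappa'} and \eqn{\kappa''} with bootstrap 95%
#' bands. Optionally overlays an external table of oscillatory-microrheology
#' points for comparison (plotting only).
#'
#' @param object A `cohort_spectrum` from [aggregate_cohort()].
#' @param overlay Optional data frame with columns `omega`, `kp`, `kpp`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_spectrum <- function(object, overlay = NULL, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(omega = object$omega, med = object$kp_med,
                   lo = object$kp_lo, hi = object$kp_hi,
                   component = "elastic k'"),
    tibble::tibble(omega = object$omega, med = object$kpp_med,
                   lo = object$kpp_lo, hi = object$kpp_hi,
                   component = "viscous k''"))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$omega, .data$med,
                                          colour = .data$component,
                                          fill = .data$component)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c("elastic k'" = "#c0392b",
                                            "viscous k''" = "#2980b9"),
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "angular frequency (rad/s)",
                  y = "complex stiffness (pN/nm)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(overlay)) {
    ov <- tidyr::pivot_longer(tibble::as_tibble(overlay),
                              cols = c("kp", "kpp"),
                              names_to = "component", values_to = "kappa")
    ov$component <- factor(ov$component, c("kp", "kpp"),
                           c("elastic k'", "viscous k''"))
    p <- p + ggplot2::geom_point(data = ov,
                                 ggplot2::aes(.data$omega, .data$kappa),
                                 shape = 4, size = 2)
  }
  p
}

#' Plot the loss tangent against lag time
#'
#' `tan delta` versus lag time `tau = 1/omega` with the `tan delta = 1`
#' viscous/elastic boundary, optionally marking extracted characteristic
#' times.
#'
#' @param spectrum A `stiffness_spectrum` or `cohort_spectrum`.
#' @param times Optional `characteristic_times` to mark.
#' @return A ggplot.
#' @export
plot_loss_tangent <- function(spectrum, times = NULL) {
  if (inherits(spectrum, "cohort_spectrum")) {
    dat <- tibble::tibble(tau = 1 / spectrum$omega, td = spectrum$tan_delta_med,
                          lo = spectrum$tan_delta_lo, hi = spectrum$tan_delta_hi)
  } else {
    dat <- tibble::tibble(tau = 1 / spectrum$omega,
                          td = spectrum$tan_delta,
                          lo = NA_real_, hi = NA_real_)
    dat <- dat[spectrum$trusted, ]
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$tau, .data$td)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "#2980b9") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "lag time (s)", y = "tan delta") +
    ggplot2::theme_minimal()
  if (all(is.finite(dat$lo))) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                                  alpha = 0.2)
  }
  if (!is.null(times)) {
    marks <- c(times$t_peak, times$t_peak_secondary, times$t_min)
    marks <- marks[is.finite(marks)]
    if (length(marks)) {
      p <- p + ggplot2::geom_vline(xintercept = marks, linetype = 3)
    }
  }
  p
}

#' Plot a force-extension curve with its fits
#'
#' @param es An [extension_series()].
#' @param stretch_fit Optional [fit_stretch_modulus()] result to draw.
#' @return A ggplot of force against extension over the ramp.
#' @export
plot_force_extension <- function(es, stretch_fit = NULL) {
  dat <- tibble::as_tibble(es[es$phase == "ramp", ])
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$lam, .data$f_mean)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "extension (nm)", y = "force (pN)") +
    ggplot2::theme_minimal()
  if (!is.null(stretch_fit)) {
    meta <- attr(es, "meta")
    # F = S * strain = S * lam / (1000 L0)
    p <- p + ggplot2::geom_abline(
      intercept = stretch_fit$intercept,
      slope = stretch_fit$S / (1000 * meta$L0), colour = "#c0392b")
  }
  p
}
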