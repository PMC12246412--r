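#' Tidy a stiffening-exponent fit
#'
#' @param x A `stiffening_fit`.
#' @param ... Unused.
#' @return One-row tibble with `term`-free wide columns `a`, `gamma`,
#'   `gamma_lo`, `gamma_hi`.
#' @export
tidy.stiffening_fit <- function(x, ...) {
  tibble::tibble(a = x$a, gamma = x$gamma,
                 gamma_lo = x$ci95[1], gamma_hi = x$ci95[2])
}

#' @rdname tidy.stiffening_fit
#' @export
glance.stiffening_fit <- function(x, ...) {
  tibble::tibble(n_points = x$n_points, n_dropped = x$n_dropped,
                 r_squared = x$diagnostics$r_squared,
                 sigma_log = x$diagnostics$sigma_log,
                 f_min = x$fit_domain[1], f_max = x$fit_domain[2],
                 method = x$method)
}

#' Tidy a stretch-modulus fit
#'
#' @param x A `stretch_modulus_fit`.
#' @param ... Unused.
#' @export
tidy.stretch_modulus_fit <- function(x, ...) {
  tibble::tibble(S = x$S, S_lo = x$ci95[1], S_hi = x$ci95[2],
                 intercept = x$intercept)
}

#' @rdname tidy.stretch_modulus_fit
#' @export
glance.stretch_modulus_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = x$n_points,
                 strain_min = x$strain_window[1], strain_max = x$strain_window[2])
}

#' Tidy a Burgers fit
#'
#' One row per parameter with the point estimate and multiplicative 95% CI.
#'
#' @param x A `burgers_fit`.
#' @param ... Unused.
#' @export
tidy.burgers_fit <- function(x, ...) {
  p <- x$params
  est <- c(kappa1 = p$kappa1, kappa2 = p$kappa2, eta1 = p$eta1, eta2 = p$eta2,
           tau1 = p$tau1, tau2 = p$tau2, tau3 = p$tau3, E1 = p$E1)
  lo <- c(x$ci95[1, ], rep(NA_real_, 4))
  hi <- c(x$ci95[2, ], rep(NA_real_, 4))
  tibble::tibble(term = names(est), estimate = unname(est),
                 conf.low = unname(lo), conf.high = unname(hi))
}

#' @rdname tidy.burgers_fit
#' @export
glance.burgers_fit <- function(x, ...) {
  tibble::tibble(cost = x$cost, n_points = x$n_points,
                 n_starts_converged = x$n_starts_converged,
                 flags = paste(x$identifiability_flags, collapse = ";"),
                 seed = x$seed)
}

#' Tidy a group comparison
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return The pairwise table with adjusted p-values.
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_global = x$p_global, df = x$df,
                 method = x$method, n = x$n)
}
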