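#' Centered moving-average smoothing
#'
#' Smooths a sampled series with a centered moving average whose window is a
#' fraction of the series length (default 1/15 of the data points). The window
#' is forced odd so the average is centered; edges use shrinking symmetric
#' windows, so the length is preserved and a constant or linear series passes
#' through unchanged in the interior.
#'
#' @param x Numeric series.
#' @param fraction Window size as a fraction of `length(x)` (default 1/15).
#' @param window Optional explicit window size (overrides `fraction`).
#' @return Smoothed series, same length as `x`.
#' @export
moving_average_smooth <- function(x, fraction = 1 / 15, window = NULL) {
  n <- length(x)
  if (n < 15L) {
    abort("series shorter than 15 points: analyse the raw series instead of smoothing.",
          class = "chromorheo_domain_error")
  }
  w <- window %||% max(3L, round(n * fraction))
  if (w %% 2L == 0L) w <- w + 1L  # force odd for a centered window
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)    # shrink symmetrically at the edges
    out[i] <- (cs[i + k + 1L] - cs[i - k]) / (2L * k + 1L)
  }
  out
}

#' Differential stiffness versus force
#'
#' Computes the numerical gradient `kappa = dF/dlambda` of the (smoothed)
#' force-extension curve by central differences and pairs it with the force at
#' the same samples. If smoothing leaves a non-monotone stretch of `lambda`,
#' the analysis window is trimmed to the longest strictly increasing run with
#' a warning.
#'
#' @param es An [extension_series()] (ramp phase is used).
#' @param smooth_fraction Moving-average window fraction applied to both
#'   channels before differentiating; `NULL` skips smoothing.
#' @return A tibble with columns `F` (pN) and `kappa` (pN/nm).
#' @export
stiffness_vs_force <- function(es, smooth_fraction = 1 / 15) {
  idx <- which(es$phase == "ramp")
  if (length(idx) < 3L) abort("need a ramp phase with at least 3 samples.",
                              class = "chromorheo_domain_error")
  lam <- es$lam[idx]
  FF <- es$f_mean[idx]
  if (!is.null(smooth_fraction) && length(idx) >= 15L) {
    lam <- moving_average_smooth(lam, smooth_fraction)
    FF <- moving_average_smooth(FF, smooth_fraction)
  }
  if (any(diff(lam) <= 0)) {
    runs <- rle(diff(lam) > 0)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    good <- which(runs$values)
    j <- good[which.max(runs$lengths[good])]
    keep <- starts[j]:(ends[j] + 1L)
    warn(sprintf("non-monotone extension after smoothing: trimmed to %d of %d samples.",
                 length(keep), length(lam)))
    lam <- lam[keep]; FF <- FF[keep]
  }
  n <- length(lam)
  kap <- (FF[c(2:n, n)] - FF[c(1, 1:(n - 1))]) /
    (lam[c(2:n, n)] - lam[c(1, 1:(n - 1))])
  tibble::tibble(F = FF, kappa = kap)
}

#' Fit the power-law stiffening exponent
#'
#' Fits `kappa = a F^gamma` to paired stiffness/force data by ordinary least
#' squares of `log(kappa)` on `log(F)` over the fit domain (scale-invariant
#' residuals across the decades `kappa` spans). `gamma` is the slope, `a` the
#' exponentiated intercept; the 95% CI comes from the regression. A nonlinear
#' least-squares alternative on the linear scale is available for sensitivity
#' checks.
#'
#' @param pairs Tibble with columns `F` and `kappa` (from
#'   [stiffness_vs_force()]).
#' @param domain Force range used for the fit; default `c(10, 0.9 * max(F))`
#'   (the low-force cutoff avoids the gradient noise floor).
#' @param method `"loglog"` (default) or `"nls"`.
#' @return An object of class `"stiffening_fit"` with elements `a`, `gamma`,
#'   `ci95` (on gamma), `fit_domain`, `n_points`, `n_dropped`, `diagnostics`.
#' @export
fit_stiffening_exponent <- function(pairs, domain = NULL,
                                    method = c("loglog", "nls")) {
  method <- match.arg(method)
  domain <- domain %||% c(10, 0.9 * max(pairs$F))
  sel <- pairs$F >= domain[1] & pairs$F <= domain[2]
  dat <- pairs[sel, ]
  pos <- dat$F > 0 & dat$kappa > 0 & is.finite(dat$kappa)
  n_dropped <- sum(!pos)
  if (n_dropped > 0.2 * nrow(dat)) {
    abort(sprintf("fit refused: %d of %d points in the domain have nonpositive stiffness.",
                  n_dropped, nrow(dat)),
          class = "chromorheo_fit_error")
  }
  dat <- dat[pos, ]
  if (nrow(dat) < 20L) {
    abort("need at least 20 (F, kappa) pairs in the fit domain.",
          class = "chromorheo_fit_error")
  }
  fit <- lm(log(kappa) ~ log(F), data = dat)
  gamma <- unname(coef(fit)[2])
  a <- exp(unname(coef(fit)[1]))
  ci <- suppressMessages(confint(fit))[2, ]
  if (method == "nls") {
    nfit <- try(minpack.lm::nlsLM(kappa ~ a * F^g, data = dat,
                                  start = list(a = a, g = gamma)),
                silent = TRUE)
    if (!inherits(nfit, "try-error")) {
      a <- unname(coef(nfit)[["a"]])
      gamma <- unname(coef(nfit)[["g"]])
      ci <- tryCatch(suppressMessages(confint(nfit))["g", ],
                     error = function(e) gamma + c(-1, 1) * 2 * summary(nfit)$coefficients["g", 2])
    }
  }
  structure(list(a = a, gamma = gamma, ci95 = unname(ci),
                 fit_domain = domain, n_points = nrow(dat),
                 n_dropped = n_dropped, method = method,
                 diagnostics = list(sigma_log = summary(fit)$sigma,
                                    r_squared = summary(fit)$r.squared)),
            class = "stiffening_fit")
}

#' @export
print.stiffening_fit <- function(x, ...) {
  cat(sprintf("<stiffening_fit> kappa = a F^gamma: gamma = %.3f [%.3f, %.3f], a = %.4g (n = %d, F in [%.3g, %.3g] pN)\n",
              x$gamma, x$ci95[1], x$ci95[2], x$a, x$n_points,
              x$fit_domain[1], x$fit_domain[2]))
  invisible(x)
}

#' Fit the stretch modulus
#'
#' Least-squares slope of chromosome force against dimensionless strain
#' `(L(t) - L0)/L0` over the ramp, within a configurable strain window. The
#' slope `S` (pN) is the spring constant of the chromosome, also called the
#' doubling force.
#'
#' @param es An [extension_series()].
#' @param meta [chromosome_meta()] with `L0` set; defaults to the series'.
#' @param strain_window Strain interval used for the fit (default (0, 0.2]).
#' @return An object of class `"stretch_modulus_fit"` with `S` (pN),
#'   `intercept` (pN), `r_squared`, `ci95` (pN) and `n_points`.
#' @export
fit_stretch_modulus <- function(es, meta = attr(es, "meta"),
                                strain_window = c(0, 0.2)) {
  if (is.null(meta) || is.na(meta$L0)) {
    abort("L0 is required for strain normalisation.",
          class = "chromorheo_validation_error")
  }
  idx <- which(es$phase == "ramp")
  strain <- (es$L[idx] - meta$L0) / meta$L0
  keep <- strain > strain_window[1] & strain <= strain_window[2]
  if (sum(keep) < 3L) {
    abort("strain window contains fewer than 3 samples.",
          class = "chromorheo_fit_error")
  }
  dat <- tibble::tibble(strain = strain[keep], F = es$f_mean[idx][keep])
  fit <- lm(F ~ strain, data = dat)
  ci <- suppressMessages(confint(fit))[2, ]
  structure(list(S = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared, ci95 = unname(ci),
                 n_points = nrow(dat), strain_window = strain_window),
            class = "stretch_modulus_fit")
}

#' @export
print.stretch_modulus_fit <- function(x, ...) {
  cat(sprintf("<stretch_modulus_fit> S = %.4g pN [%.4g, %.4g], r^2 = %.4f (n = %d)\n",
              x$S, x$ci95[1], x$ci95[2], x$r_squared, x$n_points))
  invisible(x)
}

#' Classify a ramp as linear or non-linear
#'
#' Compares a linear force-extension model with the integrated power-law
#' stiffening model (the closed-form `F(lambda)` curve whose differential
#' stiffness is `a F^gamma`) via BIC on the smoothed ramp. The response is
#' labelled `nonlinear` when the power-law model is favoured by
#' `Delta BIC > threshold` and the fitted `gamma` CI excludes 0; `linear` when
#' the linear model is favoured or the CI includes 0; `indeterminate`
#' otherwise (including degenerate data, which never raises).
#'
#' @param es An [extension_series()].
#' @param delta_bic BIC margin required to call the response nonlinear
#'   (default 10).
#' @param smooth_fraction Moving-average fraction applied before fitting.
#' @return An object of class `"response_class"` with `label` and `evidence`
#'   (the BIC difference, positive when the power-law model is favoured).
#' @export
classify_response <- function(es, delta_bic = 10, smooth_fraction = 1 / 15) {
  out <- try(classify_response_impl(es, delta_bic, smooth_fraction),
             silent = TRUE)
  if (inherits(out, "try-error")) {
    out <- structure(list(label = "indeterminate", evidence = NA_real_,
                          gamma_ci = c(NA_real_, NA_real_)),
                     class = "response_class")
  }
  out
}

classify_response_impl <- function(es, delta_bic, smooth_fraction) {
  idx <- which(es$phase == "ramp")
  # the model comparison runs on the raw samples: smoothing correlates the
  # residuals and inflates the evidence for the richer model
  lam <- es$lam[idx]
  FF <- es$f_mean[idx]
  dat <- tibble::tibble(lam = lam, F = FF)
  lin <- lm(F ~ lam, data = dat)
  pairs <- stiffness_vs_force(es, smooth_fraction)
  sf <- fit_stiffening_exponent(pairs, domain = c(max(min(FF[FF > 0]), 1e-3),
                                                  max(FF)))
  # integrated power law through (lam0, Fstart): dF/dlam = a F^gamma
  g <- sf$gamma; a0 <- sf$a
  Fstart <- max(FF[1], 1e-6)
  lam0 <- lam[1]
  pl_curve <- function(a, g, F0, l0) {
    if (abs(g - 1) < 1e-8) return(pmin(F0 * exp(a * (dat$lam - l0)), 1e8))
    base <- F0^(1 - g) + a * (1 - g) * (dat$lam - l0)
    # clamp instead of rejecting: a softly exploding prediction keeps the
    # objective finite and steerable near the domain edge
    base <- pmax(base, 1e-10 * max(abs(base), F0^(1 - g)))
    pmin(base^(1 / (1 - g)), 1e8)
  }
  rss_pl <- function(p) {
    pred <- pl_curve(exp(p[1]), p[2], exp(p[3]), lam0)
    if (any(!is.finite(pred))) return(1e12)
    sum((dat$F - pred)^2)
  }
  op <- optim(c(log(a0), g, log(Fstart)), rss_pl, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  n <- nrow(dat)
  bic_lin <- n * log(sum(residuals(lin)^2) / n) + 2 * log(n)
  bic_pl <- n * log(op$value / n) + 3 * log(n)
  evidence <- bic_lin - bic_pl  # > 0 favours the power-law model
  gamma_ci <- sf$ci95
  ci_excludes_0 <- gamma_ci[1] > 0 || gamma_ci[2] < 0
  label <- if (evidence > delta_bic && ci_excludes_0) {
    "nonlinear"
  } else if (evidence < 0 || !ci_excludes_0) {
    "linear"
  } else {
    "indeterminate"
  }
  structure(list(label = label, evidence = evidence, gamma_ci = gamma_ci),
            class = "response_class")
}

#' @export
print.response_class <- function(x, ...) {
  cat(sprintf("<response_class> %s (Delta BIC = %.1f in favour of power-law stiffening)\n",
              x$label, x$evidence))
  invisible(x)
}
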