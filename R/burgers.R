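#' Closed-form Burgers complex stiffness
#'
#' Evaluates the analytic complex stiffness of the four-element Burgers model
#' on a frequency grid:
#' \deqn{\kappa'(\omega) = \frac{(\tau_2 + \tau_3 + \tau_1^2 \tau_3 \omega^2)\,
#'   \eta_2 \omega^2}{(1 - \tau_1\tau_3\omega^2)^2 + (E_1\omega)^2}, \qquad
#'   \kappa''(\omega) = \frac{[1 + (\tau_1 + \tau_2)\tau_1\omega^2]\,
#'   \eta_2 \omega}{(1 - \tau_1\tau_3\omega^2)^2 + (E_1\omega)^2}}
#' with \eqn{\tau_1 = \eta_1/\kappa_1}, \eqn{\tau_2 = \eta_2/\kappa_1},
#' \eqn{\tau_3 = \eta_2/\kappa_2}, \eqn{E_1 = \tau_1+\tau_2+\tau_3}. At high
#' frequency \eqn{\kappa' \to \kappa_2}; at low frequency
#' \eqn{\kappa''/\omega \to \eta_2}.
#'
#' @param params [burgers_params()] (finite elements).
#' @param grid [frequency_grid()] or positive numeric vector (rad/s).
#' @return A `stiffness_spectrum` tibble (all points trusted).
#' @export
burgers_spectrum <- function(params, grid = frequency_grid()) {
  w <- as.numeric(grid)
  t1 <- params$tau1; t2 <- params$tau2; t3 <- params$tau3; E1 <- params$E1
  den <- (1 - t1 * t3 * w^2)^2 + (E1 * w)^2
  kp <- (t2 + t3 + t1^2 * t3 * w^2) * params$eta2 * w^2 / den
  kpp <- (1 + (t1 + t2) * t1 * w^2) * params$eta2 * w / den
  out <- tibble::tibble(omega = w, kp = kp, kpp = kpp,
                        tan_delta = kpp / kp, trusted = TRUE)
  attr(out, "band") <- range(w)
  class(out) <- c("stiffness_spectrum", class(tibble::tibble()))
  out
}

#' Burgers complex stiffness via the constitutive ODE
#'
#' Independent evaluation used to cross-check [burgers_spectrum()]: the
#' Kelvin-form constitutive equation
#' \deqn{F + (\tau_1+\tau_2+\tau_3)\dot F + \tau_1\tau_3 \ddot F =
#'   \eta_2\dot\lambda + \tau_1\eta_2\ddot\lambda}
#' becomes, under the substitution \eqn{d/dt \to i\omega}, the ratio of the
#' strain-side to force-side characteristic polynomials:
#' \deqn{\kappa^*(\omega) = \frac{i\omega\eta_2(1 + i\omega\tau_1)}
#'   {1 + i\omega E_1 - \tau_1\tau_3\omega^2}.}
#' The two routes must agree to machine precision; this one exists solely as
#' the oracle for that identity.
#'
#' @param params [burgers_params()].
#' @param grid Frequency grid (rad/s).
#' @return Complex vector \eqn{\kappa^*(\omega)}.
#' @export
burgers_kstar_ode <- function(params, grid = frequency_grid()) {
  w <- as.numeric(grid)
  iw <- 1i * w
  iw * params$eta2 * (1 + iw * params$tau1) /
    (1 + iw * params$E1 + iw^2 * params$tau1 * params$tau3)
}

#' Fit the Burgers model to a measured spectrum
#'
#' Nonlinear least squares of the closed-form Burgers spectrum against
#' measured \eqn{\kappa'} and \eqn{\kappa''} jointly, minimising summed
#' squared relative residuals on both components with equal weight (the
#' components span decades, so absolute residuals would be dominated by the
#' high-frequency plateau). Parameters are optimised in log space, which
#' enforces positivity by construction. The optimiser is restarted from
#' `n_starts` deterministic perturbations of a heuristic initial guess
#' (`kappa2` from the high-frequency `kp` plateau, `eta2` from the
#' low-frequency `kpp/omega`, `kappa1` from the mid-band `kp` level, `eta1`
#' from the transition frequency); the best converged start is returned.
#'
#' @param spectrum A `stiffness_spectrum` (trusted points with both
#'   components are used; pass `use_untrusted = TRUE` to fit everything).
#' @param n_starts Number of multi-starts (default 8).
#' @param seed Seed for the deterministic start perturbations.
#' @param use_untrusted Include untrusted grid points (default FALSE).
#' @return An object of class `"burgers_fit"`: `params` ([burgers_params()]),
#'   `cost`, `ci95` (per-parameter multiplicative 95% intervals from the
#'   local curvature in log space), `n_starts_converged`,
#'   `identifiability_flags`, `seed`.
#' @export
fit_burgers <- function(spectrum, n_starts = 8, seed = 1,
                        use_untrusted = FALSE) {
  dat <- spectrum[(spectrum$trusted | use_untrusted) &
                    is.finite(spectrum$kp) & is.finite(spectrum$kpp), ]
  dat <- dat[order(dat$omega), ]
  if (nrow(dat) < 8L ||
      log10(max(dat$omega) / min(dat$omega)) < 2) {
    abort("need a spectrum spanning at least 2 trusted decades with both components.",
          class = "chromorheo_fit_error")
  }
  w_all <- dat$omega
  kp_all <- dat$kp
  kpp_all <- dat$kpp

  # coherence pre-mask: for a passive model kappa' is positive and smooth in
  # log frequency, so points jumping away from their local median are
  # noise-dominated and excluded before fitting
  local_med <- stats::runmed(kp_all, 5)
  keep <- kp_all > 0 & abs(kp_all - local_med) < 0.5 * pmax(abs(local_med), 1e-12)
  if (sum(keep) < 8L) keep <- rep(TRUE, nrow(dat))

  make_resid <- function(keep, clip = 3) {
    w <- w_all[keep]; kp <- kp_all[keep]; kpp <- kpp_all[keep]
    kp_scale <- pmax(abs(kp), 1e-9 * max(abs(kp)))
    kpp_scale <- pmax(abs(kpp), 1e-9 * max(abs(kpp)))
    function(logp) {
      p <- burgers_params_unchecked(exp(logp))
      sp <- burgers_spectrum_raw(p, w)
      r <- c((sp$kp - kp) / kp_scale, (sp$kpp - kpp) / kpp_scale)
      # soft-clip relative residuals so noise-dominated points (typically the
      # small viscous component at high frequency) cannot capture the fit
      clip * tanh(r / clip)
    }
  }
  # unclipped per-point residual magnitude (max over the two components)
  point_resid <- function(logp, keep) {
    w <- w_all[keep]; kp <- kp_all[keep]; kpp <- kpp_all[keep]
    p <- burgers_params_unchecked(exp(logp))
    sp <- burgers_spectrum_raw(p, w)
    pmax(abs(sp$kp - kp) / pmax(abs(kp), 1e-9 * max(abs(kp))),
         abs(sp$kpp - kpp) / pmax(abs(kpp), 1e-9 * max(abs(kpp))))
  }

  # heuristic initials from the kept spectrum's asymptotes
  w <- w_all[keep]; kp <- kp_all[keep]; kpp <- kpp_all[keep]
  k2_0 <- stats::median(kp[w >= quantile(w, 0.9)])
  eta2_0 <- abs(stats::median((kpp / w)[w <= quantile(w, 0.1)]))
  # an elastic-dominated spectrum carries no flow information; keep the
  # initial dashpot large enough that the Maxwell time can reach the band
  eta2_0 <- max(eta2_0, 1e-3 * k2_0 / min(w), na.rm = TRUE)
  k1_0 <- max(stats::median(kp[w >= quantile(w, 0.4) & w <= quantile(w, 0.6)]),
              0.05 * k2_0)
  k2_0 <- max(k2_0, 2 * k1_0 * 1e-3)
  # transition frequency: where kpp/kp is largest in the upper half-band
  hi <- w >= stats::median(w)
  w_tr <- w[hi][which.max((kpp / pmax(kp, 1e-12))[hi])]
  eta1_0 <- k1_0 / w_tr
  init <- c(kappa1 = k1_0, kappa2 = k2_0, eta1 = eta1_0, eta2 = eta2_0)
  init[!is.finite(init) | init <= 0] <- 1e-3
  base <- log(init)

  perturb <- with_seed(seed, {
    matrix(runif(4 * n_starts, -log(4), log(4)), nrow = n_starts)
  })
  perturb[1, ] <- 0  # first start is the unperturbed heuristic

  box <- log(1e5)  # parameters stay within 1e5x of the heuristic initials
  run_starts <- function(resid_fn, starts) {
    best <- NULL
    n_conv <- 0L
    for (i in seq_len(nrow(starts))) {
      fit <- try(minpack.lm::nls.lm(
        par = starts[i, ], fn = resid_fn,
        lower = base - box, upper = base + box,
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-12)),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      converged <- fit$info %in% 1:4
      if (converged) n_conv <- n_conv + 1L
      cost <- sum(fit$fvec^2)
      if (is.null(best) || cost < best$cost) {
        best <- list(fit = fit, cost = cost, converged = converged)
      }
    }
    if (!is.null(best)) best$n_conv <- n_conv
    best
  }
  starts <- sweep(perturb, 2, base, `+`)
  best <- run_starts(make_resid(keep), starts)
  if (is.null(best)) {
    abort("all optimisation starts failed.", class = "chromorheo_fit_error")
  }
  n_conv <- best$n_conv

  # second pass: reject residual outliers (noise-dominated points that
  # survived the coherence mask) and refit from the incumbent solution
  pr <- point_resid(best$fit$par, keep)
  thr <- max(10 * stats::mad(pr), 0.2)
  good <- pr <= thr
  if (any(!good) && sum(good) >= 8L) {
    keep2 <- keep
    keep2[which(keep)[!good]] <- FALSE
    if (log10(max(w_all[keep2]) / min(w_all[keep2])) >= 2) {
      best2 <- run_starts(make_resid(keep2),
                          rbind(best$fit$par, starts[1, ]))
      if (!is.null(best2)) {
        best <- best2
        keep <- keep2
      }
    }
  }
  logp <- best$fit$par
  p <- exp(logp)
  params <- burgers_params(p[1], p[2], p[3], p[4])

  # local-curvature CIs in log space -> multiplicative intervals
  se_log <- rep(NA_real_, 4)
  dof <- max(2 * nrow(dat) - 4, 1)
  s2 <- best$cost / dof
  cov_try <- try({
    H <- best$fit$hessian
    solve(H) * 2 * s2
  }, silent = TRUE)
  if (!inherits(cov_try, "try-error") && all(is.finite(diag(cov_try))) &&
      all(diag(cov_try) >= 0)) {
    se_log <- sqrt(diag(cov_try))
  }
  ci95 <- rbind(exp(logp - 1.96 * se_log), exp(logp + 1.96 * se_log))
  colnames(ci95) <- c("kappa1", "kappa2", "eta1", "eta2")

  flags <- character()
  # a spectrum without a viscous component above the noise floor cannot pin eta1
  if (max(abs(kpp)) < 1e-6 * max(abs(kp))) flags <- c(flags, "eta1_nonidentifiable")
  if (any(!is.finite(se_log))) flags <- c(flags, "curvature_singular")
  if (any(is.finite(se_log) & se_log > log(10))) flags <- c(flags, "wide_ci")

  structure(list(params = params, cost = best$cost, ci95 = ci95,
                 n_starts_converged = n_conv, identifiability_flags = flags,
                 n_points = sum(keep), n_masked = nrow(dat) - sum(keep),
                 seed = seed),
            class = "burgers_fit")
}

# internal: skip validation inside the optimiser hot loop
burgers_params_unchecked <- function(p) {
  k1 <- p[1]; k2 <- p[2]; e1 <- p[3]; e2 <- p[4]
  t1 <- e1 / k1; t2 <- e2 / k1; t3 <- e2 / k2
  list(kappa1 = k1, kappa2 = k2, eta1 = e1, eta2 = e2,
       tau1 = t1, tau2 = t2, tau3 = t3, E1 = t1 + t2 + t3)
}

burgers_spectrum_raw <- function(params, w) {
  t1 <- params$tau1; t2 <- params$tau2; t3 <- params$tau3; E1 <- params$E1
  den <- (1 - t1 * t3 * w^2)^2 + (E1 * w)^2
  list(kp = (t2 + t3 + t1^2 * t3 * w^2) * params$eta2 * w^2 / den,
       kpp = (1 + (t1 + t2) * t1 * w^2) * params$eta2 * w / den)
}

#' @export
print.burgers_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<burgers_fit> kappa1=%.4g kappa2=%.4g pN/nm, eta1=%.4g eta2=%.4g pN.s/nm (cost %.3g, %d start(s) converged%s)\n",
              p$kappa1, p$kappa2, p$eta1, p$eta2, x$cost,
              x$n_starts_converged,
              if (length(x$identifiability_flags))
                paste0("; flags: ", paste(x$identifiability_flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Derived Burgers parameter ratios
#'
#' The ratios summarising a fitted Burgers model: `r1 = eta1/kappa1` (s, the
#' Kelvin--Voigt relaxation time), `r2 = eta2/kappa1` (s, the long-time flow
#' ratio), and a relative stiffness `rel_kappa`. "Relative kappa" is reported
#' under two readings: the default relative change `(kappa2 - kappa1)/kappa1`
#' and the plain ratio `kappa2/kappa1`; both are returned, with `definition`
#' selecting which fills `rel_kappa`.
#'
#' @param x A [burgers_params()] or [fit_burgers()] result.
#' @param definition `"relative_change"` (default) or `"ratio"`.
#' @return A tibble with `r1`, `r2`, `rel_kappa`, `rel_kappa_ratio`,
#'   `rel_kappa_change` and, when `x` is a fit with finite curvature, delta-
#'   method 95% CIs `r1_lo/hi`, `r2_lo/hi`.
#' @export
derived_ratios <- function(x, definition = c("relative_change", "ratio")) {
  definition <- match.arg(definition)
  fit <- NULL
  if (inherits(x, "burgers_fit")) {
    fit <- x
    x <- x$params
  }
  r1 <- x$eta1 / x$kappa1
  r2 <- x$eta2 / x$kappa1
  change <- (x$kappa2 - x$kappa1) / x$kappa1
  ratio <- x$kappa2 / x$kappa1
  out <- tibble::tibble(
    r1 = r1, r2 = r2,
    rel_kappa = if (definition == "relative_change") change else ratio,
    rel_kappa_change = change, rel_kappa_ratio = ratio,
    definition = definition
  )
  if (!is.null(fit) && all(is.finite(fit$ci95))) {
    # first-order deltas in log space: log r1 = log eta1 - log kappa1
    se <- (log(fit$ci95[2, ]) - log(fit$ci95[1, ])) / (2 * 1.96)
    se_r1 <- sqrt(se[["eta1"]]^2 + se[["kappa1"]]^2)
    se_r2 <- sqrt(se[["eta2"]]^2 + se[["kappa1"]]^2)
    out$r1_lo <- r1 * exp(-1.96 * se_r1); out$r1_hi <- r1 * exp(1.96 * se_r1)
    out$r2_lo <- r2 * exp(-1.96 * se_r2); out$r2_hi <- r2 * exp(1.96 * se_r2)
  }
  out
}
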