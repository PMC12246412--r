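#' Log-spaced angular-frequency grid
#'
#' @param omega_min,omega_max Grid limits in rad/s (default 1e-2 to 1e5, the
#'   seven decades a 120 s dwell with microsecond-resolved early sampling can
#'   cover).
#' @param points_per_decade Grid density (default 16).
#' @return Numeric vector of class `"frequency_grid"`, strictly increasing and
#'   uniform in log10.
#' @export
frequency_grid <- function(omega_min = 1e-2, omega_max = 1e5,
                           points_per_decade = 16) {
  if (omega_min <= 0 || omega_max <= omega_min) {
    abort("need 0 < omega_min < omega_max.", class = "chromorheo_param_error")
  }
  ndec <- log10(omega_max / omega_min)
  w <- 10^seq(log10(omega_min), log10(omega_max),
              length.out = max(2L, round(ndec * points_per_decade) + 1L))
  structure(w, points_per_decade = points_per_decade, class = "frequency_grid")
}

#' Input series for the one-sided Fourier transform
#'
#' Packages a sampled signal for [one_sided_fourier()]: times are re-zeroed so
#' `t[1] = 0` marks the start of the analysis window, `g0` is the value the
#' signal is taken to step to at `t = 0+` (for a record that rises from rest
#' use `g0 = 0` and prepend nothing), and `gdot_inf` is the terminal gradient
#' used to extend the signal beyond the last sample.
#'
#' @param t Sample times in s, strictly increasing.
#' @param g Signal values.
#' @param g0 Initial value (default: first sample).
#' @param gdot_inf Terminal gradient in units of `g` per s; `NULL` estimates
#'   it as the least-squares slope over the last `tail_fraction` of the
#'   record (approximately 0 for fully relaxed records).
#' @param tail_fraction Fraction of the record (by time) used for the
#'   terminal-gradient estimate.
#' @return A list of class `"transform_input"`.
#' @export
transform_input <- function(t, g, g0 = g[1], gdot_inf = NULL,
                            tail_fraction = 0.1) {
  if (length(t) != length(g)) abort("`t` and `g` must have equal length.",
                                    class = "chromorheo_validation_error")
  if (any(diff(t) <= 0)) abort("`t` must be strictly increasing.",
                               class = "chromorheo_validation_error")
  if (any(!is.finite(g))) abort("`g` must be finite.",
                                class = "chromorheo_validation_error")
  t <- t - t[1]
  if (is.null(gdot_inf)) {
    tail_idx <- which(t >= (1 - tail_fraction) * t[length(t)])
    gdot_inf <- if (length(tail_idx) >= 2L) {
      unname(coef(lm(g[tail_idx] ~ t[tail_idx]))[2])
    } else 0
  }
  structure(list(t = t, g = g, g0 = g0, gdot_inf = gdot_inf),
            class = "transform_input")
}

#' One-sided Fourier transform of a non-uniformly sampled signal
#'
#' Evaluates, on an arbitrary angular-frequency grid,
#' \deqn{P(\omega) = i\omega g(t_0) + \dot g_\infty e^{-i\omega t_N} +
#'   \sum_{k=1}^{N} \frac{g_k - g_{k-1}}{t_k - t_{k-1}}
#'   \left(e^{-i\omega t_{k-1}} - e^{-i\omega t_k}\right)}
#' which equals \eqn{-\omega^2 \hat g(\omega)} for the piecewise-linear
#' interpolant of the samples, extended by a step to `g0` at `t = 0+` and by
#' the terminal gradient beyond the last sample. The evaluation is exact for
#' piecewise-linear signals under any sampling, uniform or not; keeping the
#' un-normalised `P` (rather than dividing by \eqn{-\omega^2}) lets the
#' \eqn{-\omega^2} factors cancel in the complex-stiffness ratio without
#' overflow at the grid extremes.
#'
#' @param input A [transform_input()].
#' @param grid A [frequency_grid()] (or any positive increasing vector of
#'   rad/s).
#' @param block Number of samples per evaluation block (memory control).
#' @return Complex vector `P(omega)`, same length as `grid`.
#' @export
one_sided_fourier <- function(input, grid, block = 20000L) {
  if (!length(grid)) abort("empty frequency grid.", class = "chromorheo_param_error")
  w <- as.numeric(grid)
  t <- input$t
  g <- input$g
  n <- length(t)
  P <- 1i * w * input$g0 + input$gdot_inf * exp(-1i * w * t[n])
  slopes <- diff(g) / diff(t)
  # sum over increments in blocks: E_{k-1} - E_k telescoped per block
  idx <- seq_len(n - 1L)
  for (start in seq(1L, n - 1L, by = block)) {
    kk <- idx[start:min(start + block - 1L, n - 1L)]
    Ea <- exp(-1i * outer(w, t[kk]))
    Eb <- exp(-1i * outer(w, t[kk + 1L]))
    P <- P + as.vector((Ea - Eb) %*% slopes[kk])
  }
  P
}

#' Log-time decimation of a uniformly sampled record
#'
#' Reduces a high-rate record to a log-spaced time grid by per-bin averaging
#' (block averaging acts as an anti-alias filter). The first and last samples
#' are preserved exactly; bins containing a single sample pass it through, so
#' early samples stay at raw resolution.
#'
#' @param t,g Uniform high-rate record.
#' @param points_per_decade Target log-grid density (default 200).
#' @param t_min First bin edge (s); defaults to the first positive sample
#'   time.
#' @return A tibble with decimated `t`, `g` and per-bin sample counts `n`.
#' @export
log_decimate <- function(t, g, points_per_decade = 200, t_min = NULL) {
  if (length(t) != length(g)) abort("`t` and `g` must have equal length.",
                                    class = "chromorheo_validation_error")
  pos <- t > 0
  t_min <- t_min %||% min(t[pos])
  t_max <- max(t)
  n_bins <- ceiling(points_per_decade * log10(t_max / t_min))
  if (sum(pos) <= n_bins) {
    warn("fewer input points than requested log grid: passing the record through.")
    return(tibble::tibble(t = t[pos], g = g[pos], n = 1L))
  }
  edges <- 10^seq(log10(t_min), log10(t_max), length.out = n_bins + 1L)
  bin <- findInterval(t[pos], edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  tp <- t[pos]; gp <- g[pos]
  tm <- tapply(tp, bin, mean)
  gm <- tapply(gp, bin, mean)
  nn <- tapply(gp, bin, length)
  out <- tibble::tibble(t = as.numeric(tm), g = as.numeric(gm),
                        n = as.integer(nn))
  out <- out[order(out$t), ]
  # preserve the terminal sample exactly
  out$t[nrow(out)] <- tp[length(tp)]
  out$g[nrow(out)] <- gp[length(gp)]
  if (out$t[1] > tp[1]) {
    out <- dplyr::bind_rows(tibble::tibble(t = tp[1], g = gp[1], n = 1L), out)
  } else {
    out$t[1] <- tp[1]; out$g[1] <- gp[1]
  }
  out[!duplicated(out$t), ]
}

#' Complex stiffness from force and extension transforms
#'
#' Forms \eqn{\kappa^*(\omega) = \hat F(\omega) / \hat\lambda(\omega)} as the
#' ratio \eqn{P_F(\omega)/P_\lambda(\omega)} of the un-normalised one-sided
#' transforms (the \eqn{-\omega^2} factors cancel). The real part is the
#' elastic component \eqn{\kappa'}, the imaginary part the viscous component
#' \eqn{\kappa''}. Grid points within half a decade of the record-length limit
#' \eqn{2\pi/t_N} or the sampling limit \eqn{\pi/\min\Delta t} are flagged
#' untrusted rather than dropped; points where \eqn{|P_\lambda|} underflows
#' are masked.
#'
#' @param F_in [transform_input()] for the force in pN.
#' @param lam_in [transform_input()] for the deformation in nm (same time
#'   base).
#' @param grid A [frequency_grid()].
#' @param edge_margin Trusted-band trim on each side, in decades (default
#'   0.5).
#' @return A tibble of class `"stiffness_spectrum"` with columns `omega`
#'   (rad/s), `kp`, `kpp` (pN/nm), `tan_delta` and `trusted`; attributes
#'   `n_samples_used` and `band` (the trusted limits).
#' @export
complex_stiffness <- function(F_in, lam_in, grid = frequency_grid(),
                              edge_margin = 0.5) {
  if (length(F_in$t) != length(lam_in$t) ||
      max(abs(F_in$t - lam_in$t)) > 1e-12 * max(F_in$t)) {
    abort("force and extension must share the same time base.",
          class = "chromorheo_validation_error")
  }
  w <- as.numeric(grid)
  PF <- one_sided_fourier(F_in, w)
  PL <- one_sided_fourier(lam_in, w)
  floor_ <- max(abs(PL)) * 1e-12
  masked <- abs(PL) <= floor_
  ks <- PF / PL
  ks[masked] <- NA_complex_
  tN <- F_in$t[length(F_in$t)]
  dt_min <- min(diff(F_in$t))
  lo <- 2 * pi / tN * 10^edge_margin
  hi <- pi / dt_min / 10^edge_margin
  out <- tibble::tibble(
    omega = w,
    kp = Re(ks),
    kpp = Im(ks),
    tan_delta = NA_real_,
    trusted = w >= lo & w <= hi & !masked
  )
  attr(out, "n_samples_used") <- length(F_in$t)
  attr(out, "band") <- c(lo, hi)
  class(out) <- c("stiffness_spectrum", class(tibble::tibble()))
  loss_tangent(out)
}

#' Fill the loss tangent of a spectrum
#'
#' `tan delta = kappa''/kappa'` wherever the elastic component is above a
#' numeric floor; masked (NA) elsewhere. Values above 1 mean dissipation
#' dominates (fluid-like), below 1 elastic (gel-like).
#'
#' @param spectrum A `stiffness_spectrum`.
#' @param floor Relative floor on `kp` below which the ratio is masked.
#' @return The spectrum with `tan_delta` filled.
#' @export
loss_tangent <- function(spectrum, floor = 1e-9) {
  kp_floor <- floor * max(abs(spectrum$kp), na.rm = TRUE)
  spectrum$tan_delta <- ifelse(
    !is.na(spectrum$kp) & abs(spectrum$kp) > kp_floor,
    spectrum$kpp / spectrum$kp, NA_real_)
  spectrum
}

#' Broadband microrheology of one stretch/dwell record
#'
#' High-level conversion: takes a (baseline-zeroed) trace, derives the
#' extension series, windows it, builds the transform inputs and returns the
#' complex-stiffness spectrum.
#'
#' The default window, `"stretch_hold"`, places `t = 0` at ramp start so both
#' force and deformation rise continuously from rest (no step terms); the
#' transform ratio is then exact for any linear viscoelastic tether. The
#' `"dwell"` window instead treats the first dwell sample as a step from rest
#' — adequate only when the ramp is fast compared with every material
#' timescale, and provided for comparability with analyses that discard ramp
#' data.
#'
#' @param trace A [tether_trace()] (zeroed; simulated traces are born zeroed).
#' @param meta Metadata with `L0` and `kappa_OT`; defaults to the trace's.
#' @param grid [frequency_grid()].
#' @param window `"stretch_hold"` (default) or `"dwell"`.
#' @param gdot_inf Terminal gradients (list with `F` and `lam`), `NULL` to
#'   estimate from the final 10% of the record.
#' @param edge_margin Trusted-band trim in decades.
#' @return A `stiffness_spectrum` tibble.
#' @export
microrheology <- function(trace, meta = trace_meta(trace),
                          grid = frequency_grid(),
                          window = c("stretch_hold", "dwell"),
                          gdot_inf = NULL, edge_margin = 0.5) {
  window <- match.arg(window)
  es <- if (inherits(trace, "extension_series")) trace
        else extension_series(trace, meta)
  idx <- switch(window,
    stretch_hold = which(es$phase %in% c("ramp", "dwell")),
    dwell = which(es$phase == "dwell"))
  if (length(idx) < 8L) abort("too few samples in the analysis window.",
                              class = "chromorheo_domain_error")
  t <- es$t[idx]
  FF <- es$f_mean[idx]
  lam <- es$lam[idx]
  if (window == "stretch_hold") {
    # signals rise from rest: prepend the zero sample at ramp start
    t0 <- es$t[idx[1]] - min(diff(t))
    t <- c(t0, t); FF <- c(0, FF); lam <- c(0, lam)
    g0F <- 0; g0L <- 0
  } else {
    g0F <- FF[1]; g0L <- lam[1]
  }
  F_in <- transform_input(t, FF, g0 = g0F,
                          gdot_inf = if (is.null(gdot_inf)) NULL else gdot_inf$F)
  L_in <- transform_input(t, lam, g0 = g0L,
                          gdot_inf = if (is.null(gdot_inf)) NULL else gdot_inf$lam)
  complex_stiffness(F_in, L_in, grid, edge_margin = edge_margin)
}

#' Characteristic loss-tangent peak times
#'
#' Finds local maxima of `tan delta` against log frequency inside the trusted
#' band after light log-domain smoothing. The dominant peak is the global
#' interior maximum; a secondary peak is the next-highest interior maximum at
#' least `min_separation_decades` away. Characteristic times are the
#' reciprocals of the peak angular frequencies (`t = 1/omega`). A spectrum
#' whose loss tangent is monotone in-band (e.g. a Maxwell fluid) has no
#' interior peak; absence is encoded, not raised.
#'
#' @param spectrum A `stiffness_spectrum` with `tan_delta` filled.
#' @param smooth_points Width (grid points) of the moving-average smoothing.
#' @param min_separation_decades Minimum separation between reported peaks.
#' @return List of class `"characteristic_times"` with `t_peak`,
#'   `tan_delta_max`, `t_peak_secondary`, `tan_delta_secondary` (NA when
#'   absent) and `interior` (FALSE when the in-band maximum sits on the band
#'   edge).
#' @export
characteristic_peak_times <- function(spectrum, smooth_points = 5,
                                      min_separation_decades = 0.5) {
  dat <- spectrum[spectrum$trusted & !is.na(spectrum$tan_delta), ]
  n <- nrow(dat)
  empty <- structure(list(t_peak = NA_real_, tan_delta_max = NA_real_,
                          t_peak_secondary = NA_real_,
                          tan_delta_secondary = NA_real_, interior = FALSE),
                     class = "characteristic_times")
  if (n < 5L) return(empty)
  td <- smooth_k(dat$tan_delta, smooth_points)
  is_max <- which(diff(sign(diff(td))) < 0) + 1L  # strict interior maxima
  if (!length(is_max)) return(empty)
  ord <- is_max[order(td[is_max], decreasing = TRUE)]
  main <- ord[1]
  sec <- NA_integer_
  for (cand in ord[-1]) {
    if (abs(log10(dat$omega[cand] / dat$omega[main])) >= min_separation_decades) {
      sec <- cand
      break
    }
  }
  structure(list(
    t_peak = 1 / dat$omega[main],
    tan_delta_max = td[main],
    t_peak_secondary = if (is.na(sec)) NA_real_ else 1 / dat$omega[sec],
    tan_delta_secondary = if (is.na(sec)) NA_real_ else td[sec],
    interior = TRUE
  ), class = "characteristic_times")
}

smooth_k <- function(x, k) {
  if (k <= 1 || length(x) < k) return(x)
  if (k %% 2 == 0) k <- k + 1
  h <- (k - 1) %/% 2
  n <- length(x)
  out <- numeric(n)
  cs <- cumsum(c(0, x))
  for (i in seq_len(n)) {
    j <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + j + 1L] - cs[i - j]) / (2L * j + 1L)
  }
  out
}

#' Relaxation-minimum time of the loss tangent
#'
#' Models `tan delta` as a function of lag time `tau = 1/omega` beyond the
#' dominant peak with the offset + exponential + linear form
#' `c0 + c1 exp(-tau/c2) + c3 tau`, and reports the lag time at which the
#' fitted curve attains its minimum within the data range. If the fit fails
#' to converge, the smoothed empirical argmin is used and flagged; a boundary
#' argmin (monotone decay) is likewise flagged.
#'
#' @param spectrum A `stiffness_spectrum`.
#' @param t_peak Lower lag-time limit (s); default: the dominant peak time
#'   from [characteristic_peak_times()], or the shortest in-band lag when no
#'   interior peak exists.
#' @return List of class `"characteristic_times"` with `t_min`,
#'   `tan_delta_min`, `boundary` (TRUE if the minimum sits at the edge of the
#'   data range) and `fit_converged`.
#' @export
relaxation_minimum_time <- function(spectrum, t_peak = NULL) {
  dat <- spectrum[spectrum$trusted & !is.na(spectrum$tan_delta), ]
  if (is.null(t_peak)) {
    pk <- characteristic_peak_times(spectrum)
    t_peak <- if (isTRUE(pk$interior)) pk$t_peak else min(1 / dat$omega)
  }
  dd <- dat[1 / dat$omega > t_peak, ]
  dd <- dd[order(1 / dd$omega), ]
  tau <- 1 / dd$omega
  y <- dd$tan_delta
  fail <- structure(list(t_min = NA_real_, tan_delta_min = NA_real_,
                         boundary = TRUE, fit_converged = FALSE),
                    class = "characteristic_times")
  if (length(tau) < 6L) return(fail)
  # locate the valley empirically, then fit the offset+exponential+linear
  # form within half a decade either side (the global tail shape of a
  # structured spectrum is not exponential, so a wide fit biases the argmin)
  ys <- smooth_k(y, 5)
  tau_e <- tau[which.min(ys)]
  win <- tau >= tau_e / 10^0.5 & tau <= tau_e * 10^0.5
  tw <- tau[win]; yw <- y[win]
  empirical <- structure(list(t_min = tau_e, tan_delta_min = min(ys),
                              boundary = which.min(ys) %in% c(1L, length(tau)),
                              fit_converged = FALSE),
                         class = "characteristic_times")
  if (length(tw) < 6L) return(empirical)
  c2_0 <- exp(mean(log(range(tw))))
  fit <- try(minpack.lm::nlsLM(
    yw ~ c0 + c1 * exp(-tw / c2) + c3 * tw,
    start = list(c0 = min(yw), c1 = max(yw) - min(yw), c2 = c2_0, c3 = 0),
    lower = c(-Inf, 0, min(tw) / 10, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(empirical)
  tau_fine <- exp(seq(log(min(tw)), log(max(tw)), length.out = 2000))
  pred <- predict(fit, newdata = list(tw = tau_fine))
  i <- which.min(pred)
  boundary <- (i == length(tau_fine) && max(tw) == max(tau)) ||
    (i == 1L && min(tw) == min(tau))
  structure(list(t_min = tau_fine[i], tan_delta_min = pred[i],
                 boundary = boundary, fit_converged = TRUE),
            class = "characteristic_times")
}

#' @export
print.characteristic_times <- function(x, ...) {
  cat("<characteristic_times>",
      if (!is.null(x$t_peak)) sprintf("t_peak = %.4g s (tan delta %.3g)", x$t_peak, x$tan_delta_max),
      if (!is.null(x$t_peak_secondary) && !is.na(x$t_peak_secondary))
        sprintf("secondary = %.4g s", x$t_peak_secondary),
      if (!is.null(x$t_min)) sprintf("t_min = %.4g s (tan delta %.3g)", x$t_min, x$tan_delta_min),
      "\n")
  invisible(x)
}

#' Aggregate spectra across a cohort
#'
#' Per-frequency median (or mean) of `kp`, `kpp` and `tan_delta` across
#' chromosomes with percentile-bootstrap 95% confidence bands, resampling
#' chromosomes (not frequencies). Spectra on different grids are interpolated
#' in log-log space onto the first spectrum's grid.
#'
#' @param spectra List of `stiffness_spectrum` objects.
#' @param B Bootstrap resamples (default 10000).
#' @param seed Integer seed for the bootstrap.
#' @param center `"median"` (default) or `"mean"`.
#' @return A tibble of class `"cohort_spectrum"`: `omega`, then
#'   `{kp,kpp,tan_delta}_{med,lo,hi}` columns and `n`.
#' @export
aggregate_cohort <- function(spectra, B = 10000, seed = 1,
                             center = c("median", "mean")) {
  center <- match.arg(center)
  cfun <- if (center == "median") median else mean
  stopifnot(length(spectra) >= 1L)
  w <- spectra[[1]]$omega
  mats <- purrr::map(c(kp = "kp", kpp = "kpp", tan_delta = "tan_delta"),
    function(col) {
      vapply(spectra, function(sp) {
        if (length(sp$omega) == length(w) && all(sp$omega == w)) return(sp[[col]])
        ok <- is.finite(sp[[col]]) & sp[[col]] != 0
        approx(log(sp$omega[ok]), log(abs(sp[[col]][ok])), xout = log(w),
               rule = 2)$y |> exp()
      }, numeric(length(w)))
    })
  n <- length(spectra)
  if (n < 3L) warn("fewer than 3 spectra: confidence bands suppressed.")
  summ <- function(M) {
    med <- apply(M, 1, cfun, na.rm = TRUE)
    if (n < 3L) return(tibble::tibble(med = med, lo = NA_real_, hi = NA_real_))
    qs <- with_seed(seed, {
      draws <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
      boot <- apply(draws, 1, function(ix) apply(M[, ix, drop = FALSE], 1, cfun, na.rm = TRUE))
      apply(boot, 1, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    })
    tibble::tibble(med = med, lo = qs[1, ], hi = qs[2, ])
  }
  parts <- purrr::imap(mats, function(M, nm) {
    s <- summ(M)
    names(s) <- paste0(nm, c("_med", "_lo", "_hi"))
    s
  })
  out <- dplyr::bind_cols(tibble::tibble(omega = w), parts$kp, parts$kpp,
                          parts$tan_delta)
  out$n <- n
  attr(out, "center") <- center
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  class(out) <- c("cohort_spectrum", class(tibble::tibble()))
  out
}
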