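#' Burgers model parameters
#'
#' The four-element Burgers model: a Maxwell arm (spring `kappa2`, dashpot
#' `eta2`) in series with a Kelvin--Voigt element (spring `kappa1` in parallel
#' with dashpot `eta1`). Derived characteristic times are
#' `tau1 = eta1/kappa1`, `tau2 = eta2/kappa1`, `tau3 = eta2/kappa2` and
#' `E1 = tau1 + tau2 + tau3` (s).
#'
#' Infinite-element sentinels let one parameterisation cover the nested
#' models: `kappa1 = Inf` freezes the Kelvin--Voigt element (pure Maxwell);
#' `eta1 = 0` reduces it to a bare spring; `eta2 = Inf` freezes the Maxwell
#' dashpot (no long-time flow). `eta1 > 0` with `kappa1 = Inf` is rejected as
#' sentinel misuse.
#'
#' @param kappa1,kappa2 Elastic elements in pN/nm (`kappa1` may be `Inf`).
#' @param eta1,eta2 Viscous elements in pN s/nm (`eta1 >= 0`; `eta2` may be
#'   `Inf`).
#' @return A list of class `"burgers_params"` with the four elements plus
#'   `tau1`, `tau2`, `tau3`, `E1`.
#' @export
#' @examples
#' burgers_params(kappa1 = 0.05, kappa2 = 0.2, eta1 = 5e-4, eta2 = 0.075)
burgers_params <- function(kappa1, kappa2, eta1, eta2) {
  if (!is.finite(kappa2) || kappa2 <= 0) {
    abort("`kappa2` must be finite and positive.", class = "chromorheo_param_error")
  }
  if (kappa1 <= 0) abort("`kappa1` must be positive (Inf allowed).",
                         class = "chromorheo_param_error")
  if (eta1 < 0) abort("`eta1` must be >= 0.", class = "chromorheo_param_error")
  if (eta2 <= 0) abort("`eta2` must be positive (Inf allowed).",
                       class = "chromorheo_param_error")
  if (is.infinite(kappa1) && eta1 > 0) {
    abort("sentinel misuse: `eta1` > 0 with `kappa1` = Inf (a dashpot across a rigid spring has no state).",
          class = "chromorheo_param_error")
  }
  tau1 <- if (is.infinite(kappa1)) 0 else eta1 / kappa1
  tau2 <- if (is.infinite(kappa1)) 0 else eta2 / kappa1
  tau3 <- eta2 / kappa2
  structure(list(kappa1 = kappa1, kappa2 = kappa2, eta1 = eta1, eta2 = eta2,
                 tau1 = tau1, tau2 = tau2, tau3 = tau3,
                 E1 = tau1 + tau2 + tau3),
            class = "burgers_params")
}

#' @export
print.burgers_params <- function(x, ...) {
  cat(sprintf("<burgers_params> kappa1=%g kappa2=%g pN/nm, eta1=%g eta2=%g pN.s/nm | tau1=%g tau2=%g tau3=%g s\n",
              x$kappa1, x$kappa2, x$eta1, x$eta2, x$tau1, x$tau2, x$tau3))
  invisible(x)
}

#' Trap protocol for the dumbbell experiment
#'
#' Defaults reproduce the dwell protocol: trap stiffness 0.5 pN/nm, one trap
#' displaced 1 um at 100 um/s, then held for 120 s.
#'
#' @param kappa_OT Trap stiffness in pN/nm (each trap; `Inf` = rigid-trap
#'   idealisation for pure-material tests).
#' @param ramp_speed Trap displacement speed in um/s.
#' @param ramp_distance Commanded trap displacement in um.
#' @param dwell_s Hold duration in s.
#' @param baseline_s Pre-ramp baseline duration in s.
#' @param initial_separation Trap separation at protocol start in um; the
#'   tether is engaged at its natural length there, so `L0 =
#'   initial_separation`.
#' @param stop_force Optional force threshold in pN: the ramp stops when the
#'   chromosome force first reaches it (used by slow-loading protocols that
#'   displace "until a force readout" rather than a fixed distance).
#' @return A list of class `"trap_protocol"`.
#' @export
trap_protocol <- function(kappa_OT = 0.5, ramp_speed = 100, ramp_distance = 1,
                          dwell_s = 120, baseline_s = 5,
                          initial_separation = 3, stop_force = NULL) {
  vals <- c(kappa_OT, ramp_speed, ramp_distance, dwell_s, baseline_s,
            initial_separation)
  if (any(vals <= 0)) abort("all protocol values must be positive.",
                            class = "chromorheo_param_error")
  structure(list(kappa_OT = kappa_OT, ramp_speed = ramp_speed,
                 ramp_distance = ramp_distance, dwell_s = dwell_s,
                 baseline_s = baseline_s,
                 initial_separation = initial_separation,
                 stop_force = stop_force),
            class = "trap_protocol")
}

#' Sampling specification for simulated records
#'
#' Real acquisitions are uniform at up to 2.5 MHz; a 120 s dwell at that rate
#' (3e8 samples) is not a practical in-memory object, so three modes are
#' offered. `"uniform"` samples at `rate_Hz`. `"log"` places
#' `points_per_decade` log-spaced samples between `t_min` and the end of the
#' record (times measured from ramp start). `"hybrid"` (default) is uniform at
#' `1/dt_uniform` Hz through the ramp and early dwell (up to `t_uniform`),
#' then log-spaced: this resolves the fast relaxation tail that pure
#' log-spacing misses while keeping records desk-sized.
#'
#' @param mode `"uniform"`, `"log"` or `"hybrid"`.
#' @param rate_Hz Acquisition rate for uniform mode.
#' @param t_min First sample time (s after ramp start) for log mode.
#' @param points_per_decade Log-grid density (log and hybrid modes).
#' @param dt_uniform,t_uniform Uniform-segment step and extent (s) for hybrid
#'   mode.
#' @param baseline_rate_Hz Sampling rate during the pre-ramp baseline.
#' @return A list of class `"sampling_spec"`.
#' @export
sampling_spec <- function(mode = c("hybrid", "uniform", "log"),
                          rate_Hz = 1e4, t_min = 1e-6,
                          points_per_decade = 200,
                          dt_uniform = 1e-6, t_uniform = 0.05,
                          baseline_rate_Hz = 100) {
  mode <- match.arg(mode)
  structure(list(mode = mode, rate_Hz = rate_Hz, t_min = t_min,
                 points_per_decade = points_per_decade,
                 dt_uniform = dt_uniform, t_uniform = t_uniform,
                 baseline_rate_Hz = baseline_rate_Hz),
            class = "sampling_spec")
}

#' Measurement-noise specification
#'
#' Additive white Gaussian noise on the two force channels (independent
#' draws); extension is a derived quantity and inherits force noise through
#' the trap relation. Brownian bead dynamics are out of scope.
#'
#' `force_sd` is the per-sample SD of the underlying acquisition at
#' `acquisition_rate_Hz`. Because non-uniform simulated grids stand in for a
#' uniform high-rate record reduced by anti-alias block averaging (see
#' [log_decimate()]), each emitted sample representing a bin of width
#' `w` receives SD `force_sd / sqrt(max(1, rate * w))` — statistically the
#' bin mean of the full-rate record. Set `acquisition_rate_Hz = Inf` to apply
#' the raw SD to every sample regardless of spacing.
#'
#' @param force_sd Per-sample noise SD in pN at the acquisition rate (>= 0).
#' @param seed Integer seed; all randomness in a simulation flows from it.
#' @param acquisition_rate_Hz Underlying uniform acquisition rate emulated by
#'   the sample grid (default 2.5 MHz, the instrument's high-frequency mode).
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(force_sd = 0, seed = NULL,
                       acquisition_rate_Hz = 2.5e6) {
  if (force_sd < 0) abort("`force_sd` must be >= 0.", class = "chromorheo_param_error")
  structure(list(force_sd = force_sd, seed = seed,
                 acquisition_rate_Hz = acquisition_rate_Hz),
            class = "noise_spec")
}

# sample times measured from ramp start, covering ramp + dwell, on (0, T]
active_time_grid <- function(sampling, t_ramp, t_total) {
  s <- switch(sampling$mode,
    uniform = seq(1 / sampling$rate_Hz, t_total, by = 1 / sampling$rate_Hz),
    log = 10^seq(log10(sampling$t_min), log10(t_total),
                 length.out = max(2, ceiling(sampling$points_per_decade *
                                               log10(t_total / sampling$t_min)))),
    hybrid = {
      tu <- min(sampling$t_uniform, t_total)
      u <- seq(sampling$dt_uniform, tu, by = sampling$dt_uniform)
      if (tu < t_total) {
        lg <- 10^seq(log10(tu * (1 + 1e-9)), log10(t_total),
                     length.out = max(2, ceiling(sampling$points_per_decade *
                                                   log10(t_total / tu))))
        c(u, lg)
      } else u
    }
  )
  s <- sort(unique(c(s[s > 0 & s <= t_total], t_ramp, t_total)))
  # collapse floating-point near-duplicates (e.g. ramp end landing on a
  # uniform grid point)
  keep <- c(TRUE, diff(s) > 1e-12 * t_total)
  s[keep]
}

# exact response of the Burgers tether + two trap springs to an affine drive.
# state-space (lambda in nm): F = (Delta - ld - lkv)/C, C = 1/kappa2 + 2/kappa_OT
#   d ld /dt = F/eta2
#   d lkv/dt = (F - kappa1*lkv)/eta1
# sentinels reduce the state dimension; within each protocol phase the drive
# Delta(s) = d0 + d1*s is affine so the solution is a sum of exponentials and
# is evaluated in closed form (no step-size error).
burgers_dumbbell_model <- function(params, kappa_OT) {
  C <- 1 / params$kappa2 + ifelse(is.infinite(kappa_OT), 0, 2 / kappa_OT)
  spring_kv <- params$eta1 == 0 && is.finite(params$kappa1)
  rigid_kv <- is.infinite(params$kappa1) || spring_kv
  Ceff <- C + if (spring_kv) 1 / params$kappa1 else 0
  if (is.infinite(params$eta2) && rigid_kv) {
    type <- "spring"
  } else if (rigid_kv) {
    type <- "maxwell"
  } else if (is.infinite(params$eta2)) {
    type <- "kv"
  } else {
    type <- "full"
  }
  list(type = type, C = C, Ceff = Ceff, params = params)
}

# advance one phase: x0 state at s=0, Delta(s) = d0 + d1 s, times s (sorted,
# may be empty); returns list(F = at times, x_end = state at s_end)
phase_response <- function(model, x0, d0, d1, s, s_end) {
  p <- model$params
  s_all <- c(s, s_end)
  res <- switch(model$type,
    spring = {
      FF <- (d0 + d1 * s_all) / model$Ceff
      list(F = FF, x = matrix(0, 0, length(s_all)))
    },
    maxwell = {
      # d ld/dt = (Delta - ld) / (Ceff * eta2)
      pr <- 1 / (model$Ceff * p$eta2)
      beta <- d1
      alpha <- d0 - beta / pr
      x <- alpha + beta * s_all + (x0[1] - alpha) * exp(-pr * s_all)
      FF <- (d0 + d1 * s_all - x) / model$Ceff
      list(F = FF, x = matrix(x, 1))
    },
    kv = {
      # d lkv/dt = Delta/(Ceff eta1) - lkv (1/(Ceff eta1) + kappa1/eta1)
      q <- 1 / (model$Ceff * p$eta1)
      pr <- q + p$kappa1 / p$eta1
      beta <- d1 * q / pr
      alpha <- (d0 * q - beta) / pr
      x <- alpha + beta * s_all + (x0[1] - alpha) * exp(-pr * s_all)
      FF <- (d0 + d1 * s_all - x) / model$Ceff
      list(F = FF, x = matrix(x, 1))
    },
    full = {
      a <- 1 / (model$C * p$eta2)
      b <- 1 / (model$C * p$eta1)
      k <- p$kappa1 / p$eta1
      A <- matrix(c(-a, -b, -a, -(b + k)), 2, 2)
      evec <- c(a, b)
      ev <- eigen(A)
      V <- ev$vectors; L <- ev$values; Vi <- solve(V)
      beta <- -solve(A, d1 * evec)
      alpha <- solve(A, beta - d0 * evec)
      w0 <- as.vector(Vi %*% (x0 - alpha))
      EL <- rbind(exp(L[1] * s_all), exp(L[2] * s_all))
      x <- V %*% (w0 * EL) + rbind(alpha[1] + beta[1] * s_all,
                                   alpha[2] + beta[2] * s_all)
      FF <- (d0 + d1 * s_all - colSums(x)) / model$C
      list(F = Re(FF), x = Re(x))
    }
  )
  n <- length(s)
  list(F = res$F[seq_len(n)],
       x_end = if (nrow(res$x)) res$x[, n + 1L] else numeric())
}

#' Simulate a dual-trap dumbbell stretch/dwell experiment
#'
#' Integrates the Burgers tether in series with the two optical-trap springs
#' through baseline, ramp and dwell, using the exact per-phase exponential
#' solution of the linear state space (the system is linear time-invariant
#' within each phase, so there is no step-size error). Emits `f1 = +F`,
#' `f2 = -F` plus optional Gaussian channel noise. During the dwell the force
#' relaxes while the tether keeps extending, satisfying
#' `lambda(t) + 2 F(t)/kappa_OT = Delta_end` exactly.
#'
#' @param params [burgers_params()].
#' @param protocol [trap_protocol()].
#' @param sampling [sampling_spec()].
#' @param noise [noise_spec()].
#' @param id,condition Metadata passthrough.
#' @return A [tether_trace()] whose metadata carry `kappa_OT` and `L0`
#'   (= initial separation), with an attribute `truth` holding the generating
#'   parameters and the noise-free force/extension series.
#' @export
#' @examples
#' tr <- simulate_dumbbell(
#'   burgers_params(0.05, 0.2, 5e-4, 0.075),
#'   trap_protocol(dwell_s = 5),
#'   sampling_spec("log", t_min = 1e-4, points_per_decade = 50),
#'   noise_spec(0)
#' )
simulate_dumbbell <- function(params, protocol = trap_protocol(),
                              sampling = sampling_spec(),
                              noise = noise_spec(),
                              id = "sim", condition = "WT") {
  model <- burgers_dumbbell_model(params, protocol$kappa_OT)
  speed_nm <- protocol$ramp_speed * 1000       # nm/s
  dist_nm <- protocol$ramp_distance * 1000     # nm
  t_ramp <- dist_nm / speed_nm
  if (!is.null(protocol$stop_force)) {
    t_ramp <- ramp_stop_time(model, speed_nm, protocol$stop_force, t_ramp)
    dist_nm <- speed_nm * t_ramp
  }
  t_total <- t_ramp + protocol$dwell_s
  s <- active_time_grid(sampling, t_ramp, t_total)

  x0 <- numeric(if (model$type == "full") 2 else if (model$type == "spring") 0 else 1)
  sr <- s[s <= t_ramp]
  sd_ <- s[s > t_ramp]
  ramp <- phase_response(model, x0, 0, speed_nm, sr, t_ramp)
  dwell <- phase_response(model, ramp$x_end, dist_nm, 0, sd_ - t_ramp,
                          max(c(sd_ - t_ramp, 0)))
  FF <- c(ramp$F, dwell$F)
  Delta <- pmin(s * speed_nm, dist_nm)
  lam <- Delta - if (is.infinite(protocol$kappa_OT)) 0 else 2 * FF / protocol$kappa_OT

  # assemble full trace: baseline then active protocol
  tb <- seq(0, protocol$baseline_s,
            by = 1 / sampling$baseline_rate_Hz)
  tb <- tb[tb < protocol$baseline_s]
  t_all <- c(tb, protocol$baseline_s + s)
  F_all <- c(rep(0, length(tb)), FF)
  phase <- c(rep("baseline", length(tb)),
             ifelse(s <= t_ramp, "ramp", "dwell"))
  trap1 <- rep(0, length(t_all))
  trap2 <- protocol$initial_separation +
    c(rep(0, length(tb)), Delta) / 1000
  f1 <- F_all
  f2 <- -F_all
  if (noise$force_sd > 0) {
    rate <- noise$acquisition_rate_Hz %||% Inf
    sd_k <- if (is.finite(rate)) {
      # each sample stands for a bin of the full-rate record; its noise is
      # the bin-mean noise
      width <- local({
        n <- length(t_all)
        d <- diff(t_all)
        c(d[1], (d[-1] + d[-(n - 1)]) / 2, d[n - 1])
      })
      noise$force_sd / sqrt(pmax(1, rate * width))
    } else {
      rep(noise$force_sd, length(t_all))
    }
    noisy <- with_seed(noise$seed, {
      list(n1 = rnorm(length(t_all), 0, sd_k),
           n2 = rnorm(length(t_all), 0, sd_k))
    })
    f1 <- f1 + noisy$n1
    f2 <- f2 + noisy$n2
  }
  meta <- chromosome_meta(id = id, condition = condition,
                          kappa_OT = protocol$kappa_OT,
                          L0 = protocol$initial_separation,
                          length_um = protocol$initial_separation)
  tr <- tether_trace(t_all, f1, f2, trap1, trap2, phase = phase, meta = meta,
                     sampling = if (sampling$mode == "uniform") sampling$rate_Hz else "nonuniform",
                     provenance = sprintf("simulate_dumbbell(%s sampling, noise_sd=%g)",
                                          sampling$mode, noise$force_sd))
  attr(tr, "baseline_sd") <- c(f1 = noise$force_sd, f2 = noise$force_sd)
  attr(tr, "truth") <- list(params = params, protocol = protocol,
                            t_ramp = t_ramp,
                            t_active = s, F = FF, lam = lam)
  tr
}

# force-triggered ramp stop: first s with F(s) >= stop_force (exact bisection
# on the closed-form ramp response)
ramp_stop_time <- function(model, speed_nm, stop_force, t_max) {
  x0 <- numeric(if (model$type == "full") 2 else if (model$type == "spring") 0 else 1)
  Fat <- function(s) phase_response(model, x0, 0, speed_nm, s, s)$F
  if (Fat(t_max) < stop_force) return(t_max)
  stats::uniroot(function(s) Fat(s) - stop_force, c(1e-12, t_max),
                 tol = 1e-12)$root
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Worm-like-chain force for a given extension
#'
#' Interpolation formula
#' `F = (kT/Lp) * (1/(4 (1 - z)^2) - 1/4 + z)` with `z = lam/Lc`.
#'
#' @param lam Extension in nm.
#' @param Lc Contour length in nm.
#' @param Lp Persistence length in nm.
#' @param kT Thermal energy in pN nm.
#' @return Force in pN.
#' @export
wlc_force <- function(lam, Lc, Lp = 50, kT = 4.1) {
  z <- lam / Lc
  if (any(z >= 1)) abort("extension must be below the contour length.",
                         class = "chromorheo_domain_error")
  (kT / Lp) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

#' Noise-free worm-like-chain force-extension ramp
#'
#' Generates a synthetic slow-ramp trace whose force-extension curve follows
#' the worm-like-chain interpolation formula, sampled uniformly over the
#' requested force range (the extension at each force is found by inverting
#' the monotone formula). Emitted with rigid traps so the bead separation
#' equals the tether length.
#'
#' @param Lc Contour length in um.
#' @param Lp Persistence length in nm.
#' @param kT Thermal energy in pN nm.
#' @param f_range Force range in pN (both ends > 0).
#' @param n Number of samples.
#' @param L0 Natural length (um) at which the ramp starts.
#' @param ramp_speed Nominal trap speed in um/s used to assign time stamps.
#' @return A [tether_trace()] (rigid-trap, `kappa_OT = Inf`).
#' @export
wlc_force_extension <- function(Lc, Lp = 50, kT = 4.1, f_range = c(0.5, 400),
                                n = 2000, L0 = 3, ramp_speed = 0.02) {
  if (any(f_range <= 0)) abort("forces must be positive.",
                               class = "chromorheo_domain_error")
  Lc_nm <- Lc * 1000
  # invert the endpoints only, then sample uniformly in extension as a
  # constant-speed trap ramp would
  zr <- vapply(f_range, function(f) {
    stats::uniroot(function(z) wlc_force(z * Lc_nm, Lc_nm, Lp, kT) - f,
                   c(1e-12, 1 - 1e-10), tol = 1e-14)$root
  }, numeric(1))
  lam <- seq(zr[1], zr[2], length.out = n) * Lc_nm
  FF <- wlc_force(lam, Lc_nm, Lp, kT)
  elastic_curve_trace(lam, FF, L0, ramp_speed,
                      id = "wlc", note = sprintf("wlc Lc=%g um Lp=%g nm", Lc, Lp))
}

#' Exact power-law stiffening ramp
#'
#' Emits a noise-free ramp whose differential stiffness obeys
#' `dF/dlambda = a F^gamma` exactly: `lambda(F) = (F^(1-gamma) -
#' F0^(1-gamma)) / (a (1-gamma))` for `gamma != 1` and `log(F/F0)/a` for
#' `gamma = 1`. Used as the analytic oracle for the stiffening-exponent fit.
#'
#' @param a Stiffness prefactor (pN^(1-gamma)/nm), > 0.
#' @param gamma Stiffening exponent.
#' @param F0,F1 Force range in pN (`F0 > 0` required when `gamma >= 1`).
#' @param n Number of samples.
#' @param L0 Natural length in um.
#' @param ramp_speed Nominal speed (um/s) used for time stamps.
#' @return A [tether_trace()] (rigid-trap).
#' @export
powerlaw_ramp <- function(a, gamma, F0 = 1, F1 = 400, n = 2000, L0 = 3,
                          ramp_speed = 0.2) {
  if (a <= 0) abort("`a` must be positive.", class = "chromorheo_domain_error")
  if (F0 <= 0 && gamma >= 1) {
    abort("`F0` must be positive when `gamma` >= 1.",
          class = "chromorheo_domain_error")
  }
  lam_of <- function(FF) {
    if (abs(gamma - 1) < .Machine$double.eps^0.5) log(FF / F0) / a
    else (FF^(1 - gamma) - F0^(1 - gamma)) / (a * (1 - gamma))
  }
  F_of <- function(lam) {
    if (abs(gamma - 1) < .Machine$double.eps^0.5) F0 * exp(a * lam)
    else (F0^(1 - gamma) + a * (1 - gamma) * lam)^(1 / (1 - gamma))
  }
  # sample uniformly in extension (constant trap speed), exactly on the curve
  lam <- seq(0, lam_of(F1), length.out = n)
  FF <- F_of(lam)
  elastic_curve_trace(lam, FF, L0, ramp_speed, id = "powerlaw",
                      note = sprintf("powerlaw a=%g gamma=%g", a, gamma))
}

# wrap an exact (lambda, F) elastic curve as a rigid-trap ramp trace with a
# short zero-force baseline ahead of it
elastic_curve_trace <- function(lam, FF, L0, ramp_speed, id, note) {
  speed_nm <- ramp_speed * 1000
  dstep <- pmax(diff(lam), 1e-9) / speed_nm          # s per sampling step
  db <- max(stats::median(dstep), 1e-4)
  nb <- 5L
  t <- c(seq(0, by = db, length.out = nb),
         nb * db + cumsum(c(0, dstep)))
  sep <- L0 + c(rep(0, nb), lam) / 1000
  tether_trace(
    t = t,
    f1 = c(rep(0, nb), FF),
    f2 = -c(rep(0, nb), FF),
    trap1 = rep(0, length(t)),
    trap2 = sep,
    phase = c(rep("baseline", nb), rep("ramp", length(lam))),
    meta = chromosome_meta(id = id, kappa_OT = Inf, L0 = L0, length_um = L0),
    sampling = "nonuniform",
    provenance = note
  )
}
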