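grid_default <- frequency_grid()

test_that("one-sided transform is exact on steps and ramps under any sampling", {
  w <- as.numeric(frequency_grid(1e-2, 1e4, 8))
  # constant g = 5: P = 5 i w exactly (all increments vanish)
  t <- sort(c(10^seq(-5, 2, length.out = 300), runif(50, 1e-5, 100)))
  P <- one_sided_fourier(transform_input(t, rep(5, length(t)), g0 = 5,
                                         gdot_inf = 0), w)
  expect_lt(max(Mod(P - 5i * w) / Mod(5i * w)), 1e-12)

  # linear ramp g = c t with terminal gradient c: P = c exactly
  cc <- 3.7
  P2 <- one_sided_fourier(transform_input(t, cc * t, g0 = 0, gdot_inf = cc), w)
  expect_lt(max(Mod(P2 - cc) / cc), 1e-9)
})

test_that("one-sided transform matches the closed form for exponential decay", {
  tau <- 0.1
  t <- 10^seq(-6, 2, length.out = 3000)
  inp <- transform_input(t, exp(-t / tau), g0 = 1, gdot_inf = 0)
  w <- as.numeric(frequency_grid(1e-1, 1e4, 16))
  P <- one_sided_fourier(inp, w)
  ghat_true <- tau / (1 + 1i * w * tau)
  expect_lt(max(Mod(P / (-w^2) - ghat_true) / Mod(ghat_true)), 0.01)
})

test_that("transform agrees with a dense Riemann-sum oracle mid-band", {
  tau <- 0.05
  t <- seq(5e-5, 20, by = 5e-5)
  g <- exp(-t / tau) * (1 + 0.3 * sin(t / 0.3))
  w <- as.numeric(frequency_grid(1, 1e3, 8))
  P <- one_sided_fourier(transform_input(t, g, g0 = g[1], gdot_inf = 0), w)
  P_ref <- riemann_P(t, g, w)
  expect_lt(max(Mod(P - P_ref) / Mod(P_ref)), 0.02)
})

test_that("log decimation preserves endpoints and the mid-band spectrum", {
  t <- seq(1e-4, 50, by = 1e-4)
  tau <- 0.2
  g <- 80 * exp(-t / tau)
  dec <- log_decimate(t, g, points_per_decade = 150)
  expect_lt(nrow(dec), length(t) / 50)
  expect_equal(dec$t[1], t[1])
  expect_equal(dec$g[nrow(dec)], g[length(g)])

  # constant signal decimates to a constant
  decc <- log_decimate(t, rep(4, length(t)), 100)
  expect_true(all(abs(decc$g - 4) < 1e-12))

  # transform after decimation matches the full-record transform mid-band
  w <- as.numeric(frequency_grid(1, 1e3, 8))
  Pf <- one_sided_fourier(transform_input(t, g, g0 = 80, gdot_inf = 0), w)
  Pd <- one_sided_fourier(transform_input(dec$t, dec$g, g0 = 80, gdot_inf = 0), w)
  expect_lt(max(Mod(Pd - Pf) / Mod(Pf)), 0.01)

  # passthrough warning when the record is already sparse
  expect_warning(log_decimate(10^seq(-3, 1, length.out = 50), rnorm(50), 100),
                 "passing the record through")
})

test_that("complex stiffness of proportional signals is purely elastic", {
  t <- 10^seq(-5, 2, length.out = 500)
  lam <- 300 * (1 - exp(-t / 0.2))
  sp <- complex_stiffness(
    transform_input(c(0, t), c(0, 0.8 * lam), g0 = 0),
    transform_input(c(0, t), c(0, lam), g0 = 0),
    frequency_grid(1e-1, 1e3, 8))
  tb <- sp$trusted
  expect_rel(sp$kp[tb], rep(0.8, sum(tb)), 1e-6)
  expect_lt(max(abs(sp$kpp[tb])), 1e-6)
  expect_lt(max(abs(sp$tan_delta[tb])), 1e-6)
})

test_that("Maxwell step-strain pair crosses tan delta = 1 at omega = 1/tau", {
  mp <- maxwell_pair()
  sp <- complex_stiffness(mp$F, mp$lam, frequency_grid(1e-2, 1e5, 16))
  # at omega = 1/tau = 10: kp = kpp = kappa/2
  i <- which.min(abs(sp$omega - 10))
  expect_equal(sp$omega[i], 10, tolerance = 1e-9)
  expect_equal(sp$kp[i], mp$kappa / 2, tolerance = 0.01 * mp$kappa)
  expect_equal(sp$kpp[i], mp$kappa / 2, tolerance = 0.01 * mp$kappa)
  expect_equal(sp$tan_delta[i], 1, tolerance = 0.02)
  # whole-band agreement with the closed form kappa * i w tau / (1 + i w tau);
  # the viscous component is checked where it is numerically resolvable
  # (tan delta above 1e-3)
  ks_true <- mp$kappa * 1i * sp$omega * mp$tau / (1 + 1i * sp$omega * mp$tau)
  tb <- sp$trusted
  expect_rel(sp$kp[tb], Re(ks_true)[tb], 0.03)
  tv <- tb & Im(ks_true) / Re(ks_true) > 1e-3
  expect_rel(sp$kpp[tv], Im(ks_true)[tv], 0.03)
  # loss tangent of a Maxwell fluid is 1/(w tau), monotone decreasing
  expect_rel(sp$tan_delta[tv], (1 / (sp$omega * mp$tau))[tv], 0.05)
  expect_true(all(diff(sp$tan_delta[tv]) < 0))
})

test_that("scaling force or extension scales the spectrum linearly", {
  mp <- maxwell_pair()
  g <- frequency_grid(1e-1, 1e3, 8)
  sp <- complex_stiffness(mp$F, mp$lam, g)
  Fx <- mp$F; Fx$g <- 3 * Fx$g; Fx$g0 <- 3 * Fx$g0
  spF <- complex_stiffness(Fx, mp$lam, g)
  expect_equal(spF$kp, 3 * sp$kp, tolerance = 1e-12)
  expect_equal(spF$kpp, 3 * sp$kpp, tolerance = 1e-12)
  expect_equal(spF$tan_delta, sp$tan_delta, tolerance = 1e-9)
  Lx <- mp$lam; Lx$g <- 2 * Lx$g; Lx$g0 <- 2 * Lx$g0
  spL <- complex_stiffness(mp$F, Lx, g)
  expect_equal(spL$kp, sp$kp / 2, tolerance = 1e-12)
})

test_that("tan delta times kp equals kpp wherever reported", {
  tr <- simulate_dumbbell(wt_params(), fast_protocol(), fast_sampling(),
                          noise_spec(0.5, seed = 2))
  sp <- microrheology(tr, grid = frequency_grid(1e-1, 1e4, 12))
  ok <- !is.na(sp$tan_delta)
  expect_equal(sp$tan_delta[ok] * sp$kp[ok], sp$kpp[ok], tolerance = 1e-12)
})

test_that("peak extraction finds the Burgers loss-tangent maximum", {
  p <- wt_params()
  sp <- burgers_spectrum(p, frequency_grid(1e-1, 1e4, 16))
  attr(sp, "band") <- range(sp$omega)
  pk <- characteristic_peak_times(sp, smooth_points = 1)
  # brute-force argmax of the closed form on a 10x finer grid, restricted to
  # the same interior
  fine <- burgers_spectrum(p, frequency_grid(1e-1, 1e4, 160))
  interior <- fine$omega >= sp$omega[2] &
    fine$omega <= sp$omega[nrow(sp) - 1]
  td <- fine$tan_delta
  # local interior maximum of tan delta (exclude the low-frequency fluid rise)
  i_max <- which(diff(sign(diff(td))) < 0) + 1L
  i_max <- i_max[interior[i_max]]
  expect_true(isTRUE(pk$interior))
  w_true <- fine$omega[i_max[which.max(td[i_max])]]
  step <- log10(sp$omega[2] / sp$omega[1])
  expect_lt(abs(log10(1 / pk$t_peak) - log10(w_true)), step * 1.01)

  # Maxwell: monotone tan delta, no interior peak
  spm <- burgers_spectrum(burgers_params(Inf, 0.2, 0, 0.05),
                          frequency_grid(1e-1, 1e3, 16))
  pkm <- characteristic_peak_times(spm, smooth_points = 1)
  expect_false(pkm$interior)
  expect_true(is.na(pkm$t_peak))
})

test_that("peak time is stable under multiplicative noise on tan delta", {
  p <- wt_params()
  sp <- burgers_spectrum(p, frequency_grid(1e-1, 1e4, 16))
  pk0 <- characteristic_peak_times(sp)
  step <- log10(sp$omega[2] / sp$omega[1])
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    spn <- sp
    spn$tan_delta <- spn$tan_delta * (1 + rnorm(nrow(spn), 0, 0.01))
    pk <- characteristic_peak_times(spn)
    isTRUE(pk$interior) &&
      abs(log10(pk$t_peak) - log10(pk0$t_peak)) <= step * 1.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("relaxation minimum matches the calculus oracle", {
  # synthetic tan delta(tau) = 0.2 + 0.5 exp(-tau/0.05) + 0.1 tau
  f <- function(tau) 0.2 + 0.5 * exp(-tau / 0.05) + 0.1 * tau
  tau_true <- optimize(f, c(1e-3, 10))$minimum
  omega <- sort(1 / 10^seq(-3, 1, length.out = 120))
  sp <- tibble::tibble(omega = omega, kp = 1, kpp = f(1 / omega),
                       tan_delta = f(1 / omega), trusted = TRUE)
  class(sp) <- c("stiffness_spectrum", class(tibble::tibble()))
  mn <- relaxation_minimum_time(sp, t_peak = 1e-3)
  expect_false(mn$boundary)
  expect_equal(mn$t_min, tau_true, tolerance = 0.05)

  # monotone decreasing tan delta(tau): boundary flag at the largest lag
  spm <- sp
  spm$tan_delta <- 0.1 + 1 / (1 / spm$omega + 0.3)
  mn2 <- relaxation_minimum_time(spm, t_peak = 1e-3)
  expect_true(mn2$boundary)
  expect_equal(mn2$t_min, max(1 / spm$omega), tolerance = 0.02)
})

test_that("Burgers relaxation minimum sits within a grid step of the closed form", {
  p <- wt_params()
  sp <- burgers_spectrum(p, frequency_grid(1e-2, 1e4, 16))
  mn <- relaxation_minimum_time(sp)
  fine <- burgers_spectrum(p, frequency_grid(1e-2, 1e4, 320))
  pk <- characteristic_peak_times(sp, smooth_points = 1)
  taus_fine <- 1 / fine$omega
  sel <- taus_fine > pk$t_peak
  t_true <- taus_fine[sel][which.min(fine$tan_delta[sel])]
  expect_lt(abs(log10(mn$t_min) - log10(t_true)),
            1.01 * log10(sp$omega[2] / sp$omega[1]))
})

test_that("cohort aggregation is deterministic with honest intervals", {
  p <- wt_params()
  sp <- burgers_spectrum(p, frequency_grid(1e-1, 1e3, 8))
  reps <- replicate(10, sp, simplify = FALSE)
  agg <- aggregate_cohort(reps, B = 200, seed = 4)
  expect_equal(agg$kp_med, sp$kp)
  expect_equal(agg$kp_lo, agg$kp_hi)  # identical spectra: zero-width CI
  agg2 <- aggregate_cohort(reps, B = 200, seed = 4)
  expect_identical(agg$tan_delta_lo, agg2$tan_delta_lo)
})

test_that("bootstrap bands cover the true median at the nominal rate", {
  p <- wt_params()
  base <- burgers_spectrum(p, frequency_grid(1, 10, 4))
  sigma <- 0.4
  probe <- 3  # check coverage at one frequency
  true_med <- base$kp[probe]  # lognormal perturbation: median unchanged
  covered <- vapply(1:200, function(s) {
    set.seed(s)
    sps <- lapply(1:12, function(i) {
      spi <- base
      fac <- exp(rnorm(1, 0, sigma))
      spi$kp <- spi$kp * fac
      spi$kpp <- spi$kpp * fac
      spi$tan_delta <- spi$kpp / spi$kp
      spi
    })
    agg <- aggregate_cohort(sps, B = 400, seed = s)
    agg$kp_lo[probe] <= true_med && true_med <= agg$kp_hi[probe]
  }, logical(1))
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 0.995)
})
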