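# shared fixtures, all generated in code

wt_params <- function() burgers_params(0.05, 0.2, 5e-4, 0.075)

# desk-sized sampling/protocol for tests that do not probe the full band
fast_sampling <- function() {
  sampling_spec("hybrid", dt_uniform = 2e-6, t_uniform = 0.02,
                points_per_decade = 100)
}
fast_protocol <- function(...) trap_protocol(dwell_s = 10, baseline_s = 1, ...)

# analytic Maxwell step-strain pair: F = F0 exp(-t/tau), lambda constant
maxwell_pair <- function(F0 = 100, lam0 = 500, tau = 0.1,
                         t_min = 1e-6, t_max = 120, n = 2500) {
  t <- 10^seq(log10(t_min), log10(t_max), length.out = n)
  list(F = transform_input(c(0, t), c(F0, F0 * exp(-t / tau)),
                           g0 = F0, gdot_inf = 0),
       lam = transform_input(c(0, t), rep(lam0, n + 1),
                             g0 = lam0, gdot_inf = 0),
       kappa = F0 / lam0, tau = tau)
}

# independent one-sided transform oracle: plain Riemann sum over a densely,
# uniformly sampled record (zero-order hold), returning -w^2 * ghat
riemann_P <- function(t, g, w) {
  dt <- t[2] - t[1]
  E <- exp(-1i * outer(w, t))
  # midpoint rule plus the leading cell [0, t1 - dt/2]
  ghat <- as.vector(E %*% g) * dt + g[1] * (t[1] - dt / 2)
  -w^2 * ghat
}

# build a minimal hand-made trace
toy_trace <- function(n = 10, f = 0, sep = 5, phase = "baseline",
                      meta = chromosome_meta()) {
  tether_trace(t = seq_len(n) - 1, f1 = rep(f, n), f2 = rep(-f, n),
               trap1 = rep(0, n), trap2 = rep(sep, n),
               phase = rep(phase, n), meta = meta)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
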