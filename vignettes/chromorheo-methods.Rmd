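---
title: "Methods: stretch-hold microrheology and Burgers fitting for single chromosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stretch-hold microrheology and Burgers fitting for single chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromorheo)
```

This vignette documents the models, numerical choices and known limitations
behind the package, at the level of detail a user needs to judge what a
result does and does not mean.

## The measurement model

A chromosome (or any tether) is held between two optically trapped beads.
Each trap is a Hookean spring of stiffness $\kappa_{OT}$ (default
0.5 pN/nm, a typical calibrated value for 3 μm beads): the force on a bead
is $F = -\kappa_{OT}\,x$ with $x$ the bead's displacement from the trap
centre. Under tension the two beads report forces of equal magnitude and
opposite sign; the chromosome force $F(t)$ is the average of the two
magnitudes, which halves uncorrelated sensor noise. The tether length is the
bead-handle separation

$$L(t) = \big(\mathrm{trap}_2 - |f_2|/\kappa_{OT}\big)
       - \big(\mathrm{trap}_1 + |f_1|/\kappa_{OT}\big),$$

and the deformation is $\lambda(t) = L(t) - L_0$ in nm, measured past the
natural length $L_0$: the separation at which stepping a trap first
produces sustained resistive force. Bead radii and linker offsets are
absorbed into $L_0$; no absolute-length claim is made. $L_0$ detection
defaults to a 3-baseline-SD threshold held for 50 consecutive samples —
the threshold sets sensitivity, the persistence window rejects noise spikes;
both are configurable because the trade-off depends on ramp speed and noise.

Canonical units throughout: s, pN, μm for positions, nm for $\lambda$,
pN/nm for stiffness, pN·s/nm for viscosity. Unit conversion happens only in
the readers (`trace_schema()`).

## Force-extension analysis

Slow ramps (0.02 μm/s scale) are summarised by the stretch modulus $S$, the
least-squares slope of $F$ against strain $(L-L_0)/L_0$ over a configurable
strain window (default strain ≤ 0.2, inside which the response of a
linearly elastic tether is genuinely linear).

Faster ramps stiffen. The differential stiffness $\kappa = dF/d\lambda$ is
computed by central differences on the (optionally smoothed) curve and
fitted against force as $\kappa = aF^{\gamma}$ by ordinary least squares of
$\log\kappa$ on $\log F$: the exponent spans decades of $\kappa$, and
log-space residuals weight them evenly, which is why log-log OLS is the
standard exponent estimator; a nonlinear least-squares alternative on the
linear scale is available (`method = "nls"`) for sensitivity checks. The
default fit domain is $F \in [10, 0.9\,F_{max}]$ pN: below ~10 pN the
gradient sits in its noise floor.

Smoothing uses a centered moving average with a window of 1/15 of the data
points, forced odd, with shrinking symmetric edge windows. Two caveats are
documented deliberately. First, the window is a fixed *fraction*, so on a
steep curve (e.g. a worm-like chain approaching its contour length) the
window spans enough curvature to bias the fitted exponent visibly
(≈ −0.04 at $\gamma = 1.5$ over 1–400 pN); at chromosome-like exponents
($\gamma \approx 0.9$) the bias is below $10^{-3}$. Noise-free synthetic
curves are therefore differentiated unsmoothed. Second, smoothing before a
model comparison correlates residuals; the linear/non-linear classifier
(below) fits raw data for exactly that reason.

`classify_response()` compares a straight line with the integrated
power-law curve (the closed-form $F(\lambda)$ whose stiffness is
$aF^\gamma$) via BIC: a response is `nonlinear` only when the power-law
model is favoured by ΔBIC > 10 *and* the exponent's 95% CI excludes zero.
Calibration on simulated linear springs with 1 pN noise gives a
false-positive rate well under 5%.

## The stretch-hold broadband conversion

The complex stiffness is $\kappa^*(\omega) = \hat F(\omega)/\hat\lambda(\omega)$.
For finite, non-uniformly sampled records the transforms are evaluated as

$$P(\omega) = i\omega\,g(t_0) + \dot g_\infty e^{-i\omega t_N}
 + \sum_{k=1}^{N} \frac{g_k - g_{k-1}}{t_k - t_{k-1}}
   \big(e^{-i\omega t_{k-1}} - e^{-i\omega t_k}\big)
 \;=\; -\omega^2 \hat g(\omega),$$

exact for the piecewise-linear interpolant extended by a step to $g(t_0)$
at $t=0^+$ and by the terminal gradient $\dot g_\infty$ beyond the last
sample. The ratio $P_F/P_\lambda$ cancels the $-\omega^2$ factors, which is
numerically safer at the grid extremes than normalising each transform. The
terminal gradient defaults to the least-squares slope over the last 10% of
the record (≈ 0 for fully relaxed records) and is configurable to zero.

**Analysis window.** By default the transform window opens at *ramp start*
(`window = "stretch_hold"`): force and deformation then rise continuously
from rest, there are no step terms, and the transform ratio is exact for
any linear viscoelastic tether under any loading history. The alternative
`window = "dwell"` treats the first dwell sample as a step from rest. That
convention is only accurate when the ramp is fast compared with *every*
material timescale: when internal relaxation proceeds during the ramp (as
it does whenever a characteristic time is comparable to the ~10 ms ramp),
the dwell-only ratio converges at high frequency to $F(0)/\lambda(0)$
rather than to the true instantaneous stiffness — with realistic parameters
a ≈ 60% error in the high-frequency plateau. The dwell window is therefore
provided for comparability, not as the default.

**Frequency grid and trusted band.** The default grid is 16 points per
decade over $10^{-2}$–$10^{5}$ rad/s, the range a 120 s record with
microsecond-resolved early sampling can cover. Points within half a decade
of the record-length limit $2\pi/t_N$ or the sampling limit
$\pi/\min\Delta t$ are flagged untrusted rather than dropped; values below
the record-length limit derive partly from the terminal-gradient
extrapolation and should be read accordingly.

**Decimation.** `log_decimate()` reduces uniform high-rate records by
per-bin averaging onto a log-time grid (default 200 points per decade);
bin averaging is the anti-alias filter, endpoints are preserved exactly,
and single-sample bins pass raw samples through.

**Characteristic times** use $\tau = 1/\omega$ (the reciprocal of the
angular frequency, not $2\pi/\omega$). The dominant loss-tangent peak is
the global interior maximum of lightly smoothed $\tan\delta$ versus
$\log\omega$; a secondary peak must be at least half a decade away. The
relaxation minimum is the argmin of an offset + exponential + linear fit,
$c_0 + c_1 e^{-\tau/c_2} + c_3\tau$, performed within half a decade either
side of the empirical minimum: the exponential form is a documented choice
(no canonical form exists), and fitting it locally avoids the bias a global
fit accrues from the non-exponential tail of structured spectra. A
non-convergent fit falls back to the smoothed empirical argmin, flagged.

## The dumbbell simulator

The tether is a Burgers network — Maxwell arm ($\kappa_2$, $\eta_2$) in
series with a Kelvin–Voigt element ($\kappa_1 \parallel \eta_1$) — in
series with both trap springs. With $\Delta(t)$ the commanded
trap-separation increase (nm) and internal strains $\lambda_d$ (Maxwell
dashpot) and $\lambda_{KV}$:

$$F = \frac{\Delta - \lambda_d - \lambda_{KV}}{1/\kappa_2 + 2/\kappa_{OT}},
\qquad \dot\lambda_d = F/\eta_2, \qquad
\dot\lambda_{KV} = (F - \kappa_1\lambda_{KV})/\eta_1.$$

Within each protocol phase the drive is affine, so the linear state space
is advanced by its exact closed-form solution (eigendecomposition of the
2×2 state matrix, or scalar exponentials in the sentinel-reduced cases):
there is no integration error at any step size, which is what makes the
simulator usable as an oracle. The identity
$\lambda(t) + 2F(t)/\kappa_{OT} = \Delta_{end}$ holds exactly during the
dwell. Sentinels cover the nested models: $\kappa_1 = \infty$ freezes the
Kelvin–Voigt element (pure Maxwell), $\eta_1 = 0$ reduces it to a bare
spring (folded into the series compliance), $\eta_2 = \infty$ removes
long-time flow; $\eta_1 > 0$ with $\kappa_1 = \infty$ is rejected.
$\kappa_{OT} = \infty$ gives the rigid-trap idealisation. A
`stop_force` option ends the ramp when the force first reaches a trigger
(slow-loading protocols displace "until a force readout" rather than a
fixed distance); the stop time is found by bisection on the closed-form
ramp response. A soft tether can plateau below the trigger (viscous flow
limits the sustainable force to roughly $\eta_2 \times$ speed); the ramp
then runs its full commanded distance.

**Sampling.** A real acquisition is uniform at up to 2.5 MHz; 120 s of it
(3×10⁸ samples) is not a tractable in-memory object, so the simulator
offers `uniform`, `log`, and the default `hybrid` sampling (uniform at
1 MHz through the ramp and the first 50 ms of dwell, then 200
points/decade log-spaced). The uniform segment matters: fast relaxation
continues for tens of ms after the ramp, and pure log-spacing
under-resolves it, corrupting the small viscous component at high
frequency. With hybrid sampling the full pipeline reproduces the
closed-form Burgers spectrum within ~3% on both components across all
seven decades of the default grid.

**Noise.** Additive white Gaussian noise on both force channels,
independent draws; extension is derived, so it inherits force noise through
the trap relation. `force_sd` is the per-sample SD at the underlying
acquisition rate (default 2.5 MHz), and each emitted sample representing a
time bin of width $w$ receives SD $\sigma/\sqrt{\max(1, R\,w)}$ — the
statistics of a block-averaged full-rate record, which is what the
non-uniform grids stand in for. Brownian bead dynamics, trap nonlinearity
and hydrodynamic coupling are out of scope: passing tests show the analysis
chain is correct for the modelled physics, not that instrument artefacts
are handled.

**Cohort generator.** `cohort_spec()` draws per-chromosome parameters
log-normally (log-SD 0.25) around per-condition centres chosen once so each
condition's closed-form loss tangent reproduces the features that condition
exhibits experimentally — wild-type: peak ≈ 2.7 at ≈ 10 ms, minimum
≈ 1.5 s; knock-down: peak ≈ 0.6 at ≈ 4 ms, minimum ≈ 0.2 s, with reduced
high-frequency stiffness and long-time viscosity; over-expression between
the two. Working back from those features fixes
$\kappa_2/\kappa_1 \approx (2\,\tan\delta_{peak})^2$, the Kelvin–Voigt
time from the peak frequency, and $\eta_2$ from
$\tau_{min} \approx \sqrt{\tau_1\tau_2}$; the wild-type centre is
$(\kappa_1, \kappa_2, \eta_1, \eta_2) = (0.05, 1.45, 2.7\times10^{-3}, 2.0)$
in pN/nm and pN·s/nm. Chromosome lengths are normal (3.5 ± 0.6 μm), and the
default channel noise is 0.5 pN — typical high-bandwidth force noise.
Within-chromosome protocol variability, attachment geometry, and
non-Burgers behaviour are not emulated.

## Burgers fitting

`fit_burgers()` minimises summed squared *relative* residuals of
$\kappa'$ and $\kappa''$ jointly (equal weight): the components span
decades, and absolute residuals would see only the high-frequency plateau.
Parameters are optimised in log space (positive by construction) within
±5 decades of heuristic initials read off the spectrum's asymptotes
($\kappa_2$ from the high-frequency $\kappa'$ plateau, $\eta_2$ from
low-frequency $\kappa''/\omega$ with a floor that keeps the Maxwell time
inside the band when the spectrum carries no flow information, $\kappa_1$
from the mid-band level, $\eta_1$ from the transition frequency), with 8
deterministic multi-starts.

Robustness to noise uses three layers, each needed in practice: (i) a
coherence pre-mask drops grid points whose $\kappa'$ is non-positive or
jumps > 50% from its running median — for a passive material $\kappa'$ is
positive and smooth in log-frequency, so such points are noise-dominated;
(ii) residuals are soft-clipped at 3 via $3\tanh(r/3)$ so surviving
noise-dominated points (typically the small viscous component at high
frequency, the most noise-sensitive quantity in this method) cannot capture
the fit; (iii) one reject-and-refit pass excludes points whose residual
exceeds 10× the MAD. Confidence intervals come from the local curvature in
log space (multiplicative intervals); flags mark non-identifiable
$\eta_1$, singular curvature, and CIs wider than a decade.

Both per-chromosome fitting and fitting of the cohort-median spectrum are
supported (`fit_burgers()` applies unchanged to an aggregated spectrum's
median columns assembled as a spectrum); per-chromosome fits feed the group
statistics.

"Relative κ" is reported under two readings — the relative change
$(\kappa_2-\kappa_1)/\kappa_1$ (default) and the plain ratio
$\kappa_2/\kappa_1$ — because the summary is not uniquely defined; both
columns are always emitted.

## Statistics

Group comparisons are Kruskal–Wallis (tie-corrected H, chi-square
approximation via `stats::kruskal.test`) with Dunn pairwise z tests and
Holm adjustment — Dunn + Holm is a documented choice where the original
procedure is unnamed. Significance threshold 0.05. Confidence bands for
cohort spectra and medians are percentile bootstrap (default B = 10,000,
seeded), resampling chromosomes, never frequencies: frequencies within a
spectrum are strongly dependent, chromosomes are the exchangeable unit.
Calibration holds at the asymptotic level (test group sizes of 30+; at very
small n the chi-square approximation is conservative, which is a property
of the test, not of this implementation).

## Problem sizes used in the tests

The shipped tests and the acceptance script run entirely on synthetic data
generated at call time: single records of ~10⁴–5×10⁴ samples, cohorts of
3–10 chromosomes, 20-seed recovery studies, 100–1000-replicate calibration
loops, and bootstrap B of 200–1000 inside simulations (the production
default stays 10,000). These sizes make the whole suite run in minutes
while leaving every statistical band comfortably resolvable.

## Known limitations

* The Burgers model is a fluid: it cannot represent a true equilibrium
  plateau at zero frequency. Tethers that are gels at long times will show
  a fitted $\eta_2$ limited by the record length.
* Values below the record-length frequency limit rest on the
  terminal-gradient extrapolation and are flagged untrusted.
* The high-frequency viscous component is the first casualty of
  measurement noise; the fit's masking keeps parameters stable but cannot
  recover information that is not there.
* The detachment QC rule (abrupt, sustained collapse to baseline)
  deliberately ignores slow relaxation to near-zero force, which is the
  expected behaviour of a viscoelastic fluid tether, not an artefact.
* HDF5 I/O requires a `python` with h5py on PATH; CSV + JSON sidecar is
  the self-contained interchange format.
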