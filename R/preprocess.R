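#' Zero the force baseline of a trace
#'
#' Subtracts the mean of each force channel over (the tail of) the baseline
#' phase, mirroring the instrument step in which forces at both beads are
#' zeroed before any stretching. Idempotent up to the noise of the baseline
#' mean; offsets are recorded in the trace provenance.
#'
#' @param trace A [tether_trace()] containing a `baseline` phase.
#' @param window Duration in s of baseline to average over, taken from the end
#'   of the baseline phase (closest to the ramp). `NULL` uses the whole phase.
#' @return The trace with zeroed `f1`, `f2` and attributes
#'   `baseline_offsets` (the subtracted means) and `baseline_sd` (per-channel
#'   baseline noise SD, used by [detect_natural_length()]).
#' @export
zero_force_baseline <- function(trace, window = NULL) {
  idx <- which(trace$phase == "baseline")
  if (!length(idx)) {
    abort(paste("trace has no baseline phase: zero the forces by supplying",
                "explicit offsets (subtract them from f1/f2) before analysis."),
          class = "chromorheo_baseline_error")
  }
  if (!is.null(window)) {
    t_end <- trace$t[idx[length(idx)]]
    keep <- trace$t[idx] >= t_end - window
    if (!any(keep)) {
      abort(sprintf("baseline phase is shorter than the requested %g s window.", window),
            class = "chromorheo_baseline_error")
    }
    idx <- idx[keep]
  }
  off <- c(f1 = mean(trace$f1[idx]), f2 = mean(trace$f2[idx]))
  sds <- c(f1 = sd(trace$f1[idx]), f2 = sd(trace$f2[idx]))
  trace$f1 <- trace$f1 - off[["f1"]]
  trace$f2 <- trace$f2 - off[["f2"]]
  attr(trace, "baseline_offsets") <- off
  attr(trace, "baseline_sd") <- sds
  add_provenance(trace, sprintf("zero_force_baseline: offsets f1=%.6g f2=%.6g pN",
                                off[["f1"]], off[["f2"]]))
}

#' Detect the natural length of a tethered chromosome
#'
#' The natural length `L0` is the bead-handle separation just before further
#' stepping of a trap produces resistive force above the baseline noise. On a
#' baseline-zeroed ramp trace, the engagement point is the first ramp sample at
#' which the mean chromosome force exceeds `threshold_sd` baseline standard
#' deviations and stays above for `persistence` consecutive samples.
#'
#' @param trace A baseline-zeroed [tether_trace()] with a ramp phase.
#' @param meta Optional [chromosome_meta()]; defaults to the trace's own.
#' @param threshold_sd Engagement threshold as a multiple of the baseline force
#'   SD (default 3).
#' @param persistence Number of consecutive samples the force must stay above
#'   threshold (default 50).
#' @param baseline_sd Override for the baseline noise SD in pN (single value,
#'   pooled over both channels); taken from the `baseline_sd` attribute when
#'   `NULL`.
#' @return The updated `chromosome_meta` with `L0` set (um). A warning flag
#'   `"L0_at_ramp_start"` is appended to `qc_flags` if engagement occurs at the
#'   very first ramp sample, where `L0` may be underestimated.
#' @export
detect_natural_length <- function(trace, meta = trace_meta(trace),
                                  threshold_sd = 3, persistence = 50,
                                  baseline_sd = NULL) {
  if (is.null(baseline_sd)) {
    bs <- attr(trace, "baseline_sd")
    if (is.null(bs)) {
      abort("no baseline noise estimate: run zero_force_baseline() first or pass `baseline_sd`.",
            class = "chromorheo_baseline_error")
    }
    baseline_sd <- sqrt(mean(bs^2))
  }
  ridx <- which(trace$phase == "ramp")
  if (!length(ridx)) {
    abort("trace has no ramp phase.", class = "chromorheo_validation_error")
  }
  f <- (abs(trace$f1[ridx]) + abs(trace$f2[ridx])) / 2
  thr <- threshold_sd * baseline_sd
  above <- f > thr
  persistence <- min(persistence, length(above))
  # first sample from which `persistence` consecutive samples stay above
  hit <- NA_integer_
  if (any(above)) {
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    good <- which(runs$values & runs$lengths >= persistence)
    if (length(good)) hit <- starts[good[1]]
  }
  if (is.na(hit)) {
    abort(sprintf("no engagement detected: force never exceeds %g SD (= %.3g pN) for %d samples.",
                  threshold_sd, thr, persistence),
          class = "chromorheo_no_engagement")
  }
  i <- ridx[hit]
  L0 <- trace$trap2[i] - trace$trap1[i]
  if (hit == 1L) {
    warn("engagement at the first ramp sample: L0 may be underestimated.")
    meta$qc_flags <- union(meta$qc_flags, "L0_at_ramp_start")
  }
  meta$L0 <- L0
  meta
}

#' Mean chromosome force
#'
#' The stretching force transmitted along the tether, computed as the average
#' of the force magnitudes measured at the two bead handles. Under the sign
#' convention (x axis from trap 1 to trap 2, tension giving `f1 > 0`,
#' `f2 < 0`), averaging magnitudes uses both sensors for accuracy and halves
#' uncorrelated channel noise variance.
#'
#' @param trace A baseline-zeroed [tether_trace()].
#' @param warn_fraction Warn if more than this fraction of samples with
#'   appreciable force have same-sign `f1`/`f2` (convention violation).
#' @return Numeric vector of forces in pN, one per sample.
#' @export
mean_chromosome_force <- function(trace, warn_fraction = 0.05) {
  f <- (abs(trace$f1) + abs(trace$f2)) / 2
  big <- f > 6 * mad0(c(trace$f1, trace$f2))
  same <- big & (sign(trace$f1) == sign(trace$f2)) & trace$f1 != 0
  if (mean(same) > warn_fraction) {
    warn(sprintf("%.1f%% of samples have same-sign forces at both beads; check the sign convention.",
                 100 * mean(same)))
  }
  f
}

mad0 <- function(x) {
  m <- stats::mad(x)
  if (m == 0 || !is.finite(m)) m <- max(sd(x), .Machine$double.eps)
  m
}

#' Extension series of a stretch/dwell experiment
#'
#' Converts measured forces and trap positions into the chromosome length and
#' deformation record used by all downstream analyses. Each bead sits
#' displaced from its trap centre by `x = F/kappa_OT` (displacement towards
#' the tether), so the bead-handle separation is
#' `L(t) = (trap2 - |f2|/kappa_OT) - (trap1 + |f1|/kappa_OT)` (um, with forces
#' converted to um via pN / (pN/nm) / 1000) and the deformation is
#' `lambda(t) = (L(t) - L0) * 1000` in nm.
#'
#' @param trace A baseline-zeroed [tether_trace()].
#' @param meta [chromosome_meta()] with `L0` and `kappa_OT` set; defaults to
#'   the trace's own metadata.
#' @param linear_range_nm Optional bound on |bead displacement| in nm beyond
#'   which trap linearity is considered violated; offending samples are
#'   flagged in the `trap_linear` column (TRUE = within range) and a warning
#'   is raised.
#' @return A tibble of class `"extension_series"` with columns `t` (s),
#'   `lam` (nm), `L` (um), `f_mean` (pN), `phase`, and attribute `meta`.
#' @export
extension_series <- function(trace, meta = trace_meta(trace),
                             linear_range_nm = Inf) {
  if (is.null(meta) || is.na(meta$L0)) {
    abort("meta$L0 is unset: run detect_natural_length() or supply L0.",
          class = "chromorheo_validation_error")
  }
  kOT <- meta$kappa_OT
  # inward bead displacements in nm; magnitudes make the result invariant
  # under bead relabelling combined with sign flip
  x1 <- abs(trace$f1) / kOT
  x2 <- abs(trace$f2) / kOT
  L <- (trace$trap2 - trace$trap1) - (x1 + x2) / 1000
  lam <- (L - meta$L0) * 1000
  ok <- (x1 <= linear_range_nm) & (x2 <= linear_range_nm)
  if (!all(ok)) {
    warn(sprintf("%d sample(s) exceed the trap linear range (%g nm bead displacement).",
                 sum(!ok), linear_range_nm))
  }
  out <- tibble::tibble(t = trace$t, lam = lam, L = L,
                        f_mean = mean_chromosome_force(trace),
                        phase = trace$phase)
  if (is.finite(linear_range_nm)) out$trap_linear <- ok
  attr(out, "meta") <- meta
  class(out) <- c("extension_series", class(tibble::tibble()))
  out
}
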