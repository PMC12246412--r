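#' Assemble a cohort of chromosome records
#'
#' A cohort is a tibble with one row per chromosome: metadata columns spread
#' flat (`id`, `condition`, `kappa_OT`, `L0`, `length_um`, `fluorescence`),
#' a `qc_flags` list-column, and a `trace` list-column holding each
#' [tether_trace()]. A `filter_log` attribute accumulates every exclusion so
#' no record silently disappears.
#'
#' @param records A list of `tether_trace` objects (each carrying its
#'   metadata), or a list of `list(trace =, meta =)` pairs.
#' @param provenance Optional character vector of source paths/notes.
#' @return A tibble of class `"chromosome_cohort"`.
#' @export
cohort <- function(records, provenance = character()) {
  recs <- purrr::map(records, function(r) {
    if (inherits(r, "tether_trace")) list(trace = r, meta = trace_meta(r))
    else r
  })
  metas <- purrr::map(recs, "meta")
  ids <- purrr::map_chr(metas, "id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate chromosome id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
          class = "chromorheo_validation_error")
  }
  out <- tibble::tibble(
    id = ids,
    condition = purrr::map_chr(metas, "condition"),
    kappa_OT = purrr::map_dbl(metas, "kappa_OT"),
    L0 = purrr::map_dbl(metas, "L0"),
    length_um = purrr::map_dbl(metas, "length_um"),
    fluorescence = purrr::map_dbl(metas, "fluorescence"),
    qc_flags = purrr::map(metas, "qc_flags"),
    trace = purrr::map(recs, "trace")
  )
  attr(out, "provenance") <- provenance
  attr(out, "filter_log") <- tibble::tibble(id = character(), flag = character())
  class(out) <- c("chromosome_cohort", class(tibble::tibble()))
  out
}

#' @export
#' @method print chromosome_cohort
print.chromosome_cohort <- function(x, ...) {
  cat(sprintf("<chromosome_cohort> %d record(s): %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$condition)), table(x$condition)),
                    collapse = " ")))
  NextMethod()
}

#' Exclusion log of a filtered cohort
#'
#' @param coh A `chromosome_cohort`.
#' @return Tibble with columns `id`, `flag`, one row per exclusion reason.
#' @export
filter_log <- function(coh) attr(coh, "filter_log")

#' Quality-control filter for a cohort
#'
#' Applies the record-level exclusion rules: chromosomes outside the length
#' interval (closed, default 2--5 um, "between 2 and 5 um" read inclusively)
#' are flagged `"length"`; dwell records whose force collapses to baseline
#' (below `detach_sd` baseline SDs for longer than `detach_min_s`) are flagged
#' `"detached"`. Filtering never raises; an empty result is allowed with a
#' warning. All exclusions are appended to the `filter_log` attribute and kept
#' in the excluded records' `qc_flags`.
#'
#' @param coh A [cohort()].
#' @param length_range Closed inclusion interval for `length_um` (um).
#' @param detach_sd Detachment force threshold as a multiple of the baseline
#'   SD (default 2); if no baseline SD is attached to a trace, a robust noise
#'   estimate of the dwell tail is used.
#' @param detach_min_s Minimum sustained drop duration in s (default 1).
#' @return The filtered cohort with an updated `filter_log`.
#' @export
qc_filter <- function(coh, length_range = c(2, 5), detach_sd = 2,
                      detach_min_s = 1) {
  log <- filter_log(coh)
  flags <- purrr::map2(coh$qc_flags, seq_len(nrow(coh)), function(fl, i) {
    len <- coh$length_um[i]
    if (!is.na(len) && (len < length_range[1] || len > length_range[2])) {
      fl <- union(fl, "length")
    }
    tr <- coh$trace[[i]]
    if (!is.null(tr) && is_detached(tr, detach_sd, detach_min_s)) {
      fl <- union(fl, "detached")
    }
    fl
  })
  coh$qc_flags <- flags
  bad <- purrr::map_lgl(flags, ~ any(.x %in% c("length", "detached")))
  if (any(bad)) {
    log <- dplyr::bind_rows(log, tidyr::unnest(
      tibble::tibble(id = coh$id[bad],
                     flag = purrr::map(flags[bad], ~ intersect(.x, c("length", "detached")))),
      "flag"))
  }
  out <- coh[!bad, ]
  if (nrow(out) == 0L) warn("qc_filter removed every record.")
  attr(out, "filter_log") <- log
  attr(out, "provenance") <- attr(coh, "provenance")
  class(out) <- class(coh)
  out
}

# abrupt, sustained force collapse during dwell. Viscoelastic relaxation also
# ends near baseline, but it passes through intermediate force levels slowly;
# detachment is a step, so the drop from load to baseline must be fast.
is_detached <- function(trace, detach_sd = 2, detach_min_s = 1,
                        drop_window_s = 0.1) {
  idx <- which(trace$phase == "dwell")
  if (length(idx) < 3L) return(FALSE)
  f <- (abs(trace$f1[idx]) + abs(trace$f2[idx])) / 2
  bs <- attr(trace, "baseline_sd")
  noise <- if (!is.null(bs) && all(bs > 0)) sqrt(mean(bs^2)) else mad0(diff(f)) / sqrt(2)
  fmax <- max(f)
  if (fmax <= 3 * detach_sd * noise) return(FALSE)  # never under load
  below <- f < detach_sd * noise
  if (!any(below)) return(FALSE)
  t <- trace$t[idx]
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in which(runs$values & runs$lengths > 1L)) {
    if (t[ends[j]] - t[starts[j]] <= detach_min_s) next
    # abruptness: the last sample still above half the peak load must sit
    # within drop_window_s of the collapse
    i0 <- starts[j]
    prior <- which(f[seq_len(i0)] > 0.5 * fmax)
    if (!length(prior)) next
    if (t[i0] - t[max(prior)] <= drop_window_s * (1 + 1e-9)) return(TRUE)
  }
  FALSE
}
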