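#' Chromosome metadata record
#'
#' Per-chromosome metadata travelling alongside a [tether_trace()]: identity,
#' experimental condition, trap stiffness, natural length and quality-control
#' flags.
#'
#' @param id Character identifier, unique within a cohort.
#' @param condition Condition label, one of `"WT"`, `"KD"`, `"OE"`.
#' @param kappa_OT Trap stiffness in pN/nm (per trap; both traps are assumed
#'   calibrated to the same value). Must be positive; `Inf` selects the
#'   rigid-trap idealisation.
#' @param L0 Natural length in um: the bead-handle separation at which further
#'   stepping first produces resistive force. `NA` until detected or supplied.
#'   Bead radii and linker offsets are absorbed into `L0`; no absolute-length
#'   claim is made.
#' @param length_um Measured chromosome length in um (used by the 2--5 um QC
#'   filter).
#' @param fluorescence Fluorescence intensity per unit length, arbitrary units.
#' @param qc_flags Character vector of exclusion reasons accumulated by QC.
#'
#' @return A list of class `"chromosome_meta"`.
#' @export
#' @examples
#' chromosome_meta("chr1", condition = "WT", kappa_OT = 0.5, length_um = 3.2)
chromosome_meta <- function(id = "chr",
                            condition = c("WT", "KD", "OE"),
                            kappa_OT = 0.5,
                            L0 = NA_real_,
                            length_um = NA_real_,
                            fluorescence = NA_real_,
                            qc_flags = character()) {
  condition <- match.arg(condition)
  if (!is.numeric(kappa_OT) || length(kappa_OT) != 1L || kappa_OT <= 0) {
    abort("`kappa_OT` must be a single positive number (pN/nm).",
          class = "chromorheo_meta_error")
  }
  if (!is.na(L0) && L0 <= 0) {
    abort("`L0` must be positive when set.", class = "chromorheo_meta_error")
  }
  structure(
    list(id = as.character(id), condition = condition, kappa_OT = kappa_OT,
         L0 = L0, length_um = length_um, fluorescence = fluorescence,
         qc_flags = as.character(qc_flags)),
    class = "chromosome_meta"
  )
}

#' @export
print.chromosome_meta <- function(x, ...) {
  cat(sprintf(
    "<chromosome_meta> id=%s condition=%s kappa_OT=%g pN/nm L0=%s um length=%s um%s\n",
    x$id, x$condition, x$kappa_OT,
    ifelse(is.na(x$L0), "unset", format(x$L0)),
    ifelse(is.na(x$length_um), "?", format(x$length_um)),
    if (length(x$qc_flags)) paste0(" [", paste(x$qc_flags, collapse = ","), "]") else ""
  ))
  invisible(x)
}

trace_phases <- c("baseline", "ramp", "dwell", "release")

#' Time-resolved record of one stretch/dwell experiment
#'
#' A `tether_trace` is a tibble with one row per acquired sample and columns
#' `t` (s, strictly increasing, 0 at protocol start), `f1`, `f2` (x-component
#' force at each bead in pN; under tension `f1 > 0`, `f2 < 0` with the x axis
#' pointing from trap 1 to trap 2), `trap1`, `trap2` (trap-centre positions in
#' um) and `phase` (one of `baseline`, `ramp`, `dwell`, `release`, contiguous
#' in protocol order). Metadata ride along as attributes and survive dplyr
#' subsetting of rows.
#'
#' @param t,f1,f2,trap1,trap2 Numeric channels, equal length.
#' @param phase Optional character/factor phase labels; inferred from trap
#'   motion via [infer_phases()] when `NULL`.
#' @param meta A [chromosome_meta()] record.
#' @param sampling Declared acquisition rate in Hz, or the string
#'   `"nonuniform"`.
#' @param provenance Character vector of processing notes.
#'
#' @return A tibble of class `"tether_trace"`.
#' @export
tether_trace <- function(t, f1, f2, trap1, trap2, phase = NULL,
                         meta = chromosome_meta(), sampling = "nonuniform",
                         provenance = character()) {
  if (is.null(phase)) phase <- infer_phases(t, trap1, trap2)
  out <- tibble::tibble(t = as.numeric(t), f1 = as.numeric(f1),
                        f2 = as.numeric(f2), trap1 = as.numeric(trap1),
                        trap2 = as.numeric(trap2), phase = as.character(phase))
  attr(out, "meta") <- meta
  attr(out, "sampling") <- sampling
  attr(out, "provenance") <- provenance
  class(out) <- c("tether_trace", class(tibble::tibble()))
  validate_tether_trace(out)
}

#' Validate a tether trace
#'
#' Checks channel lengths, strict time monotonicity and phase-label order.
#' Called by the constructor and the readers; exported so externally built
#' tibbles can be checked too.
#'
#' @param trace A `tether_trace`.
#' @return `trace`, invisibly unchanged, or an error.
#' @export
validate_tether_trace <- function(trace) {
  need <- c("t", "f1", "f2", "trap1", "trap2", "phase")
  miss <- setdiff(need, names(trace))
  if (length(miss)) {
    abort(paste0("tether_trace is missing column(s): ", paste(miss, collapse = ", ")),
          class = "chromorheo_schema_error")
  }
  dt <- diff(trace$t)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1] + 1L
    abort(sprintf("time must be strictly increasing; first violation at row %d (t = %g).",
                  i, trace$t[i]),
          class = "chromorheo_validation_error")
  }
  ph <- rle(trace$phase)$values
  if (!all(ph %in% trace_phases)) {
    abort(paste0("unknown phase label(s): ",
                 paste(setdiff(ph, trace_phases), collapse = ", ")),
          class = "chromorheo_validation_error")
  }
  if (is.unsorted(match(ph, trace_phases), strictly = TRUE) && length(ph) > 1L) {
    abort("phase labels must be contiguous in protocol order baseline>ramp>dwell>release.",
          class = "chromorheo_validation_error")
  }
  trace
}

#' Infer per-sample protocol phases from trap motion
#'
#' Labels samples `baseline` while both traps are stationary, `ramp` while the
#' trap separation changes away from its initial value, `dwell` once traps are
#' stationary again and `release` if the separation later returns towards the
#' start.
#'
#' @param t Sample times (s).
#' @param trap1,trap2 Trap positions (um).
#' @param tol Positional tolerance in um below which a trap is considered
#'   stationary between consecutive samples.
#' @return Character vector of phase labels.
#' @export
infer_phases <- function(t, trap1, trap2, tol = 1e-6) {
  n <- length(t)
  if (n == 0L) return(character())
  sep <- trap2 - trap1
  moving <- c(FALSE, abs(diff(sep)) > tol)
  if (!any(moving)) return(rep("baseline", n))
  first_move <- which(moving)[1]
  phase <- rep("baseline", n)
  phase[first_move:n] <- "ramp"
  after <- which(!moving & seq_len(n) > first_move)
  # dwell starts at the first stationary sample after motion began
  if (length(after)) {
    dwell_start <- after[1]
    phase[dwell_start:n] <- "dwell"
    move_again <- which(moving & seq_len(n) >= dwell_start)
    if (length(move_again)) phase[move_again[1]:n] <- "release"
  }
  phase
}

#' @export
#' @method print tether_trace
print.tether_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat(sprintf("<tether_trace> %d samples, %s, sampling %s\n",
              nrow(x), paste(unique(x$phase), collapse = " > "),
              as.character(attr(x, "sampling"))))
  print(m)
  NextMethod()
}

#' Access or replace the metadata of a trace
#'
#' @param trace A `tether_trace` (or `extension_series`).
#' @return The attached [chromosome_meta()].
#' @export
trace_meta <- function(trace) attr(trace, "meta")

#' @rdname trace_meta
#' @param value A [chromosome_meta()] record.
#' @export
`trace_meta<-` <- function(trace, value) {
  stopifnot(inherits(value, "chromosome_meta"))
  attr(trace, "meta") <- value
  trace
}

trace_provenance <- function(trace) attr(trace, "provenance") %||% character()

add_provenance <- function(trace, note) {
  attr(trace, "provenance") <- c(trace_provenance(trace), note)
  trace
}

# keep class + attributes across dplyr verbs that return data frames
restore_trace_attrs <- function(out, template) {
  for (a in c("meta", "sampling", "provenance")) {
    attr(out, a) <- attr(template, a)
  }
  class(out) <- class(template)
  out
}
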