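#' Column-mapping schema for delimited trace tables
#'
#' Maps file columns onto the canonical channels and declares the units they
#' arrive in; converters run at the I/O boundary only, so everything past the
#' reader is in canonical units (s, pN, um).
#'
#' @param time,f1,f2,trap1,trap2 Column names in the file.
#' @param phase Optional phase-label column (`NULL`: inferred from trap
#'   motion).
#' @param time_unit `"s"` or `"ms"`.
#' @param force_unit `"pN"` or `"nN"`.
#' @param position_unit `"um"` or `"nm"`.
#' @return A list of class `"trace_schema"`.
#' @export
trace_schema <- function(time = "time_s", f1 = "force1_pN", f2 = "force2_pN",
                         trap1 = "trap1_um", trap2 = "trap2_um",
                         phase = "phase",
                         time_unit = c("s", "ms"),
                         force_unit = c("pN", "nN"),
                         position_unit = c("um", "nm")) {
  structure(list(time = time, f1 = f1, f2 = f2, trap1 = trap1, trap2 = trap2,
                 phase = phase,
                 time_unit = match.arg(time_unit),
                 force_unit = match.arg(force_unit),
                 position_unit = match.arg(position_unit)),
            class = "trace_schema")
}

#' Read a trace from a delimited table
#'
#' Reads a CSV (or other delimited) trace table plus its JSON metadata
#' sidecar (`<path>.json`, or metadata passed directly). Units are converted
#' to canonical (s, pN, um) per the schema; phase labels are inferred from
#' trap motion when the file has no phase column.
#'
#' @param path File path.
#' @param schema A [trace_schema()].
#' @param meta Optional [chromosome_meta()] overriding the sidecar.
#' @param sep Field separator.
#' @return A validated [tether_trace()].
#' @export
read_trace_table <- function(path, schema = trace_schema(), meta = NULL,
                             sep = ",") {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "chromorheo_io_error")
  df <- read.csv(path, sep = sep, check.names = FALSE)
  for (ch in c("time", "f1", "f2", "trap1", "trap2")) {
    col <- schema[[ch]]
    if (!col %in% names(df)) {
      abort(sprintf("schema error: required column '%s' (channel %s) not found in %s.",
                    col, ch, path),
            class = "chromorheo_schema_error")
    }
  }
  tconv <- if (schema$time_unit == "ms") 1e-3 else 1
  fconv <- if (schema$force_unit == "nN") 1e3 else 1
  pconv <- if (schema$position_unit == "nm") 1e-3 else 1
  phase <- if (!is.null(schema$phase) && schema$phase %in% names(df)) {
    as.character(df[[schema$phase]])
  } else NULL
  if (is.null(meta)) {
    sidecar <- paste0(path, ".json")
    meta <- if (file.exists(sidecar)) read_meta_sidecar(sidecar) else chromosome_meta()
  }
  tether_trace(
    t = df[[schema$time]] * tconv,
    f1 = df[[schema$f1]] * fconv,
    f2 = df[[schema$f2]] * fconv,
    trap1 = df[[schema$trap1]] * pconv,
    trap2 = df[[schema$trap2]] * pconv,
    phase = phase,
    meta = meta,
    provenance = paste0("read_trace_table: ", path)
  )
}

#' Write a trace as a delimited table with a JSON sidecar
#'
#' Canonical headers (`time_s`, `force1_pN`, `force2_pN`, `trap1_um`,
#' `trap2_um`, `phase`); values at full double precision so the round-trip is
#' exact. Metadata go to `<path>.json`.
#'
#' @param trace A [tether_trace()].
#' @param path Output file path.
#' @param sidecar Write the metadata sidecar (default TRUE)?
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(trace, path, sidecar = TRUE) {
  df <- data.frame(time_s = fmt17(trace$t), force1_pN = fmt17(trace$f1),
                   force2_pN = fmt17(trace$f2), trap1_um = fmt17(trace$trap1),
                   trap2_um = fmt17(trace$trap2), phase = trace$phase)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) write_meta_sidecar(trace_meta(trace), paste0(path, ".json"))
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

read_meta_sidecar <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  chromosome_meta(
    id = j$id %||% "chr",
    condition = j$condition %||% "WT",
    kappa_OT = j$kappa_OT_pN_per_nm %||% 0.5,
    L0 = j$L0_um %||% NA_real_,
    length_um = j$length_um %||% NA_real_,
    fluorescence = j$fluorescence_au %||% NA_real_
  )
}

write_meta_sidecar <- function(meta, path) {
  jsonlite::write_json(
    list(id = meta$id, condition = meta$condition,
         kappa_OT_pN_per_nm = meta$kappa_OT, L0_um = meta$L0,
         length_um = meta$length_um, fluorescence_au = meta$fluorescence),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

# ---- HDF5 interchange -------------------------------------------------------
# No HDF5 binding ships with this R library set, so the reader/writer drive
# the h5py library through the `python` interpreter on PATH, exchanging
# channels as full-precision (%.17g) CSV. Layout: one top-level group per
# experiment, datasets time/force1/force2/trap1/trap2 (+ optional phase),
# metadata as group attributes mirroring the JSON sidecar.

h5_python <- function() {
  py <- Sys.which("python")
  if (py == "") abort("no `python` interpreter on PATH for HDF5 interchange.",
                      class = "chromorheo_io_error")
  py
}

run_py <- function(code, args = character()) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  out <- suppressWarnings(system2(h5_python(), c(f, args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    abort(paste0("python/h5py helper failed:\n", paste(out, collapse = "\n")),
          class = "chromorheo_io_error")
  }
  out
}

#' Write traces to an HDF5 file
#'
#' @param traces A [tether_trace()] or list of them.
#' @param path Output `.h5` path.
#' @return `path`, invisibly.
#' @export
write_trace_h5 <- function(traces, path) {
  if (inherits(traces, "tether_trace")) traces <- list(traces)
  tmpdir <- tempfile("h5w")
  dir.create(tmpdir)
  on.exit(unlink(tmpdir, recursive = TRUE))
  manifest <- purrr::imap(traces, function(tr, i) {
    m <- trace_meta(tr)
    csv <- file.path(tmpdir, sprintf("g%03d.csv", i))
    write_trace_table(tr, csv, sidecar = TRUE)
    list(group = m$id, csv = csv, json = paste0(csv, ".json"))
  })
  mf <- file.path(tmpdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  run_py('
import csv, json, sys
import h5py
manifest_path, out_path = sys.argv[1], sys.argv[2]
with open(manifest_path) as fh:
    manifest = json.load(fh)
cols = {"time_s": "time", "force1_pN": "force1", "force2_pN": "force2",
        "trap1_um": "trap1", "trap2_um": "trap2"}
with h5py.File(out_path, "w") as h5:
    for ent in manifest:
        with open(ent["csv"]) as fh:
            rows = list(csv.DictReader(fh))
        g = h5.create_group(ent["group"])
        for src, dst in cols.items():
            g.create_dataset(dst, data=[float(r[src]) for r in rows], dtype="f8")
        g.create_dataset("phase", data=[r["phase"].encode() for r in rows])
        with open(ent["json"]) as fh:
            meta = json.load(fh)
        for k, v in meta.items():
            g.attrs[k] = "" if v is None else v
', args = c(mf, path))
  invisible(path)
}

#' Read traces from an HDF5 file
#'
#' Accepts the layout written by [write_trace_h5()] (one group per
#' experiment with `time`/`force1`/`force2`/`trap1`/`trap2` datasets and
#' sidecar-style attributes) and, as a fallback dialect, groups whose
#' datasets are named `time`, `force_1x`/`force_2x`, `trap_1x`/`trap_2x`
#' (instrument-style x-component exports). Groups are returned in name-sorted
#' order.
#'
#' @param path `.h5` file path.
#' @return A list of [tether_trace()] objects.
#' @export
read_trace_h5 <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "chromorheo_io_error")
  tmpdir <- tempfile("h5r")
  dir.create(tmpdir)
  on.exit(unlink(tmpdir, recursive = TRUE))
  out <- run_py('
import csv, json, sys
import h5py
in_path, outdir = sys.argv[1], sys.argv[2]
dialects = [
  {"time": "time", "f1": "force1", "f2": "force2", "t1": "trap1", "t2": "trap2"},
  {"time": "time", "f1": "force_1x", "f2": "force_2x", "t1": "trap_1x", "t2": "trap_2x"},
]
manifest = []
with h5py.File(in_path, "r") as h5:
    groups = sorted(h5.keys())
    for i, name in enumerate(groups):
        g = h5[name]
        keys = set(g.keys())
        dia = next((d for d in dialects if set(d.values()) <= keys), None)
        if dia is None:
            sys.stderr.write("unsupported dialect in group %r: datasets found %s\\n"
                             % (name, sorted(keys)))
            sys.exit(2)
        csvf = "%s/g%03d.csv" % (outdir, i)
        chans = {k: g[v][()] for k, v in dia.items()}
        phase = g["phase"][()] if "phase" in g else None
        with open(csvf, "w", newline="") as fh:
            wr = csv.writer(fh)
            hdr = ["time_s", "force1_pN", "force2_pN", "trap1_um", "trap2_um"]
            if phase is not None:
                hdr.append("phase")
            wr.writerow(hdr)
            for j in range(len(chans["time"])):
                row = ["%.17g" % chans[c][j] for c in ("time", "f1", "f2", "t1", "t2")]
                if phase is not None:
                    row.append(phase[j].decode())
                wr.writerow(row)
        meta = {k: (None if v == "" else (v.item() if hasattr(v, "item") else v))
                for k, v in g.attrs.items()}
        meta.setdefault("id", name)
        with open(csvf + ".json", "w") as fh:
            json.dump(meta, fh)
        manifest.append(csvf)
print(json.dumps(manifest))
', args = c(path, tmpdir))
  files <- jsonlite::fromJSON(out[length(out)])
  purrr::map(files, function(f) {
    read_trace_table(f, meta = read_meta_sidecar(paste0(f, ".json")))
  })
}
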