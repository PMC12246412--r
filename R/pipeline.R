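#' Read a pipeline configuration
#'
#' Configurations are YAML or JSON documents holding the seed, stage toggles
#' and per-module parameters; every field has a default, so `list()` is a
#' valid configuration. The resolved configuration (defaults merged in) is
#' embedded in each run's output directory.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or a list.
#' @return The resolved configuration list, class `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) {
    path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()  # empty document
  cfg <- coerce_numeric_strings(cfg)
  defaults <- list(
    seed = 1,
    out_dir = "chromorheo_run",
    stages = list(simulate = TRUE, fex = FALSE, rheo = TRUE,
                  fitburgers = TRUE, stats = TRUE),
    inputs = character(),
    simulate = list(n_per_condition = 4, conditions = c("WT", "KD", "OE"),
                    force_sd = 0.5,
                    protocol = list(), sampling = list()),
    grid = list(omega_min = 1e-2, omega_max = 1e5, points_per_decade = 16),
    qc = list(length_range = c(2, 5)),
    rheo = list(window = "stretch_hold"),
    bootstrap = list(B = 2000)
  )
  cfg <- modifyList(defaults, cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

# YAML 1.1 parses exponent notation without a sign ("1.0e4") as a string;
# recursively convert numeric-looking character scalars
coerce_numeric_strings <- function(x) {
  if (is.list(x)) return(lapply(x, coerce_numeric_strings))
  if (is.character(x) &&
      all(grepl("^[+-]?[0-9.]+([eE][+-]?[0-9]+)?$", x))) {
    y <- suppressWarnings(as.numeric(x))
    if (!anyNA(y)) return(y)
  }
  x
}

#' Run the analysis pipeline
#'
#' Executes the requested stages per record (QC, force-extension and/or
#' broadband microrheology, Burgers fit), then cohort aggregation and group
#' statistics, writing all tables, fit results, the exclusion log and the
#' resolved configuration into the run directory. Per-record failures are
#' logged, not fatal; the run errors only if no record survives.
#'
#' @param config A [read_pipeline_config()] result, a path, or a list.
#' @return The run directory path, invisibly; the `summary` attribute holds
#'   per-record status.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  st <- cfg$stages

  # --- assemble cohort ------------------------------------------------------
  coh <- NULL
  if (length(cfg$inputs)) {
    traces <- purrr::map(cfg$inputs, read_trace_table)
    coh <- cohort(traces, provenance = cfg$inputs)
  } else if (isTRUE(st$simulate)) {
    sim <- cfg$simulate
    coh <- generate_cohort(
      spec = cohort_spec(conditions = sim$conditions, force_sd = sim$force_sd),
      n_per_condition = sim$n_per_condition,
      seed = cfg$seed,
      protocol = do.call(trap_protocol, sim$protocol),
      sampling = do.call(sampling_spec, sim$sampling))
  }
  if (is.null(coh) || nrow(coh) == 0L) {
    if (!isTRUE(st$rheo) && !isTRUE(st$fex) && !isTRUE(st$fitburgers)) {
      jsonlite::write_json(list(), file.path(cfg$out_dir, "manifest.json"))
      return(invisible(cfg$out_dir))
    }
    abort("no input records: supply `inputs` or enable the simulate stage.",
          class = "chromorheo_pipeline_error")
  }
  coh <- qc_filter(coh, length_range = cfg$qc$length_range)
  write.csv(filter_log(coh), file.path(cfg$out_dir, "exclusions.csv"),
            row.names = FALSE)
  if (nrow(coh) == 0L) {
    abort("no records survived QC.", class = "chromorheo_pipeline_error")
  }

  grid <- frequency_grid(cfg$grid$omega_min, cfg$grid$omega_max,
                         cfg$grid$points_per_decade)
  dir.create(file.path(cfg$out_dir, "spectra"), showWarnings = FALSE)

  rows <- list()
  spectra <- list()
  status <- list()
  for (i in seq_len(nrow(coh))) {
    id <- coh$id[i]
    res <- tryCatch({
      tr <- coh$trace[[i]]
      meta <- trace_meta(tr)
      row <- tibble::tibble(id = id, condition = coh$condition[i])
      if (isTRUE(st$fex)) {
        es <- extension_series(tr, meta)
        sm <- try(fit_stretch_modulus(es, meta), silent = TRUE)
        if (!inherits(sm, "try-error")) row$S <- sm$S
        sf <- try(fit_stiffening_exponent(stiffness_vs_force(es)), silent = TRUE)
        if (!inherits(sf, "try-error")) {
          row$gamma <- sf$gamma
          row$a <- sf$a
        }
        row$response <- classify_response(es)$label
      }
      if (isTRUE(st$rheo)) {
        sp <- microrheology(tr, meta, grid, window = cfg$rheo$window)
        spectra[[id]] <- sp
        write.csv(
          data.frame(omega_rad_s = sp$omega,
                     kappa_prime_pN_per_nm = sp$kp,
                     kappa_dblprime_pN_per_nm = sp$kpp,
                     tan_delta = sp$tan_delta,
                     trusted = as.integer(sp$trusted)),
          file.path(cfg$out_dir, "spectra", paste0(id, ".csv")),
          row.names = FALSE)
        pk <- characteristic_peak_times(sp)
        mn <- relaxation_minimum_time(sp)
        td_ok <- sp$trusted & !is.na(sp$tan_delta)
        row$tan_delta_max <- if (isTRUE(pk$interior)) pk$tan_delta_max else
          suppressWarnings(max(sp$tan_delta[td_ok]))
        row$t_peak <- pk$t_peak
        row$tan_delta_10ms <- approx(log(sp$omega[td_ok]),
                                     sp$tan_delta[td_ok],
                                     xout = log(100))$y
        row$t_min <- mn$t_min
        row$tan_delta_min <- mn$tan_delta_min
        if (isTRUE(st$fitburgers)) {
          bf <- fit_burgers(sp, seed = cfg$seed)
          dr <- derived_ratios(bf)
          row$kappa1 <- bf$params$kappa1; row$kappa2 <- bf$params$kappa2
          row$eta1 <- bf$params$eta1; row$eta2 <- bf$params$eta2
          row$r1 <- dr$r1; row$r2 <- dr$r2; row$rel_kappa <- dr$rel_kappa
          jsonlite::write_json(
            c(as.list(tidyr::pivot_wider(tidy(bf)[, 1:2],
                                         names_from = "term",
                                         values_from = "estimate")),
              list(r1 = dr$r1, r2 = dr$r2, rel_kappa = dr$rel_kappa,
                   rel_kappa_ratio = dr$rel_kappa_ratio,
                   cost = bf$cost, seed = bf$seed,
                   flags = bf$identifiability_flags)),
            file.path(cfg$out_dir, "spectra", paste0(id, "_burgers.json")),
            auto_unbox = TRUE, digits = NA)
        }
      }
      rows[[id]] <- row
      "ok"
    }, error = function(e) conditionMessage(e))
    status[[id]] <- res
  }
  failed <- purrr::keep(status, ~ .x != "ok")
  if (length(failed)) {
    warn(sprintf("%d record(s) failed: %s", length(failed),
                 paste(names(failed), collapse = ", ")))
  }
  if (!length(rows)) {
    abort("every record failed.", class = "chromorheo_pipeline_error")
  }
  records <- dplyr::bind_rows(rows)
  write.csv(records, file.path(cfg$out_dir, "records.csv"), row.names = FALSE)

  # --- cohort aggregation and statistics ------------------------------------
  if (isTRUE(st$rheo) && length(spectra) >= 2L) {
    for (cd in unique(records$condition)) {
      ids <- records$id[records$condition == cd]
      sps <- spectra[intersect(names(spectra), ids)]
      if (length(sps) >= 2L) {
        agg <- suppressWarnings(
          aggregate_cohort(sps, B = cfg$bootstrap$B, seed = cfg$seed))
        write.csv(agg, file.path(cfg$out_dir,
                                 paste0("cohort_spectrum_", cd, ".csv")),
                  row.names = FALSE)
      }
    }
  }
  if (isTRUE(st$stats)) {
    metrics <- intersect(c("S", "gamma", "tan_delta_max", "tan_delta_10ms",
                           "t_min", "kappa1", "kappa2", "eta1", "eta2",
                           "r1", "r2", "rel_kappa"),
                         names(records))
    stat_rows <- purrr::map(metrics, function(m) {
      gc <- try(suppressWarnings(
        kruskal_wallis_multicomp(records, !!rlang::sym(m), condition)),
        silent = TRUE)
      if (inherits(gc, "try-error")) return(NULL)
      dplyr::mutate(tidy(gc), metric = m, H = gc$statistic,
                    p_global = gc$p_global, .before = 1)
    })
    stats_tbl <- dplyr::bind_rows(purrr::compact(stat_rows))
    if (nrow(stats_tbl)) {
      write.csv(stats_tbl, file.path(cfg$out_dir, "stats.csv"),
                row.names = FALSE)
    }
  }
  jsonlite::write_json(status, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  out <- cfg$out_dir
  attr(out, "summary") <- status
  invisible(out)
}
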