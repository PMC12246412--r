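test_that("trace construction validates channels, time order and phases", {
  tr <- toy_trace(5)
  expect_s3_class(tr, "tether_trace")
  expect_equal(nrow(tr), 5)
  expect_true(all(tr$phase == "baseline"))

  expect_error(
    tether_trace(t = c(0, 1, 1, 2, 3), f1 = rep(0, 5), f2 = rep(0, 5),
                 trap1 = rep(0, 5), trap2 = rep(5, 5),
                 phase = rep("baseline", 5)),
    class = "chromorheo_validation_error")
  expect_error(
    tether_trace(t = 0:4, f1 = rep(0, 5), f2 = rep(0, 5),
                 trap1 = rep(0, 5), trap2 = rep(5, 5),
                 phase = c("dwell", "dwell", "ramp", "ramp", "baseline")),
    class = "chromorheo_validation_error")
})

test_that("phases are inferred from trap motion", {
  t <- 0:99
  trap2 <- c(rep(5, 30), 5 + 0.01 * (1:20), rep(5.2, 50))
  ph <- infer_phases(t, rep(0, 100), trap2)
  expect_equal(unique(ph), c("baseline", "ramp", "dwell"))
  expect_equal(sum(ph == "baseline"), 30)
  expect_true(all(ph[32:50] == "ramp"))
  expect_true(all(ph[52:100] == "dwell"))
})

test_that("csv round-trip preserves channels to full precision", {
  tr <- simulate_dumbbell(wt_params(), fast_protocol(),
                          sampling_spec("log", t_min = 1e-3,
                                        points_per_decade = 30),
                          noise_spec(0.5, seed = 7))
  f <- tempfile(fileext = ".csv")
  write_trace_table(tr, f)
  tr2 <- read_trace_table(f)
  expect_identical(tr2$t, tr$t)
  expect_identical(tr2$f1, tr$f1)
  expect_identical(tr2$f2, tr$f2)
  expect_identical(tr2$trap1, tr$trap1)
  expect_identical(tr2$trap2, tr$trap2)
  expect_identical(tr2$phase, tr$phase)
  m <- trace_meta(tr2)
  expect_equal(m$kappa_OT, 0.5)
  expect_equal(m$L0, 3)
  unlink(c(f, paste0(f, ".json")))
})

test_that("schema maps alternative units and missing columns error by name", {
  tr <- toy_trace(6, f = 2)
  f <- tempfile(fileext = ".csv")
  df <- data.frame(t_ms = tr$t * 1000, F1 = tr$f1, F2 = tr$f2,
                   x1_nm = tr$trap1 * 1000, x2_nm = tr$trap2 * 1000)
  write.csv(df, f, row.names = FALSE)
  sch <- trace_schema(time = "t_ms", f1 = "F1", f2 = "F2",
                      trap1 = "x1_nm", trap2 = "x2_nm",
                      time_unit = "ms", position_unit = "nm")
  tr2 <- read_trace_table(f, schema = sch)
  expect_equal(tr2$t, tr$t)
  expect_equal(tr2$trap2, tr$trap2)

  err <- expect_error(read_trace_table(f), class = "chromorheo_schema_error")
  expect_match(conditionMessage(err), "time_s")
  unlink(f)
})

test_that("duplicated timestamp is rejected with the offending row", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 1, 1, 2), force1_pN = 0, force2_pN = 0,
                       trap1_um = 0, trap2_um = 5), f, row.names = FALSE)
  err <- expect_error(read_trace_table(f),
                      class = "chromorheo_validation_error")
  expect_match(conditionMessage(err), "row 3")
  unlink(f)
})

test_that("hdf5 round-trips bit-identically and reports unknown layouts", {
  tr1 <- simulate_dumbbell(wt_params(), fast_protocol(),
                           sampling_spec("log", t_min = 1e-3,
                                         points_per_decade = 20),
                           noise_spec(0.3, seed = 1), id = "b_second")
  tr2 <- simulate_dumbbell(wt_params(), fast_protocol(),
                           sampling_spec("log", t_min = 1e-3,
                                         points_per_decade = 20),
                           noise_spec(0.3, seed = 2), id = "a_first")
  h5 <- tempfile(fileext = ".h5")
  write_trace_h5(list(tr1, tr2), h5)
  back <- read_trace_h5(h5)
  expect_length(back, 2)
  # group-name sort order
  expect_equal(trace_meta(back[[1]])$id, "a_first")
  expect_equal(trace_meta(back[[2]])$id, "b_second")
  expect_identical(back[[2]]$f1, tr1$f1)
  expect_identical(back[[2]]$t, tr1$t)
  expect_identical(back[[1]]$trap2, tr2$trap2)

  # drop a force channel -> unsupported dialect
  system2(Sys.which("python"), c("-c", shQuote(sprintf(
    "import h5py; f = h5py.File('%s','a'); del f['a_first/force2']; f.close()",
    h5))))
  err <- expect_error(read_trace_h5(h5), class = "chromorheo_io_error")
  expect_match(conditionMessage(err), "unsupported dialect")
  unlink(h5)
})

test_that("baseline zeroing removes offsets, is idempotent, and meets the SE bound", {
  tr <- toy_trace(200)
  tr$f1 <- tr$f1 + 3.2
  tr$f2 <- tr$f2 - 1.7
  z <- zero_force_baseline(tr)
  expect_lt(abs(mean(z$f1)), 1e-9)
  expect_lt(abs(mean(z$f2)), 1e-9)
  z2 <- zero_force_baseline(z)
  expect_equal(z2$f1, z$f1)

  expect_error(zero_force_baseline(toy_trace(5, phase = "dwell")),
               class = "chromorheo_baseline_error")

  # gaussian baseline: residual mean within 3 sigma/sqrt(n)
  set.seed(11)
  n <- 1e5
  trn <- tether_trace(t = seq_len(n) * 1e-3, f1 = rnorm(n, 5, 0.5),
                      f2 = rnorm(n, -5, 0.5), trap1 = rep(0, n),
                      trap2 = rep(5, n), phase = rep("baseline", n))
  zn <- zero_force_baseline(trn)
  expect_lt(abs(mean(zn$f1)), 3 * 0.5 / sqrt(n) + 1e-12)
})

test_that("natural length is detected at spring engagement", {
  # ramp: separation grows 2.8 -> 3.4 um; spring engages at 3.0 um
  n <- 2000
  sep <- seq(2.8, 3.4, length.out = n)
  FF <- pmax(0, (sep - 3) * 1000 * 0.5)  # 0.5 pN/nm spring
  mk <- function(noise_sd, seed) {
    set.seed(seed)
    nb <- 500
    tether_trace(
      t = seq_len(nb + n) * 1e-3,
      f1 = c(rnorm(nb, 0, noise_sd), FF + rnorm(n, 0, noise_sd)),
      f2 = -c(rnorm(nb, 0, noise_sd), FF + rnorm(n, 0, noise_sd)),
      trap1 = rep(0, nb + n), trap2 = c(rep(2.8, nb), sep),
      phase = c(rep("baseline", nb), rep("ramp", n)),
      meta = chromosome_meta())
  }
  tr <- zero_force_baseline(mk(0, 1))
  m <- detect_natural_length(tr, baseline_sd = 0.01, persistence = 5)
  expect_equal(m$L0, 3.0, tolerance = 1e-3)

  # noisy: within 0.02 um across seeds
  errs <- vapply(1:20, function(s) {
    tr <- zero_force_baseline(mk(0.5, s))
    m <- detect_natural_length(tr, threshold_sd = 3, persistence = 50)
    abs(m$L0 - 3.0)
  }, numeric(1))
  expect_lt(median(errs), 0.02)
  expect_lt(max(errs), 0.05)

  flat <- zero_force_baseline(mk(0, 2))
  flat$f1[] <- 0
  flat$f2[] <- 0
  expect_error(detect_natural_length(flat, baseline_sd = 0.01),
               class = "chromorheo_no_engagement")
})

test_that("extension series follows the trap relation", {
  # traps 5 um apart, f1 = -f2 = 50 pN, kOT = 0.5 -> L = 4.8, lambda = 300 nm
  n <- 20
  tr <- tether_trace(t = seq_len(n), f1 = rep(50, n), f2 = rep(-50, n),
                     trap1 = rep(0, n), trap2 = rep(5, n),
                     phase = rep("dwell", n),
                     meta = chromosome_meta(L0 = 4.5, kappa_OT = 0.5))
  es <- extension_series(tr)
  expect_equal(unique(es$L), 4.8)
  expect_equal(unique(es$lam), 300)
  expect_equal(unique(es$f_mean), 50)

  # zero force: L = trap separation
  tr0 <- toy_trace(5, f = 0, meta = chromosome_meta(L0 = 4.5, kappa_OT = 0.5))
  es0 <- extension_series(tr0)
  expect_equal(unique(es0$L), 5)
  expect_equal(unique(es0$lam), 500)

  # doubling kappa_OT at fixed forces halves displacements
  tr2 <- tr
  trace_meta(tr2) <- chromosome_meta(L0 = 4.5, kappa_OT = 1.0)
  es2 <- extension_series(tr2)
  expect_equal(unique(es2$lam), 400)  # lambda + 2*dx*1000 with dx halved

  # invariance under bead-label exchange with sign flip
  tr3 <- tether_trace(t = tr$t, f1 = -tr$f2, f2 = -tr$f1, trap1 = tr$trap1,
                      trap2 = tr$trap2, phase = tr$phase,
                      meta = trace_meta(tr))
  expect_equal(extension_series(tr3)$lam, es$lam)
})

test_that("mean chromosome force averages magnitudes and halves noise variance", {
  n <- 4
  tr <- tether_trace(t = 1:n, f1 = rep(10.2, n), f2 = rep(-9.8, n),
                     trap1 = rep(0, n), trap2 = rep(5, n),
                     phase = rep("dwell", n))
  expect_equal(unique(mean_chromosome_force(tr)), 10)
  tr0 <- toy_trace(4, f = 0)
  expect_equal(unique(mean_chromosome_force(tr0)), 0)

  set.seed(3)
  m <- 2e4
  trn <- tether_trace(t = seq_len(m), f1 = 100 + rnorm(m), f2 = -100 + rnorm(m),
                      trap1 = rep(0, m), trap2 = rep(5, m),
                      phase = rep("dwell", m))
  expect_equal(sd(mean_chromosome_force(trn)), 1 / sqrt(2), tolerance = 0.05)
})

test_that("qc filter applies the closed length interval and logs exclusions", {
  lens <- c(1.5, 3.0, 5.5, 4.2, 2.0, 5.0)
  recs <- lapply(seq_along(lens), function(i) {
    m <- chromosome_meta(id = sprintf("c%d", i), length_um = lens[i])
    toy_trace(10, meta = m)
  })
  coh <- cohort(recs)
  out <- qc_filter(coh)
  expect_setequal(out$length_um, c(3.0, 4.2, 2.0, 5.0))  # closed interval
  log <- filter_log(out)
  expect_setequal(log$id[log$flag == "length"], c("c1", "c3"))
})

test_that("dwell force collapse flags detachment; smooth relaxation does not", {
  mk_dwell <- function(f) {
    n <- length(f)
    tr <- tether_trace(t = seq_len(n) * 0.1, f1 = f, f2 = -f,
                       trap1 = rep(0, n), trap2 = rep(5, n),
                       phase = rep("dwell", n),
                       meta = chromosome_meta(id = "d", length_um = 3))
    attr(tr, "baseline_sd") <- c(f1 = 0.5, f2 = 0.5)
    tr
  }
  # abrupt step to ~0 at t = 30 s
  f_det <- c(rep(60, 300), rep(0.1, 300))
  coh <- cohort(list(mk_dwell(f_det)))
  out <- suppressWarnings(qc_filter(coh))
  expect_equal(nrow(out), 0)
  expect_true("detached" %in% filter_log(out)$flag)

  # smooth exponential relaxation to near zero is kept
  f_rel <- 60 * exp(-(seq_len(600) * 0.1) / 5)
  coh2 <- cohort(list(mk_dwell(f_rel)))
  expect_equal(nrow(qc_filter(coh2)), 1)
})
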