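test_that("wide and long CSV layouts parse shape-preservingly", {
  wide <- tempfile(fileext = ".csv")
  write_fixture_csv(wide, n_cells = 3, t_end = 60)
  traces <- read_traces(wide, "wide", stim_time = 20)
  expect_length(traces, 3L)
  expect_named(traces, c("cell_1", "cell_2", "cell_3"))
  expect_true(all(vapply(traces, function(tr) length(tr$times) == 121L,
                         logical(1))))

  # long layout with interleaved cells sorts by time within cell
  long <- tempfile(fileext = ".csv")
  df <- data.frame(cell_id = rep(c("a", "b"), 40),
                   time_s = rep(0:39, each = 2),
                   intensity = rep(c(100, 120), 40))
  utils::write.csv(df, long, row.names = FALSE)
  lt <- read_traces(long, "long", stim_time = 25)
  expect_length(lt, 2L)
  expect_equal(lt$a$times, as.numeric(0:39))
  expect_equal(lt$b$intensities, rep(120, 40))
})

test_that("malformed trace files are rejected with informative errors", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("time_s,c1", "0,100", "1,oops", "2,100"), p)
  expect_error(read_traces(p, "wide", stim_time = 1.5), "row 2")

  writeLines(c("time_s,c1", "0,100", "1,100", "1,100", "25,100"), p)
  expect_error(read_traces(p, "wide", stim_time = 20), "increasing")
})

test_that("write_traces/read_traces round-trips both layouts exactly", {
  sim <- simulate_cells(n_per_class = 2, classes = c("SS", "SU"),
                        duration_s = 200, stim_time = 30, seed = 7)
  for (layout in c("wide", "long")) {
    p <- tempfile(fileext = ".csv")
    write_traces(sim$traces, p, layout)
    back <- read_traces(p, layout, stim_time = 30)
    expect_named(back, names(sim$traces))
    for (cid in names(back)) {
      expect_equal(back[[cid]]$times, sim$traces[[cid]]$times,
                   tolerance = 1e-12)
      expect_equal(back[[cid]]$intensities, sim$traces[[cid]]$intensities,
                   tolerance = 1e-12)
    }
  }
})

test_that("normalization divides by the baseline-window mean", {
  cfg <- analysis_config()
  # constant trace: ratio identically 1, f0 recovered
  times <- seq(0, 60, by = 0.5)
  tr <- ca_trace("c", times, rep(100, length(times)), stim_time = 25)
  nt <- normalize_trace(tr, cfg)
  expect_equal(nt$f0, 100)
  expect_true(all(nt$ratio == 1))

  # hand-checkable arithmetic: baseline {90,100,110}, post-stim 150
  tr2 <- ca_trace("c2", c(0, 1, 2, 3), c(90, 100, 110, 150), stim_time = 2.5)
  nt2 <- normalize_trace(tr2, analysis_config(baseline_window_s = 3))
  expect_equal(nt2$f0, 100)
  expect_equal(nt2$ratio[4], 1.5)
  # baseline-window mean of the ratio is 1 by construction
  expect_equal(mean(nt2$ratio[1:3]), 1, tolerance = 1e-12)
})

test_that("ratio is invariant under uniform intensity rescaling", {
  cfg <- analysis_config()
  set.seed(31)
  times <- seq(0, 100, by = 0.5)
  base <- 100 * (1 + 2 * exp(-pmax(times - 42, 0) / 8) *
                   pmin(pmax((times - 40) / 2, 0), 1)) *
    (1 + rnorm(length(times), sd = 0.01))
  tr <- ca_trace("c", times, base, stim_time = 40)
  ref <- normalize_trace(tr, cfg)$ratio
  for (k in runif(5, 0.01, 50)) {
    sc <- normalize_trace(ca_trace("c", times, k * base, 40), cfg)$ratio
    expect_equal(sc, ref, tolerance = 1e-12)
  }
})

test_that("normalization is idempotent on a unit-baseline trace", {
  nt <- ramp_ntrace()
  tr <- ca_trace("fx", nt$times, nt$ratio, nt$stim_time)  # ratio as input
  renorm <- normalize_trace(tr, analysis_config())
  expect_equal(renorm$ratio, nt$ratio, tolerance = 1e-12)
  expect_equal(renorm$f0, 1, tolerance = 1e-12)
})

test_that("pre-stimulus activity is flagged by the responder threshold", {
  cfg <- analysis_config()
  times <- seq(0, 40, by = 0.5)
  quiet <- ntrace_from_ratio(times, rep(1.02, length(times)), stim = 25)
  expect_false(excluded_prestim(quiet, cfg))

  active <- rep(1, length(times)); active[times == 10] <- 1.30
  expect_true(excluded_prestim(ntrace_from_ratio(times, active, 25), cfg))

  # boundary: exactly 1.045 does not trip the strict inequality
  edge <- rep(1, length(times)); edge[times == 10] <- 1.045
  expect_false(excluded_prestim(ntrace_from_ratio(times, edge, 25), cfg))
})

test_that("normalized output writes a per-cell F0 sidecar", {
  sim <- simulate_cells(n_per_class = 1, classes = c("SS", "SU"),
                        duration_s = 200, stim_time = 30, seed = 5)
  nts <- lapply(sim$traces, normalize_trace)
  p <- tempfile(fileext = ".csv")
  write_normalized(nts, p)
  expect_true(file.exists(p))
  meta <- yaml::read_yaml(paste0(p, ".meta.yaml"))
  expect_named(meta, names(sim$traces))
  expect_equal(meta[[1]]$f0, nts[[1]]$f0, tolerance = 1e-6)
})

test_that("config files round-trip and reject unknown keys", {
  cfg <- analysis_config(spike_threshold = 0.5, smooth_window_pts = 13L)
  p <- tempfile(fileext = ".yaml")
  write_config(cfg, p)
  back <- read_config(p)
  expect_equal(back, cfg)
  writeLines("spike_treshold: 0.5", p)
  expect_error(read_config(p), "unknown config keys")
  expect_error(analysis_config(rise_fraction_low = 0.95), "rise_fraction")
})
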