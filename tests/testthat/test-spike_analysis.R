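cfg <- analysis_config()

test_that("detrending zeroes constants and pure linear trends", {
  times <- seq(0, 600, by = 0.5)
  const <- ntrace_from_ratio(times, rep(1.3, length(times)), stim = 30)
  expect_true(all(abs(smooth_detrend(const, cfg)$values) < 1e-12))

  # symmetric truncated window: the moving average of a line is the line
  line <- ntrace_from_ratio(times, 1 + 0.001 * times, stim = 30)
  expect_true(all(abs(smooth_detrend(line, cfg)$values) < 1e-12))

  short <- ntrace_from_ratio(seq(0, 10, 0.5), rep(1, 21), stim = 5)
  expect_error(smooth_detrend(short, cfg), "shorter than the smoothing")
})

test_that("narrow pulses keep roughly (1 - width/window) of their height", {
  dt <- 0.125  # 8 Hz: 50 samples = 6.25 s
  times <- seq(0, 200, by = dt)
  h <- 2; w_pulse <- 1.25
  r <- ifelse(times >= 100 & times < 100 + w_pulse, 1 + h, 1)
  det <- smooth_detrend(ntrace_from_ratio(times, r, 30), cfg)
  expect_equal(max(det$values), h * (1 - w_pulse / 6.375), tolerance = 0.05)
})

test_that("spike detection applies threshold and minimum width", {
  times <- seq(0, 300, by = 0.5)
  flat <- detrended_series(times, rep(0, length(times)))
  expect_equal(detect_spikes(flat, cfg)$count, 0L)

  pulse <- function(w) {
    v <- numeric(length(times)); v[times >= 100 & times <= 100 + w] <- 1
    detrended_series(times, v)
  }
  expect_equal(detect_spikes(pulse(10), cfg)$count, 1L)
  expect_equal(detect_spikes(pulse(3), cfg)$count, 0L)  # fails 5 s minimum

  two <- numeric(length(times))
  two[times >= 50 & times <= 60] <- 1.2
  two[times >= 200 & times <= 212] <- c(seq(0.5, 2, length.out = 13),
                                        rep(2, 12))
  sp <- detect_spikes(detrended_series(times, two), cfg)
  expect_equal(sp$count, 2L)
  expect_equal(sp$mean_isi_s, diff(sp$spike_peak_times_s))
  expect_true(all(sp$offsets_s - sp$onsets_s >= cfg$spike_min_width_s))
})

test_that("detect_spikes agrees with a brute-force run scan", {
  set.seed(77)
  for (rep in 1:25) {
    times <- seq(0, 120, by = 0.5)
    v <- rnorm(length(times), sd = 0.3)
    n_p <- sample(0:4, 1)
    for (k in seq_len(n_p)) {
      c0 <- runif(1, 10, 110); w <- runif(1, 2, 12)
      v[times >= c0 & times <= c0 + w] <- v[times >= c0 & times <= c0 + w] +
        runif(1, 0.5, 2)
    }
    got <- detect_spikes(detrended_series(times, v), cfg)
    want <- oracle_spikes(times, v, cfg$spike_threshold,
                          cfg$spike_min_width_s)
    expect_equal(got$count, want$count)
    expect_equal(got$spike_peak_times_s, want$peak_times)
  }
})

test_that("raising the threshold or widening the minimum never adds spikes", {
  set.seed(123)
  times <- seq(0, 200, by = 0.5)
  v <- abs(rnorm(length(times), sd = 0.4))
  v[times >= 50 & times <= 65] <- v[times >= 50 & times <= 65] + 1.5
  counts_thr <- vapply(c(0.2, 0.4, 0.8, 1.2, 2), function(th)
    detect_spikes(detrended_series(times, v),
                  analysis_config(spike_threshold = th))$count, integer(1))
  expect_true(all(diff(counts_thr) <= 0))
  counts_w <- vapply(c(1, 5, 10, 20), function(w)
    detect_spikes(detrended_series(times, v),
                  analysis_config(spike_min_width_s = w))$count, integer(1))
  expect_true(all(diff(counts_w) <= 0))
})

test_that("the four class rules and their gaps are applied verbatim", {
  expect_equal(classify_response(1, NA, 100, cfg), "SS")
  expect_equal(classify_response(4, 60, 1500, cfg), "BS")   # 240 <= 300
  expect_equal(classify_response(6, 80, 900, cfg), "RS")    # 480 > 300
  expect_equal(classify_response(1, NA, 800, cfg), "SU")
  # rule gap: tight doublet without burst-level AUC, boundary AUC = 500
  expect_equal(classify_response(2, 100, 500, cfg), "UNCLASSIFIED")
  expect_equal(classify_response(0, NA, 50, cfg), "UNCLASSIFIED")
  expect_equal(classify_response(1, NA, 500, cfg), "UNCLASSIFIED")
  expect_error(classify_response(-1, NA, 100, cfg), "non-negative")
  expect_error(classify_response(2, 50, -10, cfg), "non-negative")
})

test_that("every count/ISI/AUC combination receives exactly one label", {
  for (count in 0:4) for (auc in c(100, 500, 800, 1000, 1500)) {
    isis <- if (count > 1) c(10, 75, 150, 400) else NA
    for (isi in isis) {
      lab <- classify_response(count, isi, auc, cfg)
      expect_length(lab, 1L)
      expect_true(lab %in% response_classes())
    }
  }
})

test_that("classification recovers generator ground truth per archetype", {
  for (cls in c("SS", "BS", "RS", "SU")) {
    sim <- simulate_cells(n_per_class = 10, classes = cls,
                          noise_sd = 0.01, seed = 200)
    res <- classify_population(sim$traces)
    expect_gte(mean(res$cells$label == cls), 0.95)
    expect_equal(sum(res$table), sum(res$cells$responder))
  }
})

test_that("class counts partition the responding cells", {
  sim <- simulate_cells(n_per_class = 5, seed = 11)
  res <- classify_population(sim$traces)
  expect_equal(nrow(res$cells), 20L)
  expect_equal(sum(res$table), sum(res$cells$responder))
  # determinism: identical inputs give identical labels
  res2 <- classify_population(sim$traces)
  expect_identical(res$cells$label, res2$cells$label)
  # empty input gives an all-zero table
  expect_true(all(class_count_table(character(0)) == 0L))
})
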