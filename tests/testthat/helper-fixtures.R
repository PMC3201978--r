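# Fixture builders and independent oracles shared across test files.

# Build a normalized trace directly from a ratio series (unit baseline),
# bypassing normalize_trace(), for closed-form kinetics checks.
ntrace_from_ratio <- function(times, ratio, stim_time, cell_id = "fx") {
  structure(
    list(cell_id = cell_id, times = times, ratio = ratio, f0 = 100,
         baseline_sd_ratio = stats::sd(ratio[times < stim_time]),
         stim_time = stim_time),
    class = "ca_ntrace"
  )
}

# Ratio 1 until stim, linear ramp to `peak` over `ramp_s`, then held.
ramp_ntrace <- function(stim = 20, ramp_s = 10, peak = 2, dt = 0.1,
                        t_end = 50) {
  times <- seq(0, t_end, by = dt)
  ratio <- ifelse(times < stim, 1,
                  pmin(1 + (peak - 1) * (times - stim) / ramp_s, peak))
  ntrace_from_ratio(times, ratio, stim)
}

# Ratio 1 until stim, rectangular pulse at `height` for `width_s`, record
# ends with the pulse still up unless t_end extends past it.
rect_ntrace <- function(stim = 20, height = 2, width_s = 100, dt = 0.5,
                        t_end = stim + width_s) {
  times <- seq(0, t_end, by = dt)
  ratio <- ifelse(times >= stim & times <= stim + width_s, height, 1)
  ntrace_from_ratio(times, ratio, stim)
}

# Detrended-series container for spike-detection tests.
detrended_series <- function(times, values, cell_id = "fx") {
  structure(list(cell_id = cell_id, times = times, values = values),
            class = "ca_detrended")
}

# Brute-force run-length spike scan, independent of detect_spikes().
oracle_spikes <- function(times, v, threshold, min_width_s) {
  runs <- list()
  start <- NA_integer_
  for (i in seq_along(v)) {
    if (v[i] > threshold && is.na(start)) start <- i
    if ((v[i] <= threshold || i == length(v)) && !is.na(start)) {
      end <- if (v[i] <= threshold) i - 1L else i
      runs[[length(runs) + 1L]] <- c(start, end)
      start <- NA_integer_
    }
  }
  peaks <- numeric(0)
  for (r in runs) {
    if (times[r[2L]] - times[r[1L]] >= min_width_s) {
      j <- r[1L] - 1L + which.max(v[r[1L]:r[2L]])
      peaks <- c(peaks, times[j])
    }
  }
  list(count = length(peaks), peak_times = peaks)
}

# Exact two-sided Fisher p by direct table enumeration with choose(),
# independent of the dhyper-based implementation.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pk <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- pk[ks == tab[1, 1]]
  sum(pk[pk <= p_obs + 1e-12])
}

# Wide-format trace CSV of simple synthetic cells, for I/O and CLI tests.
write_fixture_csv <- function(path, stim = 20, n_cells = 3, dt = 0.5,
                              t_end = 60, amp = c(2, 3, 0)) {
  times <- seq(0, t_end, by = dt)
  df <- data.frame(time_s = times)
  for (i in seq_len(n_cells)) {
    a <- amp[(i - 1) %% length(amp) + 1]
    ratio <- 1 + a * exp(-pmax(times - stim - 2, 0) / 5) *
      pmin(pmax((times - stim) / 2, 0), 1)
    df[[paste0("cell_", i)]] <- 100 * ratio
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
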