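#' Responder test
#'
#' A cell is a responder if its post-stimulus F/F0 exceeds the responder
#' threshold (default 1.045-fold, strictly). With
#' `responder_mode = "adaptive_3sd"` the threshold is instead three baseline
#' standard deviations above the pre-stimulation mean of 1.
#'
#' @param ntrace A `ca_ntrace` from [normalize_trace()].
#' @param config An [analysis_config()].
#' @return Logical scalar.
#' @export
is_responder <- function(ntrace, config = analysis_config()) {
  stopifnot(inherits(ntrace, "ca_ntrace"))
  post <- ntrace$ratio[ntrace$times >= ntrace$stim_time]
  max(post) > responder_threshold(ntrace, config)
}

#' Peak amplitude
#'
#' The largest post-stimulus fold change Fmax/F0 and the earliest time at
#' which it is attained.
#'
#' @param ntrace A `ca_ntrace`.
#' @return List with `peak` (fold) and `t_peak_s` (seconds).
#' @export
peak_amplitude <- function(ntrace) {
  stopifnot(inherits(ntrace, "ca_ntrace"))
  sel <- which(ntrace$times >= ntrace$stim_time)
  i <- sel[which.max(ntrace$ratio[sel])]
  list(peak = ntrace$ratio[i], t_peak_s = ntrace$times[i])
}

# First time the ratio reaches `level`, searching the segment from the last
# pre-stimulus sample up to t_peak, with linear interpolation between
# samples. Crossing times are clamped to stim_time so latency cannot be
# negative when a step sits exactly on the stimulus.
crossing_time <- function(ntrace, level, t_peak_s) {
  times <- ntrace$times; ratio <- ntrace$ratio
  lo <- max(1L, max(which(times < ntrace$stim_time), 0L))
  hi <- max(which(times <= t_peak_s))
  seg <- lo:hi
  above <- which(ratio[seg] >= level)
  if (!length(above)) return(NA_real_)
  i <- seg[above[1L]]
  if (i == seg[1L] || ratio[i - 1L] >= level) {
    tc <- times[i]
  } else {
    # linear interpolation across the bracketing interval
    f <- (level - ratio[i - 1L]) / (ratio[i] - ratio[i - 1L])
    tc <- times[i - 1L] + f * (times[i] - times[i - 1L])
  }
  max(tc, ntrace$stim_time)
}

#' Rise time (10% to 90% of peak)
#'
#' Time for the response to climb from `rise_fraction_low` to
#' `rise_fraction_high` of the baseline-subtracted peak amplitude
#' (A = peak - 1). Crossings are located at or before the peak with linear
#' interpolation between samples.
#'
#' @inheritParams is_responder
#' @return Seconds, or `NA` for a non-responder.
#' @export
rise_time <- function(ntrace, config = analysis_config()) {
  if (!is_responder(ntrace, config)) return(NA_real_)
  pk <- peak_amplitude(ntrace)
  a <- pk$peak - 1
  t10 <- crossing_time(ntrace, 1 + config$rise_fraction_low * a, pk$t_peak_s)
  t90 <- crossing_time(ntrace, 1 + config$rise_fraction_high * a, pk$t_peak_s)
  t90 - t10
}

#' Latency to 10% of peak
#'
#' Time from agonist addition to the first crossing of
#' `rise_fraction_low` of the baseline-subtracted peak amplitude.
#'
#' @inheritParams is_responder
#' @return Seconds, or `NA` for a non-responder.
#' @export
latency <- function(ntrace, config = analysis_config()) {
  if (!is_responder(ntrace, config)) return(NA_real_)
  pk <- peak_amplitude(ntrace)
  t10 <- crossing_time(ntrace, 1 + config$rise_fraction_low * (pk$peak - 1),
                       pk$t_peak_s)
  t10 - ntrace$stim_time
}

#' Area under the curve
#'
#' Trapezoidal integral of the normalized trace from the 10%-of-peak
#' crossing to the end of the recording. With
#' `config$auc_integrand = "raw_ratio"` (default) the integrand is F/F0
#' itself; with `"baseline_subtracted"` it is F/F0 - 1.
#'
#' @inheritParams is_responder
#' @return Fold-seconds, or `NA` for a non-responder.
#' @export
area_under_curve <- function(ntrace, config = analysis_config()) {
  if (!is_responder(ntrace, config)) return(NA_real_)
  pk <- peak_amplitude(ntrace)
  level10 <- 1 + config$rise_fraction_low * (pk$peak - 1)
  t10 <- crossing_time(ntrace, level10, pk$t_peak_s)
  times <- ntrace$times; ratio <- ntrace$ratio
  keep <- times > t10
  # interpolated value of the ratio at t10 starts the integration grid
  tt <- c(t10, times[keep])
  yy <- c(stats::approx(times, ratio, xout = t10)$y, ratio[keep])
  if (config$auc_integrand == "baseline_subtracted") yy <- yy - 1
  trapz(tt, yy)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Kinetic feature set for one cell
#'
#' Applies the responder rule and, for responders, computes peak amplitude,
#' 10-90% rise time, latency to 10% of peak and AUC. Non-responders carry
#' `NA` for every feature except `peak` and `t_peak_s`.
#'
#' @inheritParams is_responder
#' @return One-row data frame with columns `cell_id`, `responder`,
#'   `excluded`, `peak`, `t_peak_s`, `t10_s`, `rise_time_s`, `latency_s`,
#'   `auc`.
#' @export
kinetic_features <- function(ntrace, config = analysis_config()) {
  stopifnot(inherits(ntrace, "ca_ntrace"))
  excl <- excluded_prestim(ntrace, config)
  resp <- is_responder(ntrace, config)
  pk <- peak_amplitude(ntrace)
  out <- data.frame(
    cell_id = ntrace$cell_id, responder = resp, excluded = excl,
    peak = pk$peak, t_peak_s = pk$t_peak_s,
    t10_s = NA_real_, rise_time_s = NA_real_, latency_s = NA_real_,
    auc = NA_real_, stringsAsFactors = FALSE
  )
  if (resp) {
    lat <- latency(ntrace, config)
    out$t10_s <- ntrace$stim_time + lat
    out$latency_s <- lat
    out$rise_time_s <- rise_time(ntrace, config)
    out$auc <- area_under_curve(ntrace, config)
  }
  out
}

#' Kinetic features for a collection of traces
#'
#' Normalizes each raw trace and extracts the kinetic feature set. Excluded
#' cells (pre-stimulus activity) are flagged but retained.
#'
#' @param traces List of [ca_trace] objects (or `ca_ntrace`, used as-is).
#' @param config An [analysis_config()].
#' @return Data frame with one row per cell, as in [kinetic_features()].
#' @export
extract_features <- function(traces, config = analysis_config()) {
  rows <- lapply(traces, function(tr) {
    nt <- if (inherits(tr, "ca_ntrace")) tr else normalize_trace(tr, config)
    kinetic_features(nt, config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
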