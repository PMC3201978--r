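#' Moving-average detrend
#'
#' Smooths the normalized trace with a centered moving average of
#' `config$smooth_window_pts` adjacent samples and subtracts the smoothed
#' copy from the original, removing slow drift and plateaus so that fast
#' transients stand out for threshold-based spike detection. At the edges
#' the window shrinks symmetrically (no padding), so a constant trace
#' detrends to exactly zero and a pure linear trend detrends to zero
#' everywhere.
#'
#' @param ntrace A `ca_ntrace`.
#' @param config An [analysis_config()].
#' @return An object of class `ca_detrended` with `cell_id`, `times` and
#'   `values` (detrended ratio, dimensionless).
#' @export
smooth_detrend <- function(ntrace, config = analysis_config()) {
  stopifnot(inherits(ntrace, "ca_ntrace"))
  validate_config(config)
  x <- ntrace$ratio
  n <- length(x)
  if (n <= config$smooth_window_pts)
    stop("trace shorter than the smoothing window (", config$smooth_window_pts,
         " samples) for cell ", ntrace$cell_id, call. = FALSE)
  half <- config$smooth_window_pts %/% 2L
  i <- seq_len(n)
  k <- pmin(i - 1L, n - i, half)
  s <- cumsum(c(0, x))
  smoothed <- (s[i + k + 1L] - s[i - k]) / (2 * k + 1)
  structure(
    list(cell_id = ntrace$cell_id, times = ntrace$times,
         values = x - smoothed),
    class = "ca_detrended"
  )
}

#' Spike detection on a detrended trace
#'
#' Maximal contiguous runs of detrended values strictly above
#' `config$spike_threshold` that last at least `config$spike_min_width_s`
#' seconds (first to last supra-threshold sample) are counted as spikes.
#' The spike time is the time of the run maximum (earliest sample on a
#' tie); the mean interspike interval (ISI) is the mean spacing of
#' successive spike times, defined when there are at least two spikes.
#'
#' @param detrended A `ca_detrended` from [smooth_detrend()].
#' @param config An [analysis_config()].
#' @return An object of class `ca_spikes` with `cell_id`,
#'   `spike_peak_times_s`, `onsets_s`, `offsets_s`, `count` and
#'   `mean_isi_s` (`NA` when `count < 2`).
#' @export
detect_spikes <- function(detrended, config = analysis_config()) {
  stopifnot(inherits(detrended, "ca_detrended"))
  validate_config(config)
  v <- detrended$values
  times <- detrended$times
  above <- v > config$spike_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts <- starts[r$values]
  ends <- ends[r$values]
  if (length(starts)) {
    widths <- times[ends] - times[starts]
    keep <- widths >= config$spike_min_width_s
    starts <- starts[keep]; ends <- ends[keep]
  }
  peaks <- mapply(function(s, e) s - 1L + which.max(v[s:e]), starts, ends)
  peak_times <- times[as.integer(peaks)]
  count <- length(starts)
  structure(
    list(cell_id = detrended$cell_id,
         spike_peak_times_s = peak_times,
         onsets_s = times[starts], offsets_s = times[ends],
         count = count,
         mean_isi_s = if (count >= 2L) mean(diff(peak_times)) else NA_real_),
    class = "ca_spikes"
  )
}

#' @export
print.ca_spikes <- function(x, ...) {
  cat(sprintf("<ca_spikes> cell %s: %d spike(s)", x$cell_id, x$count))
  if (!is.na(x$mean_isi_s)) cat(sprintf(", mean ISI %.1f s", x$mean_isi_s))
  cat("\n")
  invisible(x)
}

#' Response classes
#'
#' The five labels assigned by [classify_response()]: single spike (SS),
#' burst of spikes (BS), repetitive spikes (RS), sustained response (SU),
#' and UNCLASSIFIED for feature combinations matching none of the four
#' rules.
#' @export
response_classes <- function() c("SS", "BS", "RS", "SU", "UNCLASSIFIED")

#' Classify a long-term response
#'
#' Applies the four class rules to the spike count, the mean interspike
#' interval and the AUC of a responding cell:
#' * SS (single spike): count = 1 and AUC < `class_auc_low`;
#' * BS (burst): count > 1, ISI x count <= `class_isi_product`, and
#'   AUC > `class_auc_high`;
#' * RS (repetitive): count > 1 and ISI x count > `class_isi_product`;
#' * SU (sustained): count = 1 and AUC > `class_auc_low`.
#'
#' Combinations satisfying no rule (count 0, AUC exactly on the SS/SU
#' boundary, or a tight multi-spike train without burst-level AUC) are
#' labelled UNCLASSIFIED rather than forced into a nearest class.
#'
#' @param count Number of detected spikes (non-negative integer).
#' @param mean_isi_s Mean interspike interval in seconds (`NA` when
#'   `count < 2`).
#' @param auc Area under the curve (fold-seconds).
#' @param config An [analysis_config()].
#' @return One of `response_classes()`.
#' @export
classify_response <- function(count, mean_isi_s, auc,
                              config = analysis_config()) {
  if (!is.finite(count) || count < 0 || count != round(count))
    stop("count must be a non-negative integer", call. = FALSE)
  if (!is.finite(auc) || auc < 0)
    stop("auc must be a non-negative number", call. = FALSE)
  if (count > 1L) {
    if (!is.finite(mean_isi_s) || mean_isi_s < 0)
      stop("mean_isi_s must be defined and non-negative when count > 1",
           call. = FALSE)
    prod <- mean_isi_s * count
    if (prod > config$class_isi_product) return("RS")
    if (auc > config$class_auc_high) return("BS")
    return("UNCLASSIFIED")
  }
  if (count == 1L) {
    if (auc < config$class_auc_low) return("SS")
    if (auc > config$class_auc_low) return("SU")
  }
  "UNCLASSIFIED"
}

#' Classify a population of traces
#'
#' Runs the full long-term pipeline per cell: normalize, responder test,
#' detrend, spike detection, AUC, class rules. Non-responders are labelled
#' `NR` and are not counted in the class table; excluded cells
#' (pre-stimulus activity) keep their flag but are still processed.
#'
#' For classification the AUC is computed with the baseline-subtracted
#' integrand unless `config$auc_integrand` was set explicitly via
#' `classify_integrand`: over a 20-minute recording the baseline itself
#' integrates to more fold-seconds than the class boundaries, so the
#' raw-ratio reading would leave the single-spike class empty.
#'
#' @param traces List of [ca_trace] (or `ca_ntrace`) objects.
#' @param config An [analysis_config()].
#' @param classify_integrand Integrand used for the classification AUC;
#'   default `"baseline_subtracted"`.
#' @return List with `cells` (data frame: `cell_id`, `responder`,
#'   `excluded`, `spike_count`, `mean_isi_s`, `auc`, `label`) and `table`
#'   (named integer vector of counts over `response_classes()`).
#' @export
classify_population <- function(traces, config = analysis_config(),
                                classify_integrand = c("baseline_subtracted",
                                                       "raw_ratio")) {
  classify_integrand <- match.arg(classify_integrand)
  auc_cfg <- config
  auc_cfg$auc_integrand <- classify_integrand
  rows <- lapply(traces, function(tr) {
    nt <- if (inherits(tr, "ca_ntrace")) tr else normalize_trace(tr, config)
    resp <- is_responder(nt, config)
    row <- data.frame(cell_id = nt$cell_id, responder = resp,
                      excluded = excluded_prestim(nt, config),
                      spike_count = NA_integer_, mean_isi_s = NA_real_,
                      auc = NA_real_, label = "NR",
                      stringsAsFactors = FALSE)
    if (resp) {
      sp <- detect_spikes(smooth_detrend(nt, config), config)
      auc <- area_under_curve(nt, auc_cfg)
      row$spike_count <- sp$count
      row$mean_isi_s <- sp$mean_isi_s
      row$auc <- auc
      row$label <- classify_response(sp$count, sp$mean_isi_s, auc, config)
    }
    row
  })
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  list(cells = cells, table = class_count_table(cells$label))
}

#' Tabulate class labels
#'
#' @param labels Character vector of labels from [classify_response()]
#'   (values outside `response_classes()`, e.g. `"NR"`, are ignored).
#' @return Named integer vector of counts over `response_classes()`.
#' @export
class_count_table <- function(labels) {
  cls <- response_classes()
  table(factor(labels[labels %in% cls], levels = cls))
}
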