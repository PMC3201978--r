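#' Analysis configuration
#'
#' Collects every threshold and window used by the pipeline in one validated
#' record, so that a configuration object fully documents an analysis run.
#'
#' @param baseline_window_s Length of the pre-stimulus baseline window in
#'   seconds. F0 is the mean fluorescence over
#'   `[stim_time - baseline_window_s, stim_time)`. Default 20.
#' @param responder_fold Fold-change threshold on F/F0: a cell is a responder
#'   if its post-stimulus ratio exceeds this value (strictly). Default 1.045,
#'   roughly three standard deviations above typical baseline noise.
#' @param responder_mode `"fixed"` uses `responder_fold` as-is;
#'   `"adaptive_3sd"` uses `1 + 3 * baseline_sd_ratio` per cell instead.
#' @param smooth_window_pts Number of adjacent samples averaged to build the
#'   slow trend that is subtracted before spike detection. Default 50
#'   (6.25 s at 8 Hz, 25 s at 2 Hz).
#' @param spike_threshold Threshold on the detrended F/F0 series above which
#'   a contiguous run is a candidate spike. Default 0.4.
#' @param spike_min_width_s Minimum duration in seconds of a supra-threshold
#'   run for it to count as a spike. Default 5.
#' @param class_auc_low AUC boundary (fold*s) separating single-spike from
#'   sustained responses. Default 500.
#' @param class_auc_high AUC boundary (fold*s) required for a burst of
#'   spikes. Default 1000.
#' @param class_isi_product Boundary (seconds) on mean ISI times spike count
#'   separating bursts from repetitive spiking. Default 300.
#' @param auc_integrand `"raw_ratio"` integrates F/F0 itself;
#'   `"baseline_subtracted"` integrates F/F0 - 1. Default `"raw_ratio"`.
#' @param rise_fraction_low,rise_fraction_high Fractions of the
#'   baseline-subtracted peak amplitude defining the rise-time interval.
#'   Defaults 0.10 and 0.90.
#'
#' @return An object of class `ca_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$responder_fold
#' @export
analysis_config <- function(baseline_window_s = 20,
                            responder_fold = 1.045,
                            responder_mode = c("fixed", "adaptive_3sd"),
                            smooth_window_pts = 50L,
                            spike_threshold = 0.4,
                            spike_min_width_s = 5,
                            class_auc_low = 500,
                            class_auc_high = 1000,
                            class_isi_product = 300,
                            auc_integrand = c("raw_ratio", "baseline_subtracted"),
                            rise_fraction_low = 0.10,
                            rise_fraction_high = 0.90) {
  responder_mode <- match.arg(responder_mode)
  auc_integrand <- match.arg(auc_integrand)
  cfg <- list(
    baseline_window_s = as.numeric(baseline_window_s),
    responder_fold = as.numeric(responder_fold),
    responder_mode = responder_mode,
    smooth_window_pts = as.integer(smooth_window_pts),
    spike_threshold = as.numeric(spike_threshold),
    spike_min_width_s = as.numeric(spike_min_width_s),
    class_auc_low = as.numeric(class_auc_low),
    class_auc_high = as.numeric(class_auc_high),
    class_isi_product = as.numeric(class_isi_product),
    auc_integrand = auc_integrand,
    rise_fraction_low = as.numeric(rise_fraction_low),
    rise_fraction_high = as.numeric(rise_fraction_high)
  )
  class(cfg) <- "ca_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "ca_config"))
  num_pos <- c("baseline_window_s", "responder_fold", "spike_threshold",
               "spike_min_width_s", "class_auc_low", "class_auc_high",
               "class_isi_product")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config field '", f, "' must be a single positive number",
           call. = FALSE)
  }
  if (cfg$smooth_window_pts < 2L)
    stop("smooth_window_pts must be at least 2", call. = FALSE)
  if (!(cfg$rise_fraction_low < cfg$rise_fraction_high &&
        cfg$rise_fraction_high < 1 && cfg$rise_fraction_low > 0))
    stop("require 0 < rise_fraction_low < rise_fraction_high < 1",
         call. = FALSE)
  if (cfg$class_auc_low > cfg$class_auc_high)
    stop("class_auc_low must not exceed class_auc_high", call. = FALSE)
  invisible(cfg)
}

#' @export
print.ca_config <- function(x, ...) {
  cat("Calcium-signal analysis configuration\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected so that a stale or misspelled configuration
#' cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file whose keys are arguments of
#'   [analysis_config()].
#' @return A `ca_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to a YAML file
#'
#' @param cfg A `ca_config` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
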