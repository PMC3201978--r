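#' Archetype parameters for synthetic responses
#'
#' Phenomenological parameters for one of the four response archetypes.
#' Transients are modelled as a fast linear rise (2 s) followed by an
#' exponential decay; bursts ride on a slowly decaying envelope and
#' sustained responses hold a plateau to the end of the recording. Only
#' threshold crossings, widths and areas matter to the downstream class
#' rules, and all of those have closed forms for this kernel.
#'
#' Class defaults (2 Hz, 20 min recording, stimulus at 60 s) sit well away
#' from every classification boundary:
#' * SS: one amplitude-3 transient, baseline-subtracted AUC ~ 20 fold-s;
#' * BS: five transients 35 s apart (ISI x n = 175) on an envelope that
#'   integrates to ~1500 fold-s;
#' * RS: eight constant-amplitude transients 120 s apart (ISI x n = 960);
#' * SU: a plateau of 2 fold held to the end (~2200 fold-s).
#'
#' @param class_label One of `"SS"`, `"BS"`, `"RS"`, `"SU"`.
#' @param amplitude Baseline-subtracted spike height (fold).
#' @param onset_s Delay from stimulus to response onset (seconds).
#' @param spike_width_s Decay time constant of a single transient (s).
#' @param decay_tau_s Decay time constant of the burst envelope (s);
#'   unused for other classes.
#' @param n_spikes Number of transients (>= 1).
#' @param isi_s Spacing between transients (s); must exceed
#'   `spike_width_s` for multi-spike classes.
#' @param plateau_level Envelope (BS) or plateau (SU) height (fold).
#' @param noise_sd SD of multiplicative Gaussian intensity noise.
#' @param drift_per_s Linear multiplicative intensity drift per second.
#' @return An object of class `ca_archetype`.
#' @export
archetype_params <- function(class_label = c("SS", "BS", "RS", "SU"),
                             amplitude = NULL, onset_s = 10,
                             spike_width_s = 6, decay_tau_s = 400,
                             n_spikes = NULL, isi_s = NULL,
                             plateau_level = NULL, noise_sd = 0.02,
                             drift_per_s = 2e-5) {
  class_label <- match.arg(class_label)
  def <- switch(class_label,
    SS = list(amplitude = 3, n_spikes = 1L, isi_s = NA_real_,
              plateau_level = 0),
    BS = list(amplitude = 3, n_spikes = 5L, isi_s = 35,
              plateau_level = 4),
    RS = list(amplitude = 3, n_spikes = 8L, isi_s = 120,
              plateau_level = 0),
    SU = list(amplitude = 2, n_spikes = 1L, isi_s = NA_real_,
              plateau_level = 2)
  )
  p <- list(
    class_label = class_label,
    amplitude = if (is.null(amplitude)) def$amplitude else amplitude,
    onset_s = onset_s, spike_width_s = spike_width_s,
    decay_tau_s = decay_tau_s,
    n_spikes = as.integer(if (is.null(n_spikes)) def$n_spikes else n_spikes),
    isi_s = if (is.null(isi_s)) def$isi_s else isi_s,
    plateau_level = if (is.null(plateau_level)) def$plateau_level
                    else plateau_level,
    noise_sd = noise_sd, drift_per_s = drift_per_s
  )
  if (p$amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (p$n_spikes < 1L) stop("n_spikes must be >= 1", call. = FALSE)
  if (p$n_spikes > 1L && (!is.finite(p$isi_s) || p$isi_s <= p$spike_width_s))
    stop("isi_s must exceed spike_width_s for multi-spike archetypes",
         call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(p, class = "ca_archetype")
}

# rise-then-decay transient kernel, vectorized over time-from-onset
transient_kernel <- function(tp, amplitude, tau, rise_s = 2) {
  ramp <- pmin(pmax(tp / rise_s, 0), 1)
  amplitude * ramp * exp(-pmax(tp - rise_s, 0) / tau)
}

#' Generate a synthetic fluorescence trace
#'
#' Builds the archetype's noise-free F/F0 shape, then converts to raw
#' intensity around a constant baseline (default 100 a.u., arbitrary
#' since downstream analysis is scale invariant), applies a linear
#' multiplicative drift and multiplicative Gaussian noise.
#'
#' @param params An [archetype_params()] object.
#' @param duration_s Recording length in seconds (default 1200, the
#'   long-term protocol; use 100 with `rate_hz = 8` for the short-term
#'   protocol).
#' @param rate_hz Sampling rate in Hz (default 2).
#' @param stim_time Agonist addition time in seconds (default 60).
#' @param seed Optional integer seed; the trace is deterministic given it.
#' @param cell_id Cell label.
#' @param baseline_intensity Baseline fluorescence in arbitrary units.
#' @return A [ca_trace].
#' @export
generate_trace <- function(params, duration_s = 1200, rate_hz = 2,
                           stim_time = 60, seed = NULL, cell_id = "cell_1",
                           baseline_intensity = 100) {
  stopifnot(inherits(params, "ca_archetype"), rate_hz > 0)
  if (stim_time + params$onset_s >= duration_s)
    stop("duration must cover the stimulus and response onset",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration_s, by = 1 / rate_hz)
  tp <- times - stim_time - params$onset_s
  shape <- numeric(length(times))
  ramp <- pmin(pmax(tp / 2, 0), 1)
  if (params$class_label %in% c("SS", "BS", "RS")) {
    spacing <- if (params$n_spikes > 1L) params$isi_s else 0
    for (j in seq_len(params$n_spikes) - 1L) {
      amp_j <- if (params$class_label == "BS")
        params$amplitude * 0.9^j else params$amplitude
      shape <- shape + transient_kernel(tp - j * spacing, amp_j,
                                        params$spike_width_s)
    }
  }
  if (params$class_label == "BS") {
    shape <- shape + params$plateau_level * ramp *
      exp(-pmax(tp - 2, 0) / params$decay_tau_s)
  }
  if (params$class_label == "SU") {
    shape <- shape + params$plateau_level * ramp
  }
  ratio <- 1 + shape
  intensity <- baseline_intensity * ratio * (1 + params$drift_per_s * times)
  if (params$noise_sd > 0)
    intensity <- intensity *
      (1 + stats::rnorm(length(times), sd = params$noise_sd))
  ca_trace(cell_id, times, pmax(intensity, 1e-6), stim_time)
}

#' Simulate a labelled population of traces
#'
#' Generates `n_per_class` cells per archetype with mild per-cell
#' variation (lognormal amplitude scatter, uniform onset jitter) on top of
#' the archetype defaults, together with a ground-truth table.
#'
#' @param n_per_class Cells per archetype.
#' @param classes Archetype labels to include.
#' @param noise_sd Multiplicative intensity noise SD applied to each cell.
#' @param duration_s,rate_hz,stim_time Acquisition settings, as in
#'   [generate_trace()].
#' @param seed Integer seed for the whole population.
#' @return List with `traces` (named list of [ca_trace]) and `truth`
#'   (data frame: `cell_id`, `class_label`, `amplitude`, `n_spikes`,
#'   `isi_s`, `plateau_level`, `onset_s`, `noise_sd`).
#' @export
simulate_cells <- function(n_per_class = 50L,
                           classes = c("SS", "BS", "RS", "SU"),
                           noise_sd = 0.02, duration_s = 1200, rate_hz = 2,
                           stim_time = 60, seed = 1L) {
  set.seed(seed)
  traces <- list()
  truth <- list()
  i <- 0L
  for (cls in classes) for (k in seq_len(n_per_class)) {
    i <- i + 1L
    base <- archetype_params(cls, noise_sd = noise_sd)
    scale <- stats::rlnorm(1L, meanlog = 0, sdlog = 0.08)
    p <- archetype_params(
      cls,
      amplitude = base$amplitude * scale,
      plateau_level = if (base$plateau_level > 0)
        base$plateau_level * scale else 0,
      onset_s = base$onset_s + stats::runif(1L, 0, 20),
      noise_sd = noise_sd
    )
    cid <- sprintf("%s_%03d", cls, k)
    traces[[cid]] <- generate_trace(p, duration_s, rate_hz, stim_time,
                                    seed = NULL, cell_id = cid)
    truth[[cid]] <- data.frame(
      cell_id = cid, class_label = cls, amplitude = p$amplitude,
      n_spikes = p$n_spikes, isi_s = p$isi_s,
      plateau_level = p$plateau_level, onset_s = p$onset_s,
      noise_sd = noise_sd, stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(traces = traces, truth = truth)
}

#' Draw a synthetic kinetic-parameter population
#'
#' Samples parameter values from a named right-skewed (or Gaussian)
#' distribution, emulating the skewed per-cell kinetic-parameter
#' populations seen in large imaging screens.
#'
#' @param n Number of cells.
#' @param distribution `"lognormal"` (location = meanlog, scale = sdlog),
#'   `"gamma"` (location = shape, scale = scale) or `"gaussian"`
#'   (location = mean, scale = sd).
#' @param location,scale Distribution parameters (scale > 0).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_population <- function(n, distribution = c("lognormal", "gamma",
                                                    "gaussian"),
                                location = 0, scale = 1, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(n >= 1L, scale > 0)
  if (!is.null(seed)) set.seed(seed)
  switch(distribution,
    lognormal = stats::rlnorm(n, meanlog = location, sdlog = scale),
    gamma = stats::rgamma(n, shape = location, scale = scale),
    gaussian = stats::rnorm(n, mean = location, sd = scale)
  )
}

#' Draw a Gaussian surrogate sample
#'
#' Idealized unit-variance samples used to calibrate the difference
#' metric (defaults: mean 5, SD 1, n 5000).
#'
#' @param n Sample size.
#' @param mean,sd Distribution parameters.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_gaussian_surrogate <- function(n = 5000L, mean = 5, sd = 1,
                                        seed = NULL) {
  stopifnot(n >= 1L, sd > 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mean = mean, sd = sd)
}

#' Write ground truth sidecar for a simulated population
#'
#' @param sim Result of [simulate_cells()].
#' @param dir Output directory (created if needed).
#' @param stem File stem; writes `<stem>_traces.csv` (wide layout) and
#'   `<stem>_truth.csv`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_simulation <- function(sim, dir, stem = "simulated") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tp <- file.path(dir, paste0(stem, "_traces.csv"))
  gp <- file.path(dir, paste0(stem, "_truth.csv"))
  write_traces(sim$traces, tp, layout = "wide")
  utils::write.csv(sim$truth, gp, row.names = FALSE, quote = FALSE)
  invisible(c(traces = tp, truth = gp))
}
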