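#' Construct a raw fluorescence trace
#'
#' A trace is one cell's fluorescence time series together with the time at
#' which the agonist was added. Times are seconds from the start of the
#' recording; intensities are raw fluorescence in arbitrary units.
#'
#' @param cell_id Character label for the cell.
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param intensities Numeric vector of fluorescence values, finite and
#'   positive, same length as `times`.
#' @param stim_time Time of agonist addition in seconds. Must leave room for
#'   at least part of the baseline window before it and at least one sample
#'   at or after it.
#' @param well_id Optional well label.
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(cell_id, times, intensities, stim_time, well_id = NULL) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities) || length(times) < 2L)
    stop("times and intensities must have equal length >= 2", call. = FALSE)
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing", call. = FALSE)
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be finite and > 0", call. = FALSE)
  stim_time <- as.numeric(stim_time)
  if (length(stim_time) != 1L || !is.finite(stim_time))
    stop("stim_time must be a single finite number", call. = FALSE)
  if (stim_time <= times[1L] || stim_time >= times[length(times)])
    stop("stim_time must lie within the recorded time range", call. = FALSE)
  dt <- diff(times)
  if (max(dt) / min(dt) > 1.01)
    warning("sampling interval varies by more than 1% for cell ", cell_id)
  structure(
    list(cell_id = as.character(cell_id), well_id = well_id,
         times = times, intensities = intensities, stim_time = stim_time),
    class = "ca_trace"
  )
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> cell %s: %d samples, %.1f-%.1f s, stimulus at %.1f s\n",
              x$cell_id, length(x$times), x$times[1L],
              x$times[length(x$times)], x$stim_time))
  invisible(x)
}

#' Read per-cell fluorescence traces from CSV
#'
#' Two layouts are supported. Wide: first column `time_s`, one further
#' column per cell (column name = cell id). Long: columns
#' `cell_id,time_s,intensity`; rows may be interleaved and are sorted by
#' time within each cell.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @param stim_time Agonist addition time (seconds), applied to every cell.
#' @return A named list of [ca_trace] objects, in file column (wide) or
#'   first-appearance (long) order.
#' @export
read_traces <- function(path, layout = c("wide", "long"), stim_time) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (layout == "wide") {
    if (ncol(df) < 2L)
      stop("wide layout needs a time column plus at least one cell column",
           call. = FALSE)
    times <- check_numeric_col(df[[1L]], names(df)[1L], path)
    if (any(diff(times) <= 0))
      stop("time column must be strictly increasing in ", path, call. = FALSE)
    cells <- names(df)[-1L]
    traces <- lapply(cells, function(cid) {
      ca_trace(cid, times, check_numeric_col(df[[cid]], cid, path), stim_time)
    })
    names(traces) <- cells
  } else {
    need <- c("cell_id", "time_s", "intensity")
    if (!all(need %in% names(df)))
      stop("long layout needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    df$time_s <- check_numeric_col(df$time_s, "time_s", path)
    df$intensity <- check_numeric_col(df$intensity, "intensity", path)
    ids <- unique(df$cell_id)
    traces <- lapply(ids, function(cid) {
      sub <- df[df$cell_id == cid, , drop = FALSE]
      sub <- sub[order(sub$time_s), , drop = FALSE]
      if (any(diff(sub$time_s) <= 0))
        stop("repeated time value for cell ", cid, " in ", path,
             call. = FALSE)
      ca_trace(cid, sub$time_s, sub$intensity, stim_time)
    })
    names(traces) <- ids
  }
  traces
}

check_numeric_col <- function(x, name, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad))
    stop(sprintf("non-numeric or missing value in column '%s', row %d of %s",
                 name, bad[1L], path), call. = FALSE)
  v
}

#' Write traces to CSV
#'
#' Inverse of [read_traces()]. In wide layout all traces must share one
#' time vector.
#'
#' @param traces List of [ca_trace] objects.
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(length(traces) >= 1L)
  if (layout == "wide") {
    t0 <- traces[[1L]]$times
    for (tr in traces)
      if (!isTRUE(all.equal(tr$times, t0)))
        stop("wide layout requires a shared time vector", call. = FALSE)
    df <- data.frame(time_s = t0, check.names = FALSE)
    for (tr in traces) df[[tr$cell_id]] <- tr$intensities
  } else {
    df <- do.call(rbind, lapply(traces, function(tr)
      data.frame(cell_id = tr$cell_id, time_s = tr$times,
                 intensity = tr$intensities)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a trace to F/F0
#'
#' F0 is the arithmetic mean fluorescence over the baseline window
#' `[stim_time - baseline_window_s, stim_time)`; the normalized series is
#' the pointwise ratio F(t)/F0.
#'
#' @param trace A [ca_trace].
#' @param config An [analysis_config()].
#' @return An object of class `ca_ntrace` with fields `cell_id`, `times`,
#'   `ratio`, `f0`, `baseline_sd_ratio` (SD of the baseline ratio) and
#'   `stim_time`.
#' @export
normalize_trace <- function(trace, config = analysis_config()) {
  stopifnot(inherits(trace, "ca_trace"))
  validate_config(config)
  idx <- baseline_idx(trace$times, trace$stim_time, config$baseline_window_s)
  if (length(idx) < 2L)
    stop("fewer than 2 samples in the baseline window for cell ",
         trace$cell_id, call. = FALSE)
  f0 <- mean(trace$intensities[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("non-positive baseline mean for cell ", trace$cell_id, call. = FALSE)
  ratio <- trace$intensities / f0
  structure(
    list(cell_id = trace$cell_id, times = trace$times, ratio = ratio,
         f0 = f0, baseline_sd_ratio = stats::sd(ratio[idx]),
         stim_time = trace$stim_time),
    class = "ca_ntrace"
  )
}

baseline_idx <- function(times, stim_time, baseline_window_s) {
  which(times >= stim_time - baseline_window_s & times < stim_time)
}

#' @export
print.ca_ntrace <- function(x, ...) {
  cat(sprintf("<ca_ntrace> cell %s: F0 = %.3g, baseline SD = %.4f, stimulus at %.1f s\n",
              x$cell_id, x$f0, x$baseline_sd_ratio, x$stim_time))
  invisible(x)
}

#' Flag pre-stimulus activity
#'
#' Cells whose calcium signal starts before the agonist is added cannot be
#' attributed to the stimulus and are flagged for exclusion. The criterion
#' is any pre-stimulus ratio sample strictly exceeding the responder
#' threshold (fixed or adaptive, per `config$responder_mode`).
#'
#' @param ntrace A `ca_ntrace`.
#' @param config An [analysis_config()].
#' @return `TRUE` if the cell should be excluded from further analysis.
#' @export
excluded_prestim <- function(ntrace, config = analysis_config()) {
  stopifnot(inherits(ntrace, "ca_ntrace"))
  pre <- ntrace$ratio[ntrace$times < ntrace$stim_time]
  any(pre > responder_threshold(ntrace, config))
}

responder_threshold <- function(ntrace, config) {
  if (config$responder_mode == "adaptive_3sd")
    1 + 3 * ntrace$baseline_sd_ratio
  else
    config$responder_fold
}

#' Write normalized traces with an F0 sidecar
#'
#' Writes a long-format CSV (`cell_id,time_s,ratio`) and a YAML sidecar
#' (`<path>.meta.yaml`) recording F0, the baseline ratio SD and the
#' stimulus time per cell.
#'
#' @param ntraces List of `ca_ntrace` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(ntraces, path) {
  df <- do.call(rbind, lapply(ntraces, function(nt)
    data.frame(cell_id = nt$cell_id, time_s = nt$times, ratio = nt$ratio)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- lapply(ntraces, function(nt)
    list(f0 = nt$f0, baseline_sd_ratio = nt$baseline_sd_ratio,
         stim_time = nt$stim_time))
  names(meta) <- vapply(ntraces, `[[`, "", "cell_id")
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}
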