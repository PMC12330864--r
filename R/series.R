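#' Multichannel series container
#'
#' Light S3 container for a channels x samples recording: the trajectory
#' \eqn{u_t} that all dynamics analyses consume. Amplitudes are in whatever
#' units the acquisition produced (typically uV); none of the dynamics
#' metrics depend on the global scale.
#'
#' @param values numeric matrix, channels x samples.
#' @param rate sampling rate in samples/s (> 0).
#' @param channel_names optional character vector, one per channel.
#' @param meta list of provenance entries (filters applied, coarse-grain
#'   window, phase boundaries, ...). Free-form; the preprocessing verbs
#'   append to it.
#' @return an object of class `mc_series`.
#' @export
mc_series <- function(values, rate, channel_names = NULL, meta = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(values)))
  if (length(channel_names) != nrow(values))
    stop("`channel_names` length must equal the number of channels")
  rownames(values) <- channel_names
  structure(list(values = values, rate = rate,
                 channel_names = as.character(channel_names), meta = meta),
            class = "mc_series")
}

#' @export
print.mc_series <- function(x, ...) {
  cat(sprintf("<mc_series> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$values), ncol(x$values), x$rate,
              ncol(x$values) / x$rate))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mc_series <- function(x) dim(x$values)

n_samples <- function(series) ncol(series$values)
n_channels <- function(series) nrow(series$values)

stopifnot_series <- function(series) {
  if (!inherits(series, "mc_series"))
    stop("expected an `mc_series` object")
  invisible(series)
}

#' Reject faulty channels
#'
#' Drops channels that are flat (variance below `flat_var`), saturated
#' (absolute amplitude reaching `sat_abs`), or explicitly listed. Subjects
#' with more than five faulty channels are flagged for exclusion from group
#' analyses.
#'
#' The published protocol rejects channels "qualitatively"; here the rule is
#' operationalized as variance/saturation thresholds with an explicit-list
#' override, and both defaults are recorded in the report.
#'
#' @param series an [mc_series()].
#' @param reject_list explicit channel names to drop (overrides thresholds
#'   when non-`NULL`; an empty character vector is the identity).
#' @param flat_var variance threshold below which a channel counts as flat.
#' @param sat_abs amplitude threshold at or above which a channel counts as
#'   saturated, or `Inf` to disable.
#' @param max_faulty maximum tolerated number of faulty channels before the
#'   whole subject is flagged (`subject_excluded`); default 5.
#' @return list with `series` (channels dropped, order preserved) and
#'   `report` (fields `rejected_channels`, `n_rejected`, `subject_excluded`).
#' @export
reject_channels <- function(series, reject_list = NULL,
                            flat_var = 1e-12, sat_abs = Inf,
                            max_faulty = 5L) {
  stopifnot_series(series)
  if (!is.null(reject_list)) {
    reject_list <- as.character(reject_list)
    unknown <- setdiff(reject_list, series$channel_names)
    if (length(unknown))
      stop("reject_list names not present: ", paste(unknown, collapse = ", "))
    bad <- series$channel_names %in% reject_list
  } else {
    if (flat_var < 0 || sat_abs <= 0)
      stop("thresholds must be positive")
    v <- apply(series$values, 1L, stats::var)
    sat <- apply(abs(series$values), 1L, max) >= sat_abs
    bad <- (v <= flat_var) | sat
  }
  if (all(bad)) stop("all channels rejected")
  report <- list(rejected_channels = series$channel_names[bad],
                 n_rejected = sum(bad),
                 subject_excluded = sum(bad) > max_faulty)
  keep <- !bad
  out <- mc_series(series$values[keep, , drop = FALSE], series$rate,
                   series$channel_names[keep],
                   c(series$meta, list(channel_rejection = report)))
  list(series = out, report = report)
}

#' Zero-phase lowpass filter
#'
#' Forward-backward (zero-phase) Butterworth lowpass applied per channel.
#' Zero-phase filtering avoids latency distortion of the topography
#' trajectory; a 4th-order design is used (the effective order doubles with
#' the two passes). DC is preserved.
#'
#' @param series an [mc_series()].
#' @param cutoff_hz cutoff frequency, must be below Nyquist.
#' @param order Butterworth order for one pass (default 4).
#' @return filtered `mc_series` with `meta$lowpass_hz` set.
#' @export
lowpass_filter <- function(series, cutoff_hz, order = 4L) {
  stopifnot_series(series)
  nyq <- series$rate / 2
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq)
    stop("`cutoff_hz` must lie in (0, Nyquist)")
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  n <- n_samples(series)
  # odd-reflection edge padding suppresses filtfilt startup transients
  np <- min(n - 1L, max(50L, ceiling(3 * series$rate / cutoff_hz)))
  vals <- t(apply(series$values, 1L, function(ch) {
    padded <- c(2 * ch[1L] - ch[(np + 1L):2L],
                ch,
                2 * ch[n] - ch[(n - 1L):(n - np)])
    out <- signal::filtfilt(bf, padded)
    out[(np + 1L):(np + n)]
  }))
  mc_series(vals, series$rate, series$channel_names,
            c(series$meta, list(lowpass_hz = cutoff_hz,
                                lowpass_order = order)))
}

#' Coarse-grain by non-overlapping block averaging
#'
#' Averages each channel over consecutive non-overlapping windows of
#' `window_ms` milliseconds, reducing a 1 kHz recording to 25 Hz at the
#' 40 ms default -- the rate of the behavioral video. A trailing partial
#' block is dropped (with a warning) rather than padded, to avoid a biased
#' final mean.
#'
#' @param series an [mc_series()].
#' @param window_ms window length in milliseconds (default 40).
#' @param method `"mean"` (block average, default) or `"decimate"` (keep the
#'   first sample of each block).
#' @return coarse-grained `mc_series` with rate `1000 / window_ms`.
#' @export
coarse_grain <- function(series, window_ms = 40, method = c("mean", "decimate")) {
  stopifnot_series(series)
  method <- match.arg(method)
  w <- window_ms * series$rate / 1000
  if (w < 1) stop("window shorter than one sample")
  if (abs(w - round(w)) > 1e-8)
    stop("`window_ms` must span an integer number of samples at this rate")
  w <- as.integer(round(w))
  n <- n_samples(series)
  nb <- n %/% w
  if (nb < 1L) stop("series shorter than one window")
  if (nb * w < n)
    warning(sprintf("dropping trailing partial block of %d samples", n - nb * w))
  x <- series$values[, seq_len(nb * w), drop = FALSE]
  if (method == "mean") {
    # block means per channel via a w x nb reshape (no copy of the loop body)
    vals <- matrix(0, nrow(x), nb)
    for (ch in seq_len(nrow(x)))
      vals[ch, ] <- colMeans(matrix(x[ch, ], nrow = w, ncol = nb))
  } else {
    vals <- x[, seq(1L, nb * w, by = w), drop = FALSE]
  }
  mc_series(vals, 1000 / window_ms, series$channel_names,
            c(series$meta, list(coarse_window_ms = window_ms,
                                coarse_method = method)))
}

#' Concatenate recording phases
#'
#' Joins recordings (e.g., the sampling and test phases of a memory task)
#' along the time axis. Channel names must match positionally and rates must
#' be equal. Phase boundaries are recorded in `meta$phase_boundaries`
#' (cumulative sample counts) so downstream exceedance analyses can
#' optionally censor gaps spanning a boundary.
#'
#' @param parts list of [mc_series()] objects.
#' @return a single concatenated `mc_series`.
#' @export
concat_phases <- function(parts) {
  if (!length(parts)) stop("empty list of parts")
  lapply(parts, stopifnot_series)
  ref <- parts[[1L]]
  for (p in parts[-1L]) {
    if (!identical(p$channel_names, ref$channel_names))
      stop("channel names must match positionally across parts")
    if (!isTRUE(all.equal(p$rate, ref$rate)))
      stop("sampling rates must match across parts")
  }
  vals <- do.call(cbind, lapply(parts, function(p) p$values))
  bounds <- cumsum(vapply(parts, n_samples, integer(1L)))
  mc_series(vals, ref$rate, ref$channel_names,
            c(ref$meta, list(phase_boundaries = bounds[-length(bounds)])))
}
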