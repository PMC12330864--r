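#' @title Multitaper spectral analysis
#' @description
#' Slepian-taper (DPSS) spectrograms of the raw (non-coarse-grained)
#' recording, time-averaged into relative band power per cortical region,
#' and the relative 40 Hz power used to verify gamma entrainment during
#' flicker stimulation. Tapers are computed from the standard symmetric
#' tridiagonal eigenproblem (Sturm-sequence bisection for the eigenvalues,
#' inverse iteration with sparse tridiagonal solves for the vectors), so no
#' external multitaper library is needed.
#' @name spectral-module
NULL

# ---- Slepian (DPSS) tapers ------------------------------------------------

# Sturm count: number of eigenvalues of the symmetric tridiagonal matrix
# (diag d, off-diag e) strictly less than x
sturm_count <- function(d, e, x) {
  n <- length(d)
  cnt <- 0L
  q <- d[1L] - x
  if (q < 0) cnt <- 1L
  for (i in 2:n) {
    q <- d[i] - x - if (q != 0) e[i - 1L]^2 / q else e[i - 1L]^2 / 1e-300
    if (q < 0) cnt <- cnt + 1L
  }
  cnt
}

# k-th largest eigenvalue (k = 1 is the largest) by bisection
tridiag_eigval <- function(d, e, k, tol = 1e-12) {
  n <- length(d)
  rad <- abs(d) + c(abs(e), 0) + c(0, abs(e))
  lo <- min(d - rad); hi <- max(d + rad)
  target <- n - k             # want: count of eigenvalues < x equals n - k
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sturm_count(d, e, mid) <= target) lo <- mid else hi <- mid
    if (hi - lo < tol * max(1, abs(mid))) break
  }
  (lo + hi) / 2
}

# eigenvector by inverse iteration around lambda, tridiagonal solve via Matrix
tridiag_eigvec <- function(d, e, lambda, n_iter = 4L) {
  n <- length(d)
  shift <- lambda + 1e-10 * max(1, abs(lambda))
  A <- Matrix::bandSparse(n, n, k = c(-1L, 0L, 1L),
                          diagonals = list(e, d - shift, e))
  lu <- Matrix::lu(A)
  v <- rep(1 / sqrt(n), n)
  for (i in seq_len(n_iter)) {
    v <- as.numeric(Matrix::solve(lu, v))
    v <- v / sqrt(sum(v^2))
  }
  v
}

#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' The first `k` order-(0..k-1) DPSS of length `n` with time-bandwidth
#' product `nw`, via the symmetric tridiagonal commuting-matrix
#' formulation. Sign convention: each taper's element sum (or, where that
#' vanishes, its first nonzero element) is positive.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (e.g., 3).
#' @param k number of tapers (typically `2 * nw - 1`).
#' @return n x k matrix; columns are unit-norm tapers.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k < 1 || nw <= 0 || n < 2) stop("invalid DPSS parameters")
  if (k > 2 * nw)
    warning("k > 2*nw tapers are poorly concentrated")
  w <- nw / n
  t0 <- seq_len(n) - 1
  d <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  e <- (t0 * (n - t0))[2:n] / 2
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    lam <- tridiag_eigval(d, e, j)
    v <- tridiag_eigvec(d, e, lam)
    s <- sum(v)
    if (abs(s) < 1e-8) s <- v[which(abs(v) > 1e-8)[1L]]
    if (s < 0) v <- -v
    out[, j] <- v
  }
  out
}

# ---- Spectrogram ----------------------------------------------------------

#' Multitaper spectrogram
#'
#' Sliding-window Slepian-multitaper power estimate per channel, on the raw
#' (non-coarse-grained) signal. Power in each window is the average of the
#' `n_tapers` eigenspectra; one-sided frequencies up to Nyquist.
#'
#' @param series an [mc_series()] or channels x samples matrix (with `rate`
#'   supplied).
#' @param window_s window length in seconds.
#' @param overlap_s window overlap in seconds (must be < `window_s`).
#' @param time_bandwidth time-bandwidth product NW (default 3).
#' @param n_tapers number of Slepian tapers (default 5, the standard
#'   pairing with NW = 3).
#' @param rate sampling rate, required when `series` is a plain matrix.
#' @return object of class `mt_spectrogram`: `power` (time x frequency x
#'   channel), `freq` (Hz), `times` (window centers, s), `params`.
#' @export
multitaper_spectrogram <- function(series, window_s, overlap_s = window_s / 2,
                                   time_bandwidth = 3, n_tapers = 5,
                                   rate = NULL) {
  if (inherits(series, "mc_series")) {
    x <- series$values; rate <- series$rate
    chn <- series$channel_names
  } else {
    x <- as.matrix(series)
    if (is.null(rate)) stop("`rate` required for a plain matrix")
    chn <- rownames(x)
    if (is.null(chn)) chn <- paste0("ch", seq_len(nrow(x)))
  }
  if (overlap_s >= window_s) stop("`overlap_s` must be smaller than `window_s`")
  nwin <- round(window_s * rate)
  if (nwin > ncol(x)) stop("window longer than the recording")
  step <- max(1L, round((window_s - overlap_s) * rate))
  starts <- seq(1L, ncol(x) - nwin + 1L, by = step)
  tapers <- dpss_tapers(nwin, time_bandwidth, n_tapers)
  nf <- nwin %/% 2L + 1L
  freq <- (seq_len(nf) - 1L) * rate / nwin
  pow <- array(0, dim = c(length(starts), nf, nrow(x)))
  for (wi in seq_along(starts)) {
    seg <- x[, starts[wi]:(starts[wi] + nwin - 1L), drop = FALSE]
    for (ch in seq_len(nrow(x))) {
      v <- seg[ch, ] - mean(seg[ch, ])     # demean per window
      tap <- tapers * v                    # nwin x k
      sp <- stats::mvfft(tap)
      pk <- Mod(sp[seq_len(nf), , drop = FALSE])^2
      pow[wi, , ch] <- rowMeans(pk)
    }
  }
  dimnames(pow) <- list(NULL, NULL, chn)
  structure(list(power = pow, freq = freq,
                 times = (starts - 1L + nwin / 2) / rate,
                 params = list(window_s = window_s, overlap_s = overlap_s,
                               time_bandwidth = time_bandwidth,
                               n_tapers = n_tapers, rate = rate)),
            class = "mt_spectrogram")
}

#' @export
print.mt_spectrogram <- function(x, ...) {
  cat(sprintf("<mt_spectrogram> %d windows x %d freqs x %d channels (df = %.3f Hz)\n",
              dim(x$power)[1L], dim(x$power)[2L], dim(x$power)[3L],
              x$freq[2L] - x$freq[1L]))
  invisible(x)
}

#' Default 30-channel region map
#'
#' Maps channels `ch1..ch30` onto six cortical territories (five channels
#' each): prefrontal (PFC), motor (MOC), somatosensory (SSC), parietal
#' (PAR), retrosplenial (RSC) and visual (VIS) cortex — a stand-in layout
#' mimicking a surface grid ordered front to back.
#'
#' @param channel_names channel names to map (default `ch1..ch30`).
#' @return named character vector, channel -> region.
#' @export
default_region_map <- function(channel_names = paste0("ch", 1:30)) {
  regions <- c("PFC", "MOC", "SSC", "PAR", "RSC", "VIS")
  n <- length(channel_names)
  stats::setNames(regions[pmin(length(regions),
                               ceiling(seq_len(n) * length(regions) / n))],
                  channel_names)
}

#' Default frequency bands
#'
#' Delta 0.5-4 Hz, theta 4-12 Hz, gamma 30-80 Hz (rodent conventions).
#' Bands are half-open intervals `[lo, hi)`.
#'
#' @return named list of `c(lo, hi)` pairs.
#' @export
default_bands <- function()
  list(delta = c(0.5, 4), theta = c(4, 12), gamma = c(30, 80))

#' Relative band power per region
#'
#' Averages the spectrogram over time, normalizes each channel's spectrum
#' to unit total power, integrates the named bands (sum of normalized bin
#' powers over `[lo, hi)`), and averages channels within regions.
#'
#' @param spec an [multitaper_spectrogram()] result.
#' @param bands named list of `c(lo, hi)` frequency intervals (default
#'   [default_bands()]).
#' @param region_map named character vector channel -> region (default
#'   [default_region_map()] over the spectrogram's channels).
#' @return data frame with columns `region`, `band`, `fraction`.
#' @export
relative_band_power <- function(spec, bands = default_bands(),
                                region_map = NULL) {
  stopifnot(inherits(spec, "mt_spectrogram"))
  chn <- dimnames(spec$power)[[3L]]
  if (is.null(region_map)) region_map <- default_region_map(chn)
  unknown <- setdiff(chn, names(region_map))
  if (length(unknown))
    stop("region_map missing channels: ", paste(unknown, collapse = ", "))
  hi_all <- max(spec$freq)
  for (b in bands)
    if (b[1L] < 0 || b[1L] > hi_all)
      stop("band outside the spectral range")
  mean_spec <- apply(spec$power, c(2L, 3L), mean)     # freq x channel
  norm_spec <- sweep(mean_spec, 2L, colSums(mean_spec), "/")
  rows <- list()
  for (bn in names(bands)) {
    b <- bands[[bn]]
    sel <- spec$freq >= b[1L] & spec$freq < b[2L]
    frac <- colSums(norm_spec[sel, , drop = FALSE])
    for (rg in unique(region_map[chn])) {
      rows[[length(rows) + 1L]] <-
        data.frame(region = rg, band = bn,
                   fraction = mean(frac[region_map[chn] == rg]))
    }
  }
  do.call(rbind, rows)
}

#' Relative 40 Hz power per region
#'
#' Long-window multitaper spectrum (default 60 s windows, 30 s overlap, for
#' fine frequency resolution around the 40 Hz entrainment peak), normalized
#' to unit total power; reports the power at the frequency bin nearest
#' 40 Hz (or integrated over +/- `half_bw_hz`) per region.
#'
#' @inheritParams multitaper_spectrogram
#' @param target_hz target frequency (default 40).
#' @param half_bw_hz integrate over `target_hz +/- half_bw_hz` instead of
#'   the single nearest bin (default 0 = nearest bin only).
#' @param region_map named character vector channel -> region.
#' @return data frame with columns `region`, `fraction`.
#' @export
relative_40hz_power <- function(series, window_s = 60, overlap_s = 30,
                                time_bandwidth = 3, n_tapers = 5,
                                target_hz = 40, half_bw_hz = 0,
                                region_map = NULL, rate = NULL) {
  spec <- multitaper_spectrogram(series, window_s, overlap_s,
                                 time_bandwidth, n_tapers, rate = rate)
  chn <- dimnames(spec$power)[[3L]]
  if (is.null(region_map)) region_map <- default_region_map(chn)
  mean_spec <- apply(spec$power, c(2L, 3L), mean)
  norm_spec <- sweep(mean_spec, 2L, colSums(mean_spec), "/")
  sel <- if (half_bw_hz > 0)
    abs(spec$freq - target_hz) <= half_bw_hz
  else seq_along(spec$freq) == which.min(abs(spec$freq - target_hz))
  frac <- colSums(norm_spec[sel, , drop = FALSE])
  regs <- unique(region_map[chn])
  data.frame(region = regs,
             fraction = vapply(regs, function(rg)
               mean(frac[region_map[chn] == rg]), numeric(1L)),
             row.names = NULL)
}
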