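#' @title Dynamics fluidity: extremal index of log-distance exceedances
#' @description
#' The dynamics of a multichannel recording are viewed as a trajectory
#' \eqn{u_t} in channel space. Around a reference configuration \eqn{u_0}
#' the observable \eqn{g(t) = -\log \|u_t - u_0\|} is large whenever the
#' trajectory revisits the neighborhood of \eqn{u_0}. Exceedances of a high
#' quantile of g carry the temporal clustering of such returns, quantified
#' by the extremal index \eqn{\theta \in [0, 1]}: 1 for Poisson returns (no
#' clustering, maximally fluid dynamics), 0 for a fixed point (complete
#' persistence). Estimated per reference point, this yields a time series of
#' fluidity values.
#' @name fluidity-module
NULL

#' Log-distance observable around a reference sample
#'
#' Computes \eqn{g(t) = -\log \|u_t - u_{ref}\|_2} over all samples
#' \eqn{t \neq ref}. The self point (distance 0, infinite g) is excluded;
#' any other sample at exactly zero distance is also excluded and counted in
#' the `n_zero_excluded` attribute (with a warning).
#'
#' @param series an [mc_series()] (or a channels x samples matrix).
#' @param ref_index sample index of the reference configuration.
#' @return numeric vector of g values (length `n_samples - 1 -
#'   n_zero_excluded`), with attributes `ref_index`, `times` (the sample
#'   indices retained, in increasing order) and `n_zero_excluded`.
#' @export
log_distance_series <- function(series, ref_index) {
  x <- if (inherits(series, "mc_series")) series$values else as.matrix(series)
  n <- ncol(x)
  if (ref_index < 1 || ref_index > n) stop("`ref_index` outside the series")
  d2 <- colSums((x - x[, ref_index])^2)
  keep <- seq_len(n)[-ref_index]
  zero <- d2[keep] == 0
  if (any(zero)) {
    warning(sprintf("%d non-reference samples at zero distance excluded",
                    sum(zero)))
    keep <- keep[!zero]
  }
  g <- -0.5 * log(d2[keep])
  attr(g, "ref_index") <- ref_index
  attr(g, "times") <- keep
  attr(g, "n_zero_excluded") <- sum(zero)
  g
}

#' Closed-form Süveges estimator of the extremal index
#'
#' Thresholds the observable series at its empirical `q`-quantile, extracts
#' the exceedance times \eqn{L_i}, forms inter-exceedance gaps
#' \eqn{T_i = L_{i+1} - L_i} and \eqn{S_i = T_i - 1}, and evaluates the
#' closed-form maximizer of the Süveges likelihood with
#' \eqn{p = 1 - q}:
#' \deqn{\hat\theta = \frac{p\sum S_i + N + N_c -
#'   \sqrt{(p\sum S_i + N + N_c)^2 - 8 N_c\, p\sum S_i}}{2\, p\sum S_i}}
#' where N is the number of gaps and \eqn{N_c} the number of gaps with
#' \eqn{S_i > 0}.
#'
#' Conventions at the degenerate ends: a single contiguous exceedance run
#' (\eqn{\sum S_i = 0}) returns exactly 0 (the fixed-point limit); fewer
#' than two exceedances return `NaN` with a `reason` attribute, as does a
#' series shorter than 100 samples.
#'
#' @param g numeric observable series (e.g., from
#'   [log_distance_series()]).
#' @param q threshold quantile in (0, 1); default 0.98.
#' @param gap_convention `"Tminus1"` (default, \eqn{S_i = T_i - 1}) or
#'   `"T"` (\eqn{S_i = T_i}); both exist in the extreme-value literature.
#' @param times optional integer positions of the g values on the original
#'   time axis (defaults to the `times` attribute of `g`, or 1..n); gaps are
#'   measured on this axis.
#' @return list with `theta`, `n_exceedances`, `threshold`,
#'   `exceedance_times`, and `sigma` (mean excess of g over the threshold,
#'   the exponential-GPD scale MLE — a local-dimension proxy, reported but
#'   not otherwise analyzed). `theta` is `NaN` with attribute `reason` when
#'   estimation is impossible.
#' @export
estimate_extremal_index <- function(g, q = 0.98,
                                    gap_convention = c("Tminus1", "T"),
                                    times = NULL) {
  gap_convention <- match.arg(gap_convention)
  if (q <= 0 || q >= 1) stop("`q` must lie in (0, 1)")
  if (is.null(times)) times <- attr(g, "times")
  g <- as.numeric(g)
  if (is.null(times)) times <- seq_along(g)
  if (length(g) < 100L)
    return(failed_theta("too short", length(g)))
  thr <- stats::quantile(g, q, names = FALSE, type = 7)
  exc <- g > thr
  n_exc <- sum(exc)
  if (n_exc < 2L)
    return(failed_theta("fewer than 2 exceedances", n_exc, threshold = thr))
  L <- sort(times[exc])
  Ti <- diff(L)
  Si <- if (gap_convention == "Tminus1") Ti - 1 else Ti
  p <- 1 - q
  theta <- suveges_closed_form(Si, p)
  list(theta = theta, n_exceedances = n_exc, threshold = thr,
       exceedance_times = L, sigma = mean(g[exc] - thr))
}

failed_theta <- function(reason, n_exc, threshold = NA_real_) {
  theta <- NaN
  attr(theta, "reason") <- reason
  list(theta = theta, n_exceedances = n_exc, threshold = threshold,
       exceedance_times = integer(0), sigma = NA_real_)
}

# closed-form maximizer of the Suveges likelihood
# l(theta) = (N - Nc) log(1-theta) + 2 Nc log(theta) - theta p sum(S)
suveges_closed_form <- function(Si, p) {
  N <- length(Si)
  Nc <- sum(Si > 0)
  pS <- p * sum(Si)
  if (pS == 0) return(0)          # one contiguous run: fixed-point limit
  a <- pS + N + Nc
  min(1, max(0, (a - sqrt(a * a - 8 * Nc * pS)) / (2 * pS)))
}

#' Time-resolved dynamics fluidity of a multichannel series
#'
#' Estimates the extremal index around every `ref_stride`-th sample used as
#' the reference configuration, giving the fluidity time series. Estimation
#' around each reference uses [log_distance_series()] and
#' [estimate_extremal_index()] at quantile `q`.
#'
#' Estimation is O(n) per reference, so the full per-sample series
#' (`ref_stride = 1`) is O(n^2); a stride trades temporal resolution for
#' speed without changing any single estimate.
#'
#' @param series an [mc_series()] (preprocessed/coarse-grained) or a
#'   channels x samples matrix.
#' @param q threshold quantile (default 0.98).
#' @param ref_stride stride between reference samples (default 1).
#' @param gap_convention see [estimate_extremal_index()].
#' @return object of class `fluidity` with fields `theta`, `sigma`,
#'   `n_exceedances` (per reference), `ref_times`, `quantile`,
#'   `n_failed` and `failure_reasons`.
#' @export
fluidity <- function(series, q = 0.98, ref_stride = 1L,
                     gap_convention = "Tminus1") {
  x <- if (inherits(series, "mc_series")) series$values else as.matrix(series)
  if (ref_stride < 1) stop("`ref_stride` must be >= 1")
  n <- ncol(x)
  refs <- seq(1L, n, by = as.integer(ref_stride))
  sq <- colSums(x^2)
  theta <- sigma <- rep(NA_real_, length(refs))
  n_exc <- integer(length(refs))
  reasons <- character(0)
  # distances for all references at once: d2[t] = |u_t|^2 + |u_r|^2 - 2 u_t.u_r
  G <- crossprod(x[, refs, drop = FALSE], x)     # nref x n
  for (i in seq_along(refs)) {
    r <- refs[i]
    d2 <- sq + sq[r] - 2 * G[i, ]
    d2[r] <- -1                                   # mark self point
    keep <- which(d2 > 0)
    g <- -0.5 * log(d2[keep])
    est <- estimate_extremal_index(g, q = q, gap_convention = gap_convention,
                                   times = keep)
    theta[i] <- est$theta
    sigma[i] <- est$sigma
    n_exc[i] <- est$n_exceedances
    if (is.nan(est$theta))
      reasons <- c(reasons, attr(est$theta, "reason"))
  }
  n_failed <- sum(is.nan(theta))
  if (n_failed > length(refs) / 2)
    warning("more than half of the reference points failed estimation")
  structure(list(theta = theta, sigma = sigma, n_exceedances = n_exc,
                 ref_times = refs, quantile = q,
                 gap_convention = gap_convention,
                 n_failed = n_failed,
                 failure_reasons = table(reasons)),
            class = "fluidity")
}

#' @rdname fluidity
#' @param ... passed to `fluidity()`.
#' @export
fluidity_timeseries <- function(series, ...) fluidity(series, ...)

#' @export
print.fluidity <- function(x, ...) {
  cat(sprintf("<fluidity> %d reference points, q = %g\n",
              length(x$theta), x$quantile))
  ok <- x$theta[!is.nan(x$theta)]
  if (length(ok))
    cat(sprintf("  theta: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
                mean(ok), stats::sd(ok), min(ok), max(ok)))
  if (x$n_failed)
    cat(sprintf("  failed references: %d\n", x$n_failed))
  invisible(x)
}

#' @export
summary.fluidity <- function(object, ...) {
  ok <- object$theta[!is.nan(object$theta)]
  out <- list(n_refs = length(object$theta), n_failed = object$n_failed,
              quantile = object$quantile,
              mean_theta = mean(ok), sd_theta = stats::sd(ok),
              quantiles = stats::quantile(ok, c(0.025, 0.25, 0.5, 0.75, 0.975)),
              mean_sigma = mean(object$sigma, na.rm = TRUE))
  class(out) <- "summary.fluidity"
  out
}

#' @export
print.summary.fluidity <- function(x, ...) {
  cat(sprintf("Dynamics fluidity over %d references (q = %g, %d failed)\n",
              x$n_refs, x$quantile, x$n_failed))
  cat(sprintf("  mean theta %.4f (sd %.4f), mean sigma %.4f\n",
              x$mean_theta, x$sd_theta, x$mean_sigma))
  print(round(x$quantiles, 4))
  invisible(x)
}

#' @export
mean.fluidity <- function(x, ...) mean(x$theta, na.rm = TRUE)

#' @export
plot.fluidity <- function(x, ...) {
  graphics::plot(x$ref_times, x$theta, type = "l", xlab = "reference sample",
                 ylab = expression(theta), ylim = c(0, 1), ...)
  invisible(x)
}

#' Export a fluidity series as a data frame
#'
#' One row per reference point: `ref_time`, `theta`, `sigma`,
#' `n_exceedances`. Suitable for writing as TSV.
#'
#' @param x a `fluidity` object.
#' @param ... unused.
#' @export
as.data.frame.fluidity <- function(x, ...) {
  data.frame(ref_time = x$ref_times, theta = as.numeric(x$theta),
             sigma = x$sigma, n_exceedances = x$n_exceedances)
}

#' Numerically maximized Süveges likelihood (reference implementation)
#'
#' Maximizes the Süveges log-likelihood
#' \eqn{(N - N_c)\log(1-\theta) + 2N_c\log\theta - \theta p \sum S_i}
#' over \eqn{\theta \in (0, 1)} by bounded golden-section search. Exists as
#' an independent cross-check of the closed form; the pipeline never calls
#' it.
#'
#' @param Si inter-exceedance gaps minus one (or raw gaps under the `"T"`
#'   convention).
#' @param p exceedance probability `1 - q`.
#' @param tol optimizer tolerance.
#' @return the maximizing theta.
#' @export
suveges_numeric_mle <- function(Si, p, tol = 1e-10) {
  N <- length(Si)
  Nc <- sum(Si > 0)
  pS <- p * sum(Si)
  if (pS == 0) return(0)
  negll <- function(theta)
    -((N - Nc) * log1p(-theta) + 2 * Nc * log(theta) - theta * pS)
  stats::optimize(negll, c(1e-12, 1 - 1e-12), tol = tol)$minimum
}
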