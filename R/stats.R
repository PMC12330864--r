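#' @title Resampling statistics for fluidity and behavior
#' @description
#' The bespoke resampling machinery used to compare conditions: a
#' histogram-model Monte-Carlo bootstrap of the two-sample
#' Kolmogorov-Smirnov statistic (association vs merged-null replica
#' distributions), decile-binned normalized mutual information with paired
#' and independent shuffles, and the bootstrap co-distribution of a
#' locomotor measure across fluidity deciles.
#' @name stats-module
NULL

# two-sample KS statistic (sup |ECDF difference|), no p-value machinery
ks_stat <- function(x, y) {
  n <- length(x); m <- length(y)
  z <- c(x, y)
  o <- order(z)
  w <- c(rep(1 / n, n), rep(-1 / m, m))[o]
  cw <- cumsum(w)
  # handle ties: only evaluate the ECDF difference after the last of a tie run
  zs <- z[o]
  last <- c(zs[-1L] != zs[-length(zs)], TRUE)
  max(abs(cw[last]))
}

# model a sample as a histogram on `bins` uniform-width bins over `range`,
# then draw `n` values: a bin by its probability, a point uniformly within
hist_model_draw <- function(sample, n, breaks) {
  cnt <- tabulate(findInterval(sample, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), length(breaks) - 1L)
  bin <- sample.int(length(cnt), n, replace = TRUE, prob = cnt)
  stats::runif(n, breaks[bin], breaks[bin + 1L])
}

# overlap coefficient of two samples: sum over shared bins of
# min(p_hat, q_hat)
overlap_coefficient <- function(a, b, n_bins = 50L) {
  rng <- range(a, b)
  if (rng[1L] == rng[2L]) return(1)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  pa <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(a)
  pb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(b)
  sum(pmin(pa, pb))
}

#' Bootstrap Kolmogorov-Smirnov comparison of two distributions
#'
#' Each input sample is modeled as a histogram on `n_bins` uniform-width
#' bins over the pooled range, from which `n_mc` Monte-Carlo observations
#' are redrawn per group. Bootstrap replicas of `replica_size` observations
#' are then subsampled with replacement under two hypotheses: H1 (each
#' group's own Monte-Carlo sample) and H0 (both subsamples from the merged
#' Monte-Carlo sample), and the two-sample KS statistic is computed per
#' replica.
#'
#' The H1 replica distribution is summarized by its mean and sd. The
#' p-value is the fraction of overlap between the H0 and H1 KS replica
#' distributions (overlap coefficient of their histograms); the one-sided
#' exceedance reading — the fraction of H0 replicas with KS at least the
#' H1 mean — is also reported as `p_exceed`. Both are corrected with
#' Bonferroni over `m_comparisons`. The procedure is deliberately more
#' conservative than a classical asymptotic KS test.
#'
#' @param dist_a,dist_b numeric samples (non-finite values dropped with a
#'   count in the result).
#' @param n_mc Monte-Carlo sample size per group (default 5000).
#' @param n_bins histogram resolution for the Monte-Carlo model (default
#'   200).
#' @param replica_size observations per bootstrap replica (default 500,
#'   minimum 10).
#' @param n_replicas bootstrap replicas per hypothesis (default 500).
#' @param m_comparisons Bonferroni correction factor (default 1).
#' @param seed integer seed.
#' @return object of class `bootstrap_ks`: `ks_mean_h1`, `ks_sd_h1`,
#'   `p_overlap`, `p_exceed`, `p_bonferroni`, `ks_h1`, `ks_h0` (replica
#'   values), `n_dropped`, and the parameters.
#' @export
bootstrap_ks_compare <- function(dist_a, dist_b, n_mc = 5000L,
                                 n_bins = 200L, replica_size = 500L,
                                 n_replicas = 500L, m_comparisons = 1L,
                                 seed = 1L) {
  a <- dist_a[is.finite(dist_a)]
  b <- dist_b[is.finite(dist_b)]
  n_dropped <- (length(dist_a) - length(a)) + (length(dist_b) - length(b))
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  if (replica_size < 10L) stop("`replica_size` must be at least 10")
  rng <- range(a, b)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  with_seed(seed, {
    mc_a <- hist_model_draw(a, n_mc, breaks)
    mc_b <- hist_model_draw(b, n_mc, breaks)
    merged <- c(mc_a, mc_b)
    ks_h1 <- ks_h0 <- numeric(n_replicas)
    for (i in seq_len(n_replicas)) {
      ra <- mc_a[sample.int(n_mc, replica_size, replace = TRUE)]
      rb <- mc_b[sample.int(n_mc, replica_size, replace = TRUE)]
      ks_h1[i] <- ks_stat(ra, rb)
      r0a <- merged[sample.int(2L * n_mc, replica_size, replace = TRUE)]
      r0b <- merged[sample.int(2L * n_mc, replica_size, replace = TRUE)]
      ks_h0[i] <- ks_stat(r0a, r0b)
    }
    p_overlap <- overlap_coefficient(ks_h1, ks_h0)
    p_exceed <- mean(ks_h0 >= mean(ks_h1))
    structure(list(ks_mean_h1 = mean(ks_h1), ks_sd_h1 = stats::sd(ks_h1),
                   p_overlap = p_overlap, p_exceed = p_exceed,
                   p_bonferroni = min(1, p_overlap * m_comparisons),
                   ks_h1 = ks_h1, ks_h0 = ks_h0,
                   n_dropped = n_dropped,
                   params = list(n_mc = n_mc, n_bins = n_bins,
                                 replica_size = replica_size,
                                 n_replicas = n_replicas,
                                 m_comparisons = m_comparisons,
                                 seed = seed)),
              class = "bootstrap_ks")
  })
}

#' @export
print.bootstrap_ks <- function(x, ...) {
  cat(sprintf("<bootstrap_ks> KS (H1) = %.4f +/- %.4f\n",
              x$ks_mean_h1, x$ks_sd_h1))
  cat(sprintf("  p (overlap) = %.4f, Bonferroni = %.4f  [exceedance %.4f]\n",
              x$p_overlap, x$p_bonferroni, x$p_exceed))
  invisible(x)
}

# Shannon entropy (bits) of a discrete probability vector
shannon_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

mi_bits <- function(i, j, n_bins = 10L) {
  joint <- table(factor(i, levels = 1:n_bins), factor(j, levels = 1:n_bins))
  pj <- joint / sum(joint)
  pi_ <- rowSums(pj); pj_ <- colSums(pj)
  ex <- outer(pi_, pj_)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / ex[nz]))
}

#' Decile-binned normalized mutual information
#'
#' Discretizes both series into deciles (rank-based quantile binning, ties
#' broken by position) and computes the mutual information of the decile
#' states, normalized by the larger of the two marginal entropies so the
#' result lies in [0, 1]. Two bootstrap ensembles of `n_boot` iterations
#' each are reported: a paired resample (joint indices, preserving the
#' temporal association — the observed value) and an independent resample
#' of the two series (the chance-level null).
#'
#' MI on deciles is invariant under strictly monotone transforms of either
#' series.
#'
#' @param x,y equal-length numeric series (length >= 100).
#' @param n_boot bootstrap iterations (default 100).
#' @param seed integer seed.
#' @return object of class `mi_deciles`: `mi_over_h_observed`,
#'   `mi_over_h_null`, per-iteration vectors, `n_boot`, `n_bins`, `seed`.
#' @export
mutual_information_deciles <- function(x, y, n_boot = 100L, seed = 1L) {
  if (length(x) != length(y)) stop("series must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 100L) stop("need at least 100 paired observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("constant series: deciles undefined")
  dx <- decile_bins(x)
  dy <- decile_bins(y)
  with_seed(seed, {
    obs <- nul <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      hx <- shannon_bits(tabulate(dx[idx], 10L) / n)
      hy <- shannon_bits(tabulate(dy[idx], 10L) / n)
      obs[b] <- mi_bits(dx[idx], dy[idx]) / max(hx, hy)
      ix <- sample.int(n, n, replace = TRUE)
      iy <- sample.int(n, n, replace = TRUE)
      hx0 <- shannon_bits(tabulate(dx[ix], 10L) / n)
      hy0 <- shannon_bits(tabulate(dy[iy], 10L) / n)
      nul[b] <- mi_bits(dx[ix], dy[iy]) / max(hx0, hy0)
    }
    structure(list(mi_over_h_observed = mean(obs),
                   mi_over_h_null = mean(nul),
                   observed = obs, null = nul,
                   n_boot = n_boot, n_bins = 10L, seed = seed),
              class = "mi_deciles")
  })
}

#' @export
print.mi_deciles <- function(x, ...) {
  cat(sprintf("<mi_deciles> MI/H observed = %.4f, null = %.4f (%d bootstraps)\n",
              x$mi_over_h_observed, x$mi_over_h_null, x$n_boot))
  invisible(x)
}

#' Bootstrap co-distribution of a measure across fluidity deciles
#'
#' Splits fluidity values into deciles (0:10:100 percentile bins) and
#' computes the median of the locomotor measure within each decile, then
#' bootstraps (`n_boot` iterations) the decile-wise medians under H0
#' (fluidity and measure independently resampled with replacement,
#' destroying the pairing) and H1 (both resampled with the same index
#' vector, preserving the pairing), yielding per-decile quantile bands for
#' both hypotheses.
#'
#' @param fluidity numeric fluidity series (>= 10 distinct values).
#' @param locomotor equal-length numeric locomotor measure (speed, head
#'   movement, ...).
#' @param n_boot bootstrap iterations (default 200).
#' @param probs quantiles reported for the bands (default 2.5/50/97.5%).
#' @param seed integer seed.
#' @return object of class `codistribution`: `observed` (per-decile
#'   medians), `h0_bands` and `h1_bands` (deciles x probs matrices),
#'   `n_per_decile`, `n_boot`, `seed`.
#' @export
codistribution_deciles <- function(fluidity, locomotor, n_boot = 200L,
                                   probs = c(0.025, 0.5, 0.975), seed = 1L) {
  if (length(fluidity) != length(locomotor))
    stop("series must have equal length")
  ok <- is.finite(fluidity) & is.finite(locomotor)
  f <- fluidity[ok]; l <- locomotor[ok]
  if (length(unique(f)) < 10L) stop("need >= 10 distinct fluidity values")
  n <- length(f)
  dec <- decile_bins(f)
  med_by_decile <- function(d, v) {
    out <- rep(NaN, 10L)
    for (k in 1:10) {
      vk <- v[d == k]
      if (length(vk)) out[k] <- stats::median(vk)
    }
    out
  }
  observed <- med_by_decile(dec, l)
  with_seed(seed, {
    h0 <- h1 <- matrix(NA_real_, n_boot, 10L)
    for (b in seq_len(n_boot)) {
      i1 <- sample.int(n, n, replace = TRUE)
      f1 <- f[i1]; l1 <- l[i1]
      h1[b, ] <- med_by_decile(decile_bins(f1), l1)
      i0f <- sample.int(n, n, replace = TRUE)
      i0l <- sample.int(n, n, replace = TRUE)
      h0[b, ] <- med_by_decile(decile_bins(f[i0f]), l[i0l])
    }
    band <- function(m) {
      out <- apply(m, 2L, stats::quantile, probs = probs, na.rm = TRUE)
      t(out)
    }
    structure(list(observed = observed,
                   h0_bands = band(h0), h1_bands = band(h1),
                   n_per_decile = tabulate(dec, 10L),
                   n_boot = n_boot, probs = probs, seed = seed),
              class = "codistribution")
  })
}

#' @export
print.codistribution <- function(x, ...) {
  cat(sprintf("<codistribution> %d bootstraps; observed decile medians:\n",
              x$n_boot))
  print(round(x$observed, 4))
  invisible(x)
}
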