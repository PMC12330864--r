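#' @title EEG microstate segmentation and sequence metrics
#' @description
#' Represents the coarse-grained EEG as a symbolic sequence of microstate
#' labels — stereotypical multichannel topographies — extracted either by
#' k-means clustering of all samples under the correlation distance, or by
#' clustering the topographies at global-field-power peaks and backfitting
#' every sample to the best-correlated centroid. Sequence metrics follow:
#' transition matrices, microstates fluidity (reciprocal mean diagonal),
#' minimum-description-length complexity, and microstate entropy per
#' fluidity decile.
#' @name microstates-module
NULL

new_segmentation <- function(centroids, labels, K, method, seed,
                             extra = list()) {
  structure(c(list(centroids = centroids, labels = labels, K = K,
                   method = method, distance = "correlation", seed = seed),
              extra),
            class = "microstate_segmentation")
}

#' @export
print.microstate_segmentation <- function(x, ...) {
  cat(sprintf("<microstate_segmentation> K = %d (%s), %d samples\n",
              x$K, x$method, length(x$labels)))
  occ <- tabulate(x$labels, x$K) / length(x$labels)
  cat("  occupancy:", paste(sprintf("%.2f", occ), collapse = " "), "\n")
  invisible(x)
}

# center and scale each column (sample topography) to unit variance
scale_samples <- function(x) {
  xs <- scale(x)
  attr(xs, "scaled:center") <- attr(xs, "scaled:scale") <- NULL
  xs
}

# Pearson correlation of every column of x (channels x n) with every row of
# centroids (K x channels); returns n x K. `xs` may be passed pre-scaled.
cor_to_centroids <- function(x, centroids, xs = scale_samples(x)) {
  cs <- t(scale(t(centroids)))                 # center/scale each centroid
  ch <- nrow(xs)
  crossprod(xs, t(cs)) / (ch - 1)
}

#' Microstate segmentation by correlation-distance k-means
#'
#' Lloyd-style k-means on sample topographies with distance
#' \eqn{d(x, c) = 1 - r(x, c)} (signed Pearson correlation across channels,
#' no polarity folding; set `ignore_polarity = TRUE` for the
#' human-EEG convention \eqn{1 - |r|}). The best of `n_restarts` random
#' initializations by total within-cluster distance is returned;
#' deterministic given `seed`.
#'
#' @param series an [mc_series()] or channels x samples matrix.
#' @param K number of microstates (2 <= K <= channels).
#' @param seed integer seed for the restarts.
#' @param n_restarts random initializations (default 10).
#' @param ignore_polarity cluster on `|r|` instead of signed r.
#' @param max_iter Lloyd iteration cap per restart.
#' @return a `microstate_segmentation` with `centroids` (K x channels),
#'   `labels` (1-based per sample), and `within_dist` (sum of assigned
#'   distances).
#' @export
segment_kmeans <- function(series, K, seed, n_restarts = 10L,
                           ignore_polarity = FALSE, max_iter = 100L) {
  x <- if (inherits(series, "mc_series")) series$values else as.matrix(series)
  ch <- nrow(x); n <- ncol(x)
  if (K < 2) stop("`K` must be at least 2")
  if (K > ch) stop("`K` must not exceed the number of channels")
  if (n <= 10 * K) stop("series too short for K clusters (need > 10 K samples)")
  if (any(apply(x, 2L, stats::sd) == 0))
    stop("constant samples have undefined correlation distance")
  xs <- scale_samples(x)
  best <- NULL
  with_seed(seed, {
    for (rs in seq_len(n_restarts)) {
      fit <- kmeans_cor_once(x, xs, K, max_iter, ignore_polarity)
      if (is.null(best) || fit$within < best$within) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed on every restart")
  new_segmentation(best$centroids, best$labels, K, "kmeans", seed,
                   list(within_dist = best$within,
                        n_restarts = n_restarts,
                        ignore_polarity = ignore_polarity))
}

kmeans_cor_once <- function(x, xs, K, max_iter, ignore_polarity) {
  n <- ncol(x)
  cent <- t(x[, sample.int(n, K)])
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    r <- cor_to_centroids(x, cent, xs)
    if (ignore_polarity) r <- abs(r)
    new_labels <- max.col(r, ties.method = "first")
    empty <- setdiff(seq_len(K), unique(new_labels))
    if (length(empty)) {
      # re-seed empty clusters at the worst-fit samples
      fit <- r[cbind(seq_len(n), new_labels)]
      worst <- order(fit)[seq_along(empty)]
      for (j in seq_along(empty)) {
        cent[empty[j], ] <- x[, worst[j]]
        new_labels[worst[j]] <- empty[j]
      }
    }
    if (it > 1L && all(new_labels == labels)) break
    labels <- new_labels
    for (k in seq_len(K))
      cent[k, ] <- rowMeans(x[, labels == k, drop = FALSE])
  }
  r <- cor_to_centroids(x, cent, xs)
  if (ignore_polarity) r <- abs(r)
  within <- sum(1 - r[cbind(seq_len(n), labels)])
  list(centroids = cent, labels = labels, within = within)
}

#' Global field power of a multichannel series
#'
#' Across-channel variance of the topography at each sample.
#'
#' @param series an [mc_series()] or channels x samples matrix.
#' @return numeric vector, one value per sample.
#' @export
global_field_power <- function(series) {
  x <- if (inherits(series, "mc_series")) series$values else as.matrix(series)
  apply(x, 2L, stats::var)
}

# Local maxima of v with topographic prominence >= min_prominence.
# Prominence of a peak = height minus the higher of the two minima reached
# before meeting a strictly higher value on each side (series edge counts
# as a barrier).
find_peaks <- function(v, min_prominence = 0) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  core <- which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
  if (!length(core)) return(integer(0))
  if (min_prominence <= 0) return(core)
  prom <- vapply(core, function(i) {
    lmin <- v[i]; j <- i
    while (j > 1L && v[j - 1L] <= v[i]) { j <- j - 1L; lmin <- min(lmin, v[j]) }
    left <- if (j == 1L && v[1L] <= v[i]) min(lmin, v[1L]) else lmin
    rmin <- v[i]; j <- i
    while (j < n && v[j + 1L] <= v[i]) { j <- j + 1L; rmin <- min(rmin, v[j]) }
    right <- if (j == n && v[n] <= v[i]) min(rmin, v[n]) else rmin
    v[i] - max(left, right)
  }, numeric(1L))
  core[prom >= min_prominence]
}

#' Microstate segmentation from global-field-power peaks
#'
#' The human-EEG-style procedure: GFP (across-channel variance) peaks with
#' topographic prominence at least `min_prominence` are selected, their
#' topographies clustered by correlation-distance k-means, and every sample
#' of the series backfitted to the centroid with the highest Pearson
#' correlation.
#'
#' The prominence threshold applies to the raw variance signal (whose units
#' depend on amplitude scale); `zscore_gfp = TRUE` applies it to the
#' z-scored GFP instead.
#'
#' @inheritParams segment_kmeans
#' @param min_prominence minimum peak prominence (default 0.5).
#' @param zscore_gfp apply the prominence threshold to z-scored GFP.
#' @return a `microstate_segmentation` (method `"gfp-peaks"`) with
#'   `gfp_peaks` (sample indices used for clustering).
#' @export
segment_gfp <- function(series, K, seed, min_prominence = 0.5,
                        n_restarts = 10L, ignore_polarity = FALSE,
                        zscore_gfp = FALSE) {
  x <- if (inherits(series, "mc_series")) series$values else as.matrix(series)
  if (K < 2) stop("`K` must be at least 2")
  gfp <- global_field_power(x)
  gv <- if (zscore_gfp) as.numeric(scale(gfp)) else gfp
  peaks <- find_peaks(gv, min_prominence)
  if (length(peaks) < K)
    stop(sprintf(paste0("only %d GFP peaks found for K = %d; ",
                        "lower `min_prominence`"), length(peaks), K))
  km <- segment_kmeans(x[, peaks, drop = FALSE], K, seed,
                       n_restarts = n_restarts,
                       ignore_polarity = ignore_polarity)
  r <- cor_to_centroids(x, km$centroids)
  if (ignore_polarity) r <- abs(r)
  labels <- max.col(r, ties.method = "first")
  new_segmentation(km$centroids, labels, K, "gfp-peaks", seed,
                   list(gfp_peaks = peaks, min_prominence = min_prominence,
                        zscore_gfp = zscore_gfp,
                        ignore_polarity = ignore_polarity))
}

#' Microstate transition matrix
#'
#' `counts[i, j]` is the number of consecutive pairs with state i followed
#' by state j; `probs` are row-normalized counts (so the diagonal holds the
#' stay probabilities). Rows of states never departed from (including
#' never-visited states) are `NaN`.
#'
#' @param labels integer state sequence (1-based, values <= K).
#' @param K number of states.
#' @return list of class `transition_matrix` with `probs`, `counts`.
#' @export
transition_matrix <- function(labels, K) {
  labels <- as.integer(labels)
  if (!length(labels)) stop("`labels` must be nonempty")
  if (max(labels) > K || min(labels) < 1L)
    stop("labels must lie in 1..K")
  counts <- matrix(0L, K, K)
  if (length(labels) > 1L) {
    from <- labels[-length(labels)]
    to <- labels[-1L]
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  }
  rs <- rowSums(counts)
  probs <- counts / rs                      # rows with rs = 0 become NaN
  structure(list(probs = probs, counts = counts), class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix>\n")
  print(round(x$probs, 3))
  invisible(x)
}

#' Microstates fluidity
#'
#' Reciprocal of the mean diagonal of the transition probability matrix,
#' taken over states with at least one observed departure. Ranges from 1
#' (never switches) to `Inf` (strict alternation, zero diagonal); `NaN` for
#' a sequence with no transitions at all.
#'
#' @param tm a [transition_matrix()] result.
#' @return a single number in `[1, Inf]`.
#' @export
microstate_fluidity <- function(tm) {
  d <- diag(tm$probs)
  d <- d[!is.nan(d)]
  if (!length(d)) return(NaN)
  m <- mean(d)
  if (m == 0) Inf else 1 / m
}

#' Minimum-description-length complexity of a label sequence
#'
#' The sequence is described two ways in token counts. The original
#' description lists each dictionary label followed by every position where
#' it occurs: `L_orig = |dictionary| + N_words`. The compressed description
#' lists, per label, its runs as (length, shift) token pairs — the shift
#' being the offset to the next run of the same label — with the final run
#' of each label carrying no shift token:
#' `L_comp = |dictionary| + sum over labels of (2 n_runs - 1)`.
#' The reported complexity is `100^(L_comp / L_orig)`, a base-100
#' exponential transform that brings the ratio onto an approximately normal
#' scale; values above 100 mean the run-length description is longer than
#' the plain listing (an incompressible, rapidly switching sequence).
#'
#' @param labels nonempty vector of state labels (any atomic type).
#' @return list of class `mdl_complexity` with `L_orig`, `L_comp`,
#'   `dl_complexity`, `dictionary_size`, `n_words`.
#' @export
mdl_complexity <- function(labels) {
  if (!length(labels)) stop("`labels` must be nonempty")
  labels <- as.vector(labels)
  dict <- unique(labels)
  n_words <- length(labels)
  L_orig <- length(dict) + n_words
  r <- rle(labels)
  runs_per_label <- table(factor(r$values, levels = dict))
  L_comp <- length(dict) + sum(2L * as.integer(runs_per_label) - 1L)
  structure(list(L_orig = L_orig, L_comp = L_comp,
                 dl_complexity = 100^(L_comp / L_orig),
                 dictionary_size = length(dict), n_words = n_words),
            class = "mdl_complexity")
}

#' @export
print.mdl_complexity <- function(x, ...) {
  cat(sprintf("<mdl_complexity> L_orig = %d, L_comp = %d, DL = %.3f\n",
              x$L_orig, x$L_comp, x$dl_complexity))
  invisible(x)
}

#' Microstate entropy per fluidity decile
#'
#' Splits the fluidity time series into 10 deciles (rank-based, ties broken
#' by position) and computes, within each decile, the Shannon entropy (bits)
#' of the microstate occupancy distribution over the K states. Maximum
#' possible entropy is `log2(K)`; 0 means the decile is dominated by a
#' single microstate. `NaN` where a decile is empty after dropping failed
#' fluidity estimates.
#'
#' @param labels microstate label sequence (1-based) on the same time base
#'   as the fluidity series; if `fluidity` was estimated with a stride, the
#'   labels at `ref_times` are used.
#' @param fluidity a [fluidity()] object or plain numeric vector of theta
#'   values.
#' @param K number of microstates (default 4).
#' @return numeric length-10 vector of entropies, names `"d1"`..`"d10"`.
#' @export
entropy_by_fluidity_decile <- function(labels, fluidity, K = 4L) {
  if (inherits(fluidity, "fluidity")) {
    theta <- fluidity$theta
    labs <- labels[fluidity$ref_times]
  } else {
    theta <- as.numeric(fluidity)
    if (length(labels) != length(theta))
      stop("labels and fluidity must be aligned on the same time base")
    labs <- labels
  }
  if (max(labs, na.rm = TRUE) > K) stop("labels exceed K")
  ok <- !is.nan(theta) & !is.na(labs)
  theta <- theta[ok]; labs <- labs[ok]
  dec <- decile_bins(theta)
  out <- rep(NaN, 10)
  for (d in 1:10) {
    in_d <- labs[dec == d]
    if (!length(in_d)) next
    p <- tabulate(in_d, K) / length(in_d)
    p <- p[p > 0]
    out[d] <- -sum(p * log2(p))
  }
  names(out) <- paste0("d", 1:10)
  out
}

# rank-based decile assignment; ties broken by original position so bins
# are near-equal even for heavily tied data
decile_bins <- function(x, n_bins = 10L) {
  rk <- rank(x, ties.method = "first")
  pmin(n_bins, ceiling(rk * n_bins / length(x)))
}

#' Sweep over the number of microstates
#'
#' Segments the series for every K in `k_min:k_max` (k-means by default),
#' computing microstates fluidity and MDL complexity per K, and their
#' arithmetic means across K — the single-value summaries used when the
#' cluster count is treated as a nuisance dimension.
#'
#' @inheritParams segment_kmeans
#' @param k_min,k_max cluster range (defaults 3 and 8).
#' @param method `"kmeans"` or `"gfp"`.
#' @param ... extra arguments passed to the segmentation function.
#' @return list of class `microstate_sweep`: `per_k` (data frame with K,
#'   fluidity, dl_complexity), `mean_fluidity`, `mean_complexity`,
#'   `segmentations` (list by K).
#' @export
sweep_k <- function(series, k_min = 3L, k_max = 8L, seed,
                    method = c("kmeans", "gfp"), ...) {
  method <- match.arg(method)
  if (k_min < 2 || k_max < k_min) stop("need k_max >= k_min >= 2")
  ks <- k_min:k_max
  segs <- vector("list", length(ks))
  fl <- dl <- rep(NA_real_, length(ks))
  errs <- character(0)
  for (i in seq_along(ks)) {
    res <- tryCatch({
      seg <- if (method == "kmeans")
        segment_kmeans(series, ks[i], seed = seed, ...)
      else segment_gfp(series, ks[i], seed = seed, ...)
      tm <- transition_matrix(seg$labels, ks[i])
      list(seg = seg, fl = microstate_fluidity(tm),
           dl = mdl_complexity(seg$labels)$dl_complexity)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, sprintf("K=%d: %s", ks[i], conditionMessage(res)))
    } else {
      segs[[i]] <- res$seg
      fl[i] <- res$fl
      dl[i] <- res$dl
    }
  }
  if (all(is.na(fl)))
    stop("segmentation failed for every K: ", paste(errs, collapse = "; "))
  structure(list(per_k = data.frame(K = ks, fluidity = fl,
                                    dl_complexity = dl),
                 mean_fluidity = mean(fl, na.rm = TRUE),
                 mean_complexity = mean(dl, na.rm = TRUE),
                 segmentations = segs, errors = errs),
            class = "microstate_sweep")
}

#' @export
print.microstate_sweep <- function(x, ...) {
  cat("<microstate_sweep>\n")
  print(x$per_k, row.names = FALSE)
  cat(sprintf("  mean fluidity %.4f, mean complexity %.4f\n",
              x$mean_fluidity, x$mean_complexity))
  invisible(x)
}

#' Match estimated centroids to reference templates
#'
#' Finds the one-to-one assignment of centroids to templates maximizing the
#' total absolute Pearson correlation (exhaustive search over permutations;
#' intended for K <= 8). Used for parameter-recovery checks against
#' generator ground truth.
#'
#' @param centroids K x channels matrix.
#' @param templates K x channels matrix.
#' @return list with `perm` (template index assigned to each centroid) and
#'   `abs_r` (per-centroid matched |r|).
#' @export
match_templates <- function(centroids, templates) {
  K <- nrow(centroids)
  if (nrow(templates) != K) stop("centroid/template counts differ")
  if (K > 8) stop("exhaustive matching supported for K <= 8")
  r <- abs(stats::cor(t(centroids), t(templates)))
  perms <- all_perms(K)
  best <- NULL; best_sum <- -Inf
  for (i in seq_len(nrow(perms))) {
    s <- sum(r[cbind(seq_len(K), perms[i, ])])
    if (s > best_sum) { best_sum <- s; best <- perms[i, ] }
  }
  list(perm = best, abs_r = r[cbind(seq_len(K), best)])
}

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}
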