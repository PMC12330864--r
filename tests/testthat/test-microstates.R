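test_that("correlation-distance k-means recovers HMM templates and labels", {
  e <- gen_microstate_hmm(K = 4, n_channels = 30, n_samples = 6000,
                          mean_dwell = 10, noise_sd = 0.3, seed = 21)
  seg <- segment_kmeans(e$series, 4, seed = 1)
  m <- match_templates(seg$centroids, e$true_templates)
  expect_true(all(m$abs_r >= 0.95))
  expect_gt(label_agreement(seg$labels, e$true_labels, 4), 0.95)
  # noiseless two-template alternation is recovered exactly
  q <- gen_microstate_hmm(K = 2, n_channels = 8, n_samples = 400,
                          mean_dwell = 3, noise_sd = 0, seed = 22)
  sq <- segment_kmeans(q$series, 2, seed = 2)
  expect_equal(label_agreement(sq$labels, q$true_labels, 2), 1)
  expect_error(segment_kmeans(e$series, 1, seed = 1), "at least 2")
  expect_error(segment_kmeans(e$series, 31, seed = 1), "channels")
  # determinism given seed
  expect_identical(seg$labels, segment_kmeans(e$series, 4, seed = 1)$labels)
})

test_that("GFP-peak segmentation agrees with k-means and peak rules hold", {
  e <- gen_microstate_hmm(K = 3, n_channels = 20, n_samples = 4000,
                          mean_dwell = 12, noise_sd = 0.25, seed = 23)
  km <- segment_kmeans(e$series, 3, seed = 3)
  gf <- segment_gfp(e$series, 3, seed = 3, min_prominence = 0)
  agree <- label_agreement(km$labels, gf$labels, 3)
  expect_gte(agree, 0.8)
  # prominence 0 returns exactly the strict local maxima of GFP
  gfp <- global_field_power(e$series)
  expect_equal(eegfluidity:::find_peaks(gfp, 0), brute_local_maxima(gfp))
  # constant series: no peaks, informative error
  flat <- mc_series(matrix(1:8, 8, 100), 25)
  expect_error(segment_gfp(flat, 2, seed = 1), "peaks")
  # absurd prominence: too few peaks
  expect_error(segment_gfp(e$series, 3, seed = 1, min_prominence = 1e9),
               "prominence")
})

test_that("prominence filter keeps major peaks and drops shoulder ripples", {
  v <- c(0, 1, 0.9, 1.05, 0, 5, 0, 0.5, 0.4, 0.45, 0)
  all_peaks <- eegfluidity:::find_peaks(v, 0)
  expect_equal(all_peaks, brute_local_maxima(v))
  big <- eegfluidity:::find_peaks(v, 2)
  expect_equal(big, 6L)
})

test_that("transition matrix and microstate fluidity match hand counts", {
  tm <- transition_matrix(c(1, 1, 2, 2), 2)
  expect_equal(tm$counts, matrix(c(1L, 0L, 1L, 1L), 2))
  expect_equal(diag(tm$probs), c(0.5, 1.0))
  expect_equal(microstate_fluidity(tm), 4 / 3)
  # constant sequence: diagonal 1 on the visited state, fluidity 1
  tmc <- transition_matrix(rep(1, 10), 3)
  expect_equal(tmc$probs[1, 1], 1)
  expect_true(all(is.nan(tmc$probs[2, ])))
  expect_equal(microstate_fluidity(tmc), 1)
  # strict alternation: zero diagonal, infinite fluidity
  tma <- transition_matrix(rep(1:2, 10), 2)
  expect_equal(diag(tma$probs), c(0, 0))
  expect_equal(microstate_fluidity(tma), Inf)
  # rows with departures sum to 1
  set.seed(24)
  tmr <- transition_matrix(sample(1:4, 500, replace = TRUE), 4)
  expect_equal(rowSums(tmr$probs), rep(1, 4))
  # no transitions at all
  expect_true(is.nan(microstate_fluidity(transition_matrix(2L, 3))))
  expect_error(transition_matrix(c(1, 5), 4), "1..K")
})

test_that("HMM dwell ties to the transition diagonal closed form", {
  e <- gen_microstate_hmm(K = 4, n_channels = 12, n_samples = 30000,
                          mean_dwell = 8, noise_sd = 0.2, seed = 25)
  tm <- transition_matrix(e$true_labels, 4)
  dwell_from_diag <- 1 / (1 - mean(diag(tm$probs)))
  expect_lt(abs(dwell_from_diag / mean(rle(e$true_labels)$lengths) - 1), 0.1)
})

test_that("MDL complexity reproduces exact hand-counted token values", {
  a4 <- mdl_complexity(c("A", "A", "A", "A"))
  expect_identical(a4$L_orig, 5L)
  expect_identical(a4$L_comp, 2L)
  expect_equal(a4$dl_complexity, 100^(2 / 5))
  a1 <- mdl_complexity("A")
  expect_identical(c(a1$L_orig, a1$L_comp), c(2L, 2L))
  expect_equal(a1$dl_complexity, 100)
  ab <- mdl_complexity(rep(c("A", "B"), 4))
  expect_identical(ab$L_orig, 10L)
  expect_identical(ab$L_comp, 16L)
  expect_gt(ab$dl_complexity, 100)
  # permutation invariance under state relabeling
  set.seed(26)
  s <- sample(1:4, 300, replace = TRUE)
  relab <- c(3, 1, 4, 2)[s]
  expect_equal(mdl_complexity(s)$dl_complexity,
               mdl_complexity(relab)$dl_complexity)
  expect_error(mdl_complexity(integer(0)), "nonempty")
})

test_that("entropy per fluidity decile separates uniform, constant and dependent labels", {
  set.seed(27)
  fl <- runif(5000)
  uni <- sample(1:4, 5000, replace = TRUE)
  h <- entropy_by_fluidity_decile(uni, fl, K = 4)
  expect_length(h, 10L)
  expect_true(all(abs(h - 2) < 0.1))
  hc <- entropy_by_fluidity_decile(rep(2L, 5000), fl, K = 4)
  expect_equal(unname(hc), rep(0, 10))
  # labels perfectly determined by the decile: 0 bits per decile, 2 pooled
  dec <- eegfluidity:::decile_bins(fl)
  det <- (dec %% 4) + 1L
  hd <- entropy_by_fluidity_decile(det, fl, K = 4)
  expect_equal(unname(hd), rep(0, 10))
  pooled <- tabulate(det, 4) / length(det)
  expect_lt(abs(-sum(pooled * log2(pooled)) - 2), 0.1)
  # alignment with a strided fluidity object via ref_times
  e <- gen_iid_gaussian(4, 600, seed = 28)
  f <- fluidity(e$series, ref_stride = 2)
  labs <- sample(1:4, 600, replace = TRUE)
  expect_length(entropy_by_fluidity_decile(labs, f, K = 4), 10L)
  expect_error(entropy_by_fluidity_decile(uni[1:10], fl[1:20], K = 4),
               "aligned")
})

test_that("K sweep averages per-K metrics and responds to dwell time", {
  e5 <- gen_microstate_hmm(K = 4, n_channels = 12, n_samples = 3000,
                           mean_dwell = 5, noise_sd = 0.2, seed = 29)
  e50 <- gen_microstate_hmm(K = 4, n_channels = 12, n_samples = 3000,
                            mean_dwell = 50, noise_sd = 0.2, seed = 29)
  s5 <- sweep_k(e5$series, 3, 5, seed = 1)
  s50 <- sweep_k(e50$series, 3, 5, seed = 1)
  expect_gt(s5$mean_fluidity, s50$mean_fluidity)
  # averaged fluidity lies within the per-K range
  expect_gte(s5$mean_fluidity, min(s5$per_k$fluidity))
  expect_lte(s5$mean_fluidity, max(s5$per_k$fluidity))
  # degenerate sweep equals the single-K values
  s4 <- sweep_k(e5$series, 4, 4, seed = 7)
  seg <- segment_kmeans(e5$series, 4, seed = 7)
  expect_equal(s4$mean_fluidity,
               microstate_fluidity(transition_matrix(seg$labels, 4)))
  expect_equal(s4$mean_complexity, mdl_complexity(seg$labels)$dl_complexity)
  expect_error(sweep_k(e5$series, 5, 3, seed = 1), "k_max")
})
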