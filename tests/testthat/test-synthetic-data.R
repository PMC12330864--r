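test_that("iid Gaussian generator has standard-normal moments and is seed-reproducible", {
  e <- gen_iid_gaussian(30, 10000, seed = 1)
  expect_equal(dim(e$series$values), c(30L, 10000L))
  expect_lt(max(abs(rowMeans(e$series$values))), 0.05)
  expect_lt(max(abs(apply(e$series$values, 1, var) - 1)), 0.1)
  e2 <- gen_iid_gaussian(30, 10000, seed = 1)
  expect_identical(e$series$values, e2$series$values)
  e3 <- gen_iid_gaussian(30, 10000, seed = 2)
  expect_false(identical(e$series$values, e3$series$values))
  # independence: lag-1 autocorrelation small at n = 100
  s <- gen_iid_gaussian(1, 100, seed = 2)$series$values[1, ]
  expect_lt(abs(cor(s[-1], s[-100])), 0.2)
  expect_error(gen_iid_gaussian(0, 1000, seed = 1), "n_channels")
  expect_error(gen_iid_gaussian(3, 50, seed = 1), "n_samples")
})

test_that("AR(1) generator matches closed-form autocorrelation and variance", {
  a <- gen_var1(1, 20000, persistence = 0.9, seed = 3)
  x <- a$series$values[1, ]
  expect_lt(abs(cor(x[-1], x[-length(x)]) - 0.9), 0.05)
  # stationary variance noise_sd^2 / (1 - phi^2) within 5% at n = 50000
  b <- gen_var1(1, 50000, persistence = 0.7, noise_sd = 2, seed = 4)
  expect_lt(abs(var(b$series$values[1, ]) / (4 / (1 - 0.49)) - 1), 0.05)
  # persistence 0 is distributionally iid standard normal
  z <- gen_var1(2, 50000, persistence = 0, seed = 5)
  expect_lt(max(abs(apply(z$series$values, 1, var) - 1)), 0.05)
  expect_lt(abs(cor(z$series$values[1, -1], z$series$values[1, -50000])), 0.02)
  expect_error(gen_var1(1, 1000, persistence = 1, seed = 1), "stationarity")
  expect_error(gen_var1(1, 1000, persistence = 0.5, noise_sd = 0, seed = 1),
               "noise_sd")
})

test_that("microstate HMM generator matches its design: dwell, marginals, templates", {
  e <- gen_microstate_hmm(K = 4, n_channels = 30, n_samples = 50000,
                          mean_dwell = 10, noise_sd = 0.3, seed = 6)
  expect_length(e$true_labels, 50000L)
  expect_true(all(e$true_labels %in% 1:4))
  # geometric dwell: empirical mean run length within 15% of target
  runs <- rle(e$true_labels)$lengths
  expect_lt(abs(mean(runs) / 10 - 1), 0.15)
  # label marginals uniform across states within sampling error
  occ <- tabulate(e$true_labels, 4) / 50000
  expect_lt(max(abs(occ - 0.25)), 0.03)
  # templates unit-norm and pairwise |r| < 0.7
  expect_equal(sqrt(rowSums(e$true_templates^2)), rep(1, 4))
  r <- cor(t(e$true_templates))
  expect_lt(max(abs(r[upper.tri(r)])), 0.7)
  # noiseless samples correlate |r| = 1 with their template
  q <- gen_microstate_hmm(K = 3, n_channels = 10, n_samples = 500,
                          mean_dwell = 5, noise_sd = 0, seed = 7)
  rr <- cor(q$series$values, t(q$true_templates))
  expect_equal(abs(rr[cbind(1:500, q$true_labels)]), rep(1, 500))
  expect_error(gen_microstate_hmm(K = 12, n_channels = 10, n_samples = 500,
                                  mean_dwell = 5, noise_sd = 0.1, seed = 1),
               "quasi-orthogonal")
})

test_that("pose-track generator camera transform is exactly invertible", {
  trk <- gen_pose_track(400, camera_offset = c(133, -72),
                        camera_angle = pi / 4, arena_size_px = 512, seed = 8)
  nt <- normalize_arena(trk)
  expect_lt(max(abs(nt$corners - unit_sq)), 1e-9)
  expect_lt(max(abs(nt$coords - attr(trk, "ground_truth")$coords)), 1e-9)
  # normalized track is invariant to the camera parameters
  trk0 <- gen_pose_track(400, camera_angle = 0, seed = 8)
  expect_lt(max(abs(nt$coords - normalize_arena(trk0)$coords)), 1e-9)
  # stationary walk has identically zero speed
  still <- gen_pose_track(100, seed = 9, step_sd = 0)
  expect_equal(max(compute_speed(normalize_arena(still))$values), 0)
  expect_error(gen_pose_track(1, seed = 1), "n_frames")
  expect_error(gen_pose_track(10, arena_size_px = 0, seed = 1), "arena_size")
})

test_that("cohort generator keeps groups identical except the persistence gap", {
  co <- gen_cohort(2, c(0.3, 0.8), n_channels = 6, n_samples = 500, seed = 10)
  expect_length(co$subjects, 4L)
  expect_equal(co$group, c("A", "A", "B", "B"))
  pers <- vapply(co$subjects, function(s) s$params$persistence, numeric(1))
  expect_equal(pers, c(0.3, 0.3, 0.8, 0.8))
  seeds <- vapply(co$subjects, function(s) s$params$seed, numeric(1))
  expect_equal(seeds, 10 + 1:4)
  expect_error(gen_cohort(1, c(0.3, 0.8), 6, 500, seed = 1), "n_per_group")
  expect_error(gen_cohort(2, c(0.3, 0.8), 6, 500, seed = 1,
                          group_labels = c("A", "A")), "distinct")
})
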