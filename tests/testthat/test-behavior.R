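test_that("arena normalization inverts the camera transform exactly", {
  trk <- gen_pose_track(300, camera_offset = c(87, 41),
                        camera_angle = pi / 6, arena_size_px = 600, seed = 41)
  nt <- normalize_arena(trk)
  expect_lt(max(abs(nt$corners - unit_sq)), 1e-6)
  expect_lt(max(abs(nt$coords - attr(trk, "ground_truth")$coords)), 1e-6)
  # already-normalized track (identity camera) is unchanged
  id <- gen_pose_track(300, seed = 41)
  expect_lt(max(abs(normalize_arena(id)$coords - id$coords)), 1e-12)
  # collinear corners are rejected
  bad <- id
  bad$corners <- matrix(c(0, 0, 1, 0, 2, 0, 3, 0), 4, 2, byrow = TRUE)
  expect_error(normalize_arena(bad), "collinear")
})

test_that("barycenter speed follows displacement geometry and is camera-invariant", {
  # barycenter moving (0.03, 0.04) per frame: speed 0.05 each step
  n <- 20
  centers <- cbind(0.2 + 0.03 * (0:(n - 1)), 0.2 + 0.04 * (0:(n - 1)))
  tr <- rigid_track(n, centers, rep(pi / 2, n))
  sp <- compute_speed(tr)
  expect_equal(sp$values, rep(0.05, n - 1))
  expect_equal(sp$mean, 0.05)
  expect_length(sp$values, n - 1L)
  # per-second option multiplies by fps
  expect_equal(compute_speed(tr, per_second = TRUE)$mean, 0.05 * 25)
  # speed invariant under any camera rotation applied before normalization
  set.seed(42)
  for (ang in runif(3, -pi, pi)) {
    t1 <- gen_pose_track(200, camera_angle = ang, arena_size_px = 500,
                         camera_offset = c(11, -5), seed = 43)
    t0 <- gen_pose_track(200, seed = 43)
    expect_equal(compute_speed(normalize_arena(t1))$values,
                 compute_speed(normalize_arena(t0))$values,
                 tolerance = 1e-9)
  }
  one <- rigid_track(1, matrix(0.5, 1, 2), pi / 2)
  expect_error(compute_speed(one), "2 frames")
})

test_that("egocentric head movement vanishes for rigid motion and sees posture change", {
  n <- 15
  # rigid translation at fixed heading
  tr <- rigid_track(n, cbind(0.1 + 0.02 * (1:n), rep(0.4, n)), rep(1.1, n))
  expect_lt(max(compute_head_movement(tr)$values), 1e-9)
  # rigid in-place rotation
  rot <- rigid_track(n, matrix(0.5, n, 2), seq(0, 3, length.out = n))
  expect_lt(max(compute_head_movement(rot)$values), 1e-9)
  # combined translation + rotation
  both <- rigid_track(n, cbind(seq(0.2, 0.8, length.out = n),
                               seq(0.3, 0.6, length.out = n)),
                      seq(-1, 2, length.out = n))
  expect_lt(max(compute_head_movement(both)$values), 1e-9)
  # nose displaced egocentrically by 0.01 in one frame: movement 0.01
  still <- rigid_track(3, matrix(0.5, 3, 2), rep(pi / 2, 3))
  still$coords[2, "nose", 2] <- still$coords[2, "nose", 2] + 0.01
  hm <- compute_head_movement(still)
  expect_equal(hm$values, c(0.01, 0.01), tolerance = 1e-12)
  noears <- rigid_track(3, matrix(0.5, 3, 2), rep(pi / 2, 3))
  noears$coords <- noears$coords[, c("nose", "neck", "body_mid"), , drop = FALSE]
  expect_error(compute_head_movement(noears), "ear_left")
})

test_that("memory index follows its defining ratio and is antisymmetric", {
  expect_equal(memory_index(10, 10), 0)
  expect_equal(memory_index(15, 5), 0.5)
  expect_equal(memory_index(0, 8), -1)
  expect_equal(memory_index(8, 0), 1)
  for (pair in list(c(3, 9), c(12.5, 4.5))) {
    expect_equal(memory_index(pair[1], pair[2]),
                 -memory_index(pair[2], pair[1]))
  }
  expect_warning(mi <- memory_index(0, 0), "no exploration")
  expect_true(is.nan(mi))
  expect_error(memory_index(-1, 5), ">= 0")
})

test_that("DLC CSV round-trip preserves coordinates, corners and fps", {
  trk <- gen_pose_track(120, fps = 30, camera_offset = c(10, 2),
                        camera_angle = 0.3, arena_size_px = 400, seed = 44)
  path <- file.path(tempdir(), "track.csv")
  write_dlc_csv(trk, path)
  back <- read_dlc_csv(path)
  expect_equal(back$coords, trk$coords, tolerance = 1e-9)
  expect_equal(back$corners, trk$corners, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$fps, 30)
  hdr <- readLines(path, n = 3)
  expect_match(hdr[1], "^scorer,")
  expect_match(hdr[2], "^bodyparts,")
  expect_match(hdr[3], "^coords,")
  unlink(c(path, paste0(path, ".meta.json")))
})
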