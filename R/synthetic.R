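#' @title Synthetic EEG-like data generators
#' @description
#' Generators for multichannel series with the statistical structure the
#' dynamics analyses assume: temporally independent Gaussian vectors (the
#' Poisson-return limit of the extremal index), first-order autoregressive
#' persistence (a fluidity dial), and hidden-Markov microstate switching
#' with known templates (ground truth for segmentation). All generators are
#' bit-reproducible given a seed.
#' @name synthetic
NULL

new_synthetic_eeg <- function(values, rate, params,
                              true_labels = NULL, true_templates = NULL) {
  obj <- list(series = mc_series(values, rate,
                                 meta = list(generator = params$generator)),
              true_labels = true_labels,
              true_templates = true_templates,
              params = params)
  class(obj) <- "synthetic_eeg"
  obj
}

#' @export
print.synthetic_eeg <- function(x, ...) {
  cat(sprintf("<synthetic_eeg> generator=%s, %d channels x %d samples, seed=%s\n",
              x$params$generator, nrow(x$series$values),
              ncol(x$series$values), format(x$params$seed)))
  invisible(x)
}

check_dims <- function(n_channels, n_samples) {
  if (!is.numeric(n_channels) || n_channels < 1)
    stop("`n_channels` must be a positive count")
  if (!is.numeric(n_samples) || n_samples < 100)
    stop("`n_samples` must be at least 100")
}

#' Independent multivariate Gaussian series
#'
#' Every sample is an independent standard-normal vector: the regime in
#' which threshold exceedances of the log-distance observable have
#' Poisson-distributed return times, so the extremal index tends to 1.
#'
#' @param n_channels number of channels (>= 1).
#' @param n_samples number of samples (>= 100).
#' @param seed integer RNG seed.
#' @param rate nominal sampling rate attached to the output (default 25 Hz,
#'   the coarse-grained rate).
#' @return a `synthetic_eeg` object.
#' @export
gen_iid_gaussian <- function(n_channels, n_samples, seed, rate = 25) {
  check_dims(n_channels, n_samples)
  vals <- with_seed(seed, matrix(stats::rnorm(n_channels * n_samples),
                                 nrow = n_channels))
  new_synthetic_eeg(vals, rate,
                    list(generator = "iid_gaussian", n_channels = n_channels,
                         n_samples = n_samples, seed = seed))
}

#' First-order autoregressive multichannel series
#'
#' Per channel, \eqn{x_{t+1} = \phi x_t + \epsilon_t} with iid normal
#' innovations of sd `noise_sd`. `persistence` (\eqn{\phi}) dials temporal
#' clustering: higher persistence lowers the dynamics fluidity of the
#' series. The first 1000 samples are discarded as burn-in so the output is
#' stationary (stationary variance `noise_sd^2 / (1 - persistence^2)`).
#'
#' @inheritParams gen_iid_gaussian
#' @param persistence AR(1) coefficient in `[0, 1)`.
#' @param noise_sd innovation standard deviation (> 0).
#' @param burn_in samples discarded before the output (default 1000).
#' @return a `synthetic_eeg` object.
#' @export
gen_var1 <- function(n_channels, n_samples, persistence, noise_sd = 1,
                     seed, rate = 25, burn_in = 1000L) {
  check_dims(n_channels, n_samples)
  if (!is.numeric(persistence) || persistence < 0 || persistence >= 1)
    stop("`persistence` must lie in [0, 1) (stationarity)")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  ntot <- n_samples + burn_in
  vals <- with_seed(seed, {
    eps <- matrix(stats::rnorm(n_channels * ntot, sd = noise_sd),
                  nrow = n_channels)
    if (persistence == 0) eps else {
      x <- eps
      for (t in 2:ntot) x[, t] <- persistence * x[, t - 1L] + eps[, t]
      x
    }
  })
  vals <- vals[, (burn_in + 1L):ntot, drop = FALSE]
  new_synthetic_eeg(vals, rate,
                    list(generator = "var1", n_channels = n_channels,
                         n_samples = n_samples, persistence = persistence,
                         noise_sd = noise_sd, seed = seed,
                         burn_in = burn_in))
}

draw_templates <- function(K, n_channels, max_abs_r = 0.7, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    tpl <- matrix(stats::rnorm(K * n_channels), nrow = K)
    tpl <- tpl / sqrt(rowSums(tpl^2))
    r <- stats::cor(t(tpl))
    if (all(abs(r[upper.tri(r)]) < max_abs_r)) return(tpl)
  }
  stop("could not draw quasi-orthogonal templates; lower K or raise n_channels")
}

#' Hidden-Markov microstate series
#'
#' A hidden state follows a K-state Markov chain with stay probability
#' `1 - 1/mean_dwell` (geometric dwell times of mean `mean_dwell`) and
#' uniform switching among the other states. The observation at time t is
#' the state's unit-norm template topography times `amplitude` plus iid
#' Gaussian channel noise. Templates are redrawn until all pairwise
#' |Pearson r| < 0.7 so the clusters are identifiable; the criterion is
#' recorded in `params`.
#'
#' @inheritParams gen_iid_gaussian
#' @param K number of states (2 <= K <= n_channels).
#' @param mean_dwell mean dwell time in samples (>= 1).
#' @param noise_sd channel noise sd, as a fraction of per-channel signal RMS
#'   at the default amplitude.
#' @param amplitude template scaling. Defaults to `sqrt(n_channels)`, which
#'   gives the unit-norm templates a per-channel RMS of 1, so `noise_sd`
#'   reads directly as the noise-to-signal amplitude ratio.
#' @return a `synthetic_eeg` with `true_labels` (1-based state indices) and
#'   `true_templates` (K x channels).
#' @export
gen_microstate_hmm <- function(K, n_channels, n_samples, mean_dwell,
                               noise_sd, seed, amplitude = sqrt(n_channels),
                               rate = 25) {
  check_dims(n_channels, n_samples)
  if (K < 2) stop("`K` must be at least 2")
  if (K > n_channels)
    stop("`K` must not exceed `n_channels` (templates cannot be quasi-orthogonal)")
  if (mean_dwell < 1) stop("`mean_dwell` must be >= 1")
  p_stay <- 1 - 1 / mean_dwell
  out <- with_seed(seed, {
    tpl <- draw_templates(K, n_channels)
    states <- integer(n_samples)
    states[1L] <- sample.int(K, 1L)
    switches <- stats::runif(n_samples) > p_stay
    for (t in 2:n_samples) {
      states[t] <- if (switches[t]) {
        others <- seq_len(K)[-states[t - 1L]]
        others[sample.int(K - 1L, 1L)]
      } else states[t - 1L]
    }
    obs <- t(tpl[states, , drop = FALSE]) * amplitude
    if (noise_sd > 0)
      obs <- obs + matrix(stats::rnorm(n_channels * n_samples, sd = noise_sd),
                          nrow = n_channels)
    list(tpl = tpl, states = states, obs = obs)
  })
  new_synthetic_eeg(out$obs, rate,
                    list(generator = "microstate_hmm", K = K,
                         n_channels = n_channels, n_samples = n_samples,
                         mean_dwell = mean_dwell, noise_sd = noise_sd,
                         amplitude = amplitude, seed = seed,
                         template_max_abs_r = 0.7),
                    true_labels = out$states, true_templates = out$tpl)
}

#' Synthetic cohort with group-specific persistence
#'
#' Builds two groups of AR(1) subjects that are identical in every
#' parameter except the designed persistence gap, for end-to-end group
#' comparison tests. Subject seeds are `seed + subject index`, so draws are
#' reproducible without seed collisions.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param persistence_by_group numeric length-2, AR(1) persistence per group.
#' @param n_channels,n_samples per-subject series dimensions.
#' @param seed master integer seed.
#' @param group_labels two distinct labels (default `"A"`, `"B"`).
#' @param noise_sd innovation sd passed to [gen_var1()].
#' @return list of class `synthetic_cohort`: `subjects` (list of
#'   `synthetic_eeg`), `group` (per-subject label), `design`, `seed`.
#' @export
gen_cohort <- function(n_per_group, persistence_by_group, n_channels,
                       n_samples, seed, group_labels = c("A", "B"),
                       noise_sd = 1) {
  if (n_per_group < 2) stop("`n_per_group` must be at least 2")
  if (length(persistence_by_group) != 2L)
    stop("`persistence_by_group` must have length 2")
  if (length(group_labels) != 2L || group_labels[1L] == group_labels[2L])
    stop("group labels must be two distinct values")
  subjects <- list()
  group <- character(0)
  idx <- 0L
  for (gi in 1:2) {
    for (s in seq_len(n_per_group)) {
      idx <- idx + 1L
      subjects[[idx]] <- gen_var1(n_channels, n_samples,
                                  persistence = persistence_by_group[gi],
                                  noise_sd = noise_sd, seed = seed + idx)
      group <- c(group, group_labels[gi])
    }
  }
  structure(list(subjects = subjects, group = group,
                 design = list(persistence_by_group = persistence_by_group,
                               n_channels = n_channels,
                               n_samples = n_samples, noise_sd = noise_sd),
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), persistence %s\n",
              length(x$subjects),
              paste(names(table(x$group)), table(x$group), sep = ":",
                    collapse = ", "),
              paste(x$design$persistence_by_group, collapse = " vs ")))
  invisible(x)
}

#' Synthetic open-field pose track
#'
#' Generates a smooth random walk of the animal barycenter inside the unit
#' arena, attaches an 8-point skeleton (nose, ears, neck, body midpoint,
#' three tail points) in egocentric coordinates aligned with the heading,
#' and then maps everything through a camera transform (rotation by
#' `camera_angle`, scaling by `arena_size_px`, translation by
#' `camera_offset`) so that arena normalization can be tested against known
#' ground truth. Arena corners are stored in camera coordinates in the
#' pinned order bottom-left, bottom-right, top-right, top-left.
#'
#' @param n_frames number of frames (>= 2).
#' @param fps frame rate (default 25).
#' @param camera_offset numeric length-2 pixel offset of the arena origin.
#' @param camera_angle camera rotation in radians.
#' @param arena_size_px arena wall length in pixels (> 0).
#' @param seed integer seed.
#' @param step_sd sd of the smoothed barycenter increments in arena units
#'   per frame (0 gives a stationary animal).
#' @return a `pose_track` (see [pose_track()]) in camera coordinates, with
#'   attribute `ground_truth` holding the arena-frame track.
#' @export
gen_pose_track <- function(n_frames, fps = 25, camera_offset = c(0, 0),
                           camera_angle = 0, arena_size_px = 1, seed,
                           step_sd = 0.01) {
  if (n_frames < 2) stop("`n_frames` must be at least 2")
  if (arena_size_px <= 0) stop("`arena_size_px` must be positive")
  parts <- dlc_bodyparts()
  ego <- skeleton_template()
  out <- with_seed(seed, {
    # smoothed random-walk barycenter, reflected into [0.1, 0.9]
    inc <- matrix(stats::rnorm(2L * n_frames, sd = step_sd), ncol = 2L)
    if (n_frames > 4L)
      inc <- apply(inc, 2L, function(v) as.numeric(stats::filter(
        v, rep(1 / 3, 3L), sides = 2L, circular = TRUE)))
    bary <- apply(inc, 2L, cumsum)
    bary <- 0.1 + 0.8 * reflect01((bary + 0.5))
    if (step_sd == 0) bary <- matrix(0.5, n_frames, 2L)
    # heading follows the direction of motion, smoothed; constant if static
    if (step_sd > 0) {
      d <- rbind(bary[2L, ] - bary[1L, ], diff(bary))
      heading <- atan2(d[, 2L], d[, 1L])
      heading[!is.finite(heading)] <- 0
      heading <- cumsum(c(heading[1L], wrap_angle(diff(heading)) * 0.5))
    } else heading <- rep(0, n_frames)
    list(bary = bary, heading = heading)
  })
  # world (arena) coordinates of every body part: egocentric template has the
  # animal facing +y; rotate by heading - pi/2 and translate to barycenter
  coords <- array(0, dim = c(n_frames, length(parts), 2L),
                  dimnames = list(NULL, parts, c("x", "y")))
  for (f in seq_len(n_frames)) {
    R <- rot2(out$heading[f] - pi / 2)
    pts <- ego %*% t(R)
    coords[f, , 1L] <- pts[, 1L] + out$bary[f, 1L]
    coords[f, , 2L] <- pts[, 2L] + out$bary[f, 2L]
  }
  truth <- pose_track(coords, corners = unit_corners(), fps = fps)
  # camera transform: p_cam = R(angle) %*% (p * size) + offset
  Rc <- rot2(camera_angle)
  cam <- coords
  for (f in seq_len(n_frames)) {
    p <- cbind(coords[f, , 1L], coords[f, , 2L]) * arena_size_px
    p <- p %*% t(Rc)
    cam[f, , 1L] <- p[, 1L] + camera_offset[1L]
    cam[f, , 2L] <- p[, 2L] + camera_offset[2L]
  }
  corners_cam <- unit_corners() * arena_size_px
  corners_cam <- corners_cam %*% t(Rc)
  corners_cam <- sweep(corners_cam, 2L, -camera_offset)
  trk <- pose_track(cam, corners = corners_cam, fps = fps)
  attr(trk, "ground_truth") <- truth
  attr(trk, "params") <- list(n_frames = n_frames, fps = fps,
                              camera_offset = camera_offset,
                              camera_angle = camera_angle,
                              arena_size_px = arena_size_px, seed = seed,
                              step_sd = step_sd)
  trk
}

# reflect values into [0,1] (triangular wrap)
reflect01 <- function(x) {
  x <- x %% 2
  ifelse(x > 1, 2 - x, x)
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

rot2 <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)

unit_corners <- function()
  matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2L, byrow = TRUE,
         dimnames = list(c("bottom_left", "bottom_right",
                           "top_right", "top_left"), c("x", "y")))

# egocentric skeleton (arena units), animal facing +y, barycenter at origin;
# barycenter = mean(neck, body_mid) must hold, so those two are symmetric
skeleton_template <- function() {
  m <- rbind(nose       = c(0,     0.080),
             ear_left   = c(-0.022, 0.055),
             ear_right  = c(0.022,  0.055),
             neck       = c(0,     0.030),
             body_mid   = c(0,    -0.030),
             tail_base  = c(0,    -0.080),
             tail_mid   = c(0.01, -0.130),
             tail_end   = c(0.02, -0.180))
  colnames(m) <- c("x", "y")
  m
}

# run code with a local, restorable RNG state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
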