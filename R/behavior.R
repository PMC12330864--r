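#' @title Pose-track normalization and kinematics
#' @description
#' Consumes pose-estimation output (DeepLabCut CSV layout) for an 8-point
#' rodent skeleton in an open-field arena. Camera placement varies between
#' recordings, so coordinates are first normalized: translated to the
#' arena origin, rotated so the bottom wall lies on the x-axis, and scaled
#' so each wall spans [0, 1]. Derived measures: barycenter speed,
#' egocentric head movement (orientation-corrected), and the memory index
#' from object-exploration times.
#' @name behavior-module
NULL

#' Canonical body-part names
#' @return character vector of the 8 tracked body parts.
#' @export
dlc_bodyparts <- function()
  c("nose", "ear_left", "ear_right", "neck", "body_mid",
    "tail_base", "tail_mid", "tail_end")

#' Pose track container
#'
#' @param coords numeric array frames x bodyparts x 2 (x, y), with body-part
#'   dimnames; or a data frame with `<part>_x` / `<part>_y` columns.
#' @param corners 4 x 2 matrix of arena corners in the same coordinate
#'   frame, in the pinned order bottom-left, bottom-right, top-right,
#'   top-left.
#' @param fps frame rate (> 0).
#' @param likelihoods optional frames x bodyparts confidence matrix.
#' @return object of class `pose_track`.
#' @export
pose_track <- function(coords, corners, fps, likelihoods = NULL) {
  if (is.data.frame(coords)) {
    parts <- unique(sub("_[xy]$", "", names(coords)))
    arr <- array(0, dim = c(nrow(coords), length(parts), 2L),
                 dimnames = list(NULL, parts, c("x", "y")))
    for (p in parts) {
      arr[, p, 1L] <- coords[[paste0(p, "_x")]]
      arr[, p, 2L] <- coords[[paste0(p, "_y")]]
    }
    coords <- arr
  }
  if (length(dim(coords)) != 3L || dim(coords)[3L] != 2L)
    stop("`coords` must be frames x bodyparts x 2")
  corners <- as.matrix(corners)
  if (!all(dim(corners) == c(4L, 2L)))
    stop("`corners` must be a 4 x 2 matrix")
  if (fps <= 0) stop("`fps` must be positive")
  structure(list(coords = coords, corners = corners, fps = fps,
                 likelihoods = likelihoods,
                 frame_count = dim(coords)[1L],
                 normalized = FALSE),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> %d frames @ %g fps, %d body parts%s\n",
              x$frame_count, x$fps, dim(x$coords)[2L],
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Normalize a pose track to arena coordinates
#'
#' Translates all coordinates so the bottom-left corner is the origin,
#' rotates by the angle of the bottom wall so it aligns with the x-axis,
#' and scales x by the bottom-wall length and y by the left-wall length so
#' each wall spans [0, 1]. For an exact similarity camera the corners map
#' onto the unit square; per-axis scaling also absorbs anisotropic pixels
#' or non-square arenas.
#'
#' @param track a [pose_track()] with corners in camera coordinates.
#' @return the normalized `pose_track` (corners replaced by their
#'   normalized images, `normalized = TRUE`).
#' @export
normalize_arena <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  cr <- track$corners
  bl <- cr[1L, ]; br <- cr[2L, ]; tl <- cr[4L, ]
  bottom <- br - bl; left <- tl - bl
  cross <- bottom[1L] * left[2L] - bottom[2L] * left[1L]
  if (sqrt(sum(bottom^2)) == 0 || sqrt(sum(left^2)) == 0 ||
      abs(cross) < 1e-9 * sqrt(sum(bottom^2)) * sqrt(sum(left^2)))
    stop("degenerate arena corners (collinear)")
  ang <- atan2(bottom[2L], bottom[1L])
  R <- rot2(-ang)
  sx <- sqrt(sum(bottom^2))
  sy <- sqrt(sum((R %*% left)[2L]^2))
  tx <- function(p) {
    q <- (p - matrix(bl, nrow(p), 2L, byrow = TRUE)) %*% t(R)
    q[, 1L] <- q[, 1L] / sx
    q[, 2L] <- q[, 2L] / sy
    q
  }
  out <- track
  for (f in seq_len(track$frame_count))
    out$coords[f, , ] <- tx(track$coords[f, , , drop = TRUE])
  out$corners <- tx(cr)
  out$normalized <- TRUE
  out
}

get_part <- function(track, part) {
  parts <- dimnames(track$coords)[[2L]]
  if (!(part %in% parts)) stop("missing body part: ", part)
  track$coords[, part, , drop = TRUE]
}

#' Barycenter of a pose track
#'
#' Mean of the neck and body-midpoint coordinates per frame.
#'
#' @param track a [pose_track()].
#' @return frames x 2 matrix.
#' @export
barycenter <- function(track) {
  (get_part(track, "neck") + get_part(track, "body_mid")) / 2
}

#' Instantaneous barycenter speed
#'
#' Euclidean displacement of the barycenter between consecutive frames, in
#' arena units per frame (multiply by `fps` for units/s via
#' `per_second = TRUE`).
#'
#' @param track a normalized [pose_track()].
#' @param per_second report units/s instead of units/frame.
#' @return list of class `kinematic_series`: `values` (length
#'   `frame_count - 1`), `kind = "speed"`, `mean`.
#' @export
compute_speed <- function(track, per_second = FALSE) {
  stopifnot(inherits(track, "pose_track"))
  if (track$frame_count < 2L) stop("need at least 2 frames")
  b <- barycenter(track)
  v <- sqrt(rowSums(diff(b)^2))
  if (per_second) v <- v * track$fps
  structure(list(values = v, kind = "speed", mean = mean(v),
                 per_second = per_second),
            class = "kinematic_series")
}

#' @export
print.kinematic_series <- function(x, ...) {
  cat(sprintf("<kinematic_series> %s, %d frames, mean %.4g\n",
              x$kind, length(x$values), x$mean))
  invisible(x)
}

# egocentric coordinates: center on barycenter, rotate so the neck lies on
# the +y axis (multiply by e^{i(pi/2 - phi)}, phi = angle of the neck
# vector), which removes the animal's orientation in space
egocentric_coords <- function(track, parts) {
  b <- barycenter(track)
  neck <- get_part(track, "neck") - b
  phi <- atan2(neck[, 2L], neck[, 1L])
  rot <- exp(1i * (pi / 2 - phi))
  out <- array(0, dim = c(track$frame_count, length(parts), 2L),
               dimnames = list(NULL, parts, c("x", "y")))
  for (p in seq_along(parts)) {
    xy <- get_part(track, parts[p]) - b
    z <- complex(real = xy[, 1L], imaginary = xy[, 2L]) * rot
    out[, p, 1L] <- Re(z)
    out[, p, 2L] <- Im(z)
  }
  out
}

#' Egocentric head movement
#'
#' Expresses the three head points (nose, both ears) in egocentric
#' coordinates — centered on the barycenter and rotation-corrected so the
#' neck points along +y — and returns, per frame, the norm of the
#' frame-to-frame difference of the stacked 6-vector of head coordinates.
#' Rigid whole-body translation and rotation therefore contribute nothing;
#' only posture change of the head relative to the body registers.
#'
#' @param track a normalized [pose_track()] containing nose, ear_left,
#'   ear_right, neck and body_mid.
#' @return list of class `kinematic_series` (`kind = "head_movement"`,
#'   length `frame_count - 1`).
#' @export
compute_head_movement <- function(track) {
  stopifnot(inherits(track, "pose_track"))
  if (track$frame_count < 2L) stop("need at least 2 frames")
  head_parts <- c("nose", "ear_left", "ear_right")
  ego <- egocentric_coords(track, head_parts)
  m <- cbind(ego[, 1L, ], ego[, 2L, ], ego[, 3L, ])   # frames x 6
  v <- sqrt(rowSums(diff(m)^2))
  structure(list(values = v, kind = "head_movement", mean = mean(v)),
            class = "kinematic_series")
}

#' Memory index from exploration times
#'
#' `(t_new - t_familiar) / (t_new + t_familiar)`: 0 is chance (equal
#' exploration of the novel and familiar object), 1 exclusive novelty
#' preference, -1 exclusive familiarity preference.
#'
#' @param t_new seconds exploring the new (or displaced) object (>= 0).
#' @param t_familiar seconds exploring the familiar object (>= 0).
#' @return a number in `[-1, 1]`; `NaN` with a warning if both times are 0.
#' @export
memory_index <- function(t_new, t_familiar) {
  if (t_new < 0 || t_familiar < 0) stop("exploration times must be >= 0")
  tot <- t_new + t_familiar
  if (tot == 0) {
    warning("no exploration at all; memory index undefined")
    return(NaN)
  }
  (t_new - t_familiar) / tot
}

# ---- DeepLabCut-layout CSV I/O -------------------------------------------

#' Write a pose track in DeepLabCut CSV layout
#'
#' Three header rows (scorer / bodyparts / coords) above one row per frame;
#' columns are x, y (and likelihood when present) per body part. Corners
#' and fps go to a JSON sidecar `<path>.meta.json`.
#'
#' @param track a [pose_track()].
#' @param path output CSV path.
#' @param scorer scorer tag used in the header (default "synthetic").
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(track, path, scorer = "synthetic") {
  parts <- dimnames(track$coords)[[2L]]
  has_lik <- !is.null(track$likelihoods)
  per <- if (has_lik) c("x", "y", "likelihood") else c("x", "y")
  hdr1 <- c("scorer", rep(scorer, length(parts) * length(per)))
  hdr2 <- c("bodyparts", rep(parts, each = length(per)))
  hdr3 <- c("coords", rep(per, length(parts)))
  body <- matrix(0, track$frame_count, length(parts) * length(per))
  ci <- 1L
  for (p in parts) {
    body[, ci] <- track$coords[, p, 1L]
    body[, ci + 1L] <- track$coords[, p, 2L]
    if (has_lik) body[, ci + 2L] <- track$likelihoods[, p]
    ci <- ci + length(per)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(hdr1, collapse = ","), paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ",")), con)
  utils::write.table(cbind(seq_len(track$frame_count) - 1L, body), con,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fps = track$fps,
                            corners = unclass(track$corners),
                            normalized = isTRUE(track$normalized)),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pose track from DeepLabCut CSV layout
#'
#' Inverse of [write_dlc_csv()]; corners/fps are taken from the JSON
#' sidecar unless supplied explicitly.
#'
#' @param path CSV path.
#' @param corners optional 4 x 2 corner matrix (overrides the sidecar).
#' @param fps optional frame rate (overrides the sidecar).
#' @return a [pose_track()].
#' @export
read_dlc_csv <- function(path, corners = NULL, fps = NULL) {
  hdr <- readLines(path, n = 3L)
  h2 <- strsplit(hdr[2L], ",")[[1L]][-1L]
  h3 <- strsplit(hdr[3L], ",")[[1L]][-1L]
  dat <- utils::read.csv(path, skip = 3L, header = FALSE)
  dat <- dat[, -1L, drop = FALSE]              # frame-index column
  parts <- unique(h2)
  coords <- array(0, dim = c(nrow(dat), length(parts), 2L),
                  dimnames = list(NULL, parts, c("x", "y")))
  lik <- NULL
  if ("likelihood" %in% h3)
    lik <- matrix(NA_real_, nrow(dat), length(parts),
                  dimnames = list(NULL, parts))
  for (p in parts) {
    coords[, p, 1L] <- dat[[which(h2 == p & h3 == "x")]]
    coords[, p, 2L] <- dat[[which(h2 == p & h3 == "y")]]
    if (!is.null(lik)) lik[, p] <- dat[[which(h2 == p & h3 == "likelihood")]]
  }
  meta_path <- paste0(path, ".meta.json")
  if ((is.null(corners) || is.null(fps)) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (is.null(corners)) corners <- matrix(unlist(meta$corners), 4L, 2L)
    if (is.null(fps)) fps <- meta$fps
  }
  if (is.null(corners) || is.null(fps))
    stop("corners and fps must come from the sidecar or be supplied")
  pose_track(coords, corners, fps, likelihoods = lik)
}
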