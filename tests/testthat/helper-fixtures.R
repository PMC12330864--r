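# shared fixtures and small independent oracles

# permutation-maximized label agreement between two labelings with K states
label_agreement <- function(a, b, K) {
  perms <- eegfluidity:::all_perms(K)
  best <- 0
  for (i in seq_len(nrow(perms))) {
    best <- max(best, mean(perms[i, ][a] == b))
  }
  best
}

# brute-force strict local maxima of a vector (indep. of find_peaks)
brute_local_maxima <- function(v) {
  out <- integer(0)
  for (i in 2:(length(v) - 1L))
    if (v[i] > v[i - 1L] && v[i] > v[i + 1L]) out <- c(out, i)
  out
}

# a rigid-skeleton track built directly from the egocentric template
rigid_track <- function(n_frames, centers, headings) {
  ego <- eegfluidity:::skeleton_template()
  coords <- array(0, c(n_frames, 8L, 2L),
                  dimnames = list(NULL, dlc_bodyparts(), c("x", "y")))
  for (f in seq_len(n_frames)) {
    R <- eegfluidity:::rot2(headings[f] - pi / 2)
    p <- ego %*% t(R)
    coords[f, , 1L] <- p[, 1L] + centers[f, 1L]
    coords[f, , 2L] <- p[, 2L] + centers[f, 2L]
  }
  pose_track(coords, eegfluidity:::unit_corners(), fps = 25)
}

unit_sq <- eegfluidity:::unit_corners()
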