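test_that("DPSS tapers are orthonormal and spectrally concentrated", {
  tp <- dpss_tapers(400, 3, 5)
  expect_equal(crossprod(tp), diag(5), tolerance = 1e-7)
  # leading taper concentrates its energy inside |f| <= NW/N
  sp <- Mod(fft(c(tp[, 1], rep(0, 3600))))^2
  inband <- sum(sp[1:31])          # 4000-point grid: bin 31 ~ 3/400
  expect_gt(inband / sum(sp[1:2000]), 0.999)
})

test_that("multitaper spectrogram localizes tones and keeps white noise flat", {
  rate <- 250
  t <- seq_len(rate * 30) / rate
  tone <- mc_series(matrix(sin(2 * pi * 8 * t), 1), rate)
  sp <- multitaper_spectrogram(tone, window_s = 5, overlap_s = 2.5)
  # peak at the bin nearest 8 Hz in every window
  for (w in seq_len(dim(sp$power)[1]))
    expect_equal(sp$freq[which.max(sp$power[w, , 1])], 8)
  # white noise: log-power slope over frequency ~ 0
  set.seed(31)
  slopes <- replicate(5, {
    wn <- mc_series(matrix(rnorm(rate * 30), 1), rate)
    sw <- multitaper_spectrogram(wn, 5, 2.5)
    m <- apply(sw$power[, , 1], 2, mean)
    unname(coef(lm(log(m[-1]) ~ sw$freq[-1]))[2])
  })
  expect_lt(max(abs(slopes)), 0.005)
  # equal-amplitude 8 + 50 Hz tones carry equal integrated power
  two <- mc_series(matrix(sin(2 * pi * 8 * t) + sin(2 * pi * 50 * t), 1), rate)
  s2 <- multitaper_spectrogram(two, 5, 2.5)
  m <- apply(s2$power[, , 1], 2, mean)
  p8 <- sum(m[abs(s2$freq - 8) <= 2])
  p50 <- sum(m[abs(s2$freq - 50) <= 2])
  expect_lt(abs(p8 / p50 - 1), 0.1)
  expect_error(multitaper_spectrogram(tone, 5, 5), "overlap")
  expect_error(multitaper_spectrogram(tone, 60), "window longer")
})

test_that("relative band power integrates to band-membership fractions", {
  rate <- 250
  t <- seq_len(rate * 30) / rate
  mk <- function(f) mc_series(matrix(sin(2 * pi * f * t), 1), rate)
  rmap <- c(ch1 = "PFC")
  sp8 <- multitaper_spectrogram(mk(8), 5, 2.5)
  bp8 <- relative_band_power(sp8, region_map = rmap)
  expect_gt(bp8$fraction[bp8$band == "theta"], 0.9)
  expect_lt(sum(bp8$fraction[bp8$band != "theta"]), 0.1)
  sp2 <- multitaper_spectrogram(mk(2), 5, 2.5)
  bp2 <- relative_band_power(sp2, region_map = rmap)
  expect_gt(bp2$fraction[bp2$band == "delta"], 0.9)
  # an exact partition of the spectral range sums to 1
  part <- list(lo = c(0, 40), hi = c(40, 126))
  bpp <- relative_band_power(sp8, bands = part, region_map = rmap)
  expect_equal(sum(bpp$fraction), 1, tolerance = 1e-6)
  # invariance under global gain
  spg <- multitaper_spectrogram(mc_series(7 * mk(8)$values, rate), 5, 2.5)
  expect_equal(relative_band_power(spg, region_map = rmap)$fraction,
               bp8$fraction, tolerance = 1e-9)
  expect_error(relative_band_power(sp8, bands = list(x = c(300, 400)),
                                   region_map = rmap), "spectral range")
  expect_error(relative_band_power(sp8, region_map = c(chX = "PFC")),
               "missing channels")
})

test_that("40 Hz relative power recovers an injected tone and scales with amplitude", {
  rate <- 200
  t <- seq_len(rate * 120) / rate
  set.seed(32)
  x <- sqrt(2) * sin(2 * pi * 40 * t) + rnorm(length(t))   # SNR 0 dB
  s <- mc_series(matrix(x, 1), rate)
  rmap <- c(ch1 = "VIS")
  f40 <- relative_40hz_power(s, region_map = rmap)
  f35 <- relative_40hz_power(s, target_hz = 35, region_map = rmap)
  expect_gte(f40$fraction / f35$fraction, 10)
  # pure white noise: 40 Hz fraction ~ one bin's share of the bandwidth
  wn <- mc_series(matrix(rnorm(length(t)), 1), rate)
  fw <- relative_40hz_power(wn, region_map = rmap)
  n_bins <- rate * 60 / 2 + 1
  expect_lt(fw$fraction, 10 / n_bins)
  # amplitude doubling leaves the fraction unchanged
  f40b <- relative_40hz_power(mc_series(2 * s$values, rate),
                              region_map = rmap)
  expect_equal(f40b$fraction, f40$fraction, tolerance = 1e-9)
  # injected amplitude and recovered fraction are monotonically related
  set.seed(33)
  noise <- rnorm(length(t))
  fr <- vapply(c(0.3, 1, 3), function(a) {
    ss <- mc_series(matrix(a * sin(2 * pi * 40 * t) + noise, 1), rate)
    relative_40hz_power(ss, region_map = rmap)$fraction
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})
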