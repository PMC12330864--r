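test_that("log-distance observable follows the Euclidean metric", {
  # 3-4-5 triangle: two channels, ref at origin
  x <- cbind(c(0, 0), c(3, 4))
  g <- log_distance_series(x, 1)
  expect_equal(as.numeric(g), -log(5))
  expect_equal(attr(g, "times"), 2L)
  # unit step on one channel gives g = 0
  y <- cbind(c(0, 0), c(1, 0))
  expect_equal(as.numeric(log_distance_series(y, 1)), 0)
  # doubling all amplitudes shifts every g by -log(2)
  set.seed(1)
  z <- matrix(rnorm(40), 4)
  g1 <- log_distance_series(z, 3)
  g2 <- log_distance_series(2 * z, 3)
  expect_equal(as.numeric(g2), as.numeric(g1) - log(2))
  # duplicated reference point excluded with a warning
  dup <- cbind(c(1, 1), c(1, 1), c(0, 3))
  expect_warning(gd <- log_distance_series(dup, 1), "zero distance")
  expect_equal(attr(gd, "n_zero_excluded"), 1L)
  expect_error(log_distance_series(z, 99), "outside")
})

test_that("Suveges closed form equals numerical likelihood maximization", {
  set.seed(42)
  for (i in 1:50) {
    n_exc <- sample(5:200, 1)
    L <- sort(sample.int(20000, n_exc))
    Si <- diff(L) - 1
    p <- runif(1, 0.005, 0.05)
    closed <- eegfluidity:::suveges_closed_form(Si, p)
    numeric <- suveges_numeric_mle(Si, p)
    expect_lt(abs(closed - numeric), 1e-6)
  }
  # spot-check the numeric MLE itself against a dense grid search
  L <- c(10, 20, 30, 40)
  Si <- diff(L) - 1
  grid <- seq(1e-6, 1 - 1e-6, length.out = 200000)
  ll <- function(th) {
    N <- length(Si); Nc <- sum(Si > 0); pS <- 0.02 * sum(Si)
    (N - Nc) * log1p(-th) + 2 * Nc * log(th) - th * pS
  }
  expect_lt(abs(suveges_numeric_mle(Si, 0.02) - grid[which.max(ll(grid))]),
            1e-4)
})

test_that("extremal index hits its analytic limits and degenerate contracts", {
  # iid observable: theta near 1 (Poisson returns)
  set.seed(7)
  g <- rnorm(100000)
  est <- estimate_extremal_index(g)
  expect_gt(est$theta, 0.95)
  expect_lte(est$theta, 1)
  expect_equal(est$n_exceedances, sum(g > est$threshold))
  # one contiguous exceedance run: fixed point, theta exactly 0
  run <- c(rep(0, 400), rep(5, 6), rep(0, 400))
  expect_identical(estimate_extremal_index(run, q = 0.98)$theta, 0)
  # fewer than two exceedances -> NaN with reason
  one <- c(rep(0, 400), 9)
  est1 <- estimate_extremal_index(one, q = 0.999)
  expect_true(is.nan(est1$theta))
  expect_match(attr(est1$theta, "reason"), "fewer than 2")
  # too-short series -> NaN with reason
  est2 <- estimate_extremal_index(rnorm(50))
  expect_true(is.nan(est2$theta))
  expect_match(attr(est2$theta, "reason"), "too short")
  expect_error(estimate_extremal_index(g, q = 1.2), "q")
  # sigma is the mean excess over the threshold
  expect_equal(est$sigma, mean(g[g > est$threshold]) - est$threshold)
})

test_that("fluidity series is invariant under scaling and channel permutation", {
  e <- gen_var1(6, 3000, persistence = 0.6, seed = 11)
  x <- e$series$values
  f1 <- fluidity(x, ref_stride = 100)
  f2 <- fluidity(5.5 * x, ref_stride = 100)
  expect_equal(f1$theta, f2$theta)
  f3 <- fluidity(x[sample(6), ], ref_stride = 100)
  expect_equal(f1$theta, f3$theta)
  expect_equal(f1$ref_times, seq(1, 3000, by = 100))
  # degenerate stride: single reference
  fs <- fluidity(x, ref_stride = 3000)
  expect_length(fs$theta, 1L)
  expect_error(fluidity(x, ref_stride = 0), "ref_stride")
})

test_that("theta distribution is time-reversal invariant on stationary series", {
  pvals <- vapply(1:5, function(s) {
    x <- gen_var1(6, 4000, persistence = 0.7, seed = s)$series$values
    fwd <- fluidity(x, ref_stride = 40)$theta
    rev_ <- fluidity(x[, ncol(x):1], ref_stride = 40)$theta
    suppressWarnings(
      ks.test(fwd[!is.nan(fwd)], rev_[!is.nan(rev_)])$p.value)
  }, numeric(1))
  # a distributional null: allow one seed in five at the 5% level
  expect_gte(sum(pvals > 0.05), 4L)
})

test_that("gap convention option changes the estimate in the documented direction", {
  set.seed(13)
  g <- as.numeric(arima.sim(list(ar = 0.8), 5000))
  a <- estimate_extremal_index(g, gap_convention = "Tminus1")
  b <- estimate_extremal_index(g, gap_convention = "T")
  expect_gt(b$theta, a$theta)   # S = T inflates gaps, pushing theta up
})

test_that("fluidity data-frame export carries one row per reference", {
  f <- fluidity(gen_iid_gaussian(4, 500, seed = 1)$series, ref_stride = 50)
  df <- as.data.frame(f)
  expect_equal(nrow(df), length(f$ref_times))
  expect_named(df, c("ref_time", "theta", "sigma", "n_exceedances"))
})
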