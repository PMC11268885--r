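test_that("trajectory labels are signed circular grid distances", {
  d <- data.frame(loc1_nom = c(0, 0), loc2_nom = c(40, 40),
                  loc3_nom = c(80, 320), col1_nom = c(120, 120),
                  col2_nom = c(160, 200), col3_nom = c(200, 240))
  expect_equal(trajectory_labels(d, "location", "12"), c(40, 40))
  expect_equal(trajectory_labels(d, "location", "23")[2], -80)  # 320 - 40 wraps
  expect_equal(trajectory_labels(d, "color", "13"), c(80, 120))
})

test_that("the 9-point ring admits exactly 8 distinct trajectory distances", {
  grid <- ring_grid()
  pairs <- expand.grid(a = grid, b = grid)
  pairs <- pairs[pairs$a != pairs$b, ]
  dists <- sort(unique(circ_diff(pairs$b, pairs$a)))
  expect_equal(dists, c(-160, -120, -80, -40, 40, 80, 120, 160))
})

test_that("a full design populates every trajectory class", {
  d <- generate_design(648, seed = 81)
  for (leg in c("12", "23", "13")) {
    census <- table(trajectory_labels(d, "location", leg))
    expect_equal(length(census), 8)
    expect_true(all(census >= 2))
  }
})

test_that("zero trajectory distance is rejected", {
  d <- data.frame(loc1_nom = 0, loc2_nom = 0, loc3_nom = 40,
                  col1_nom = 80, col2_nom = 120, col3_nom = 160)
  expect_error(trajectory_labels(d, "location", "12"), "zero")
})

test_that("Morlet power is band-selective and scales quadratically", {
  fs <- 200
  d <- generate_design(2, seed = 82)
  tt <- seq(0, 3, by = 1 / fs)
  mk <- function(f, amp = 1) {
    arr <- array(0, c(2, 1, length(tt)))
    arr[1, 1, ] <- amp * sin(2 * pi * f * tt)
    arr[2, 1, ] <- amp * sin(2 * pi * f * tt)
    epoch_set(arr, fs, 0, c(1, 2), d)
  }
  mid <- function(p) mean(p[1, 1, 200:400])
  p10 <- morlet_alpha_power(mk(10))
  p30 <- morlet_alpha_power(mk(30))
  expect_gt(mid(p10) / mid(p30), 10)
  p10x2 <- morlet_alpha_power(mk(10, amp = 2))
  expect_equal(mid(p10x2) / mid(p10), 4, tolerance = 1e-6)
})

test_that("white-noise alpha power matches the analytic filter gain", {
  fs <- 200; cycles <- 7
  set.seed(83)
  n <- 8000
  sigma <- 1.3
  d <- generate_design(1, seed = 84)
  arr <- array(rnorm(n, 0, sigma), c(1, 1, n))
  ep <- epoch_set(arr, fs, 0, 1, d)
  p <- morlet_alpha_power(ep, band = c(8, 12), cycles = cycles)
  observed <- mean(p[1, 1, 500:(n - 500)])
  # E|conv(x, w)|^2 = sigma^2 * sum |w_t|^2; for a unit-peak complex Morlet
  # sum |w_t|^2 ~ fs * integral exp(-t^2/sd^2) dt = fs * sd * sqrt(pi)
  expected <- mean(vapply(8:12, function(f) {
    sd_t <- cycles / (2 * pi * f)
    sigma^2 * fs * sd_t * sqrt(pi)
  }, numeric(1)))
  expect_lt(abs(observed - expected) / expected, 0.1)
})

test_that("degenerate wavelet inputs are rejected", {
  d <- generate_design(1, seed = 85)
  short <- epoch_set(array(rnorm(20), c(1, 1, 20)), 100, 0, 1, d)
  expect_error(morlet_alpha_power(short), "shorter than the widest wavelet")
  lowfs <- epoch_set(array(rnorm(200), c(1, 1, 200)), 20, 0, 1, d)
  expect_error(morlet_alpha_power(lowfs), "sampling rate")
})

test_that("separable classes are decoded near-perfectly", {
  set.seed(86)
  classes <- c(-160, -120, -80, -40, 40, 80, 120, 160)
  labs <- rep(classes, each = 8)
  mu <- matrix(rnorm(8 * 6, 0, 10), 8, 6)
  feat <- mu[match(labs, classes), ] + matrix(rnorm(64 * 6, 0, 0.05), 64, 6)
  acc <- decode_trajectory(feat, labs, n_folds = 4, n_repeats = 2, seed = 1)
  expect_gt(as.numeric(acc), 0.99)
})

test_that("accuracy is invariant to a global rescaling of the features", {
  set.seed(87)
  classes <- c(-160, -120, -80, -40, 40, 80, 120, 160)
  labs <- rep(classes, each = 6)
  feat <- matrix(rnorm(48 * 5), 48, 5) +
    outer(match(labs, classes), rep(1, 5)) * 0.8
  a1 <- decode_trajectory(feat, labs, n_folds = 3, n_repeats = 2, seed = 2)
  a2 <- decode_trajectory(feat * 50, labs, n_folds = 3, n_repeats = 2, seed = 2)
  expect_equal(as.numeric(a1), as.numeric(a2))
})

test_that("the repeat-mean accuracy stabilizes as repeats grow", {
  set.seed(88)
  classes <- c(-160, -120, -80, -40, 40, 80, 120, 160)
  labs <- rep(classes, each = 6)
  feat <- matrix(rnorm(48 * 4), 48, 4)
  one_rep <- vapply(1:6, function(s)
    as.numeric(decode_trajectory(feat, labs, n_folds = 3, n_repeats = 1,
                                 seed = 100 + s)), numeric(1))
  eight_rep <- vapply(1:6, function(s)
    as.numeric(decode_trajectory(feat, labs, n_folds = 3, n_repeats = 8,
                                 seed = 200 + s)), numeric(1))
  expect_lt(sd(eight_rep), sd(one_rep))
})

test_that("a missing class is rejected with a census", {
  labs <- rep(c(-160, -120, -80, -40, 40, 80, 120), each = 6)
  feat <- matrix(rnorm(42 * 4), 42, 4)
  expect_error(decode_trajectory(feat, labs, seed = 1), "8 trajectory classes")
})
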