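test_that("basis responses hit the tuning-curve landmarks", {
  b <- make_basis()
  r <- basis_eval(b, b$centers)
  expect_equal(diag(r), rep(1, 9))                 # own center -> 1
  expect_equal(basis_eval(b, 40 + 90)[1, 2], 0)    # 90 deg away -> rectified 0
  expect_equal(basis_eval(b, 40)[1, 1], cos(40 * pi / 180)^8,
               tolerance = 1e-12)                  # one grid step away
  expect_true(all(r >= 0))
})

test_that("basis is rotationally symmetric and rejects duplicate centers", {
  b <- make_basis()
  r1 <- basis_eval(b, 73)
  b2 <- make_basis(centers = wrap360(ring_grid() + 15))
  r2 <- basis_eval(b2, 73 + 15)
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(make_basis(centers = c(0, 40, 400)), "duplicate")
})

test_that("weight training recovers an exact linear mapping", {
  set.seed(31)
  k <- 9; m <- 14; n <- 60
  C1 <- t(basis_eval(make_basis(), runif(n, 0, 360)))
  W0 <- matrix(rnorm(m * k), m, k)
  W <- train_weights(W0 %*% C1, C1)
  expect_equal(W, W0, tolerance = 1e-8)
  expect_error(train_weights(matrix(0, m, 5), C1[, 1:5]), "fewer trials")
})

test_that("training residuals are orthogonal to the channel predictors", {
  set.seed(32)
  k <- 9; m <- 12; n <- 80
  C1 <- t(basis_eval(make_basis(), runif(n, 0, 360)))
  B1 <- matrix(rnorm(m * k), m, k) %*% C1 + matrix(rnorm(m * n, 0, 0.5), m, n)
  W <- train_weights(B1, C1)
  expect_lt(max(abs((B1 - W %*% C1) %*% t(C1))), 1e-8)
  # agrees with an independent least-squares solve per sensor
  W_lm <- t(stats::lm.fit(t(C1), t(B1))$coefficients)
  expect_equal(unname(W), unname(W_lm), tolerance = 1e-8)
})

test_that("inversion is a left inverse and is unbiased under sensor noise", {
  set.seed(33)
  m <- 16; k <- 9; n <- 20
  W <- matrix(rnorm(m * k), m, k)
  C <- matrix(runif(n * k), n, k)
  expect_equal(invert_weights(W, W %*% t(C)), C, tolerance = 1e-10)
  expect_equal(invert_weights(W, matrix(0, m, n)), matrix(0, n, k))
  # Monte-Carlo mean of noisy inversions approaches the truth
  reps <- 400
  est <- matrix(0, n, k)
  for (i in seq_len(reps)) {
    B2 <- W %*% t(C) + matrix(rnorm(m * n, 0, 0.5), m, n)
    est <- est + invert_weights(W, B2)
  }
  expect_lt(max(abs(est / reps - C)), 0.05)
  expect_error(invert_weights(W[, c(1:8, 8)], W[, c(1:8, 8)] %*% t(C)),
               "rank")
})

test_that("full IEM round trip is exact for any full-rank weights", {
  set.seed(34)
  for (i in 1:5) {
    m <- sample(9:20, 1); n <- sample(20:40, 1); k <- 9
    C <- t(basis_eval(make_basis(), runif(n, 0, 360))) +
      matrix(runif(k * n, 0, 0.1), k, n)
    W0 <- matrix(rnorm(m * k), m, k)
    B <- W0 %*% C
    expect_equal(invert_weights(train_weights(B, C), B), t(C),
                 tolerance = 1e-8)
  }
})

test_that("recentering aligns responses to the 0-degree channel", {
  grid <- ring_grid()
  n <- 18
  set.seed(35)
  feats <- sample(grid, n, replace = TRUE)
  # delta responses at each trial's own feature channel
  C2 <- t(vapply(feats, function(f) as.numeric(grid == f), numeric(9)))
  avg <- recenter_average(C2, feats)
  expect_equal(avg, c(1, rep(0, 8)))
  # flat responses stay flat
  expect_equal(recenter_average(matrix(1, n, 9), feats), rep(1, 9))
  # basis-shaped responses recenter onto the basis curve at 0
  b <- make_basis()
  C2b <- basis_eval(b, feats)  # trial i's response peaks at its feature
  # response vector per trial: channel j responds f_j(feat)
  avg_b <- recenter_average(C2b, feats)
  expect_equal(avg_b, basis_eval(b, 0)[1, ], tolerance = 1e-12)
  expect_error(recenter_average(C2, feats + 25), "grid")
})

test_that("recentering is equivariant to a one-step rotation of all features", {
  set.seed(36)
  feats <- sample(ring_grid(), 30, replace = TRUE)
  C2 <- basis_eval(make_basis(), feats) + matrix(rnorm(30 * 9, 0, 0.1), 30, 9)
  a1 <- recenter_average(C2, feats)
  # rotating features one grid step and the channel responses one slot
  C2rot <- C2[, c(9, 1:8)]
  a2 <- recenter_average(C2rot, wrap360(feats + 40))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("slope score is signed and matches an independent regression", {
  b <- make_basis()
  curve <- basis_eval(b, 0)[1, ]
  expect_equal(response_slope(rep(0.3, 9)), 0)
  s <- response_slope(curve)
  expect_gt(s, 0)
  # oracle: lm on the folded curve
  offs <- abs(wrap180(ring_grid()))
  folded <- tapply(curve, offs, mean)
  d <- as.numeric(names(folded))
  fit <- stats::lm(folded ~ I((180 - d) / 180))
  expect_equal(s, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(response_slope(-curve), -s, tolerance = 1e-12)
})

test_that("Gaussian smoothing has the contracted kernel and edge behavior", {
  fs <- 100
  x <- c(rep(0, 50), 1, rep(0, 50))
  y <- gaussian_smooth(x, 0.040, fs)
  # profile proportional to a Gaussian with SD 4 samples around the impulse
  # (the kernel is truncated at 4 SD, so compare within that support)
  tt <- seq_along(x) - 51
  g <- exp(-tt^2 / (2 * (0.04 * fs)^2))
  inside <- abs(tt) <= 16
  expect_equal((y / max(y))[inside], (g / max(g))[inside], tolerance = 1e-10)
  expect_true(all(y[abs(tt) > 16] == 0))
  # renormalization: constant input is exactly preserved, also at the edges
  expect_equal(gaussian_smooth(rep(2.5, 30), 0.040, fs), rep(2.5, 30))
})

test_that("decoding finds the activation window and not the silence", {
  d <- small_design(72)
  sim <- simulate_eeg(d, n_sensors = 16, snr = Inf, fs = 50, tmin = -0.2,
                      tmax = 1.0, item_latencies = c(0.1, 0.5, 0.9),
                      envelope_width = 0.1, seed = 41)
  dec <- suppressWarnings(
    decode_timecourse(sim$epochs, d$loc1_nom, smoothing_sd = 0))
  inside <- sim$epochs$times > 0.12 & sim$epochs$times < 0.18
  before <- sim$epochs$times < 0.08
  expect_true(all(dec$slope[inside] > 0.2))
  expect_true(all(abs(dec$slope[before]) < 1e-8))
})

test_that("shuffled labels give a near-zero mean slope", {
  d <- small_design(96)
  sim <- simulate_eeg(d, n_sensors = 16, snr = 2, fs = 50, tmin = 0,
                      tmax = 1.0, item_latencies = c(0.1, 0.4, 0.7),
                      envelope_width = 0.25, seed = 42)
  set.seed(43)
  dec <- suppressWarnings(
    decode_timecourse(sim$epochs, sample(d$loc1_nom)))
  expect_lt(abs(mean(dec$slope)), 0.05)
})

test_that("decoding slope grows with SNR", {
  d <- small_design(72)
  means <- vapply(c(0.25, 1, 4), function(snr) {
    m <- 0
    for (r in 1:3) {
      sim <- simulate_eeg(d, n_sensors = 16, snr = snr, fs = 50, tmin = 0,
                          tmax = 0.6, item_latencies = c(0.1, 0.3, 0.45),
                          envelope_width = 0.15, seed = 50 + r)
      dec <- suppressWarnings(decode_timecourse(sim$epochs, d$loc1_nom))
      m <- m + mean(dec$slope[sim$epochs$times >= 0.1 &
                                sim$epochs$times <= 0.25])
    }
    m / 3
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("single-block data are rejected", {
  d <- small_design(24, n_blocks = 1)
  sim <- simulate_eeg(d, n_sensors = 12, snr = 1, fs = 50, tmin = 0,
                      tmax = 0.5, item_latencies = c(0, 0.1, 0.2),
                      envelope_width = 0.2, seed = 44)
  expect_error(decode_timecourse(sim$epochs, d$loc1_nom), "2 blocks")
})
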