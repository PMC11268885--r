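test_that("lagged correlation peaks at a pure shift", {
  set.seed(61)
  fs <- 100
  x <- rnorm(300)
  L0 <- 12
  y <- c(rep(0, L0), x)[1:300]
  lr <- lagged_correlation(x, y, 0.3, fs)
  expect_equal(lr$lag[which.max(lr$r)], L0 / fs)
  expect_gt(max(lr$r), 0.95)
})

test_that("independent noise stays inside the null band", {
  set.seed(62)
  lr <- lagged_correlation(rnorm(500), rnorm(500), 0.2, 100)
  expect_true(all(abs(lr$r) < 0.15))
})

test_that("peak height under additive noise matches the analytic attenuation", {
  set.seed(63)
  fs <- 100; n <- 4000; L0 <- 10; a <- 0.8; sn <- 1.5
  peaks <- replicate(10, {
    x <- rnorm(n)
    y <- a * c(rep(0, L0), x)[1:n] + rnorm(n, 0, sn)
    lagged_correlation(x, y, 0.2, fs)$r[L0 + 1]
  })
  expected <- a / sqrt(a^2 + sn^2)  # unit-variance x
  se <- sd(peaks) / sqrt(length(peaks))
  expect_lt(abs(mean(peaks) - expected), 3 * se + 0.005)
})

test_that("zero-variance overlaps are flagged as undefined", {
  expect_warning(lr <- lagged_correlation(rep(1, 50), rnorm(50), 0.1, 100),
                 "zero-variance")
  expect_true(all(is.na(lr$r)))
})

test_that("direction asymmetry is antisymmetric and zero under exchange symmetry", {
  set.seed(64)
  fs <- 100
  x <- rnorm(200); y <- rnorm(200); z <- rnorm(200)
  tc <- rbind(x, y, z)
  prof <- direction_asymmetry(tc, 0.3, fs)
  swapped <- direction_asymmetry(rbind(y, x, z), 0.3, fs)
  expect_equal(swapped$asym[1, ], -prof$asym[1, ], tolerance = 1e-12)
  same <- direction_asymmetry(rbind(x, x, z), 0.3, fs)
  expect_equal(same$asym[1, ], rep(0, length(same$lags)), tolerance = 1e-12)
})

test_that("a planted forward chain gives positive asymmetry that flips on reversal", {
  set.seed(65)
  fs <- 100; n <- 400; L0 <- 13
  base <- gaussian_smooth(rnorm(n), 0.02, fs)
  x1 <- base + rnorm(n, 0, 0.2)
  x2 <- c(rep(0, L0), base)[1:n] + rnorm(n, 0, 0.2)
  x3 <- c(rep(0, 2 * L0), base)[1:n] + rnorm(n, 0, 0.2)
  prof <- direction_asymmetry(rbind(x1, x2, x3), 0.3, fs)
  expect_equal(find_peak_lag(prof), L0 / fs)
  expect_gt(max(prof$mean), 0.3)
  rev_prof <- direction_asymmetry(rbind(x3, x2, x1), 0.3, fs)
  expect_equal(rev_prof$mean, -prof$mean, tolerance = 1e-12)
})

test_that("peak lag takes the smallest lag on ties and warns when flat", {
  prof <- structure(list(lags = c(0, 0.01, 0.02, 0.03),
                         mean = c(0.1, 0.5, 0.5, 0.2)),
                    class = "LagProfile")
  expect_equal(find_peak_lag(prof), 0.01)
  flat <- structure(list(lags = c(0, 0.01, 0.02), mean = rep(0.2, 3)),
                    class = "LagProfile")
  expect_warning(pl <- find_peak_lag(flat), "flat")
  expect_equal(pl, 0)
})

test_that("theoretical transition matrices have superdiagonal ones", {
  expect_equal(theoretical_matrix(3),
               rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)))
  expect_equal(theoretical_matrix(2), rbind(c(0, 1), c(0, 0)))
  m4 <- theoretical_matrix(4)
  expect_equal(which(m4 == 1), which(row(m4) + 1 == col(m4)))
})

test_that("empirical matrix has unit diagonal at zero lag and sees the chain", {
  set.seed(66)
  fs <- 100; n <- 400; L0 <- 10
  base <- gaussian_smooth(rnorm(n), 0.02, fs)
  x1 <- base + rnorm(n, 0, 0.1)
  x2 <- c(rep(0, L0), base)[1:n] + rnorm(n, 0, 0.1)
  x3 <- c(rep(0, 2 * L0), base)[1:n] + rnorm(n, 0, 0.1)
  tc <- rbind(x1, x2, x3)
  m0 <- empirical_matrix(tc, 0, fs)
  expect_equal(diag(m0), rep(1, 3))
  mL <- empirical_matrix(tc, L0 / fs, fs)
  chain <- c(mL[1, 2], mL[2, 3])
  others <- mL[!(row(mL) + 1 == col(mL))]
  expect_gt(min(chain), max(others))
})

test_that("matrix similarity identities hold and degenerate input is flagged", {
  TT <- theoretical_matrix(3)
  expect_equal(matrix_similarity(TT, TT), 1)
  expect_equal(matrix_similarity(1 - TT, TT), -1)
  expect_warning(s <- matrix_similarity(matrix(0.5, 3, 3), TT), "constant")
  expect_true(is.na(s))
  # off-diagonal option drops the diagonal cells
  E <- TT; diag(E) <- 9
  expect_equal(matrix_similarity(E, TT, include_diagonal = FALSE), 1)
})

test_that("permutation null is deterministic and degenerates to a constant", {
  set.seed(67)
  tcs <- array(rnorm(5 * 3 * 80), c(5, 3, 80))
  const_stat <- function(tc) 42
  pn <- replay_permutation_null(tcs, const_stat, n_perm = 200, seed = 2)
  expect_equal(pn$threshold, 42)
  expect_equal(pn$observed, 42)
  st <- stat_peak_asymmetry(0.2, 100)
  p1 <- replay_permutation_null(tcs, st, n_perm = 200, seed = 3)
  p2 <- replay_permutation_null(tcs, st, n_perm = 200, seed = 3)
  expect_identical(p1$perms, p2$perms)
  expect_warning(replay_permutation_null(tcs, const_stat, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("permutation test keeps its false-positive rate near the nominal level", {
  set.seed(68)
  fs <- 100
  hits <- replicate(150, {
    tcs <- array(NA_real_, c(5, 3, 80))
    for (s in 1:5) for (i in 1:3)
      tcs[s, i, ] <- gaussian_smooth(rnorm(80), 0.04, fs)
    pn <- replay_permutation_null(tcs, stat_peak_asymmetry(0.2, fs),
                                  n_perm = 199, seed = sample.int(1e6, 1))
    pn$observed > pn$threshold
  })
  rate <- mean(hits)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
})
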