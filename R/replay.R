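#' Lagged cross-correlation of two time courses
#'
#' At each nonnegative lag L (in samples), the Pearson correlation of
#' `x(t)` with `y(t + L)` over the overlapping window. A positive peak at
#' lag L means y follows x by L samples.
#'
#' @param x,y Equal-length numeric time courses.
#' @param max_lag Maximum lag in seconds (must leave at least 3 overlapping
#'   samples).
#' @param fs Sampling rate in Hz.
#' @return data.frame with `lag` (seconds) and `r`; zero-variance overlaps
#'   yield NA with a warning.
#' @export
lagged_correlation <- function(x, y, max_lag, fs) {
  stopifnot(length(x) == length(y), max_lag >= 0, fs > 0)
  n <- length(x)
  lmax <- floor(max_lag * fs)
  if (n - lmax < 3)
    stop("max_lag too large for the window length")
  r <- numeric(lmax + 1)
  degenerate <- FALSE
  for (L in 0:lmax) {
    a <- x[1:(n - L)]; b <- y[(1 + L):n]
    m <- n - L
    sa <- sum(a); sb <- sum(b)
    va <- sum(a * a) - sa * sa / m
    vb <- sum(b * b) - sb * sb / m
    if (va <= 0 || vb <= 0) {
      r[L + 1] <- NA_real_
      degenerate <- TRUE
    } else {
      r[L + 1] <- (sum(a * b) - sa * sb / m) / sqrt(va * vb)
    }
  }
  if (degenerate)
    warning("zero-variance overlap at some lag(s); coefficients undefined there")
  data.frame(lag = (0:lmax) / fs, r = r)
}

#' Forward-minus-reverse cross-correlation asymmetry
#'
#' For three item time courses, computes the lagged correlation in the forward
#' direction (item 1 leading item 2; item 2 leading item 3) and in the reverse
#' direction, and their difference per lag. The asymmetry removes the shared
#' autocorrelation component so that a directional (sequential) structure
#' shows as a signed peak: positive for forward replay, negative for reverse.
#' The two pair profiles are averaged into a consensus profile.
#'
#' @param tc 3 x time matrix (rows = items in presentation order) or list of
#'   three equal-length time courses.
#' @param max_lag Maximum lag in seconds (default 0.5).
#' @param fs Sampling rate in Hz.
#' @return Object of class `LagProfile`: list with `lags`, per-pair `fwd`,
#'   `rev`, `asym` (matrices 2 x lags for pairs 1-2 and 2-3) and `mean`
#'   (average asymmetry profile).
#' @export
direction_asymmetry <- function(tc, max_lag = 0.5, fs) {
  if (is.list(tc)) tc <- do.call(rbind, tc)
  stopifnot(nrow(tc) == 3)
  pairs <- list(c(1, 2), c(2, 3))
  fwd <- rev <- NULL
  for (p in pairs) {
    f <- lagged_correlation(tc[p[1], ], tc[p[2], ], max_lag, fs)
    b <- lagged_correlation(tc[p[2], ], tc[p[1], ], max_lag, fs)
    fwd <- rbind(fwd, f$r)
    rev <- rbind(rev, b$r)
  }
  lags <- lagged_correlation(tc[1, ], tc[2, ], max_lag, fs)$lag
  asym <- fwd - rev
  structure(list(lags = lags, fwd = fwd, rev = rev, asym = asym,
                 mean = colMeans(asym)),
            class = "LagProfile")
}

#' Peak lag of a mean asymmetry profile
#'
#' Lag (seconds) at which the mean forward-minus-reverse asymmetry is maximal.
#' Ties are broken to the smallest lag; a flat profile returns the smallest
#' lag with a degeneracy warning.
#'
#' @param profile A `LagProfile` from [direction_asymmetry()].
#' @return Peak lag in seconds.
#' @export
find_peak_lag <- function(profile) {
  m <- profile$mean
  if (all(is.na(m))) stop("all-undefined asymmetry profile")
  if (length(unique(m[!is.na(m)])) == 1L)
    warning("flat asymmetry profile; peak lag is degenerate")
  profile$lags[which.max(m)]  # which.max takes the first (smallest lag) on ties
}

#' Theoretical forward-transition matrix
#'
#' The idealized ordered-pair correlation pattern of a clean forward replay at
#' the consensus lag: 1 at every (i, i+1) cell, 0 elsewhere (diagonal
#' included).
#'
#' @param n_items Number of sequence items (default 3).
#' @return n x n numeric matrix.
#' @export
theoretical_matrix <- function(n_items = 3) {
  stopifnot(n_items >= 2)
  m <- matrix(0, n_items, n_items)
  m[cbind(seq_len(n_items - 1), 2:n_items)] <- 1
  m
}

#' Empirical transition matrix at a fixed lag
#'
#' All nine ordered-pair lagged correlations of the three item time courses at
#' the given lag: `M[i, j] = cor(x_i(t), x_j(t + lag))`, diagonal included.
#'
#' @param tc 3 x time matrix or list of three time courses.
#' @param lag Lag in seconds.
#' @param fs Sampling rate in Hz.
#' @return 3 x 3 numeric matrix.
#' @export
empirical_matrix <- function(tc, lag, fs) {
  if (is.list(tc)) tc <- do.call(rbind, tc)
  n <- nrow(tc)
  L <- round(lag * fs)
  nt <- ncol(tc)
  stopifnot(L >= 0, nt - L >= 3)
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- tc[i, 1:(nt - L)]; b <- tc[j, (1 + L):nt]
    out[i, j] <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
                 else stats::cor(a, b)
  }
  out
}

#' Similarity of empirical and theoretical transition matrices
#'
#' Pearson correlation over all cells (diagonal included by default).
#'
#' @param E,TT Same-shape numeric matrices (empirical, theoretical).
#' @param include_diagonal Include diagonal cells (default TRUE).
#' @return Correlation coefficient; NA with a warning if either matrix is
#'   constant over the compared cells.
#' @export
matrix_similarity <- function(E, TT, include_diagonal = TRUE) {
  stopifnot(all(dim(E) == dim(TT)))
  sel <- if (include_diagonal) rep(TRUE, length(E)) else !diag(nrow(E))
  e <- E[sel]; th <- TT[sel]
  if (stats::sd(e, na.rm = TRUE) == 0 || stats::sd(th, na.rm = TRUE) == 0) {
    warning("constant matrix; similarity undefined")
    return(NA_real_)
  }
  stats::cor(e, th, use = "complete.obs")
}

#' Label-shuffle permutation null for a group replay statistic
#'
#' The group statistic is evaluated on the grand-average item time courses
#' across subjects. Under each permutation the item-identity assignment of the
#' decoded time courses is independently permuted within each subject before
#' grand-averaging, destroying any consistent sequential order while
#' preserving each subject's autocorrelation structure. Returns the 95th
#' percentile of the permutation distribution as the 0.05-level threshold.
#'
#' @param tcs Array subjects x 3 items x time of decoded time courses.
#' @param statistic Function taking a 3 x time matrix (grand-average item time
#'   courses) and returning a scalar.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed for the permutation stream.
#' @return List: `observed`, `threshold` (95th percentile), `p`
#'   ((b+1)/(n_perm+1) convention), `perms` (the permutation distribution).
#' @export
replay_permutation_null <- function(tcs, statistic, n_perm = 1000, seed = 1) {
  stopifnot(length(dim(tcs)) == 3, dim(tcs)[2] == 3)
  if (dim(tcs)[1] < 2) stop("need at least 2 subjects")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse threshold")
  set.seed(seed)
  ns <- dim(tcs)[1]
  grand <- apply(tcs, c(2, 3), mean)
  observed <- statistic(grand)
  nstat <- length(observed)  # statistic may be vector-valued (named)
  perms <- vapply(seq_len(n_perm), function(p) {
    g <- matrix(0, 3, dim(tcs)[3])
    for (s in seq_len(ns)) g <- g + tcs[s, sample(3), ]
    statistic(g / ns)
  }, numeric(nstat))
  perms <- matrix(perms, nrow = nstat)
  threshold <- apply(perms, 1, stats::quantile, probs = 0.95, na.rm = TRUE)
  pval <- vapply(seq_len(nstat), function(i)
    (1 + sum(perms[i, ] >= observed[i], na.rm = TRUE)) / (n_perm + 1),
    numeric(1))
  names(threshold) <- names(pval) <- names(observed)
  if (nstat == 1L) {
    list(observed = unname(observed), threshold = unname(threshold),
         p = unname(pval), perms = perms[1, ])
  } else {
    list(observed = observed, threshold = threshold, p = pval, perms = perms)
  }
}

#' Default group replay statistic: peak mean asymmetry
#'
#' Factory returning a statistic for [replay_permutation_null()]: the maximum
#' over lags of the mean forward-minus-reverse asymmetry profile.
#'
#' @param max_lag Maximum lag in seconds.
#' @param fs Sampling rate in Hz.
#' @return Function: 3 x time matrix -> scalar.
#' @export
stat_peak_asymmetry <- function(max_lag = 0.5, fs) {
  function(tc) max(direction_asymmetry(tc, max_lag, fs)$mean, na.rm = TRUE)
}

#' Group replay statistic: transition-matrix similarity at the peak lag
#'
#' Factory returning a statistic: find the peak lag of the mean asymmetry
#' profile, build the empirical transition matrix at that lag, and correlate
#' it with the theoretical forward pattern.
#'
#' @inheritParams stat_peak_asymmetry
#' @return Function: 3 x time matrix -> scalar.
#' @export
stat_matrix_similarity <- function(max_lag = 0.5, fs) {
  TT <- theoretical_matrix(3)
  function(tc) {
    prof <- direction_asymmetry(tc, max_lag, fs)
    lag <- find_peak_lag(prof)
    matrix_similarity(empirical_matrix(tc, lag, fs), TT)
  }
}
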