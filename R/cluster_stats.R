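#' Pointwise one-sample t-test across subjects
#'
#' One-sample t versus `null_value` at every time sample, two-tailed p.
#' Zero-variance samples give infinite t (flagged suprathreshold, p = 0).
#'
#' @param data Subjects x time numeric matrix (>= 3 subjects).
#' @param null_value Null-hypothesis value (scalar).
#' @return data.frame with `t` and `p` per time sample.
#' @export
pointwise_test <- function(data, null_value = 0) {
  stopifnot(is.matrix(data), nrow(data) >= 3)
  n <- nrow(data)
  m <- colMeans(data) - null_value
  s <- sqrt(pmax(0, (colSums(data^2) - n * colMeans(data)^2) / (n - 1)))
  tt <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf), m / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  data.frame(t = tt, p = p)
}

# maximal runs of TRUE; returns list of (start, end) index pairs
contiguous_runs <- function(mask) {
  if (!any(mask)) return(list())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  Map(c, starts[r$values], ends[r$values])
}

# largest suprathreshold cluster size for a t/p vector, sign-homogeneous
cluster_sizes <- function(tt, p, alpha) {
  sizes <- integer(0)
  bounds <- list()
  for (sgn in c(1, -1)) {
    mask <- (p < alpha) & (sign(tt) == sgn)
    mask[is.na(mask)] <- FALSE
    for (run in contiguous_runs(mask)) {
      sizes <- c(sizes, run[2] - run[1] + 1L)
      bounds <- c(bounds, list(run))
    }
  }
  list(sizes = sizes, bounds = bounds)
}

#' Cluster-based permutation test for a time course of group data
#'
#' Mass-univariate one-sample test with cluster correction: contiguous runs of
#' samples whose pointwise two-tailed p falls below `cluster_alpha` (same
#' t-sign within a run) form clusters scored by their size in samples. The
#' null distribution of the maximal cluster size is built by a Monte Carlo
#' randomization in which each subject's deviation from the null value is
#' randomly sign-flipped (the exchange of observed values with the null
#' constant); corrected p per cluster is `(b + 1) / (n_perm + 1)` where `b`
#' counts permutations whose maximal cluster size reaches the observed size.
#'
#' @param data Subjects x time matrix (>= 3 subjects).
#' @param null_value Null value tested against (0 for slope scores, 0.125 for
#'   8-way classifier accuracy).
#' @param cluster_alpha Cluster-defining pointwise threshold (default 0.05;
#'   0.001 is the stringent choice for strong encoding-period effects).
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @return Object of class `ClusterResult`: `clusters` data.frame (start/end
#'   sample index, size, corrected p), `pointwise` ([pointwise_test()] output),
#'   `max_null` (permutation distribution of maximal cluster sizes) and the
#'   parameters. An effect-free input yields an empty cluster table.
#' @export
cluster_permutation <- function(data, null_value = 0, cluster_alpha = 0.05,
                                n_perm = 1000, seed = 1) {
  stopifnot(is.matrix(data), nrow(data) >= 3, n_perm >= 100)
  set.seed(seed)
  dev <- data - null_value
  pw <- pointwise_test(data, null_value)
  obs <- cluster_sizes(pw$t, pw$p, cluster_alpha)

  ns <- nrow(dev)
  max_null <- vapply(seq_len(n_perm), function(i) {
    flip <- sample(c(-1, 1), ns, replace = TRUE)
    d2 <- dev * flip
    pw2 <- pointwise_test(d2, 0)
    cs <- cluster_sizes(pw2$t, pw2$p, cluster_alpha)
    if (length(cs$sizes)) as.numeric(max(cs$sizes)) else 0
  }, numeric(1))

  clusters <- if (length(obs$sizes)) {
    data.frame(
      start = vapply(obs$bounds, function(b) as.integer(b[1]), integer(1)),
      end = vapply(obs$bounds, function(b) as.integer(b[2]), integer(1)),
      size = as.integer(obs$sizes),
      p_corrected = vapply(obs$sizes, function(s)
        (1 + sum(max_null >= s)) / (n_perm + 1), numeric(1))
    )
  } else {
    data.frame(start = integer(0), end = integer(0), size = integer(0),
               p_corrected = numeric(0))
  }
  structure(list(clusters = clusters, pointwise = pw, max_null = max_null,
                 params = list(null_value = null_value,
                               cluster_alpha = cluster_alpha,
                               n_perm = n_perm, seed = seed)),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("ClusterResult: %d cluster(s) at cluster_alpha = %g, %d permutations\n",
              nrow(x$clusters), x$params$cluster_alpha, x$params$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Bootstrap test of a group-mean difference
#'
#' Resamples each group with replacement `n_boot` times, recomputes the
#' difference of group means, and reports a two-sided p from the proportion of
#' bootstrap differences crossing zero (with the (b+1)/(n+1) convention, so
#' fully separated groups bottom out at 2/(n_boot+1)).
#'
#' @param groupA,groupB Per-subject scalar statistics (length >= 2 each).
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return List with `p` (two-sided), `diff` (observed mean difference) and
#'   `boot` (bootstrap distribution).
#' @export
bootstrap_group_diff <- function(groupA, groupB, n_boot = 10000, seed = 1) {
  stopifnot(length(groupA) >= 2, length(groupB) >= 2, n_boot >= 1)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(sample(groupA, replace = TRUE)) - mean(sample(groupB, replace = TRUE))
  }, numeric(1))
  p <- 2 * min((1 + sum(boot <= 0)) / (n_boot + 1),
               (1 + sum(boot >= 0)) / (n_boot + 1))
  list(p = min(p, 1), diff = mean(groupA) - mean(groupB), boot = boot)
}
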