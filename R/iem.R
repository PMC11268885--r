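#' Idealized tuning basis
#'
#' Nine (by default) idealized feature-tuning channels: half-wave rectified
#' cosines of the angular distance to each channel center, raised to a power.
#' `f_k(theta) = max(0, cos(theta - phi_k))^exponent`, 360-degree period, so
#' the response at a channel's own center is exactly 1 and channels more than
#' 90 degrees away are silent before exponentiation.
#'
#' @param centers Channel centers in degrees (distinct; default the 9-point
#'   ring grid).
#' @param exponent Positive integer power (default 8).
#' @return Object of class `BasisSet` with `centers` and `exponent`.
#' @export
make_basis <- function(centers = ring_grid(), exponent = 8) {
  stopifnot(exponent >= 1)
  if (anyDuplicated(wrap360(centers)))
    stop("duplicate channel centers")
  structure(list(centers = wrap360(centers), exponent = exponent),
            class = "BasisSet")
}

#' Evaluate a tuning basis
#'
#' @param basis A `BasisSet` from [make_basis()].
#' @param theta Feature values in degrees.
#' @return Matrix length(theta) x k of channel responses in [0, 1].
#' @export
basis_eval <- function(basis, theta) {
  d <- cos(outer(deg2rad(theta), deg2rad(basis$centers), `-`))
  d[d < 0] <- 0
  d^basis$exponent
}

#' Train encoding-model weights by least squares
#'
#' Solves `B1 = W C1` for the sensor weights:
#' `W-hat = B1 C1' (C1 C1')^-1`. The residual `B1 - W-hat C1` is orthogonal to
#' the rows of `C1` (normal equations).
#'
#' @param B1 Sensor data, m sensors x n trials.
#' @param C1 Predicted channel responses, k channels x n trials (n >= k,
#'   full row rank).
#' @return Weight matrix, m x k.
#' @export
train_weights <- function(B1, C1) {
  stopifnot(is.matrix(B1), is.matrix(C1), ncol(B1) == ncol(C1))
  k <- nrow(C1)
  if (ncol(C1) < k)
    stop("fewer trials (", ncol(C1), ") than channels (", k, ")")
  G <- tcrossprod(C1)
  qrG <- qr(G)
  if (qrG$rank < k)
    stop("C1 C1' is singular (rank ", qrG$rank, " < ", k,
         "); some channels are not spanned by the training labels")
  t(solve(qrG, tcrossprod(C1, B1)))
}

#' Invert trained weights on test data
#'
#' Reconstructs channel responses from held-out sensor data via the
#' pseudoinverse: `C2-hat = (W'W)^-1 W' B2`, applied per time sample.
#'
#' @param W Weight matrix, m sensors x k channels, full column rank (m >= k).
#' @param B2 Test data: m x n matrix, or n trials x m sensors x time array.
#' @return For matrix input, an n x k matrix of channel estimates; for array
#'   input, an n x k x time array (`ChannelResponseEstimate`).
#' @export
invert_weights <- function(W, B2) {
  k <- ncol(W)
  G <- crossprod(W)
  qrG <- qr(G)
  if (qrG$rank < k)
    stop("weight matrix is rank-deficient (rank ", qrG$rank, " < ", k, ")")
  if (is.matrix(B2)) {
    stopifnot(nrow(B2) == nrow(W))
    return(t(solve(qrG, crossprod(W, B2))))
  }
  stopifnot(length(dim(B2)) == 3, dim(B2)[2] == nrow(W))
  n <- dim(B2)[1]; nt <- dim(B2)[3]
  out <- array(NA_real_, c(n, k, nt))
  for (t in seq_len(nt))
    out[, , t] <- t(solve(qrG, crossprod(W, t(B2[, , t, drop = TRUE]))))
  out
}

#' Recenter and average channel responses
#'
#' Circularly shifts each trial's estimated channel-response vector by whole
#' channel steps so that the trial's feature of interest lands on the
#' 0-degree channel, then averages across trials. Features must sit on the
#' channel grid (jitter below half a grid step is snapped).
#'
#' @param C2 Channel estimates: n x k matrix or n x k x time array.
#' @param features Feature value per trial, degrees.
#' @param centers Channel centers (degrees), default the 9-point grid.
#' @param snap_tol Largest distance (degrees) from the grid tolerated when
#'   snapping features to channels; defaults to 5, comfortably above the
#'   design's +-3 degree jitter.
#' @return Recentered mean response: length-k vector (matrix input) or
#'   k x time matrix (array input). The first element/row is the 0-degree
#'   (feature-aligned) channel; subsequent entries follow increasing offset.
#' @export
recenter_average <- function(C2, features, centers = ring_grid(),
                             snap_tol = 5) {
  k <- length(centers)
  step <- centers[2] - centers[1]
  shift <- round(wrap360(features) / step) %% k
  snapped <- wrap360(shift * step)
  off <- abs(wrap180(features - snapped))
  if (any(off > snap_tol))
    stop("feature values further than half a grid step from the channel grid")
  mat3 <- length(dim(C2)) == 3
  if (!mat3) C2 <- array(C2, c(dim(C2), 1))
  stopifnot(dim(C2)[1] == length(features), dim(C2)[2] == k)
  acc <- array(0, dim(C2)[2:3])
  for (i in seq_along(features)) {
    idx <- ((seq_len(k) - 1 + shift[i]) %% k) + 1
    acc <- acc + C2[i, idx, , drop = TRUE]
  }
  out <- acc / length(features)
  if (mat3) out else drop(out)
}

#' Slope score of a recentered channel response
#'
#' Folds the recentered tuning curve about its center (averaging the +d and
#' -d offsets), then regresses the folded response on a proximity axis
#' `(180 - d)/180` so that a center-peaked reconstruction yields a positive
#' slope. The score is the least-squares regression slope, in
#' channel-response units per unit proximity.
#'
#' @param centered Length-k recentered response (odd k, center first, as from
#'   [recenter_average()]) or k x time matrix.
#' @param centers Channel centers used to derive the offsets.
#' @param include_center Include the 0-offset point in the regression
#'   (default TRUE).
#' @return Scalar slope, or a per-time vector for matrix input.
#' @export
response_slope <- function(centered, centers = ring_grid(),
                           include_center = TRUE) {
  k <- length(centers)
  stopifnot(k %% 2 == 1)
  offs <- abs(wrap180(centers - centers[1]))      # 0,40,...,160,160,...,40
  d <- sort(unique(offs))                         # 0,40,80,120,160
  vec_in <- !is.matrix(centered)
  if (vec_in) {
    stopifnot(length(centered) == k)
    centered <- matrix(centered, ncol = 1)
  }
  stopifnot(nrow(centered) == k)
  folded <- matrix(NA_real_, length(d), ncol(centered))
  for (j in seq_along(d))
    folded[j, ] <- colMeans(centered[offs == d[j], , drop = FALSE])
  x <- (180 - d) / 180
  if (!include_center) {
    folded <- folded[-1, , drop = FALSE]
    x <- x[-1]
  }
  xc <- x - mean(x)
  slopes <- unname(colSums(xc * folded) / sum(xc^2))
  if (vec_in) slopes[1] else slopes
}

#' Gaussian smoothing with edge renormalization
#'
#' Convolves a time course with a Gaussian kernel of the given SD; near the
#' edges the kernel is renormalized over the valid support, so no padding
#' assumption is made. `sd = 0` returns the input.
#'
#' @param x Numeric time course.
#' @param sd Kernel SD in seconds.
#' @param fs Sampling rate in Hz.
#' @return Smoothed vector, same length.
#' @export
gaussian_smooth <- function(x, sd, fs) {
  if (sd <= 0) return(x)
  h <- max(1L, ceiling(4 * sd * fs))
  kk <- exp(-((-h:h) / (sd * fs))^2 / 2)
  n <- length(x)
  xp <- c(rep(NA, h), x, rep(NA, h))
  vapply(seq_len(n), function(i) {
    seg <- xp[i:(i + 2 * h)]
    ok <- !is.na(seg)
    sum(seg[ok] * kk[ok]) / sum(kk[ok])
  }, numeric(1))
}

#' Time-resolved IEM decoding with leave-one-block-out cross-validation
#'
#' At every time sample, encoding-model weights are trained on all blocks but
#' one ([train_weights()]; C1 from the idealized basis evaluated at the
#' training trials' labels), inverted on the held-out block
#' ([invert_weights()]), and the estimated channel responses are recentered to
#' the trial's label ([recenter_average()]). Folding over all blocks decodes
#' every trial exactly once; the recentered responses are averaged over all
#' trials and scored by [response_slope()], and the slope time course is
#' smoothed with a Gaussian kernel (default SD 40 ms).
#'
#' @param epochs An `EpochSet`.
#' @param labels Feature value per trial in degrees, on the nominal grid.
#' @param basis Tuning basis (default [make_basis()]).
#' @param smoothing_sd Gaussian kernel SD in seconds (default 0.040).
#' @param include_center Passed to [response_slope()].
#' @param sensors Optional sensor indices to restrict decoding to (e.g., a
#'   posterior subset); default all.
#' @return Object of class `DecodingTimecourse`: list with `times`, `slope`
#'   (smoothed), `slope_raw`, `mean_response` (k x time recentered average),
#'   and metadata (`smoothing_sd`, `n_blocks`).
#' @export
decode_timecourse <- function(epochs, labels, basis = make_basis(),
                              smoothing_sd = 0.040, include_center = TRUE,
                              sensors = NULL) {
  stopifnot(inherits(epochs, "EpochSet"),
            length(labels) == dim(epochs$data)[1])
  blocks <- unique(epochs$block_ids)
  if (length(blocks) < 2)
    stop("leave-one-block-out cross-validation needs at least 2 blocks")
  cover <- table(epochs$block_ids, factor(round(wrap360(labels))))
  if (any(cover == 0))
    warning("some blocks are missing some labels; training sets are unbalanced")
  data <- epochs$data
  if (!is.null(sensors)) data <- data[, sensors, , drop = FALSE]
  k <- length(basis$centers)
  nt <- dim(data)[3]

  acc <- matrix(0, k, nt)  # running sum of recentered responses
  n_dec <- 0L
  for (b in blocks) {
    test <- which(epochs$block_ids == b)
    train <- which(epochs$block_ids != b)
    C1 <- t(basis_eval(basis, labels[train]))          # k x n_train
    G <- tcrossprod(C1)
    if (qr(G)$rank < k) {
      # a label value absent from this training fold leaves its channel
      # unconstrained; fall back to the minimum-norm (pseudoinverse) solution
      warning("incomplete label coverage in fold for block ", b,
              "; using the pseudoinverse")
      sv <- svd(G)
      pos <- sv$d > max(sv$d) * 1e-10
      Ginv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      A <- crossprod(C1, Ginv)
    } else {
      A <- crossprod(C1, solve(G))                     # n_train x k
    }
    shift <- round(wrap360(labels[test]) /
                     (basis$centers[2] - basis$centers[1])) %% k
    for (t in seq_len(nt)) {
      B1t <- matrix(data[train, , t], nrow = length(train))  # n_train x m
      B2t <- matrix(data[test, , t], nrow = length(test))    # n_test x m
      W <- crossprod(B1t, A)                                 # m x k
      G <- crossprod(W)
      if (qr(G)$rank < k) {
        # degenerate sample (e.g., zero signal in a noiseless simulation):
        # no channel information, contribute a flat (zero) response
        next
      }
      C2 <- t(solve(G, crossprod(W, t(B2t))))                # n_test x k
      for (i in seq_along(test)) {
        idx <- ((seq_len(k) - 1 + shift[i]) %% k) + 1
        acc[, t] <- acc[, t] + C2[i, idx]
      }
    }
    n_dec <- n_dec + length(test)
  }
  mean_resp <- acc / n_dec
  slope_raw <- response_slope(mean_resp, basis$centers, include_center)
  slope <- gaussian_smooth(slope_raw, smoothing_sd, epochs$fs)
  structure(list(times = epochs$times, slope = slope, slope_raw = slope_raw,
                 mean_response = mean_resp,
                 smoothing_sd = smoothing_sd, n_blocks = length(blocks)),
            class = "DecodingTimecourse")
}

#' @export
print.DecodingTimecourse <- function(x, ...) {
  cat(sprintf("DecodingTimecourse: %d samples, t = [%.3f, %.3f] s, mean slope %.4f\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              mean(x$slope)))
  invisible(x)
}
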