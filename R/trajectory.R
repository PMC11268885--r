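#' Trajectory-distance label of a trial
#'
#' Signed circular distance between the two nominal grid values of a leg
#' (later minus earlier), wrapped to (-180, 180]. On the 9-point ring the
#' distance is a nonzero multiple of 40 with magnitude at most 160, so there
#' are exactly eight classes: +/-40, +/-80, +/-120, +/-160.
#'
#' @param design Design table ([generate_design()]).
#' @param domain "location" or "color".
#' @param leg "12", "23" or "13".
#' @return Numeric vector of signed distances in degrees, one per trial.
#' @export
trajectory_labels <- function(design, domain = c("location", "color"),
                              leg = c("12", "23", "13")) {
  domain <- match.arg(domain)
  leg <- match.arg(leg)
  pre <- substr(domain, 1, 3)
  i <- as.integer(substr(leg, 1, 1))
  j <- as.integer(substr(leg, 2, 2))
  d <- circ_diff(design[[paste0(pre, j, "_nom")]],
                 design[[paste0(pre, i, "_nom")]])
  if (any(d == 0))
    stop("zero trajectory distance encountered; design violates distinctness")
  d
}

# complex Morlet kernel at frequency f (Hz): gaussian envelope with
# sd_t = cycles / (2 pi f), support +/- 4 sd_t, unit-peak envelope
morlet_kernel <- function(f, fs, cycles) {
  sd_t <- cycles / (2 * pi * f)
  t <- seq(-4 * sd_t, 4 * sd_t, by = 1 / fs)
  exp(1i * 2 * pi * f * t) * exp(-t^2 / (2 * sd_t^2))
}

# same-length complex convolution via FFT
conv_same <- function(x, w) {
  n <- length(x); m <- length(w)
  N <- n + m - 1
  full <- stats::fft(stats::fft(c(x, rep(0, N - n))) *
                       stats::fft(c(w, rep(0, N - m))), inverse = TRUE) / N
  half <- (m - 1) %/% 2
  full[(half + 1):(half + n)]
}

#' Morlet-wavelet alpha-band power
#'
#' Time-frequency power from complex Morlet wavelets with a fixed number of
#' cycles (default 7), averaged over the band frequencies in 1 Hz steps
#' (default 8-12 Hz, the alpha band).
#'
#' @param epochs An `EpochSet` (fs must be at least twice the upper band
#'   edge; the epoch must be longer than the widest wavelet).
#' @param band Length-2 Hz pair (default c(8, 12)).
#' @param cycles Wavelet width in cycles (default 7).
#' @return Array trials x sensors x time of band-average power.
#' @export
morlet_alpha_power <- function(epochs, band = c(8, 12), cycles = 7) {
  stopifnot(inherits(epochs, "EpochSet"), length(band) == 2,
            band[1] <= band[2])
  fs <- epochs$fs
  if (fs < 2 * band[2])
    stop("sampling rate below twice the upper band edge")
  freqs <- seq(band[1], band[2], by = 1)
  kernels <- lapply(freqs, morlet_kernel, fs = fs, cycles = cycles)
  nt <- dim(epochs$data)[3]
  if (max(lengths(kernels)) > nt)
    stop("epoch shorter than the widest wavelet (",
         max(lengths(kernels)), " samples at ", band[1], " Hz)")
  out <- array(0, dim(epochs$data))
  for (i in seq_len(dim(epochs$data)[1])) {
    for (s in seq_len(dim(epochs$data)[2])) {
      x <- epochs$data[i, s, ]
      pw <- rowMeans(vapply(kernels, function(w) Mod(conv_same(x, w))^2,
                            numeric(nt)))
      out[i, s, ] <- pw
    }
  }
  out
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

# one-vs-rest linear SVM: returns predicted class labels for newx
ovr_svm_predict <- function(x, y, newx, cost = 1) {
  classes <- sort(unique(y))
  scores <- vapply(classes, function(cl) {
    yy <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    m <- e1071::svm(x, yy, kernel = "linear", cost = cost, scale = TRUE)
    dv <- attr(stats::predict(m, newx, decision.values = TRUE),
               "decision.values")
    # orient so larger = more "pos": e1071 orients toward the first level
    if (colnames(dv)[1] == "neg/pos") -dv[, 1] else dv[, 1]
  }, numeric(nrow(newx)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  classes[max.col(scores, ties.method = "first")]
}

#' Eight-way trajectory-distance classification
#'
#' Stratified k-fold cross-validation of a linear maximum-margin one-vs-rest
#' classifier on the eight signed trajectory-distance classes, repeated with
#' fresh random partitions and averaged. With time-resolved features the
#' procedure runs independently at each time sample and returns an accuracy
#' time course (chance level 1/8).
#'
#' @param features Trials x features matrix, or trials x features x time
#'   array.
#' @param labels Trajectory labels, one per trial ([trajectory_labels()]);
#'   all 8 classes must be present with >= 2 instances each.
#' @param n_folds Folds per repeat (default 5, stratified).
#' @param n_repeats Number of random re-partitions (default 50).
#' @param cost SVM regularization cost (default 1).
#' @param seed Integer seed.
#' @return For matrix input, scalar mean accuracy (attribute `per_repeat`
#'   holds the repeat-level accuracies); for array input, a numeric accuracy
#'   vector over time.
#' @export
decode_trajectory <- function(features, labels, n_folds = 5, n_repeats = 50,
                              cost = 1, seed = 1) {
  labels <- as.character(labels)
  census <- table(labels)
  if (length(census) != 8 || any(census < 2)) {
    stop("need all 8 trajectory classes with >= 2 instances each; census: ",
         paste(names(census), census, sep = "=", collapse = ", "))
  }
  set.seed(seed)
  run_one <- function(x) {
    acc_rep <- vapply(seq_len(n_repeats), function(r) {
      fold <- stratified_folds(labels, n_folds)
      hits <- 0L
      for (f in seq_len(n_folds)) {
        te <- fold == f
        pred <- ovr_svm_predict(x[!te, , drop = FALSE], labels[!te],
                                x[te, , drop = FALSE], cost)
        hits <- hits + sum(pred == labels[te])
      }
      hits / length(labels)
    }, numeric(1))
    structure(mean(acc_rep), per_repeat = acc_rep)
  }
  if (length(dim(features)) == 3) {
    vapply(seq_len(dim(features)[3]),
           function(t) as.numeric(run_one(features[, , t, drop = TRUE])),
           numeric(1))
  } else {
    run_one(as.matrix(features))
  }
}
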