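#' Preprocess epoched sensor data
#'
#' Standard epoch conditioning: zero-phase Butterworth band-pass (default
#' 2-50 Hz), decimation to a target rate, per-trial per-sensor baseline
#' subtraction (mean over a pre-stimulus window, default -300 to -100 ms), and
#' variance-based trial rejection (a trial is dropped when its variance,
#' collapsed over sensors and time, exceeds the median trial variance times
#' `reject_multiplier`).
#'
#' @param epochs An `EpochSet`.
#' @param band Length-2 Hz band edges; the sampling rate must be at least
#'   twice the upper edge. NULL skips filtering.
#' @param target_fs Target sampling rate in Hz; must divide fs. NULL skips
#'   decimation.
#' @param baseline Length-2 seconds window within the epoch; NULL skips
#'   baseline correction.
#' @param reject_multiplier Variance threshold multiplier (default 5); NULL
#'   skips rejection.
#' @param order Butterworth order (default 6, which keeps a > 20 dB stopband
#'   just past the upper band edge while remaining stable under filtfilt).
#' @return List: `epochs` (preprocessed `EpochSet`) and `rejected` (indices of
#'   dropped trials in the input ordering).
#' @export
preprocess <- function(epochs, band = c(2, 50), target_fs = 100,
                       baseline = c(-0.3, -0.1), reject_multiplier = 5,
                       order = 6) {
  stopifnot(inherits(epochs, "EpochSet"))
  data <- epochs$data
  fs <- epochs$fs
  d <- dim(data)

  if (!is.null(band)) {
    stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
    if (fs < 2 * band[2])
      stop("sampling rate ", fs, " Hz below twice the upper band edge")
    bf <- signal::butter(order, band / (fs / 2), type = "pass")
    for (i in seq_len(d[1])) for (s in seq_len(d[2]))
      data[i, s, ] <- signal::filtfilt(bf, data[i, s, ])
  }

  times <- epochs$times
  if (!is.null(target_fs) && target_fs != fs) {
    stopifnot(target_fs > 0, fs %% target_fs == 0)
    if (!is.null(band) && band[2] > target_fs / 2)
      warning("band upper edge exceeds the post-decimation Nyquist rate")
    keep <- seq(1, d[3], by = fs / target_fs)
    data <- data[, , keep, drop = FALSE]
    times <- times[keep]
    fs <- target_fs
    d <- dim(data)
  }

  if (!is.null(baseline)) {
    sel <- times >= baseline[1] & times <= baseline[2]
    if (!any(sel))
      stop("baseline window [", baseline[1], ", ", baseline[2],
           "] s outside the epoch")
    bl <- apply(data[, , sel, drop = FALSE], c(1, 2), mean)
    data <- data - as.vector(bl)  # recycles over the time dimension
  }

  rejected <- integer(0)
  if (!is.null(reject_multiplier)) {
    v <- apply(data, 1, function(x) stats::var(as.vector(x)))
    thr <- stats::median(v) * reject_multiplier
    rejected <- which(v > thr)
  }
  keep_tr <- setdiff(seq_len(d[1]), rejected)
  out <- epoch_set(data[keep_tr, , , drop = FALSE], fs, times[1],
                   epochs$block_ids[keep_tr],
                   epochs$design[keep_tr, , drop = FALSE])
  list(epochs = out, rejected = rejected)
}
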