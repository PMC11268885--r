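#' Raised-cosine temporal envelope
#'
#' Smooth unimodal envelope spanning `[onset, onset + width]`, peaking at the
#' midpoint; zero elsewhere. Used as the item-locked activation profile of the
#' simulated tuning-channel responses.
#'
#' @param times Time axis in seconds.
#' @param onset Envelope onset in seconds.
#' @param width Envelope duration in seconds (> 0).
#' @return Numeric vector aligned to `times`, in [0, 1].
#' @export
raised_cosine <- function(times, onset, width) {
  stopifnot(width > 0)
  u <- (times - onset) / width
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

#' Simulate forward-model sensor epochs
#'
#' Generates multi-sensor epochs under the linear encoding assumption that
#' each sensor reads out a weighted sum of nine feature-tuned channels per
#' domain: `B = W_loc C_loc(t) + W_col C_col(t) + noise`, where each channel
#' response is the idealized tuning curve evaluated at the trial's item values,
#' gated by an item-locked raised-cosine envelope. With `replay_lag` set, a
#' recall-period epoch is produced instead, in which the three items of
#' `replay_domain` reactivate sequentially at `replay_onset`,
#' `replay_onset + lag`, `replay_onset + 2*lag` (a planted forward replay with
#' known lag, for end-to-end recovery tests).
#'
#' Noise is iid Gaussian per sensor and sample, scaled so that
#' `var(signal) / var(noise) = snr` over the whole array; `snr = Inf` yields
#' noiseless data, in which case sensor data lie exactly in the column space
#' of the true weights.
#'
#' @param design Design table from [generate_design()].
#' @param n_sensors Number of sensors (>= 9, the channel count).
#' @param snr Signal-to-noise variance ratio (> 0 or Inf).
#' @param fs Sampling rate, Hz.
#' @param tmin,tmax Epoch bounds in seconds.
#' @param item_latencies Onsets of the three item envelopes in an encoding
#'   epoch (seconds; defaults mirror 1 s presentations with 0.5 s gaps).
#' @param envelope_width Envelope duration in seconds.
#' @param replay_lag Inter-item reactivation lag in seconds, or NULL for an
#'   encoding epoch.
#' @param replay_onset Onset of the first reactivation (recall epochs).
#' @param replay_domain "color" (default) or "location": which feature
#'   sequence reactivates in a recall epoch.
#' @param basis Tuning basis from [make_basis()].
#' @param seed Integer seed.
#' @return List with `epochs` (an [epoch_set()]) and `truth` (class
#'   `GroundTruth`: true weight matrices per domain, latencies, replay lag,
#'   snr, seed).
#' @export
simulate_eeg <- function(design, n_sensors = 32, snr = 1, fs = 100,
                         tmin = -0.5, tmax = 4.5,
                         item_latencies = c(0, 1.5, 3.0),
                         envelope_width = 0.8,
                         replay_lag = NULL, replay_onset = 0.1,
                         replay_domain = c("color", "location"),
                         basis = make_basis(), seed = 1) {
  stopifnot(n_sensors >= length(basis$centers), snr > 0)
  replay_domain <- match.arg(replay_domain)
  set.seed(seed)
  k <- length(basis$centers)
  n <- nrow(design)

  if (!is.null(replay_lag)) {
    stopifnot(replay_lag >= 0)
    if (missing(tmin)) tmin <- 0
    if (missing(tmax)) tmax <- 1.0
    onsets <- replay_onset + (0:2) * replay_lag
  } else {
    onsets <- item_latencies
  }
  stopifnot(length(onsets) == 3)
  if (any(onsets < tmin) || any(onsets + envelope_width > tmax))
    stop("item envelope extends past epoch bounds [", tmin, ", ", tmax, "] s")

  times <- seq(tmin, tmax, by = 1 / fs)
  nt <- length(times)
  env <- vapply(onsets, function(o) raised_cosine(times, o, envelope_width),
                numeric(nt))  # nt x 3

  W <- list(location = matrix(rnorm(n_sensors * k), n_sensors, k),
            color    = matrix(rnorm(n_sensors * k), n_sensors, k))

  lab <- list(
    location = as.matrix(design[, c("loc1_nom", "loc2_nom", "loc3_nom")]),
    color    = as.matrix(design[, c("col1_nom", "col2_nom", "col3_nom")])
  )
  domains <- if (is.null(replay_lag)) c("location", "color") else replay_domain

  data <- array(0, c(n, n_sensors, nt))
  for (dm in domains) {
    for (item in 1:3) {
      resp <- basis_eval(basis, lab[[dm]][, item])     # n x k
      sens <- resp %*% t(W[[dm]])                      # n x sensors
      # outer product in time: add sens[i, s] * env[t, item]
      data <- data + outer(sens, env[, item])
    }
  }

  if (is.finite(snr)) {
    sig_var <- stats::var(as.vector(data))
    noise_sd <- sqrt(sig_var / snr)
    data <- data + array(rnorm(length(data), 0, noise_sd), dim(data))
  }

  truth <- structure(list(W = W, item_latencies = onsets,
                          envelope_width = envelope_width,
                          replay_lag = replay_lag, snr = snr, seed = seed,
                          basis = basis),
                     class = "GroundTruth")
  list(epochs = epoch_set(data, fs, tmin, design$block, design),
       truth = truth)
}
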