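# Shared small fixtures, built in code at test time.

# tiny design for fast decoding tests
small_design <- function(n = 72, n_blocks = 4, seed = 11) {
  generate_design(n, n_blocks = n_blocks, seed = seed)
}

# recall-period epochs with planted forward replay of the color sequence
replay_epochs <- function(seed, lag = 0.13, n = 72, snr = 4,
                          n_sensors = 16, fs = 100) {
  d <- generate_design(n, n_blocks = 4, seed = seed)
  simulate_eeg(d, n_sensors = n_sensors, snr = snr, fs = fs,
               tmin = 0, tmax = 1, envelope_width = 0.07,
               replay_lag = lag, replay_onset = 0.1, seed = seed + 5000L)
}

# decoded color-item slope time courses for a cohort: subjects x 3 x time
cohort_timecourses <- function(n_subjects, lag, seed, n = 72, snr = 4,
                               fs = 100) {
  nt <- length(seq(0, 1, by = 1 / fs))
  tcs <- array(NA_real_, c(n_subjects, 3, nt))
  for (s in seq_len(n_subjects)) {
    sim <- replay_epochs(seed + s, lag = lag, n = n, snr = snr, fs = fs)
    for (item in 1:3) {
      lab <- sim$epochs$design[[paste0("col", item, "_nom")]]
      # unsmoothed slopes: lag estimation at the sampling resolution needs
      # the sharp time courses, not the display-smoothed ones
      dec <- suppressWarnings(decode_timecourse(sim$epochs, lab,
                                                smoothing_sd = 0))
      tcs[s, item, ] <- dec$slope
    }
  }
  tcs
}

# group statistic returning both the peak asymmetry and the transition-matrix
# similarity at the peak lag, for a single shared permutation stream
stat_asym_and_similarity <- function(max_lag, fs) {
  TT <- theoretical_matrix(3)
  function(tc) {
    prof <- direction_asymmetry(tc, max_lag, fs)
    lag <- suppressWarnings(find_peak_lag(prof))
    c(asym = max(prof$mean, na.rm = TRUE),
      sim = matrix_similarity(empirical_matrix(tc, lag, fs), TT))
  }
}

# null subjects for cluster-test calibration: temporally smooth time courses
# (the 40 ms-smoothed class of data the cluster test consumes)
smooth_null_subjects <- function(n_subjects, n_samples, fs = 100, sd = 0.04) {
  t(replicate(n_subjects, gaussian_smooth(rnorm(n_samples), sd, fs)))
}
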