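#' Construct an epoched multi-sensor data set
#'
#' Container for trials x sensors x time data with a uniform time axis,
#' per-trial recording-block ids, and the per-trial feature labels (nominal
#' grid values per serial position and domain) carried from the design.
#'
#' @param data Numeric array, trials x sensors x time.
#' @param fs Sampling rate in Hz (> 0).
#' @param tmin Time of the first sample in seconds relative to epoch onset.
#' @param block_ids Integer vector, one per trial.
#' @param design Design data.frame ([generate_design()]) aligned to trials.
#' @return An object of class `EpochSet` (list with `data`, `fs`, `times`,
#'   `block_ids`, `design`).
#' @export
epoch_set <- function(data, fs, tmin, block_ids, design) {
  stopifnot(length(dim(data)) == 3, fs > 0,
            length(block_ids) == dim(data)[1],
            nrow(design) == dim(data)[1])
  times <- tmin + (seq_len(dim(data)[3]) - 1) / fs
  structure(list(data = data, fs = fs, times = times,
                 block_ids = as.integer(block_ids), design = design),
            class = "EpochSet")
}

#' @export
print.EpochSet <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("EpochSet: %d trials x %d sensors x %d samples @ %g Hz, t = [%.3f, %.3f] s, %d blocks\n",
              d[1], d[2], d[3], x$fs, x$times[1], x$times[length(x$times)],
              length(unique(x$block_ids))))
  invisible(x)
}

#' Select a subset of trials from an EpochSet
#' @param x An `EpochSet`.
#' @param idx Trial indices (logical or integer).
#' @return A new `EpochSet`.
#' @export
subset_epochs <- function(x, idx) {
  epoch_set(x$data[idx, , , drop = FALSE], x$fs, x$times[1],
            x$block_ids[idx], x$design[idx, , drop = FALSE])
}

#' Write an EpochSet to plain-text files
#'
#' Serializes as `<prefix>_meta.json` (fs, tmin, dims, block ids),
#' `<prefix>_data.csv` (one row per trial-sensor pair, one column per sample)
#' and `<prefix>_labels.csv` (the design table). Text-only round trip;
#' suitable for desk-scale epochs.
#'
#' @param x An `EpochSet`.
#' @param prefix File path prefix.
#' @return Invisibly, the paths written.
#' @export
write_epochs <- function(x, prefix) {
  d <- dim(x$data)
  meta <- list(fs = x$fs, tmin = x$times[1],
               n_trials = d[1], n_sensors = d[2], n_samples = d[3],
               block_ids = x$block_ids)
  paths <- paste0(prefix, c("_meta.json", "_data.csv", "_labels.csv"))
  jsonlite::write_json(meta, paths[1], auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  utils::write.table(flat, paths[2], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(x$design, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read an EpochSet written by [write_epochs()]
#' @param prefix File path prefix used at write time.
#' @return An `EpochSet`.
#' @export
read_epochs <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(prefix, "_data.csv"), sep = ","))
  design <- utils::read.csv(paste0(prefix, "_labels.csv"),
                            stringsAsFactors = FALSE)
  data <- aperm(array(t(flat), c(meta$n_samples, meta$n_sensors, meta$n_trials)),
                c(3, 2, 1))
  epoch_set(data, meta$fs, meta$tmin, meta$block_ids, design)
}
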