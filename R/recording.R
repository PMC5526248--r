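#' Construct a continuous EEG recording
#'
#' @param samples Numeric matrix, channels x time, microvolts.
#' @param channel_labels Character vector, one label per row of `samples`.
#' @param fs Sampling rate, Hz.
#' @param reference Reference description, e.g. `"nose"` or
#'   `"average-mastoid"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, channel_labels, fs, reference = "nose") {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channel_labels))
    stop("samples must have one row per channel label", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  rownames(samples) <- channel_labels
  structure(list(samples = samples,
                 channel_labels = as.character(channel_labels),
                 fs = fs, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$reference))
  invisible(x)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz, %g..%g ms (%d targets)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              min(x$times), max(x$times), sum(x$labels)))
  invisible(x)
}

#' Construct a set of stimulus-locked epochs
#'
#' @param data Numeric array, epoch x channel x time, microvolts.
#' @param times Time axis in ms relative to stimulus onset.
#' @param channel_labels Channel labels (length = dim 2).
#' @param labels Logical vector, `TRUE` for target epochs.
#' @param meta Data frame with one row per epoch (stimulus_id, block,
#'   repetition, paradigm).
#' @param fs Sampling rate of the epoch time axis, Hz.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, channel_labels, labels, meta, fs) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[1] != length(labels) || dim(data)[1] != nrow(meta))
    stop("labels/meta must have one entry per epoch", call. = FALSE)
  if (dim(data)[2] != length(channel_labels))
    stop("channel_labels must match data dimension 2", call. = FALSE)
  if (dim(data)[3] != length(times))
    stop("times must match data dimension 3", call. = FALSE)
  structure(list(data = data, times = times,
                 channel_labels = as.character(channel_labels),
                 labels = as.logical(labels), meta = meta, fs = fs),
            class = "epoch_set")
}

#' Subset an epoch set by epoch index
#'
#' @param epochs An [epoch_set()].
#' @param i Integer or logical epoch index.
#' @return A new `epoch_set` with the selected epochs.
#' @export
subset_epochs <- function(epochs, i) {
  epoch_set(epochs$data[i, , , drop = FALSE], epochs$times,
            epochs$channel_labels, epochs$labels[i],
            epochs$meta[i, , drop = FALSE], epochs$fs)
}
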