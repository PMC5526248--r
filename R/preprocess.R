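#' Re-reference a recording to the average of the two mastoids
#'
#' Subtracts the mean of the left and right mastoid channels from every
#' channel, the standard off-line reference for ERP speller data. Any
#' signal common to all channels (including the original reference) is
#' removed.
#'
#' @param recording An [eeg_recording()].
#' @param left_label,right_label Mastoid channel labels (default
#'   `"M1"`/`"M2"`).
#' @return The re-referenced [eeg_recording()] with its `reference`
#'   field set to `"average-mastoid"`.
#' @export
rereference_mastoids <- function(recording, left_label = "M1",
                                 right_label = "M2") {
  stopifnot(inherits(recording, "eeg_recording"))
  for (lab in c(left_label, right_label))
    if (!lab %in% recording$channel_labels)
      stop("channel not found: ", lab, call. = FALSE)
  ref <- colMeans(recording$samples[c(left_label, right_label), , drop = FALSE])
  out <- recording
  out$samples <- sweep(recording$samples, 2, ref, "-")
  out$reference <- "average-mastoid"
  out
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, applied as a
#' second-order high-pass at `low_hz` followed by a second-order
#' low-pass at `high_hz` (effective order 4 after the two passes per
#' section). DC is removed; mid-band gain is within a few percent of
#' unity; attenuation one octave outside the band exceeds 20 dB.
#'
#' @param recording An [eeg_recording()].
#' @param low_hz,high_hz Band edges in Hz (defaults 0.5 and 40).
#' @return Filtered [eeg_recording()].
#' @export
bandpass <- function(recording, low_hz = 0.5, high_hz = 40) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (!(low_hz > 0 && high_hz > low_hz && high_hz < fs / 2))
    stop("invalid band: need 0 < low_hz < high_hz < fs/2", call. = FALSE)
  hp <- signal::butter(2, low_hz / (fs / 2), "high")
  lp <- signal::butter(2, high_hz / (fs / 2), "low")
  out <- recording
  for (ch in seq_len(nrow(out$samples))) {
    x <- signal::filtfilt(hp, out$samples[ch, ])
    out$samples[ch, ] <- signal::filtfilt(lp, x)
  }
  out
}

#' Down-sample a recording
#'
#' Resamples each channel onto the target-rate time grid by cubic-spline
#' interpolation. The input is assumed band-limited below the new
#' Nyquist frequency — in the standard pipeline [bandpass()] (40 Hz
#' low-pass) runs first, so no further anti-alias filtering is needed
#' for the default 500 -> 200 Hz step.
#'
#' @param recording An [eeg_recording()].
#' @param target_fs New sampling rate, Hz (default 200; must not exceed
#'   the current rate).
#' @return Resampled [eeg_recording()]; duration preserved within one
#'   sample.
#' @export
downsample <- function(recording, target_fs = 200) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (target_fs > fs) stop("target_fs must not exceed fs", call. = FALSE)
  if (target_fs == fs) return(recording)
  n <- ncol(recording$samples)
  t_old <- (seq_len(n) - 1) / fs
  t_new <- seq(0, (n - 1) / fs, by = 1 / target_fs)
  out <- recording
  out$samples <- t(apply(recording$samples, 1, function(x)
    stats::spline(t_old, x, xout = t_new, method = "fmm")$y))
  rownames(out$samples) <- recording$channel_labels
  out$fs <- target_fs
  out
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' Extracts the half-open window `[t_min_ms, t_max_ms)` around every
#' event onset, so the default -200..800 ms window at 200 Hz yields
#' exactly 200 samples per channel. Events whose window extends past
#' either end of the recording are dropped with a warning reporting the
#' count.
#'
#' @param recording An [eeg_recording()].
#' @param events Event table (see [generate_events()]).
#' @param t_min_ms,t_max_ms Epoch window relative to stimulus onset, ms.
#' @return An [epoch_set()] carrying the event metadata.
#' @export
extract_epochs <- function(recording, events, t_min_ms = -200,
                           t_max_ms = 800) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (t_max_ms <= t_min_ms) stop("t_max_ms must exceed t_min_ms", call. = FALSE)
  offsets <- seq(round(t_min_ms / 1000 * fs), round(t_max_ms / 1000 * fs) - 1)
  times <- offsets / fs * 1000
  n <- ncol(recording$samples)
  onset_samp <- round(events$onset * fs) + 1
  ok <- onset_samp + offsets[1] >= 1 & onset_samp + offsets[length(offsets)] <= n
  if (!all(ok))
    warning(sum(!ok), " of ", length(ok),
            " event(s) dropped: epoch window outside recording")
  onset_samp <- onset_samp[ok]
  keep <- events[ok, , drop = FALSE]
  n_ch <- nrow(recording$samples)
  data <- array(0, dim = c(length(onset_samp), n_ch, length(offsets)))
  for (e in seq_along(onset_samp))
    data[e, , ] <- recording$samples[, onset_samp[e] + offsets]
  epoch_set(data, times, recording$channel_labels,
            labels = keep$is_target,
            meta = keep[c("stimulus_id", "block", "repetition", "paradigm")],
            fs = fs)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean amplitude over the
#' half-open pre-stimulus window `[b_min_ms, b_max_ms)`. Idempotent.
#'
#' @param epochs An [epoch_set()].
#' @param b_min_ms,b_max_ms Baseline window, ms (defaults -200 and 0).
#' @return Baseline-corrected [epoch_set()].
#' @export
baseline_correct <- function(epochs, b_min_ms = -200, b_max_ms = 0) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$times >= b_min_ms & epochs$times < b_max_ms
  if (!any(sel)) stop("empty baseline window", call. = FALSE)
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - as.vector(base)      # recycles over dim 3
  out
}

#' Drop epochs exceeding a peak-amplitude threshold
#'
#' Simple artifact-rejection hook: removes every epoch whose absolute
#' amplitude exceeds `threshold_uv` on any channel and reports the
#' count. (Component-based ocular artifact removal is a recording-level
#' concern outside this package's pipeline; simulated data carries no
#' such artifacts.)
#'
#' @param epochs An [epoch_set()].
#' @param threshold_uv Rejection threshold, microvolts (> 0).
#' @return The surviving epochs as an [epoch_set()].
#' @export
reject_by_amplitude <- function(epochs, threshold_uv) {
  stopifnot(inherits(epochs, "epoch_set"), threshold_uv > 0)
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= threshold_uv
  if (!all(keep))
    warning(sum(!keep), " of ", length(keep),
            " epoch(s) rejected above ", threshold_uv, " uV")
  if (!any(keep))
    warning("all epochs rejected; returning empty epoch set")
  subset_epochs(epochs, keep)
}
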