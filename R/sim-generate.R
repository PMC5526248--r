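#' Render a single component waveform
#'
#' Gaussian bump whose extremum equals the class-specific amplitude at
#' `peak_latency_ms`, hard-truncated to zero beyond three half-widths
#' from the peak (tail amplitude there is < 0.3% of the extremum).
#'
#' @param spec A [component_spec()].
#' @param role `"target"` or `"nontarget"`; selects the amplitude.
#' @param fs Sampling rate, Hz.
#' @param duration_ms Waveform length, ms; must cover
#'   `peak_latency_ms + 2 * half_width_ms`.
#' @return Numeric vector of `round(duration_ms / 1000 * fs)` samples
#'   (microvolts), time-locked to stimulus onset at sample 1.
#' @export
make_component_waveform <- function(spec, role = c("target", "nontarget"),
                                    fs, duration_ms) {
  role <- match.arg(role)
  if (!is.numeric(fs) || fs <= 0 || !is.numeric(duration_ms) || duration_ms <= 0)
    stop("fs and duration_ms must be positive", call. = FALSE)
  if (duration_ms < spec$peak_latency_ms + 2 * spec$half_width_ms)
    stop("duration_ms must cover peak_latency_ms + 2 * half_width_ms",
         call. = FALSE)
  amp <- if (role == "target") spec$amplitude_target else spec$amplitude_nontarget
  t_ms <- (seq_len(round(duration_ms / 1000 * fs)) - 1) / fs * 1000
  sigma <- spec$half_width_ms / sqrt(2 * log(2))   # HWHM -> Gaussian sd
  w <- amp * exp(-0.5 * ((t_ms - spec$peak_latency_ms) / sigma)^2)
  w[abs(t_ms - spec$peak_latency_ms) > 3 * spec$half_width_ms] <- 0
  w
}

#' Generate the stimulus-event table for a session
#'
#' Each block presents a random permutation of the `n_stimuli` stimulus
#' ids, re-drawn independently for each of the `n_repetitions`
#' repetitions; one stimulus id per block is the (attended) target.
#' Onsets advance by the stimulus-onset asynchrony within a block and by
#' an additional `inter_block_gap_s` between blocks.
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `onset` (s), `stimulus_id` (0-based),
#'   `is_target`, `block`, `repetition`, `paradigm`; one row per
#'   stimulus presentation, onsets strictly increasing.
#' @export
generate_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .draw_events(config)
}

# event drawing from the current RNG state (shared with generate_recording)
.draw_events <- function(config) {
  soa_s <- config$soa_ms / 1000
  block_dur <- config$n_repetitions * config$n_stimuli * soa_s
  rows <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    target <- sample.int(config$n_stimuli, 1L) - 1L
    block_start <- (b - 1) * (block_dur + config$inter_block_gap_s) +
      config$inter_block_gap_s
    per_rep <- lapply(seq_len(config$n_repetitions), function(r) {
      order <- sample.int(config$n_stimuli) - 1L
      data.frame(
        onset = block_start + ((r - 1) * config$n_stimuli +
                                 seq_len(config$n_stimuli) - 1) * soa_s,
        stimulus_id = order,
        is_target = order == target,
        block = b,
        repetition = r,
        paradigm = config$paradigm,
        stringsAsFactors = FALSE)
    })
    rows[[b]] <- do.call(rbind, per_rep)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# one channel of 1/f-shaped noise via spectral shaping of white noise
.pink_noise <- function(n, exponent) {
  x <- stats::rnorm(n)
  if (exponent == 0) return(x)
  f <- c(1, seq_len(n - 1))                      # avoid DC blow-up
  f <- pmin(f, n - f + 1)                        # two-sided spectrum
  shaped <- Re(stats::fft(stats::fft(x) * f^(-exponent / 2), inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

# band-limited alpha (8-12 Hz) noise, unit sd
.alpha_noise <- function(n, fs) {
  b <- signal::butter(2, c(8, 12) / (fs / 2), "pass")
  x <- signal::filtfilt(b, stats::rnorm(n))
  s <- stats::sd(x)
  if (s < .Machine$double.eps) rep(0, n) else x / s
}

#' Simulate a continuous EEG recording with its event table
#'
#' Background noise (1/f-shaped + alpha-band + white, independent per
#' channel) plus, at every stimulus onset, the superposition of all
#' configured component waveforms scaled by the per-channel topography
#' and the target/non-target amplitude. Because the stimulus-onset
#' asynchrony (330 ms) is shorter than the analysis epoch (1 s),
#' responses of neighbouring stimuli overlap additively, as in the real
#' rapid-presentation paradigm.
#'
#' @param config A [sim_config()]; `config$seed` makes the output fully
#'   deterministic.
#' @return List with elements `recording` ([eeg_recording()]) and
#'   `events` (the event table of [generate_events()]).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  events <- .draw_events(config)

  fs <- config$fs
  tail_s <- 1.2                                  # room for the last epoch
  n <- ceiling((max(events$onset) + tail_s) * fs)
  n_ch <- length(config$channel_labels)

  noise <- config$noise
  samples <- matrix(0, n_ch, n)
  if (noise$pink_sd > 0 || noise$alpha_sd > 0 || noise$white_sd > 0) {
    for (ch in seq_len(n_ch)) {
      x <- numeric(n)
      if (noise$pink_sd > 0)
        x <- x + noise$pink_sd * .pink_noise(n, noise$exponent)
      if (noise$alpha_sd > 0)
        x <- x + noise$alpha_sd * .alpha_noise(n, fs)
      if (noise$white_sd > 0)
        x <- x + stats::rnorm(n, sd = noise$white_sd)
      samples[ch, ] <- x
    }
  }

  # pre-render waveforms once per component and role
  for (cmp in config$components) {
    dur <- cmp$peak_latency_ms + 3 * cmp$half_width_ms
    idx <- match(names(cmp$topography), config$channel_labels)
    gains <- unname(cmp$topography)
    for (role in c("target", "nontarget")) {
      w <- make_component_waveform(cmp, role, fs, dur)
      L <- length(w)
      block <- outer(gains, w)                   # active channels x time
      onsets <- round(events$onset[events$is_target == (role == "target")] * fs) + 1
      for (s0 in onsets) {
        span <- s0:min(s0 + L - 1, n)
        samples[idx, span] <- samples[idx, span] + block[, seq_along(span)]
      }
    }
  }

  rec <- eeg_recording(samples, config$channel_labels, fs, reference = "nose")
  list(recording = rec, events = events)
}
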