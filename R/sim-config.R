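#' Specify one evoked component of the simulated ERP
#'
#' A component is a smooth unimodal (Gaussian) bump added to the EEG at
#' every stimulus onset, with separate amplitudes for target and
#' non-target stimuli and a per-channel topographic gain map.
#'
#' @param name Label, e.g. `"N2"` or `"P3"`.
#' @param peak_latency_ms Latency of the extremum, ms post-stimulus.
#' @param half_width_ms Half-width at half maximum of the bump, ms (> 0).
#' @param amplitude_target Signed extremum for target stimuli, microvolts.
#' @param amplitude_nontarget Signed extremum for non-target stimuli,
#'   microvolts.
#' @param topography Named numeric vector mapping channel label to a
#'   unitless gain in `[0, 1]`; at least one gain must be positive.
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, peak_latency_ms, half_width_ms,
                           amplitude_target, amplitude_nontarget,
                           topography) {
  if (!is.numeric(half_width_ms) || half_width_ms <= 0)
    stop("half_width_ms must be > 0", call. = FALSE)
  if (is.null(names(topography)) || any(!nzchar(names(topography))))
    stop("topography must be a named vector of channel gains", call. = FALSE)
  if (any(topography < 0) || any(topography > 1))
    stop("topography gains must lie in [0, 1]", call. = FALSE)
  if (!any(topography > 0))
    stop("at least one topography gain must be positive", call. = FALSE)
  structure(list(name = name,
                 peak_latency_ms = peak_latency_ms,
                 half_width_ms = half_width_ms,
                 amplitude_target = amplitude_target,
                 amplitude_nontarget = amplitude_nontarget,
                 topography = topography),
            class = "component_spec")
}

#' Default component set for a stimulation condition
#'
#' Components N2 (~200 ms, negative), P3 (~350 ms, positive), N4
#' (~440 ms, negative) and P5 (~620 ms, positive). In the
#' `"incongruent"` condition the class-independent (common) part of the
#' N2 and P3 amplitudes is scaled by `congruency_scale` while the
#' target-minus-non-target contrast is left unchanged, emulating a
#' paradigm that evokes larger ERPs for both classes without changing
#' their discriminability.
#'
#' @param paradigm `"congruent"` or `"incongruent"`.
#' @param congruency_scale Scaling of the common N2/P3 amplitude in the
#'   incongruent condition (default 1.5).
#' @param contrast_scale Scaling of the target-minus-non-target contrast
#'   of every component (default 1; set 0 for a null paradigm with no
#'   class information).
#' @return List of [component_spec()] objects.
#' @export
default_components <- function(paradigm = c("congruent", "incongruent"),
                               congruency_scale = 1.5,
                               contrast_scale = 1) {
  paradigm <- match.arg(paradigm)
  base <- list(
    list("N2", 200, 40, -5.0, -2.0, scaled = TRUE),
    list("P3", 350, 60,  6.0,  2.0, scaled = TRUE),
    list("N4", 440, 45, -2.5, -1.0, scaled = FALSE),
    list("P5", 620, 70,  2.0,  1.0, scaled = FALSE))
  lapply(base, function(b) {
    common <- b[[5]]                       # non-target amplitude
    contrast <- (b[[4]] - b[[5]]) * contrast_scale
    if (paradigm == "incongruent" && b$scaled) common <- common * congruency_scale
    component_spec(b[[1]], b[[2]], b[[3]],
                   amplitude_target = common + contrast,
                   amplitude_nontarget = common,
                   topography = component_topography(b[[1]]))
  })
}

#' Restrict component topographies to a reduced montage
#'
#' Convenience for fast, low-channel-count simulations: keeps only the
#' topography gains whose channels exist in `channel_labels`. A
#' component whose topography vanishes entirely on the reduced montage
#' is an error.
#'
#' @param components List of [component_spec()].
#' @param channel_labels Labels of the reduced montage.
#' @return List of [component_spec()] with restricted topographies.
#' @export
restrict_components <- function(components, channel_labels) {
  lapply(components, function(cmp) {
    keep <- names(cmp$topography) %in% channel_labels
    if (!any(keep & cmp$topography > 0))
      stop("component ", cmp$name,
           " has no channel on the reduced montage", call. = FALSE)
    cmp$topography <- cmp$topography[keep]
    cmp
  })
}

#' Background-noise settings for the simulator
#'
#' @param pink_sd Standard deviation of the 1/f-shaped component,
#'   microvolts (per sample, per channel).
#' @param alpha_sd Standard deviation of the 8-12 Hz alpha-band
#'   component, microvolts.
#' @param white_sd Standard deviation of the white component, microvolts.
#' @param exponent Spectral exponent of the 1/f component (power ~
#'   f^-exponent).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(pink_sd = 4, alpha_sd = 1.5, white_sd = 1,
                       exponent = 1) {
  stopifnot(pink_sd >= 0, alpha_sd >= 0, white_sd >= 0, exponent >= 0)
  structure(list(pink_sd = pink_sd, alpha_sd = alpha_sd,
                 white_sd = white_sd, exponent = exponent),
            class = "noise_spec")
}

#' Simulation configuration for the audiovisual oddball paradigm
#'
#' Defines a recording session: blocks of `n_stimuli` distinct stimuli
#' presented in random order and repeated `n_repetitions` times at a
#' fixed stimulus-onset asynchrony (330 ms = 130 ms stimulus duration +
#' 200 ms inter-stimulus interval), with exactly one target stimulus per
#' block (target:non-target ratio 1:3 with the default four stimuli).
#'
#' @param channel_labels Montage labels; default [montage_64()].
#' @param fs Sampling rate, Hz (default 500).
#' @param soa_ms Stimulus-onset asynchrony, ms (default 330).
#' @param n_blocks Number of blocks (default 4).
#' @param n_repetitions Stimulus-sequence repetitions per block
#'   (default 10).
#' @param n_stimuli Distinct stimuli per repetition (default 4, >= 2).
#' @param paradigm Condition label, `"congruent"` or `"incongruent"`.
#' @param components List of [component_spec()]; default
#'   [default_components()] for the chosen paradigm.
#' @param noise A [noise_spec()].
#' @param inter_block_gap_s Quiet interval between blocks, seconds
#'   (default 2, the cue-to-block interval of the paradigm).
#' @param seed Integer seed driving every stochastic step.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(channel_labels = montage_64(), fs = 500,
                       soa_ms = 330, n_blocks = 4, n_repetitions = 10,
                       n_stimuli = 4,
                       paradigm = c("congruent", "incongruent"),
                       components = NULL,
                       noise = noise_spec(),
                       inter_block_gap_s = 2, seed = 1L) {
  paradigm <- match.arg(paradigm)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (soa_ms <= 0) stop("soa_ms must be positive", call. = FALSE)
  if (n_stimuli < 2) stop("n_stimuli must be >= 2", call. = FALSE)
  if (n_blocks < 1 || n_repetitions < 1)
    stop("n_blocks and n_repetitions must be >= 1", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("channel_labels must be unique", call. = FALSE)
  if (is.null(components)) components <- default_components(paradigm)
  for (cmp in components) {
    if (!inherits(cmp, "component_spec"))
      stop("components must be component_spec objects", call. = FALSE)
    unknown <- setdiff(names(cmp$topography), channel_labels)
    if (length(unknown))
      stop("unknown channel label(s) in topography of ", cmp$name, ": ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(channel_labels = channel_labels, fs = fs, soa_ms = soa_ms,
                 n_blocks = n_blocks, n_repetitions = n_repetitions,
                 n_stimuli = n_stimuli, paradigm = paradigm,
                 components = components, noise = noise,
                 inter_block_gap_s = inter_block_gap_s,
                 seed = as.integer(seed)),
            class = "sim_config")
}
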