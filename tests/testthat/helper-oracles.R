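# Independent oracles and small builders shared across tests.

# Literal transcription of the classifiability definition with the
# population standard deviation, kept independent of r_squared().
r2_definition <- function(xt, xn) {
  mt <- length(xt); mn <- length(xn)
  pooled <- c(xt, xn)
  s <- sqrt(sum((pooled - mean(pooled))^2) / length(pooled))
  (sqrt(mt * mn) * (mean(xt) - mean(xn)) / ((mt + mn) * s))^2
}

# Brute-force Benjamini-Hochberg step-up: adjusted p_i = min over
# j with p_j >= p_i of min(1, m * p_(j) / rank(j)).
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Reduced montage for fast simulations: feature channels, the stats
# channels, the mastoids and a few neighbours used by the topographies.
small_montage <- function() {
  c(speller_channels(), "POz", "P1", "P2", "CP1", "CP2", "C1", "C2",
    "FCz", "Fz", "O1", "O2", "PO3", "PO4", "M1", "M2")
}

quick_config <- function(seed = 1, n_blocks = 2, n_repetitions = 10,
                         paradigm = "congruent",
                         components = NULL, noise = noise_spec()) {
  ch <- small_montage()
  if (is.null(components))
    components <- restrict_components(default_components(paradigm), ch)
  sim_config(channel_labels = ch, n_blocks = n_blocks,
             n_repetitions = n_repetitions, paradigm = paradigm,
             components = components, noise = noise, seed = seed)
}

# Epoch set built directly from an array (bypasses the simulator).
make_epochs <- function(data, fs = 200, t_min = -200, labels = NULL,
                        channel_labels = NULL) {
  d <- dim(data)
  times <- t_min + (seq_len(d[3]) - 1) / fs * 1000
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(d[2]))
  if (is.null(labels)) labels <- rep(c(TRUE, FALSE), length.out = d[1])
  meta <- data.frame(stimulus_id = rep(0L, d[1]),
                     block = rep(1L, d[1]),
                     repetition = seq_len(d[1]),
                     paradigm = "congruent")
  epoch_set(data, times, channel_labels, labels, meta, fs)
}

# Score-level block simulator: target scores N(contrast, 1), others
# N(0, 1); used for decoding-curve properties without the EEG chain.
sim_score_blocks <- function(n_blocks, n_reps = 10, n_stim = 4,
                             contrast = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_blocks), function(b) {
    target <- sample.int(n_stim, 1) - 1L
    s <- matrix(rnorm(n_reps * n_stim), n_reps, n_stim)
    s[, target + 1] <- s[, target + 1] + contrast
    meta <- data.frame(
      stimulus_id = rep(0:(n_stim - 1), n_reps),
      repetition = rep(seq_len(n_reps), each = n_stim))
    block_scores(as.vector(t(s)), meta, true_target = target, block = b)
  })
}
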