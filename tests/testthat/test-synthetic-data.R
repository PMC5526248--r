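test_that("component waveforms peak at the configured amplitude and latency", {
  p3 <- component_spec("P3", 350, 60, 5, 2, c(Pz = 1))
  w <- make_component_waveform(p3, "target", fs = 500, duration_ms = 800)
  t_ms <- (seq_along(w) - 1) / 500 * 1000
  expect_equal(max(w), 5)
  expect_equal(t_ms[which.max(w)], 350)
  expect_equal(max(abs(w[abs(t_ms - 350) > 180])), 0)   # zero beyond 3 HWHM

  n2 <- component_spec("N2", 200, 40, -3, -1, c(Cz = 1))
  wn <- make_component_waveform(n2, "target", fs = 500, duration_ms = 600)
  expect_equal(min(wn), -3)
  expect_equal((which.min(wn) - 1) / 500 * 1000, 200)

  zero <- component_spec("P3", 350, 60, 0, 0, c(Pz = 1))
  expect_true(all(make_component_waveform(zero, "target", 500, 800) == 0))

  expect_error(make_component_waveform(p3, "target", fs = -1, duration_ms = 800),
               "positive")
  expect_error(make_component_waveform(p3, "target", fs = 500, duration_ms = 100),
               "cover")
})

test_that("component and config invariants are enforced", {
  expect_error(component_spec("x", 100, -5, 1, 0, c(Cz = 1)), "half_width")
  expect_error(component_spec("x", 100, 10, 1, 0, c(Cz = 2)), "\\[0, 1\\]")
  expect_error(component_spec("x", 100, 10, 1, 0, c(Cz = 0)), "positive")
  expect_error(sim_config(n_stimuli = 1), "n_stimuli")
  bad <- component_spec("x", 100, 10, 1, 0, c(NotAChannel = 1))
  expect_error(sim_config(components = list(bad)), "NotAChannel")
})

test_that("event tables satisfy the block/repetition structure", {
  cfg <- quick_config(seed = 11, n_blocks = 2, n_repetitions = 10)
  ev <- generate_events(cfg)
  expect_equal(nrow(ev), 2 * 10 * 4)
  expect_equal(mean(ev$is_target), 1 / 4)
  expect_true(all(diff(ev$onset) > 0))
  # every repetition presents each stimulus exactly once
  for (b in unique(ev$block)) for (r in unique(ev$repetition)) {
    ids <- ev$stimulus_id[ev$block == b & ev$repetition == r]
    expect_setequal(ids, 0:3)
  }
  # exactly one target id per block
  for (b in unique(ev$block))
    expect_length(unique(ev$stimulus_id[ev$block == b & ev$is_target]), 1)
  expect_identical(ev, generate_events(cfg))
})

test_that("target ratio and row count hold across seeds", {
  for (seed in c(2, 23, 301)) {
    cfg <- quick_config(seed = seed, n_blocks = 3, n_repetitions = 4)
    ev <- generate_events(cfg)
    expect_equal(nrow(ev), 3 * 4 * 4)
    for (b in unique(ev$block))
      expect_equal(mean(ev$is_target[ev$block == b]), 1 / 4)
  }
})

test_that("noiseless generation reproduces the component superposition", {
  ch <- c("Pz", "Cz", "M1", "M2")
  p3 <- component_spec("P3", 350, 50, 5, 1, c(Pz = 1, Cz = 0.5))
  cfg <- sim_config(channel_labels = ch, n_blocks = 1, n_repetitions = 1,
                    n_stimuli = 2, soa_ms = 1500, components = list(p3),
                    noise = noise_spec(0, 0, 0), seed = 4)
  sim <- generate_recording(cfg)
  x <- sim$recording$samples
  fs <- cfg$fs
  tgt_onset <- sim$events$onset[sim$events$is_target]
  nt_onset <- sim$events$onset[!sim$events$is_target]
  peak <- function(on) round((on + 0.350) * fs) + 1
  expect_equal(unname(x["Pz", peak(tgt_onset)]), 5, tolerance = 1e-9)
  expect_equal(unname(x["Cz", peak(tgt_onset)]), 2.5, tolerance = 1e-9)
  expect_equal(unname(x["Pz", peak(nt_onset)]), 1, tolerance = 1e-9)
  expect_true(all(x[c("M1", "M2"), ] == 0))

  # linear in component amplitudes
  p3x2 <- component_spec("P3", 350, 50, 10, 2, c(Pz = 1, Cz = 0.5))
  cfg2 <- sim_config(channel_labels = ch, n_blocks = 1, n_repetitions = 1,
                     n_stimuli = 2, soa_ms = 1500, components = list(p3x2),
                     noise = noise_spec(0, 0, 0), seed = 4)
  expect_equal(generate_recording(cfg2)$recording$samples, 2 * x,
               tolerance = 1e-12)
})

test_that("same seed gives bit-identical recordings", {
  cfg <- quick_config(seed = 9, n_blocks = 1, n_repetitions = 3)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)
})

test_that("epoch-averaged target minus non-target recovers the P3 contrast", {
  cfg <- quick_config(seed = 31, n_blocks = 3, n_repetitions = 10)
  sim <- generate_recording(cfg)
  ep <- baseline_correct(extract_epochs(sim$recording, sim$events))
  # P3 contrast at Pz (topography gain 1): target 6, non-target 2
  pz <- match("Pz", ep$channel_labels)
  at <- which.min(abs(ep$times - 350))
  vt <- ep$data[ep$labels, pz, at]
  vn <- ep$data[!ep$labels, pz, at]
  se <- sqrt(var(vt) / length(vt) + var(vn) / length(vn))
  expect_lt(abs((mean(vt) - mean(vn)) - 4), 3 * se)
})

test_that("EDF files round-trip within the quantization step", {
  set.seed(5)
  x <- matrix(rnorm(3 * 1000, sd = 20), 3)
  rec <- eeg_recording(x, c("Cz", "Pz", "Oz"), fs = 500, reference = "nose")
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$reference, "nose")
  step <- apply(x, 1, function(v) diff(range(v))) / 65535
  for (ch in 1:3)
    expect_lt(max(abs(back$samples[ch, ] - x[ch, ])), step[ch] * 1.01)
})

test_that("malformed EDF input raises a parse error naming the field", {
  path <- tempfile(fileext = ".edf")
  writeBin(charToRaw(paste(rep("9", 300), collapse = "")), path)
  expect_error(read_edf(path), "version")
})

test_that("event files round-trip losslessly and enforce invariants", {
  ev <- generate_events(quick_config(seed = 3, n_blocks = 2))
  path <- tempfile(fileext = ".tsv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back, ev, tolerance = 1e-12)

  bad <- ev
  bad$onset[2] <- bad$onset[1]                    # non-increasing
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(bad, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_events(path2), "onset")

  utils::write.table(ev[, -2], path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_events(path2), "stimulus_id")
})
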