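#' Configuration of a full simulated speller study
#'
#' Bundles every stage's settings for [run_experiment()]. The defaults
#' replicate the study conditions the simulator emulates: 11 subjects,
#' two conditions (congruent / incongruent audiovisual stimulation),
#' 4 blocks x 10 repetitions x 4 stimuli per condition, 64 channels at
#' 500 Hz, the standard preprocessing chain, the 120-feature spec, and
#' both classifiers evaluated by rotating the 3/4 : 1/4 block split.
#'
#' @param n_subjects Number of simulated subjects (default 11).
#' @param n_blocks Blocks per condition per subject (default 4).
#' @param n_repetitions Repetitions per block (default 10).
#' @param channel_labels Montage (default [montage_64()]).
#' @param fs Acquisition sampling rate, Hz (default 500).
#' @param target_fs Analysis sampling rate, Hz (default 200).
#' @param noise A [noise_spec()].
#' @param congruency_scale Common-amplitude scaling of N2/P3 in the
#'   incongruent condition (default 1.5).
#' @param contrast_scale Target-minus-non-target contrast scaling of
#'   every component in both conditions (default 1; 0 gives a
#'   no-information null study).
#' @param subject_sd Between-subject standard deviation of the
#'   multiplicative component-amplitude factor (default 0.1).
#' @param fspec A [feature_spec()].
#' @param methods Classifiers to run, subset of `c("swlda", "svm")`.
#' @param swlda_cap Retained-feature cap for SWLDA (default 60).
#' @param C_grid,cv_folds Penalty grid and CV folds for the linear
#'   max-margin classifier.
#' @param train_fraction Block fraction defining the rotated split
#'   (default 3/4).
#' @param stat_iters Bootstrap iterations for all tests (default 1000).
#' @param erp_channels Channels for component measurement (default
#'   `c("Cz", "POz", "FC5")`).
#' @param components_measured Components measured per channel (default
#'   `c("N2", "P3")`).
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param out_dir Directory for artifacts, or `NULL` to skip writing.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_subjects = 11, n_blocks = 4, n_repetitions = 10,
                       channel_labels = montage_64(), fs = 500,
                       target_fs = 200, noise = noise_spec(),
                       congruency_scale = 1.5, contrast_scale = 1,
                       subject_sd = 0.1,
                       fspec = feature_spec(),
                       methods = c("swlda", "svm"),
                       swlda_cap = 60,
                       C_grid = 10^(-2:1), cv_folds = 10,
                       train_fraction = 3 / 4,
                       stat_iters = 1000,
                       erp_channels = c("Cz", "POz", "FC5"),
                       components_measured = c("N2", "P3"),
                       seed = 1L, out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

# deterministic per-stage seed derived from the master seed
.derive_seed <- function(seed, subject, condition_index, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + subject * 131 +
                condition_index * 17 + salt) %% 2147483647)
}

# simulate + preprocess + classify one subject under one condition
.run_subject_condition <- function(config, subject, condition) {
  cond_idx <- match(condition, c("congruent", "incongruent"))
  sseed <- .derive_seed(config$seed, subject, cond_idx)

  # between-subject amplitude variability: one factor per subject,
  # shared by the two conditions so the paired design is respected
  set.seed(.derive_seed(config$seed, subject, 0L))
  subj_scale <- max(0.2, 1 + stats::rnorm(1, sd = config$subject_sd))

  comps <- default_components(condition,
                              congruency_scale = config$congruency_scale,
                              contrast_scale = config$contrast_scale)
  comps <- lapply(comps, function(cmp) {
    cmp$amplitude_target <- cmp$amplitude_target * subj_scale
    cmp$amplitude_nontarget <- cmp$amplitude_nontarget * subj_scale
    cmp
  })
  comps <- restrict_components(comps, config$channel_labels)
  sim <- generate_recording(sim_config(
    channel_labels = config$channel_labels, fs = config$fs,
    n_blocks = config$n_blocks, n_repetitions = config$n_repetitions,
    paradigm = condition, components = comps, noise = config$noise,
    seed = sseed))

  rec <- rereference_mastoids(sim$recording)
  rec <- bandpass(rec)
  rec <- downsample(rec, config$target_fs)
  epochs <- extract_epochs(rec, sim$events)
  epochs <- baseline_correct(epochs)

  features <- extract_features(epochs, config$fspec)
  blocks <- sort(unique(features$meta$block))
  scores <- list()
  for (method in config$methods)
    scores[[method]] <- numeric(nrow(features$values))
  for (b in blocks) {
    tr <- features$meta$block != b
    train <- subset_features(features, tr)
    for (method in config$methods) {
      model <- if (method == "swlda")
        fit_swlda(train, max_features = config$swlda_cap)
      else
        fit_linear_margin(train, C_grid = config$C_grid,
                          folds = config$cv_folds,
                          seed = .derive_seed(config$seed, subject,
                                              cond_idx, salt = b))
      scores[[method]][!tr] <-
        decision_scores(model, subset_features(features, !tr))
    }
  }

  block_sets <- lapply(config$methods, function(method) {
    lapply(blocks, function(b) {
      i <- features$meta$block == b
      block_scores(scores[[method]][i], features$meta[i, , drop = FALSE],
                   labels = features$labels[i], block = b,
                   condition = condition)
    })
  })
  names(block_sets) <- config$methods

  scalp <- setdiff(epochs$channel_labels, c("M1", "M2"))
  scalp_idx <- match(scalp, epochs$channel_labels)
  erp <- list(
    target = subject_erp(epochs, "target")[scalp_idx, , drop = FALSE],
    nontarget = subject_erp(epochs, "nontarget")[scalp_idx, , drop = FALSE])

  list(accuracy = vapply(config$methods, function(m)
         single_trial_accuracy(scores[[m]], features$labels), 0),
       blocks = block_sets, erp = erp, times = epochs$times,
       n_epochs = nrow(features$values))
}

#' Run the complete simulated speller study
#'
#' Simulates every subject under both conditions, runs the full
#' preprocessing / feature / classification / decoding chain, and
#' performs the study's statistical comparisons: per-method single-trial
#' accuracy and recognition-curve contrasts between conditions (paired
#' bootstrap t-tests), point-wise ERP-map comparisons with FDR
#' correction for target and non-target responses, and N2/P3
#' amplitude/latency contrasts at the configured electrodes. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return A result bundle (list) with elements `accuracy` (data
#'   frame), `accuracy_tests`, `curves` (data frame), `curve_tests`,
#'   `erp_maps` (target/nontarget [compare_erp_maps()] results),
#'   `components` (data frame of per-subject measures),
#'   `component_tests` (data frame), `times`, and `manifest`. When
#'   `config$out_dir` is set, artifacts are written there and listed
#'   with their MD5 hashes in the manifest.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  conditions <- c("congruent", "incongruent")
  runs <- list()
  for (s in seq_len(config$n_subjects))
    for (cond in conditions)
      runs[[paste(s, cond)]] <- .run_subject_condition(config, s, cond)

  grab <- function(s, cond) runs[[paste(s, cond)]]
  subjects <- seq_len(config$n_subjects)

  # --- single-trial accuracy table and paired tests -------------------
  accuracy <- do.call(rbind, lapply(subjects, function(s)
    do.call(rbind, lapply(conditions, function(cond)
      data.frame(subject = s, condition = cond,
                 method = config$methods,
                 accuracy = unname(grab(s, cond)$accuracy),
                 stringsAsFactors = FALSE)))))
  accuracy_tests <- lapply(config$methods, function(m) {
    a <- accuracy$accuracy[accuracy$method == m &
                             accuracy$condition == "incongruent"]
    b <- accuracy$accuracy[accuracy$method == m &
                             accuracy$condition == "congruent"]
    bootstrap_t(a, b, iters = config$stat_iters,
                seed = .derive_seed(config$seed, 0L, 0L,
                                    salt = match(m, config$methods)))
  })
  names(accuracy_tests) <- config$methods

  # --- recognition curves and per-k comparisons ----------------------
  k_max <- config$n_repetitions
  curve_rows <- list()
  curve_mats <- list()
  for (m in config$methods) for (cond in conditions) {
    mat <- t(vapply(subjects, function(s)
      recognition_curve(grab(s, cond)$blocks[[m]], k_max)$accuracy,
      numeric(k_max)))
    curve_mats[[paste(m, cond)]] <- mat
    curve_rows[[paste(m, cond)]] <- data.frame(
      k = seq_len(k_max), accuracy = colMeans(mat),
      method = m, condition = cond, n_blocks = config$n_blocks,
      stringsAsFactors = FALSE)
  }
  curves <- do.call(rbind, c(curve_rows, make.row.names = FALSE))
  curve_tests <- lapply(config$methods, function(m)
    compare_curves(curve_mats[[paste(m, "incongruent")]],
                   curve_mats[[paste(m, "congruent")]],
                   iters = config$stat_iters,
                   seed = .derive_seed(config$seed, 0L, 1L,
                                       salt = match(m, config$methods))))
  names(curve_tests) <- config$methods

  # --- spatio-temporal ERP comparisons -------------------------------
  erp_maps <- lapply(c(target = "target", nontarget = "nontarget"),
                     function(cls)
    compare_erp_maps(
      lapply(subjects, function(s) grab(s, "incongruent")$erp[[cls]]),
      lapply(subjects, function(s) grab(s, "congruent")$erp[[cls]]),
      iters = config$stat_iters,
      seed = .derive_seed(config$seed, 0L, 2L,
                          salt = match(cls, c("target", "nontarget")))))

  # --- component measures on target ERPs -----------------------------
  times <- runs[[1]]$times
  cw <- component_windows()
  components <- do.call(rbind, lapply(subjects, function(s)
    do.call(rbind, lapply(conditions, function(cond)
      do.call(rbind, lapply(config$erp_channels, function(ch)
        do.call(rbind, lapply(config$components_measured, function(cp) {
          erp <- grab(s, cond)$erp$target
          mm <- measure_component(erp[ch, ], times, cw[[cp]]$window,
                                  cw[[cp]]$polarity, component = cp,
                                  channel = ch)
          data.frame(subject = s, condition = cond, channel = ch,
                     component = cp, amplitude = mm$amplitude,
                     latency_ms = mm$latency_ms,
                     stringsAsFactors = FALSE)
        }))))))))
  component_tests <- do.call(rbind, lapply(config$erp_channels, function(ch)
    do.call(rbind, lapply(config$components_measured, function(cp)
      do.call(rbind, lapply(c("amplitude", "latency_ms"), function(what) {
        pick <- function(cond) components[[what]][
          components$channel == ch & components$component == cp &
            components$condition == cond]
        bt <- bootstrap_t(pick("incongruent"), pick("congruent"),
                          iters = config$stat_iters,
                          seed = .derive_seed(config$seed, 0L, 3L,
                                              salt = match(ch, config$erp_channels)))
        data.frame(channel = ch, component = cp, measure = what,
                   t = bt$t_statistic, p = bt$p_value,
                   stringsAsFactors = FALSE)
      }))))))

  bundle <- list(accuracy = accuracy, accuracy_tests = accuracy_tests,
                 curves = curves, curve_tests = curve_tests,
                 erp_maps = erp_maps, components = components,
                 component_tests = component_tests, times = times,
                 manifest = list(seed = config$seed,
                                 n_subjects = config$n_subjects,
                                 n_blocks = config$n_blocks,
                                 n_repetitions = config$n_repetitions,
                                 n_channels = length(config$channel_labels),
                                 methods = config$methods,
                                 epochs_per_condition = runs[[1]]$n_epochs))
  if (!is.null(config$out_dir)) bundle <- .write_bundle(bundle, config)
  bundle
}

# write the documented tab-separated / JSON artifacts and hash them
.write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[length(paths) + 1]] <<- p
  }
  wtsv(bundle$accuracy, "single_trial_accuracy.tsv")
  wtsv(bundle$curves, "recognition_curves.tsv")
  wtsv(bundle$components, "component_measures.tsv")
  wtsv(bundle$component_tests, "component_tests.tsv")
  for (m in names(bundle$curve_tests))
    wtsv(bundle$curve_tests[[m]], paste0("curve_test_", m, ".tsv"))
  for (cls in names(bundle$erp_maps)) {
    pm <- bundle$erp_maps[[cls]]$p_adjusted
    wtsv(data.frame(channel = rownames(pm), pm, check.names = FALSE),
         paste0("erp_pmap_", cls, ".tsv"))
  }
  p <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(list(
    accuracy_tests = lapply(bundle$accuracy_tests, function(x)
      list(t = x$t_statistic, p = x$p_value)),
    erp_map_fraction_significant = lapply(bundle$erp_maps,
                                          `[[`, "fraction_significant")),
    p, auto_unbox = TRUE, digits = NA)
  paths[[length(paths) + 1]] <- p
  bundle$manifest$files <- data.frame(
    file = basename(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths))),
    stringsAsFactors = FALSE)
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mp, auto_unbox = TRUE, digits = NA)
  bundle
}
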