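#' Arrange decision scores of one block by repetition and stimulus
#'
#' @param scores Decision scores for the block's epochs.
#' @param meta Metadata rows for those epochs (`stimulus_id`,
#'   `repetition`).
#' @param true_target 0-based id of the block's attended stimulus; if
#'   omitted, taken from a logical `labels` argument via the meta rows.
#' @param labels Optional logical target labels used to infer
#'   `true_target`.
#' @param block Block id (informational).
#' @param condition Condition label (informational).
#' @return An object of class `block_scores`: `scores` is a
#'   repetition x stimulus matrix.
#' @export
block_scores <- function(scores, meta, true_target = NULL, labels = NULL,
                         block = NA, condition = NA) {
  stim <- sort(unique(meta$stimulus_id))
  reps <- sort(unique(meta$repetition))
  m <- matrix(NA_real_, length(reps), length(stim),
              dimnames = list(NULL, stim))
  for (i in seq_along(scores))
    m[match(meta$repetition[i], reps),
      match(meta$stimulus_id[i], stim)] <- scores[i]
  if (anyNA(m))
    stop("each (repetition, stimulus) pair needs exactly one score",
         call. = FALSE)
  if (is.null(true_target)) {
    if (is.null(labels)) stop("supply true_target or labels", call. = FALSE)
    true_target <- unique(meta$stimulus_id[labels])
    if (length(true_target) != 1)
      stop("labels must mark exactly one target stimulus", call. = FALSE)
  }
  structure(list(scores = m, stimuli = stim, true_target = true_target,
                 block = block, condition = condition),
            class = "block_scores")
}

#' Decide the attended character from the first k repetitions
#'
#' Sums each stimulus' decision scores over the first `k` repetitions
#' (presentation order) and returns the argmax; ties resolve to the
#' lowest stimulus id.
#'
#' @param block A [block_scores()].
#' @param k Number of repetitions to use (1..available).
#' @return Predicted 0-based stimulus id.
#' @export
character_decision <- function(block, k) {
  stopifnot(inherits(block, "block_scores"))
  if (k < 1 || k > nrow(block$scores))
    stop("k out of range 1..", nrow(block$scores), call. = FALSE)
  sums <- colSums(block$scores[seq_len(k), , drop = FALSE])
  block$stimuli[which.max(sums)]                 # first max -> lowest id
}

#' Character recognition rate versus repetition count
#'
#' For each k in 1..`k_max`, the fraction of blocks whose
#' [character_decision()] with k repetitions equals the true target.
#'
#' @param blocks List of [block_scores()].
#' @param k_max Largest repetition count (default 10).
#' @return Data frame with columns `k` and `accuracy`.
#' @export
recognition_curve <- function(blocks, k_max = 10) {
  if (!length(blocks)) stop("no blocks supplied", call. = FALSE)
  acc <- vapply(seq_len(k_max), function(k) {
    mean(vapply(blocks, function(b)
      character_decision(b, min(k, nrow(b$scores))) == b$true_target,
      TRUE))
  }, 0)
  data.frame(k = seq_len(k_max), accuracy = acc)
}

#' Compare two recognition curves across subjects
#'
#' Paired bootstrap t-test ([bootstrap_t()]) of the per-subject
#' recognition rates at each repetition count, optionally FDR-corrected
#' across the k values.
#'
#' @param curves_a,curves_b Numeric matrices, subjects x k, of paired
#'   per-subject recognition rates under the two conditions.
#' @param iters Bootstrap iterations (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @param fdr Apply Benjamini-Hochberg correction across k (default
#'   `TRUE`).
#' @return Data frame with columns `k`, `t`, `p` and (if `fdr`)
#'   `p_adjusted`.
#' @export
compare_curves <- function(curves_a, curves_b, iters = 1000, seed = 1L,
                           fdr = TRUE) {
  curves_a <- as.matrix(curves_a); curves_b <- as.matrix(curves_b)
  if (!all(dim(curves_a) == dim(curves_b)))
    stop("curves must be paired: equal subjects x k dimensions",
         call. = FALSE)
  res <- lapply(seq_len(ncol(curves_a)), function(k)
    bootstrap_t(curves_a[, k], curves_b[, k], iters = iters,
                seed = seed + k))
  out <- data.frame(k = seq_len(ncol(curves_a)),
                    t = vapply(res, `[[`, 0, "t_statistic"),
                    p = vapply(res, `[[`, 0, "p_value"))
  if (fdr) out$p_adjusted <- fdr_correct(out$p)$p_adjusted
  out
}
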