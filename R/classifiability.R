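#' Classifiability (r-squared) of one feature
#'
#' The squared point-biserial correlation between a scalar feature and
#' the target/non-target label,
#' \deqn{r^2 = \left(\frac{\sqrt{M_T M_N}\,(\mathrm{mean}(X_T) -
#'   \mathrm{mean}(X_N))}{(M_T + M_N)\,\mathrm{std}(X_T \cup X_N)}
#'   \right)^2}
#' where \eqn{M_T, M_N} are the class sample sizes and the standard
#' deviation is the population (biased) one over the pooled sample —
#' the convention that makes the statistic exactly the squared Pearson
#' correlation between feature and binary label.
#'
#' @param x_target Feature values over target epochs.
#' @param x_nontarget Feature values over non-target epochs.
#' @return r-squared in `[0, 1]`. A pooled variance of zero is a
#'   degenerate (constant) feature and scores 0.
#' @export
#' @examples
#' r_squared(c(2, 4), c(1, 3))   # 0.2
r_squared <- function(x_target, x_nontarget) {
  mt <- length(x_target); mn <- length(x_nontarget)
  if (mt < 1 || mn < 1)
    stop("both classes must be non-empty", call. = FALSE)
  pooled <- c(x_target, x_nontarget)
  v <- mean(pooled^2) - mean(pooled)^2           # population variance
  if (v <= 0) return(0)
  num <- sqrt(mt * mn) * (mean(x_target) - mean(x_nontarget))
  (num / ((mt + mn) * sqrt(v)))^2
}

#' Spatio-temporal classifiability map
#'
#' Applies [r_squared()] independently to the amplitude at every
#' (channel, time) point of an epoch set, giving the channels x times
#' map used to pick discriminative electrodes and time windows.
#'
#' @param epochs An [epoch_set()] containing both classes.
#' @return An object of class `classifiability_map`: list with `values`
#'   (channel x time matrix in `[0, 1]`), `channel_labels`, `times`.
#' @export
classifiability_map <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  lab <- epochs$labels
  if (!any(lab)) stop("no target epochs in input", call. = FALSE)
  if (all(lab)) stop("no non-target epochs in input", call. = FALSE)
  d <- dim(epochs$data)
  X <- matrix(epochs$data, nrow = d[1])          # epochs x (channel*time)
  mt <- sum(lab); mn <- sum(!lab); m <- mt + mn
  mean_t <- colMeans(X[lab, , drop = FALSE])
  mean_n <- colMeans(X[!lab, , drop = FALSE])
  v <- colMeans(X^2) - colMeans(X)^2
  r2 <- numeric(ncol(X))
  ok <- v > 0
  r2[ok] <- (sqrt(mt * mn) * (mean_t[ok] - mean_n[ok]))^2 / (m^2 * v[ok])
  structure(list(values = matrix(r2, d[2], d[3],
                                 dimnames = list(epochs$channel_labels, NULL)),
                 channel_labels = epochs$channel_labels,
                 times = epochs$times),
            class = "classifiability_map")
}

#' Average a classifiability map over time windows
#'
#' @param map A [classifiability_map()].
#' @param windows List of `c(start_ms, end_ms)` pairs; each window is
#'   half-open and must contain at least one time sample.
#' @return Matrix channels x windows of mean r-squared values; window
#'   columns are named `"start-end"`.
#' @export
window_average <- function(map, windows) {
  stopifnot(inherits(map, "classifiability_map"))
  out <- sapply(windows, function(w) {
    sel <- map$times >= w[1] & map$times < w[2]
    if (!any(sel)) stop("empty window ", w[1], "-", w[2], " ms", call. = FALSE)
    rowMeans(map$values[, sel, drop = FALSE])
  })
  colnames(out) <- vapply(windows, function(w) paste0(w[1], "-", w[2]), "")
  rownames(out) <- map$channel_labels
  out
}

#' Rank channels by window-averaged classifiability
#'
#' Data-driven alternative to the fixed [speller_channels()] set:
#' channels are ordered by their best window-averaged r-squared.
#'
#' @param map A [classifiability_map()].
#' @param windows Windows as in [window_average()].
#' @param n Number of channels to return.
#' @return Character vector of `n` channel labels, best first.
#' @export
select_channels <- function(map, windows, n = 10) {
  wa <- window_average(map, windows)
  score <- apply(wa, 1, max)
  names(sort(score, decreasing = TRUE))[seq_len(min(n, length(score)))]
}

#' Feature-extraction specification
#'
#' Defaults reproduce the standard speller feature set: three
#' discriminative time windows (180-280, 300-450, 480-530 ms)
#' down-sampled to 40 Hz on 10 channels, i.e. (4 + 6 + 2) x 10 = 120
#' features per stimulus epoch.
#'
#' @param channels Channel labels to use (default [speller_channels()]).
#' @param windows List of `c(start_ms, end_ms)` pairs, non-overlapping
#'   and inside the epoch span.
#' @param feature_rate_hz Rate to which each window is reduced by
#'   block-averaging (default 40; must divide the epoch sampling rate).
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(channels = speller_channels(),
                         windows = list(c(180, 280), c(300, 450), c(480, 530)),
                         feature_rate_hz = 40) {
  o <- order(vapply(windows, `[`, 0, 1))
  w <- windows[o]
  for (i in seq_along(w)) {
    if (w[[i]][2] <= w[[i]][1]) stop("window must have positive length", call. = FALSE)
    if (i > 1 && w[[i]][1] < w[[i - 1]][2])
      stop("windows must be non-overlapping", call. = FALSE)
  }
  structure(list(channels = channels, windows = windows,
                 feature_rate_hz = feature_rate_hz),
            class = "feature_spec")
}

#' Extract windowed, rate-reduced features from epochs
#'
#' Within each window of the spec, each selected channel's signal is
#' reduced to consecutive non-overlapping block means at
#' `feature_rate_hz` (200 Hz epochs at 40 Hz: means of 5-sample
#' blocks), then concatenated over windows and channels in registry
#' order. The default spec on 200 Hz epochs yields 120 features per
#' epoch.
#'
#' @param epochs An [epoch_set()].
#' @param spec A [feature_spec()].
#' @return An object of class `feature_matrix`: list with `values`
#'   (epochs x features), `registry` (data frame: feature, channel,
#'   window_start, window_end, time_ms of each block centre), `labels`,
#'   `meta`.
#' @export
extract_features <- function(epochs, spec = feature_spec()) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "feature_spec"))
  fs <- epochs$fs
  block <- fs / spec$feature_rate_hz
  if (abs(block - round(block)) > 1e-9)
    stop("feature_rate_hz must divide the epoch sampling rate", call. = FALSE)
  block <- as.integer(round(block))
  missing <- setdiff(spec$channels, epochs$channel_labels)
  if (length(missing))
    stop("channel(s) not in epochs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ch_idx <- match(spec$channels, epochs$channel_labels)
  n_epochs <- dim(epochs$data)[1]

  cols <- list(); reg <- list(); k <- 0L
  for (w in spec$windows) {
    sel <- which(epochs$times >= w[1] & epochs$times < w[2])
    nb <- round((w[2] - w[1]) * spec$feature_rate_hz / 1000)
    if (nb < 1 || length(sel) < nb * block)
      stop("window ", w[1], "-", w[2],
           " ms does not fit inside the epochs", call. = FALSE)
    sel <- sel[seq_len(nb * block)]
    grp <- rep(seq_len(nb), each = block)
    for (ci in seq_along(ch_idx)) {
      sig <- epochs$data[, ch_idx[ci], sel, drop = FALSE]  # ep x 1 x t
      sig <- matrix(sig, n_epochs, length(sel))
      means <- sapply(seq_len(nb), function(b)
        rowMeans(sig[, grp == b, drop = FALSE]))
      if (n_epochs == 1) means <- matrix(means, nrow = 1)
      cols[[length(cols) + 1L]] <- means
      reg[[length(reg) + 1L]] <- data.frame(
        feature = k + seq_len(nb),
        channel = spec$channels[ci],
        window_start = w[1], window_end = w[2],
        time_ms = epochs$times[sel[grp == 1]][1] +
          (seq_len(nb) - 0.5) * block / fs * 1000,
        stringsAsFactors = FALSE)
      k <- k + nb
    }
  }
  structure(list(values = do.call(cbind, cols),
                 registry = do.call(rbind, reg),
                 labels = epochs$labels, meta = epochs$meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%d targets)\n",
              nrow(x$values), ncol(x$values), sum(x$labels)))
  invisible(x)
}
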