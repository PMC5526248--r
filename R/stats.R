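#' Paired bootstrap t-test
#'
#' Computes the ordinary paired t statistic on the observed differences
#' and derives its p-value from a bootstrap null distribution built by
#' resampling the mean-centered differences with replacement and
#' recomputing the t statistic (`iters` draws, two-sided). No normality
#' assumption is made about the differences.
#'
#' @param a,b Paired samples (equal length, n >= 2).
#' @param iters Bootstrap iterations (default 1000).
#' @param seed Seed for the resampling.
#' @param conf_level Confidence level for the bootstrap-t interval of
#'   the mean difference (default 0.95).
#' @return An object of class `bootstrap_result`: list with
#'   `t_statistic`, `p_value`, `iterations`, `ci` (bootstrap-t
#'   confidence interval), `mean_difference`, `n`.
#' @export
bootstrap_t <- function(a, b, iters = 1000, seed = 1L,
                        conf_level = 0.95) {
  if (length(a) != length(b)) stop("samples must be paired", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need n >= 2 pairs", call. = FALSE)
  if (iters < 1) stop("iters must be >= 1", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sd_d <- stats::sd(d)
  # zero-variance differences: no evidence if the mean is 0 too,
  # overwhelming evidence otherwise
  t_obs <- if (sd_d < .Machine$double.eps) {
    if (abs(md) < .Machine$double.eps) 0 else sign(md) * Inf
  } else md / (sd_d / sqrt(n))

  set.seed(seed)
  dc <- d - md
  idx <- matrix(sample.int(n, n * iters, replace = TRUE), iters, n)
  xs <- matrix(dc[idx], iters, n)
  m_star <- rowMeans(xs)
  v_star <- pmax((rowSums(xs^2) - n * m_star^2) / (n - 1), 0)
  t_star <- ifelse(v_star < .Machine$double.eps, 0,
                   m_star / sqrt(v_star / n))
  # plug-in bootstrap p; resolution 1/iters, 0 = beyond resolution
  p <- mean(abs(t_star) >= abs(t_obs))

  # bootstrap-t interval: resample the raw differences' t-pivot
  alpha <- 1 - conf_level
  q <- stats::quantile(t_star, c(1 - alpha / 2, alpha / 2), names = FALSE)
  ci <- md - q * sd_d / sqrt(n)
  structure(list(t_statistic = t_obs, p_value = p, iterations = iters,
                 ci = ci, conf_level = conf_level,
                 mean_difference = md, n = n),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap t-test: t(%d) = %.3f, p = %.4g (%d iterations)\n",
              x$n - 1, x$t_statistic, x$p_value, x$iterations))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a vector of p-values; features flagged
#' significant are those with adjusted p at or below `q`.
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` (same order as input) and
#'   `significant` (logical mask).
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = adj <= q)
}

#' Grand-average ERP across subjects
#'
#' Averages per-subject mean ERPs with equal subject weights (a subject
#' with more epochs does not count more), per channel and time point.
#'
#' @param subject_epochs List with one element per subject: either an
#'   [epoch_set()] (averaged over the selected class here) or an
#'   already-averaged channels x times matrix.
#' @param class For epoch-set input, which epochs to average:
#'   `"target"`, `"nontarget"` or `"all"`.
#' @return Channels x times matrix (microvolts) with the shared channel
#'   labels as row names; attributes `times` and `n_subjects`.
#' @export
grand_average <- function(subject_epochs,
                          class = c("target", "nontarget", "all")) {
  class <- match.arg(class)
  per_subject <- lapply(subject_epochs, function(s) {
    if (inherits(s, "epoch_set")) subject_erp(s, class) else as.matrix(s)
  })
  ref <- per_subject[[1]]
  for (m in per_subject[-1])
    if (!all(dim(m) == dim(ref)) ||
        !identical(rownames(m), rownames(ref)))
      stop("subjects must share the channel/time grid", call. = FALSE)
  out <- Reduce(`+`, per_subject) / length(per_subject)
  attr(out, "n_subjects") <- length(per_subject)
  s1 <- subject_epochs[[1]]
  if (inherits(s1, "epoch_set")) attr(out, "times") <- s1$times
  out
}

#' Per-subject mean ERP
#'
#' @param epochs An [epoch_set()].
#' @param class `"target"`, `"nontarget"` or `"all"`.
#' @return Channels x times matrix of mean amplitude.
#' @export
subject_erp <- function(epochs, class = c("target", "nontarget", "all")) {
  class <- match.arg(class)
  keep <- switch(class, target = epochs$labels,
                 nontarget = !epochs$labels,
                 all = rep(TRUE, length(epochs$labels)))
  if (!any(keep)) stop("no epochs of class ", class, call. = FALSE)
  m <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  rownames(m) <- epochs$channel_labels
  m
}

#' Measure an ERP component's amplitude and latency
#'
#' Amplitude is the polarity-matching extremum inside the window;
#' latency is its time. A flat (all-equal) waveform inside the window is
#' degenerate: amplitude 0, latency at the window start, `flagged`.
#'
#' @param waveform Single-channel ERP, microvolts.
#' @param times Time axis, ms (same length as `waveform`).
#' @param window `c(start_ms, end_ms)` search window (half-open).
#' @param polarity `"+"` (positive component, e.g. P3) or `"-"`
#'   (negative, e.g. N2).
#' @param component Optional component label carried into the result.
#' @param channel Optional channel label carried into the result.
#' @return List with `component`, `channel`, `window`, `polarity`,
#'   `amplitude` (microvolts), `latency_ms`, `flagged`.
#' @export
measure_component <- function(waveform, times, window,
                              polarity = c("+", "-"),
                              component = NA, channel = NA) {
  polarity <- match.arg(polarity)
  sel <- which(times >= window[1] & times < window[2])
  if (!length(sel)) stop("empty component window", call. = FALSE)
  w <- waveform[sel]
  if (diff(range(w)) < .Machine$double.eps) {
    return(list(component = component, channel = channel, window = window,
                polarity = polarity, amplitude = 0,
                latency_ms = times[sel[1]], flagged = TRUE))
  }
  i <- if (polarity == "+") which.max(w) else which.min(w)
  list(component = component, channel = channel, window = window,
       polarity = polarity, amplitude = w[i], latency_ms = times[sel[i]],
       flagged = FALSE)
}

#' Default component measurement windows
#'
#' Search windows bracketing the four components' nominal peaks
#' (N2 ~200 ms, P3 ~350 ms, N4 ~440 ms, P5 ~620 ms).
#'
#' @return Named list of `list(window, polarity)` per component.
#' @export
component_windows <- function() {
  list(N2 = list(window = c(150, 280), polarity = "-"),
       P3 = list(window = c(280, 450), polarity = "+"),
       N4 = list(window = c(400, 480), polarity = "-"),
       P5 = list(window = c(550, 700), polarity = "+"))
}

#' Point-wise bootstrap comparison of two ERP map sets
#'
#' Runs the paired bootstrap t-test at every (channel, time) point of
#' per-subject ERP maps under two conditions and applies
#' Benjamini-Hochberg correction jointly across all points. One shared
#' set of bootstrap resamples drives all points, which makes the
#' channel x time sweep a pair of matrix products.
#'
#' @param erps_a,erps_b Lists (one channels x times matrix per subject,
#'   paired and on a common grid).
#' @param iters Bootstrap iterations (default 1000).
#' @param seed Seed for the resampling.
#' @param q FDR level (default 0.05).
#' @return List with matrices `t` (observed t), `p` (bootstrap p),
#'   `p_adjusted`, `significant` (all channels x times), and
#'   `fraction_significant`.
#' @export
compare_erp_maps <- function(erps_a, erps_b, iters = 1000, seed = 1L,
                             q = 0.05) {
  if (length(erps_a) != length(erps_b))
    stop("conditions must have paired subjects", call. = FALSE)
  n <- length(erps_a)
  if (n < 2) stop("need >= 2 subjects", call. = FALSE)
  dims <- dim(erps_a[[1]])
  for (m in c(erps_a, erps_b))
    if (!all(dim(m) == dims))
      stop("all subjects must share the channel/time grid", call. = FALSE)

  # points x subjects matrix of paired differences
  D <- vapply(seq_len(n), function(s) as.vector(erps_a[[s]] - erps_b[[s]]),
              numeric(prod(dims)))
  md <- rowMeans(D)
  v <- pmax((rowSums(D^2) - n * md^2) / (n - 1), 0)
  t_obs <- ifelse(v < .Machine$double.eps,
                  ifelse(abs(md) < .Machine$double.eps, 0, sign(md) * Inf),
                  md / sqrt(v / n))

  set.seed(seed)
  Dc <- D - md
  # counts matrix: how often each subject appears in each resample
  idx <- matrix(sample.int(n, n * iters, replace = TRUE), iters, n)
  M <- t(apply(idx, 1, tabulate, nbins = n))     # iters x subjects
  S1 <- Dc %*% t(M)                              # points x iters sums
  S2 <- (Dc^2) %*% t(M)
  m_star <- S1 / n
  v_star <- pmax((S2 - n * m_star^2) / (n - 1), 0)
  t_star <- ifelse(v_star < .Machine$double.eps, 0,
                   m_star / sqrt(v_star / n))
  p <- rowSums(abs(t_star) >= abs(t_obs)) / iters

  fdr <- fdr_correct(p, q)
  shape <- function(x) {
    m <- matrix(x, dims[1], dims[2])
    rownames(m) <- rownames(erps_a[[1]])
    m
  }
  list(t = shape(t_obs), p = shape(p),
       p_adjusted = shape(fdr$p_adjusted),
       significant = shape(fdr$significant),
       fraction_significant = mean(fdr$significant))
}
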