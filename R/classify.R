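#' @keywords internal
.as_feature_values <- function(features) {
  if (inherits(features, "feature_matrix")) features$values
  else as.matrix(features)
}

.feature_labels <- function(features, labels) {
  if (is.null(labels)) {
    if (!inherits(features, "feature_matrix"))
      stop("labels must be supplied for a plain matrix", call. = FALSE)
    features$labels
  } else as.logical(labels)
}

#' Linear target/non-target model
#'
#' Shared container for the two classifiers: a weight vector over the
#' retained features, a bias, and the retained-feature index set.
#' Scores are `weights . x[retained] + bias`, larger = more
#' target-like.
#'
#' @param weights Numeric weights, one per retained feature.
#' @param bias Intercept.
#' @param retained Column indices of the retained features.
#' @param method `"swlda"` or `"svm"`.
#' @param training_meta List of tuning settings recorded at fit time.
#' @param null_model `TRUE` when stepwise selection retained nothing;
#'   such a model scores every epoch 0.
#' @return An object of class `linear_model`.
#' @export
linear_model <- function(weights, bias, retained, method,
                         training_meta = list(), null_model = FALSE) {
  if (length(weights) != length(retained))
    stop("weights and retained must have equal length", call. = FALSE)
  structure(list(weights = as.numeric(weights), bias = as.numeric(bias),
                 retained = as.integer(retained), method = method,
                 training_meta = training_meta, null_model = null_model),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("<linear_model> method=%s, %d feature(s) retained%s\n",
              x$method, length(x$retained),
              if (x$null_model) " [null model]" else ""))
  invisible(x)
}

# Partial-F p-values for adding each candidate column, given the
# orthonormal basis Q of the current design (intercept included).
# Returns NA for candidates (numerically) inside the current span.
.forward_pvalues <- function(X, y, Q, rss, df_new) {
  R <- X - Q %*% crossprod(Q, X)
  ss <- colSums(R^2)
  num <- drop(crossprod(R, y))
  ssr <- ifelse(ss > 1e-10, num^2 / ss, NA_real_)
  f <- ssr / ((rss - ssr) / df_new)
  p <- stats::pf(f, 1, df_new, lower.tail = FALSE)
  p[!is.finite(f) | f < 0] <- NA_real_
  p
}

#' Stepwise linear discriminant analysis (SWLDA)
#'
#' Linear classifier whose features are chosen by the union of forward
#' and backward stepwise ordinary-least-squares calculations on the
#' class label coded +1/-1: forward steps add the candidate with the
#' smallest partial-F p-value while it is below `p_enter`; backward
#' steps drop any retained feature whose coefficient p-value exceeds
#' `p_remove`; the cycle repeats until the retained set is stable or
#' the cap of `max_features` is reached. Final weights are the OLS
#' regression coefficients of the label on the retained features.
#'
#' @param features A `feature_matrix` or plain numeric matrix
#'   (epochs x features).
#' @param labels Logical target labels; taken from the feature matrix
#'   if omitted.
#' @param p_enter Entry p-value threshold (default 0.10).
#' @param p_remove Removal p-value threshold (default 0.15).
#' @param max_features Cap on the retained-feature count (default 60).
#' @return A [linear_model()]. If no candidate passes entry the model
#'   is flagged `null_model` with an empty retained set.
#' @export
fit_swlda <- function(features, labels = NULL, p_enter = 0.10,
                      p_remove = 0.15, max_features = 60) {
  X <- .as_feature_values(features)
  lab <- .feature_labels(features, labels)
  if (!any(lab) || all(lab))
    stop("both classes must be present", call. = FALSE)
  y <- ifelse(lab, 1, -1)
  n <- nrow(X); p_all <- ncol(X)

  retained <- integer(0)
  # orthonormal basis of the current design, starting from the intercept
  Q <- matrix(1 / sqrt(n), n, 1)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 1000L) {
      warning("stepwise selection did not stabilise within 1000 cycles")
      break
    }
    changed <- FALSE
    # forward entry
    if (length(retained) < max_features) {
      cand <- setdiff(seq_len(p_all), retained)
      df_new <- n - length(retained) - 2
      if (length(cand) && df_new > 0) {
        y_res <- y - Q %*% crossprod(Q, y)
        rss <- sum(y_res^2)
        pv <- .forward_pvalues(X[, cand, drop = FALSE], y, Q, rss, df_new)
        if (any(!is.na(pv)) && min(pv, na.rm = TRUE) < p_enter) {
          best <- cand[which.min(pv)]            # ties -> lowest index
          retained <- c(retained, best)
          r <- X[, best] - Q %*% crossprod(Q, X[, best])
          Q <- cbind(Q, r / sqrt(sum(r^2)))
          changed <- TRUE
        }
      }
    }
    # backward removal (worst offender, one at a time)
    repeat {
      if (length(retained) < 1) break
      fit <- stats::lm.fit(cbind(1, X[, retained, drop = FALSE]), y)
      df <- n - length(retained) - 1
      if (df <= 0) break
      sigma2 <- sum(fit$residuals^2) / df
      Rq <- qr.R(fit$qr)
      XtXi <- chol2inv(Rq)
      se <- sqrt(sigma2 * diag(XtXi))[-1]
      tstat <- fit$coefficients[-1] / se
      pv <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
      worst <- which.max(pv)
      if (pv[worst] > p_remove) {
        retained <- retained[-worst]
        # rebuild the orthonormal basis after a removal
        Q <- qr.Q(qr(cbind(1 / sqrt(n), X[, retained, drop = FALSE])))
        changed <- TRUE
      } else break
    }
    if (!changed || length(retained) >= max_features) {
      if (length(retained) >= max_features && changed) next
      break
    }
  }

  meta <- list(p_enter = p_enter, p_remove = p_remove,
               max_features = max_features)
  if (!length(retained))
    return(linear_model(numeric(0), 0, integer(0), "swlda", meta,
                        null_model = TRUE))
  fit <- stats::lm.fit(cbind(1, X[, retained, drop = FALSE]), y)
  linear_model(fit$coefficients[-1], fit$coefficients[1], retained,
               "swlda", meta)
}

# stratified fold assignment: each class split as evenly as possible
.stratified_folds <- function(lab, folds) {
  if (min(sum(lab), sum(!lab)) < folds)
    stop("folds must not exceed the smaller class count", call. = FALSE)
  f <- integer(length(lab))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(lab == cls))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Linear maximum-margin classifier with cross-validated penalty
#'
#' Soft-margin linear support-vector classifier; the penalty C is
#' chosen by stratified k-fold cross validation over `C_grid`
#' (maximum mean accuracy, ties broken toward the smallest C). The
#' quadratic-programming solver is delegated to \pkg{e1071} (libsvm);
#' the resulting hyperplane is re-expressed as an explicit
#' [linear_model()] oriented so targets score higher.
#'
#' @param features A `feature_matrix` or numeric matrix.
#' @param labels Logical target labels; taken from the feature matrix
#'   if omitted.
#' @param C_grid Candidate penalty values (default `10^(-2:1)`).
#' @param folds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return A [linear_model()] with `method = "svm"`; `training_meta`
#'   records the chosen C and the CV accuracy per grid point.
#' @export
fit_linear_margin <- function(features, labels = NULL,
                              C_grid = 10^(-2:1), folds = 10,
                              seed = 1L) {
  X <- .as_feature_values(features)
  lab <- .feature_labels(features, labels)
  if (!any(lab) || all(lab))
    stop("both classes must be present", call. = FALSE)
  set.seed(seed)
  C_grid <- sort(C_grid)
  fold_id <- .stratified_folds(lab, folds)
  yf <- factor(ifelse(lab, "target", "nontarget"),
               levels = c("nontarget", "target"))
  cv_acc <- vapply(C_grid, function(C) {
    acc <- vapply(seq_len(folds), function(k) {
      tr <- fold_id != k
      m <- e1071::svm(X[tr, , drop = FALSE], yf[tr], kernel = "linear",
                      cost = C, scale = FALSE)
      mean(stats::predict(m, X[!tr, , drop = FALSE]) == yf[!tr])
    }, 0)
    mean(acc)
  }, 0)
  best_C <- C_grid[which.max(cv_acc)]            # ties -> smallest C
  m <- e1071::svm(X, yf, kernel = "linear", cost = best_C, scale = FALSE)
  w <- drop(crossprod(m$coefs, m$SV))
  b <- -m$rho
  # libsvm's decision sign follows label order; orient toward targets
  s <- drop(X %*% w) + b
  if (mean(s[lab]) < mean(s[!lab])) { w <- -w; b <- -b }
  linear_model(w, b, seq_len(ncol(X)), "svm",
               training_meta = list(C = best_C, folds = folds,
                                    C_grid = C_grid, cv_accuracy = cv_acc))
}

#' Decision scores of a linear model
#'
#' @param model A [linear_model()].
#' @param features A `feature_matrix` or numeric matrix with the same
#'   feature columns the model was trained on.
#' @return Numeric score per epoch (`weights . x + bias`); a null model
#'   scores every epoch 0.
#' @export
decision_scores <- function(model, features) {
  stopifnot(inherits(model, "linear_model"))
  X <- .as_feature_values(features)
  if (model$null_model) return(rep(0, nrow(X)))
  if (max(model$retained) > ncol(X))
    stop("feature matrix lacks retained feature column(s): ",
         paste(model$retained[model$retained > ncol(X)], collapse = ", "),
         call. = FALSE)
  drop(X[, model$retained, drop = FALSE] %*% model$weights) + model$bias
}

#' Block-wise train/test split
#'
#' Assigns whole blocks to the training or testing side (never
#' splitting a block), at a train fraction of the blocks rounded to the
#' nearest whole block — the standard 3/4 : 1/4 split with four blocks.
#'
#' @param features A `feature_matrix` whose `meta$block` identifies
#'   blocks.
#' @param train_fraction Fraction of blocks to train on (default 3/4).
#' @param seed Seed for the block assignment.
#' @return List with `train` and `test` logical epoch masks and the
#'   chosen `train_blocks` / `test_blocks`.
#' @export
split_blocks <- function(features, train_fraction = 3 / 4, seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  blocks <- unique(features$meta$block)
  if (length(blocks) < 2)
    stop("need at least 2 blocks for a block-wise split", call. = FALSE)
  n_train <- max(1, min(length(blocks) - 1,
                        round(train_fraction * length(blocks))))
  set.seed(seed)
  train_blocks <- sort(sample(blocks, n_train))
  train <- features$meta$block %in% train_blocks
  list(train = train, test = !train,
       train_blocks = train_blocks,
       test_blocks = setdiff(blocks, train_blocks))
}

#' Subset a feature matrix by epoch mask
#'
#' @param features A `feature_matrix`.
#' @param i Logical or integer epoch index.
#' @return A `feature_matrix` with the selected epochs.
#' @export
subset_features <- function(features, i) {
  structure(list(values = features$values[i, , drop = FALSE],
                 registry = features$registry,
                 labels = features$labels[i],
                 meta = features$meta[i, , drop = FALSE]),
            class = "feature_matrix")
}

#' Single-trial classification accuracy
#'
#' Fraction of epochs whose thresholded score matches the label.
#'
#' @param scores Decision scores.
#' @param labels Logical target labels.
#' @param threshold Decision threshold (default 0).
#' @return Fraction correct in `[0, 1]`.
#' @export
single_trial_accuracy <- function(scores, labels, threshold = 0) {
  if (!length(scores)) stop("empty input", call. = FALSE)
  mean((scores > threshold) == as.logical(labels))
}

#' Serialize a linear model to JSON
#'
#' @param model A [linear_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a linear model written by [write_model()]
#' @param path JSON path.
#' @return A [linear_model()].
#' @export
read_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_model(m$weights, m$bias, m$retained, m$method,
               as.list(m$training_meta), isTRUE(m$null_model))
}
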