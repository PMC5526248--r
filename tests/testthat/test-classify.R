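# labelled feature matrix with planted class-mean separations
make_features <- function(n, p, informative = integer(0), sep = 1,
                          seed = 1) {
  set.seed(seed)
  lab <- rep(c(TRUE, FALSE, FALSE, FALSE), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  for (j in informative) X[lab, j] <- X[lab, j] + sep
  structure(list(values = X,
                 registry = data.frame(feature = seq_len(p)),
                 labels = lab,
                 meta = data.frame(stimulus_id = rep(0:3, length.out = n),
                                   block = rep(1:4, each = n / 4)[seq_len(n)],
                                   repetition = seq_len(n),
                                   paradigm = "congruent")),
            class = "feature_matrix")
}

test_that("SWLDA finds a perfectly separating feature among noise", {
  fm <- make_features(200, 51, informative = 26, sep = 0, seed = 42)
  fm$values[, 26] <- ifelse(fm$labels, 1, -1)      # perfect separator
  m <- fit_swlda(fm)
  expect_true(26 %in% m$retained)
  expect_false(m$null_model)
  acc <- single_trial_accuracy(decision_scores(m, fm), fm$labels)
  expect_equal(acc, 1.0)
})

test_that("SWLDA returns a flagged null model when nothing can enter", {
  fm <- make_features(80, 20, seed = 7)
  m <- fit_swlda(fm, p_enter = 1e-9)
  expect_true(m$null_model)
  expect_length(m$retained, 0)
  expect_equal(decision_scores(m, fm), rep(0, 80))
})

test_that("SWLDA respects the retained-feature cap", {
  fm <- make_features(300, 120, informative = 1:100, sep = 1.2, seed = 8)
  m <- fit_swlda(fm, max_features = 10)
  expect_lte(length(m$retained), 10)
  m60 <- fit_swlda(fm)
  expect_lte(length(m60$retained), 60)
  expect_gt(length(m60$retained), 10)              # plenty of signal to use
})

test_that("no retained feature is removable at termination", {
  fm <- make_features(150, 30, informative = 1:6, sep = 0.9, seed = 9)
  m <- fit_swlda(fm)
  X <- fm$values[, m$retained, drop = FALSE]
  y <- ifelse(fm$labels, 1, -1)
  fit <- lm(y ~ X)
  pv <- summary(fit)$coefficients[-1, 4]
  expect_true(all(pv <= 0.15 + 1e-12))
})

test_that("greedy SWLDA agrees with exhaustive best-subset OLS on a clear instance", {
  set.seed(10)
  n <- 60
  lab <- rep(c(TRUE, FALSE), n / 2)
  y <- ifelse(lab, 1, -1)
  X <- cbind(y + rnorm(n, sd = 0.4),               # strong
             y + rnorm(n, sd = 1.2),               # medium
             rnorm(n), rnorm(n))                   # noise
  fm <- structure(list(values = X, registry = data.frame(feature = 1:4),
                       labels = lab,
                       meta = data.frame(stimulus_id = 0, block = 1,
                                         repetition = seq_len(n),
                                         paradigm = "x")),
                  class = "feature_matrix")
  m <- fit_swlda(fm)
  k <- length(m$retained)
  rss <- function(cols) sum(lm.fit(cbind(1, X[, cols, drop = FALSE]),
                                   y)$residuals^2)
  best <- combn(4, k, simplify = FALSE)
  best <- best[[which.min(vapply(best, rss, 0))]]
  expect_setequal(m$retained, best)
})

test_that("linear max-margin classifier separates a separable toy and is stable to duplicated columns", {
  X <- rbind(c(2, 2), c(1.5, 2.5), c(-2, -2), c(-2.5, -1.5))
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  m <- fit_linear_margin(X, lab, folds = 2, seed = 1)
  expect_equal(single_trial_accuracy(decision_scores(m, X), lab), 1.0)

  fm <- make_features(120, 6, informative = 1:2, sep = 1.5, seed = 11)
  m1 <- fit_linear_margin(fm, folds = 5, seed = 2)
  Xdup <- cbind(fm$values, fm$values)
  m2 <- fit_linear_margin(Xdup, fm$labels, folds = 5, seed = 2)
  # duplicating columns rescales the linear kernel, so decision values
  # are equivalent up to that scaling: same ranking, same decisions
  s1 <- decision_scores(m1, fm$values)
  s2 <- decision_scores(m2, Xdup)
  expect_gt(cor(s1, s2), 0.95)
  expect_gt(mean((s1 > 0) == (s2 > 0)), 0.95)
})

test_that("cross-validated accuracy sits at chance for label-independent features", {
  fm <- make_features(400, 10, seed = 12)
  set.seed(12)
  fm$labels <- sample(rep(c(TRUE, FALSE), 200))    # balanced, independent
  m <- fit_linear_margin(fm, folds = 10, seed = 3)
  expect_gte(mean(m$training_meta$cv_accuracy), 0.40)
  expect_lte(mean(m$training_meta$cv_accuracy), 0.60)
})

test_that("decision scores are the affine feature map", {
  m <- linear_model(c(1, -1), 0, c(1, 2), "swlda")
  expect_equal(decision_scores(m, rbind(c(3, 1))), 2)
  expect_equal(decision_scores(m, rbind(c(6, 2))), 4)   # linear in x
  mb <- linear_model(c(1, -1), 5, c(1, 2), "swlda")
  expect_equal(decision_scores(mb, rbind(c(3, 1))), 7)
  expect_error(decision_scores(m, rbind(1)), "retained feature")
})

test_that("block-wise split partitions epochs and blocks 3:1", {
  fm <- make_features(160, 5, seed = 13)
  sp <- split_blocks(fm, seed = 4)
  expect_length(sp$train_blocks, 3)
  expect_length(sp$test_blocks, 1)
  expect_true(all(xor(sp$train, sp$test)))
  expect_false(any(fm$meta$block[sp$train] %in% fm$meta$block[sp$test]))
  sp2 <- split_blocks(fm, seed = 4)
  expect_identical(sp$train_blocks, sp2$train_blocks)

  one <- make_features(40, 5, seed = 13)
  one$meta$block <- 1
  expect_error(split_blocks(one), "at least 2 blocks")
})

test_that("single-trial accuracy counts thresholded agreements", {
  expect_equal(single_trial_accuracy(c(1, 1, -1), c(TRUE, TRUE, FALSE)), 1.0)
  expect_equal(single_trial_accuracy(c(-1, 1), c(TRUE, FALSE)), 0.0)
  expect_equal(single_trial_accuracy(c(2, 2, -3, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(single_trial_accuracy(numeric(0), logical(0)), "empty")
})

test_that("linear models serialize to JSON and back", {
  m <- linear_model(c(0.5, -1.25), 0.3, c(2, 7), "swlda",
                    training_meta = list(p_enter = 0.1))
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$weights, m$weights)
  expect_equal(back$bias, m$bias)
  expect_identical(back$retained, m$retained)
})
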