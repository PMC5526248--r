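test_that("r_squared matches its worked values and the Pearson identity", {
  expect_equal(r_squared(c(1, 1), c(0, 0)), 1.0)
  expect_equal(r_squared(c(3, 5), c(3, 5)), 0.0)
  expect_equal(r_squared(c(2, 4), c(1, 3)), 0.2)

  set.seed(14)
  for (i in 1:200) {
    mt <- sample(2:15, 1); mn <- sample(2:15, 1)
    xt <- rnorm(mt, mean = runif(1, -2, 2))
    xn <- rnorm(mn)
    lab <- c(rep(1, mt), rep(0, mn))
    expect_equal(r_squared(xt, xn), cor(c(xt, xn), lab)^2,
                 tolerance = 1e-12)
    expect_equal(r_squared(xt, xn), r2_definition(xt, xn),
                 tolerance = 1e-12)
  }
})

test_that("r_squared is affine-invariant, symmetric in class swap, total", {
  set.seed(15)
  xt <- rnorm(8); xn <- rnorm(12)
  base <- r_squared(xt, xn)
  expect_equal(r_squared(3.7 * xt - 2, 3.7 * xn - 2), base, tolerance = 1e-12)
  expect_equal(r_squared(-xt, -xn), base, tolerance = 1e-12)
  expect_equal(r_squared(xn, xt), base, tolerance = 1e-12)
  expect_equal(r_squared(c(2, 2), c(2, 2)), 0)     # degenerate -> 0
  expect_error(r_squared(numeric(0), xn), "non-empty")
})

test_that("classifiability maps localize a planted effect and are zero without one", {
  set.seed(16)
  n <- 120
  d <- array(rnorm(n * 4 * 200), c(n, 4, 200))
  lab <- rep(c(TRUE, FALSE, FALSE, FALSE), n / 4)
  sel <- 101:130                                   # 300-445 ms at 200 Hz
  d[lab, 2, sel] <- d[lab, 2, sel] + 2
  ep <- make_epochs(d, labels = lab,
                    channel_labels = c("Cz", "Pz", "Oz", "Fz"))
  map <- classifiability_map(ep)
  expect_true(all(map$values >= 0 & map$values <= 1))
  top <- which(map$values == max(map$values), arr.ind = TRUE)
  expect_equal(map$channel_labels[top[1]], "Pz")
  expect_true(map$times[top[2]] >= 300 && map$times[top[2]] < 450)

  # identical epochs in both classes -> all-zero map
  same <- array(rep(rnorm(2 * 50), each = 4), c(4, 2, 50))
  ep0 <- make_epochs(same, labels = c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(classifiability_map(ep0)$values < 1e-20))

  ep1 <- make_epochs(d, labels = rep(TRUE, n))
  expect_error(classifiability_map(ep1), "non-target")
})

test_that("null labels give map values at the 1/(n-1) chance scale", {
  set.seed(17)
  n <- 200
  d <- array(rnorm(n * 3 * 100), c(n, 3, 100))
  ep <- make_epochs(d, labels = sample(rep(c(TRUE, FALSE), n / 2)))
  m <- mean(classifiability_map(ep)$values)
  expect_lt(abs(m - 1 / (n - 1)), 2 / (n - 1))
})

test_that("window averages reduce the map correctly", {
  map <- structure(list(values = matrix(0.4, 3, 100),
                        channel_labels = c("a", "b", "c"),
                        times = seq(-200, 295, by = 5)),
                   class = "classifiability_map")
  wa <- window_average(map, list(c(0, 100), c(100, 200)))
  expect_true(all(wa == 0.4))

  map$values[2, ] <- seq_len(100) / 100
  full <- window_average(map, list(c(-200, 300)))
  expect_equal(full[2, 1], mean(map$values[2, ]))

  map$values[1, map$times >= 0 & map$times < 10] <- c(0.1, 0.3)
  expect_equal(window_average(map, list(c(0, 10)))[1, 1], 0.2)
  expect_error(window_average(map, list(c(900, 950))), "empty window")
})

test_that("default feature extraction yields 120 features with a consistent registry", {
  set.seed(18)
  d <- array(rnorm(12 * 25 * 200), c(12, 25, 200))
  ep <- make_epochs(d, channel_labels = small_montage())
  fm <- extract_features(ep)
  expect_equal(ncol(fm$values), 120)
  expect_equal(nrow(fm$registry), 120)
  expect_equal(as.integer(table(fm$registry$channel)[speller_channels()]),
               rep(12L, 10))
  expect_setequal(unique(fm$registry$window_start), c(180, 300, 480))

  # block means: feature = mean of its 5-sample block
  f1 <- fm$registry[1, ]
  ch <- match(f1$channel, ep$channel_labels)
  sel <- which(ep$times >= 180 & ep$times < 205)
  expect_equal(fm$values[3, 1], mean(d[3, ch, sel]), tolerance = 1e-12)
})

test_that("feature counts follow the window-length formula for arbitrary specs", {
  set.seed(19)
  d <- array(rnorm(6 * 25 * 200), c(6, 25, 200))
  ep <- make_epochs(d, channel_labels = small_montage())

  one <- extract_features(ep, feature_spec(channels = "Cz",
                                           windows = list(c(300, 400)),
                                           feature_rate_hz = 40))
  expect_equal(ncol(one$values), 4)                # 100 ms x 40 Hz

  for (i in 1:8) {
    n_ch <- sample(1:5, 1)
    chans <- sample(small_montage()[1:10], n_ch)
    starts <- c(-150, 100, 400) + sample(0:50, 3, replace = TRUE)
    rate <- sample(c(20, 40), 1)
    wins <- lapply(starts, function(s) c(s, s + sample(c(50, 100, 150), 1)))
    fm <- extract_features(ep, feature_spec(chans, wins, rate))
    expected <- sum(vapply(wins, function(w)
      round((w[2] - w[1]) * rate / 1000), 0)) * n_ch
    expect_equal(ncol(fm$values), expected)
  }

  const <- make_epochs(array(3, c(2, 25, 200)),
                       channel_labels = small_montage())
  expect_true(all(extract_features(const)$values == 3))

  expect_error(extract_features(ep, feature_spec(windows = list(c(700, 900)))),
               "fit inside")
  expect_error(feature_spec(windows = list(c(0, 100), c(50, 150))),
               "non-overlapping")
})
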