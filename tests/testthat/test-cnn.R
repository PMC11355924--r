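test_that("min-max normalization implements the rescaling identity", {
  n <- minmax_normalize(matrix(c(2, 4, 6), ncol = 1))
  expect_equal(as.numeric(n$values), c(0, 0.5, 1))
  x <- matrix(runif(300), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  nm <- minmax_normalize(x)
  back <- minmax_denormalize(nm$values, nm)
  expect_equal(unname(back), unname(x), tolerance = 1e-12)
  expect_equal(as.numeric(nm$values[which.min(x[, 1]), 1]), 0)
  expect_error(minmax_normalize(cbind(a = rep(3, 5), b = 1:5)), "a")
})

test_that("normalization statistics come from the training split only", {
  train <- matrix(c(0, 10), ncol = 1)
  test <- matrix(c(20), ncol = 1)
  norm <- minmax_normalize(train)
  te <- minmax_normalize(test, ranges = norm)
  expect_equal(as.numeric(te$values), 2)  # outside [0,1]: test range unseen
  expect_equal(unname(norm$max), 10)      # untouched by the test value
})

test_that("dataset splits are disjoint, exhaustive and reproducible", {
  s <- split_dataset(10, 0.8, seed = 3)
  expect_identical(length(s$train), 8L)
  expect_identical(length(s$test), 2L)
  expect_identical(sort(c(s$train, s$test)), 1:10)
  expect_identical(split_dataset(10, 0.8, seed = 3), s)
  expect_false(identical(split_dataset(10, 0.8, seed = 4), s))
  expect_error(split_dataset(4), "at least 5")
  expect_error(split_dataset(10, 1.2), "strictly in")
})

test_that("the tuned architecture presets build as specified", {
  m1 <- build_cnn(cnn_preset(1), input_resolution = 172)
  expect_identical(length(m1$conv), 3L)
  expect_identical(sapply(m1$conv, function(l) ncol(l$w)),
                   c(8L, 16L, 32L))
  expect_identical(nrow(m1$conv[[1]]$w), 9L * 4L)  # 3x3 kernel, 4 channels
  expect_identical(sapply(m1$dense, function(l) nrow(l$w)),
                   c(128L, 64L, 6L))
  m3 <- build_cnn(cnn_preset(3), input_resolution = 64)
  expect_identical(sapply(m3$conv, function(l) ncol(l$w)),
                   c(16L, 32L, 64L))
  expect_identical(nrow(m3$dense[[3]]$w), 9L)
  expect_identical(m3$config$n_epochs, 250L)
  expect_equal(m3$config$dropout_rate, 0.5)
  # a pooling stack deeper than the input is rejected
  expect_error(build_cnn(cnn_preset(1), input_resolution = 10),
               "too small")
  expect_error(cnn_config(n_outputs = 7), "n_outputs")
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(10)
  N <- 50
  x <- array(runif(16 * 16 * 4 * N), c(16, 16, 4, N))
  y <- cbind(apply(x[, , 1, ], 3, mean), apply(x[, , 2, ], 3, mean))
  y <- minmax_normalize(cbind(y, y, y))$values
  cfg <- cnn_config(conv_filters = c(4, 8), hidden_widths = c(32),
                    n_outputs = 6, dropout_rate = 0.1, learning_rate = 1e-3,
                    n_epochs = 20, batch_size = 16, seed = 6)
  m <- train_cnn(build_cnn(cfg, 16, 4), x, y)
  expect_identical(length(m$loss_history), 20L)
  expect_lt(mean(tail(m$loss_history, 5)), mean(head(m$loss_history, 5)))
  m2 <- train_cnn(build_cnn(cfg, 16, 4), x, y)
  expect_identical(m$loss_history, m2$loss_history)
})

test_that("zero epochs and zero learning rate leave the model untouched", {
  set.seed(11)
  x <- array(runif(12 * 12 * 4 * 8), c(12, 12, 4, 8))
  y <- matrix(runif(8 * 6), 8, 6)
  cfg0 <- cnn_config(conv_filters = c(4), hidden_widths = c(16),
                     n_outputs = 6, n_epochs = 0, seed = 2)
  m0 <- build_cnn(cfg0, 12, 4)
  t0 <- train_cnn(m0, x, y)
  expect_identical(length(t0$loss_history), 0L)
  expect_identical(t0$conv[[1]]$w, m0$conv[[1]]$w)
  cfgz <- cnn_config(conv_filters = c(4), hidden_widths = c(16),
                     n_outputs = 6, n_epochs = 5, learning_rate = 0,
                     dropout_rate = 0, seed = 2)
  tz <- train_cnn(build_cnn(cfgz, 12, 4), x, y)
  expect_equal(max(tz$loss_history) - min(tz$loss_history), 0)
})

test_that("R-squared report matches the hand-computed Pearson oracle", {
  pred <- matrix(c(1, 2, 3, 4), ncol = 1)
  truth <- matrix(c(1, 2, 2, 3), ncol = 1)
  rep <- evaluate_regression(pred, truth, names = "t")
  # direct arithmetic: r = cov/sd/sd
  r <- sum((pred - mean(pred)) * (truth - mean(truth))) /
       sqrt(sum((pred - mean(pred))^2) * sum((truth - mean(truth))^2))
  expect_equal(rep$r_squared, r^2, tolerance = 1e-12)
  expect_equal(rep$r_squared, 0.9, tolerance = 1e-12)
  # perfect prediction
  rp <- evaluate_regression(truth, truth)
  expect_equal(rp$r_squared, 1)
  # uncorrelated noise has near-zero R^2
  set.seed(12)
  rn <- evaluate_regression(matrix(rnorm(1000)), matrix(rnorm(1000)))
  expect_lt(rn$r_squared, 0.02)
  expect_error(evaluate_regression(matrix(1), matrix(1)), "2 test samples")
})

test_that("evaluate_cnn learns per-sample image intensities end to end", {
  set.seed(13)
  N <- 60
  # strong per-sample signal: each channel is a sample-specific offset plus
  # pixel noise, and the targets are the offsets
  off <- matrix(runif(N * 4), N, 4)
  x <- array(0, c(16, 16, 4, N))
  for (i in seq_len(N)) for (ch in 1:4)
    x[, , ch, i] <- off[i, ch] + 0.3 * runif(256)
  targ <- cbind(o1 = off[, 1], o2 = off[, 2], o3 = off[, 3],
                o4 = off[, 4], s = rowSums(off[, 1:2]), d = off[, 1] - off[, 3])
  cfg <- cnn_config(conv_filters = c(4, 8), hidden_widths = c(32),
                    n_outputs = 6, dropout_rate = 0, learning_rate = 1e-3,
                    n_epochs = 150, batch_size = 16, seed = 7)
  ev <- evaluate_cnn(x, targ, cfg)
  # shared-trunk optimization at this tiny sample size leaves per-output
  # variance; require strong recovery of the first target and broad signal
  expect_gt(ev$report$r_squared[1], 0.7)
  expect_gt(mean(ev$report$r_squared), 0.4)
  # denormalized predictions are in native units
  expect_lt(abs(mean(attr(ev$report, "true")[, 1]) - 0.5), 0.15)
})
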