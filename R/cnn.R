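#' Min-max normalization of regression targets
#'
#' Rescales each target to [0, 1] by `x' = (x - min) / (max - min)`. The
#' (min, max) must come from the training split only and be reused for test
#' data, which is what [train_cnn()]/[evaluate_cnn()] do.
#'
#' @param values numeric matrix (samples x targets) or vector.
#' @param ranges optional precomputed normalization (list with `min`,
#'   `max`), e.g. from the training split.
#' @return list with `values` (normalized), `min`, `max` (named per
#'   target).
#' @export
minmax_normalize <- function(values, ranges = NULL) {
  v <- as.matrix(values)
  if (is.null(colnames(v)))
    colnames(v) <- paste0("t", seq_len(ncol(v)))
  if (is.null(ranges)) {
    mn <- apply(v, 2, min)
    mx <- apply(v, 2, max)
    flat <- which(mx - mn == 0)
    if (length(flat))
      stop(sprintf("constant target cannot be normalized: %s",
                   paste(colnames(v)[flat], collapse = ", ")))
  } else {
    mn <- ranges$min; mx <- ranges$max
  }
  out <- sweep(sweep(v, 2, mn, "-"), 2, mx - mn, "/")
  list(values = out, min = mn, max = mx)
}

#' @rdname minmax_normalize
#' @param normalized matrix/vector of normalized values.
#' @param norm a normalization (list with `min`, `max`).
#' @export
minmax_denormalize <- function(normalized, norm) {
  v <- as.matrix(normalized)
  sweep(sweep(v, 2, norm$max - norm$min, "*"), 2, norm$min, "+")
}

#' Random train/test split
#'
#' @param n_samples total number of samples (>= 5).
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed RNG seed; fixed seed gives an identical split.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(n_samples, train_fraction = 0.8, seed = 1L) {
  if (n_samples < 5L) stop("need at least 5 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly in (0, 1)")
  n_train <- round(train_fraction * n_samples)
  n_train <- max(1L, min(n_samples - 1L, n_train))
  perm <- with_seed(seed, sample.int(n_samples))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n_samples]))
}

#' CNN architecture/training configuration
#'
#' Mirrors the tuned architectures used for curvature-projection regression
#' (see [cnn_preset()] for the three presets): conv stages of
#' `conv(filters_i, kernel) + maxpool(pool)`, a flatten, dense hidden
#' layers with dropout, and a linear output per target.
#'
#' @param kernel_size conv kernel side (square).
#' @param pool_size max-pool side.
#' @param conv_filters ordered filter counts, one per conv stage.
#' @param hidden_widths dense hidden layer widths.
#' @param n_outputs number of regression targets (6 histomorphometric, 8
#'   geometric, or 9 stiffness constants).
#' @param learning_rate Adam learning rate.
#' @param n_epochs training epochs.
#' @param dropout_rate dropout on dense hidden layers, in [0, 1).
#' @param batch_size minibatch size.
#' @param augment apply a random dihedral (rotate/flip) transform to each
#'   training image every epoch (default FALSE). Volume-level targets are
#'   exactly invariant under in-plane rotations and flips of the projection,
#'   so this augmentation adds no label noise.
#' @param seed seed for weight init, shuffling and dropout.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(kernel_size = 3L, pool_size = 2L,
                       conv_filters = c(8L, 16L, 32L),
                       hidden_widths = c(128L, 64L), n_outputs = 6L,
                       learning_rate = 1e-4, n_epochs = 200L,
                       dropout_rate = 0.3, batch_size = 16L,
                       augment = FALSE, seed = 1L) {
  if (any(conv_filters <= 0) || any(hidden_widths <= 0))
    stop("filter counts and hidden widths must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must lie in [0, 1)")
  if (!n_outputs %in% c(6L, 8L, 9L))
    stop("n_outputs must be 6 (histomorphometric), 8 (geometric) or 9 (stiffness)")
  structure(list(kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 conv_filters = as.integer(conv_filters),
                 hidden_widths = as.integer(hidden_widths),
                 n_outputs = as.integer(n_outputs),
                 learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' The three tuned CNN presets
#'
#' Preset 1 predicts the six histomorphometric parameters (kernel 3x3,
#' filters 8-16-32, dense 128-64, dropout 0.3, 200 epochs); preset 2 the
#' eight plate/rod geometric parameters (kernel 5x5, filters 16-16-64,
#' dropout 0.4, 300 epochs); preset 3 the nine orthotropic stiffness
#' constants (kernel 3x3, filters 16-32-64, dropout 0.5, 250 epochs). All
#' use pool 2x2, learning rate 1e-4.
#'
#' @param model preset number (1, 2 or 3).
#' @param ... overrides passed to [cnn_config()].
#' @return a [cnn_config()].
#' @export
cnn_preset <- function(model = 1L, ...) {
  base <- switch(as.character(model),
    "1" = list(kernel_size = 3L, conv_filters = c(8L, 16L, 32L),
               n_outputs = 6L, n_epochs = 200L, dropout_rate = 0.3),
    "2" = list(kernel_size = 5L, conv_filters = c(16L, 16L, 64L),
               n_outputs = 8L, n_epochs = 300L, dropout_rate = 0.4),
    "3" = list(kernel_size = 3L, conv_filters = c(16L, 32L, 64L),
               n_outputs = 9L, n_epochs = 250L, dropout_rate = 0.5),
    stop("model must be 1, 2 or 3"))
  do.call(cnn_config, utils::modifyList(base, list(...)))
}

#' Build an (untrained) CNN regressor
#'
#' He-initialized weights, seeded from `config$seed`. Fails if the pooling
#' stack shrinks the input below one pixel.
#'
#' @param config a [cnn_config()].
#' @param input_resolution input image side in pixels (square).
#' @param n_channels input channels (default 4: k1, k2, Gaussian, mean).
#' @return object of class `cnn_model`.
#' @export
build_cnn <- function(config, input_resolution, n_channels = 4L) {
  stopifnot(inherits(config, "cnn_config"))
  k <- config$kernel_size; p <- config$pool_size
  H <- as.integer(input_resolution); C <- as.integer(n_channels)
  dims <- list()
  for (i in seq_along(config$conv_filters)) {
    Hc <- H - k + 1L
    if (Hc < 1L) stop("input too small for the convolution stack")
    Hp <- Hc %/% p
    if (Hp < 1L) stop("input too small for the pooling stack")
    dims[[i]] <- c(conv = Hc, pool = Hp)
    H <- Hp
  }
  flat <- H * H * tail(config$conv_filters, 1)
  model <- with_seed(config$seed, {
    conv <- list()
    Cin <- C
    for (i in seq_along(config$conv_filters)) {
      Cout <- config$conv_filters[i]
      fan_in <- k * k * Cin
      conv[[i]] <- list(w = matrix(rnorm(fan_in * Cout, sd = sqrt(2 / fan_in)),
                                   fan_in, Cout),
                        b = rep(0, Cout))
      Cin <- Cout
    }
    dense <- list()
    widths <- c(flat, config$hidden_widths, config$n_outputs)
    for (i in seq_len(length(widths) - 1L)) {
      fin <- widths[i]; fout <- widths[i + 1]
      dense[[i]] <- list(w = matrix(rnorm(fout * fin, sd = sqrt(2 / fin)),
                                    fout, fin),
                         b = rep(0, fout))
    }
    list(conv = conv, dense = dense)
  })
  structure(list(conv = model$conv, dense = model$dense, config = config,
                 input_resolution = as.integer(input_resolution),
                 n_channels = C, stage_dims = dims, flat_size = flat,
                 normalization = NULL, trained = FALSE),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(paste0("cnn_model: %dx%dx%d input, conv filters (%s) kernel %d,",
                     " dense (%s), %d outputs%s\n"),
              x$input_resolution, x$input_resolution, x$n_channels,
              paste(x$config$conv_filters, collapse = ", "),
              x$config$kernel_size,
              paste(x$config$hidden_widths, collapse = ", "),
              x$config$n_outputs,
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

# one of the 8 symmetries of the square applied to an (H, W, C, 1) slab:
# t %% 4 quarter-turns, then a flip if t >= 4
dihedral_transform <- function(a, t) {
  d <- dim(a)
  m <- array(a, d[1:3])
  rot <- t %% 4L
  for (r in seq_len(rot)) m <- aperm(m, c(2, 1, 3))[dim(m)[2]:1, , , drop = FALSE]
  if (t >= 4L) m <- m[dim(m)[1]:1, , , drop = FALSE]
  array(m, c(dim(m), 1L))
}

# forward pass; x: (H, W, C, B) array. Returns prediction (K x B) and,
# when train = TRUE, the cache needed for backprop.
cnn_forward <- function(model, x, train = FALSE, dropout_masks = NULL) {
  p <- model$config$pool_size
  cache <- if (train) list(conv = list(), pool = list()) else NULL
  a <- x
  for (i in seq_along(model$conv)) {
    z <- .conv_forward(a, dim(a), model$conv[[i]]$w, model$conv[[i]]$b)
    r <- z * (z > 0)
    pl <- .maxpool_forward(r, dim(r), p)
    if (train)
      cache$conv[[i]] <- list(x = a, relu_mask = (z > 0), zdim = dim(z),
                              argmax = pl$argmax, outdim = dim(pl$out))
    a <- pl$out
  }
  B <- dim(a)[4]
  flat <- matrix(a, nrow = model$flat_size, ncol = B)
  if (train) cache$flat_in_dim <- dim(a)
  act <- flat
  nden <- length(model$dense)
  if (train) cache$dense <- list()
  for (i in seq_len(nden)) {
    z <- model$dense[[i]]$w %*% act + model$dense[[i]]$b
    last <- (i == nden)
    zr <- if (last) z else z * (z > 0)
    if (!last && !is.null(dropout_masks)) zr <- zr * dropout_masks[[i]]
    if (train) cache$dense[[i]] <- list(a_in = act, relu_mask = if (last) NULL else (z > 0))
    act <- zr
  }
  list(pred = act, cache = cache)
}

#' Train a CNN regressor
#'
#' Minimizes the mean squared error on min-max-normalized targets with the
#' Adam optimizer at the configured learning rate, for `n_epochs` epochs of
#' seeded shuffled minibatches. Dropout applies to the dense hidden layers
#' only. Fully deterministic for a fixed `config$seed`.
#'
#' @param model a [build_cnn()] model.
#' @param x input array (H, W, C, N): curvature projection stacks.
#' @param y numeric matrix (N x n_outputs) of normalized targets in [0,1].
#' @param config optional [cnn_config()] override (defaults to the model's).
#' @param verbose print the loss every 10 epochs.
#' @return the fitted model, with `loss_history` (per-epoch training MSE)
#'   attached.
#' @export
train_cnn <- function(model, x, y, config = model$config, verbose = FALSE) {
  stopifnot(inherits(model, "cnn_model"))
  y <- as.matrix(y)
  N <- dim(x)[4]
  if (nrow(y) != N) stop("x and y disagree on the number of samples")
  K <- model$config$n_outputs
  if (ncol(y) != K) stop(sprintf("y must have %d columns", K))
  lr <- config$learning_rate
  nep <- config$n_epochs
  bs <- min(config$batch_size, N)
  drop_p <- config$dropout_rate
  # Adam state
  adam <- list()
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step_t <- 0
  get_state <- function(key, template) {
    if (is.null(adam[[key]])) adam[[key]] <<- list(m = template * 0, v = template * 0)
    adam[[key]]
  }
  upd <- function(key, par, grad) {
    st <- get_state(key, par)
    st$m <- beta1 * st$m + (1 - beta1) * grad
    st$v <- beta2 * st$v + (1 - beta2) * grad^2
    adam[[key]] <<- st
    mhat <- st$m / (1 - beta1^step_t)
    vhat <- st$v / (1 - beta2^step_t)
    par - lr * mhat / (sqrt(vhat) + eps)
  }
  history <- numeric(0)
  p <- config$pool_size
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(nep)) {
      ord <- sample.int(N)
      epoch_loss <- 0
      nb <- 0
      for (start in seq(1, N, by = bs)) {
        idx <- ord[start:min(start + bs - 1, N)]
        xb <- x[, , , idx, drop = FALSE]
        if (isTRUE(config$augment)) {
          for (bi in seq_along(idx)) {
            tf <- sample.int(8L, 1L) - 1L
            xb[, , , bi] <- dihedral_transform(xb[, , , bi, drop = FALSE], tf)
          }
        }
        yb <- t(y[idx, , drop = FALSE])  # K x B
        B <- length(idx)
        masks <- NULL
        if (drop_p > 0) {
          masks <- lapply(model$config$hidden_widths, function(wd)
            matrix((runif(wd * B) >= drop_p) / (1 - drop_p), wd, B))
        }
        fw <- cnn_forward(model, xb, train = TRUE, dropout_masks = masks)
        err <- fw$pred - yb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stop(sprintf("non-finite training loss at epoch %d", epoch))
        epoch_loss <- epoch_loss + loss
        nb <- nb + 1
        step_t <- step_t + 1
        # backprop
        delta <- 2 * err / length(err)       # K x B
        nden <- length(model$dense)
        for (i in rev(seq_len(nden))) {
          cd <- fw$cache$dense[[i]]
          if (i < nden) {
            if (!is.null(masks)) delta <- delta * masks[[i]]
            delta <- delta * cd$relu_mask
          }
          dw <- delta %*% t(cd$a_in)
          db <- rowSums(delta)
          if (i > 1) delta <- t(model$dense[[i]]$w) %*% delta
          else delta_flat <- t(model$dense[[1]]$w) %*% delta
          model$dense[[i]]$w <- upd(paste0("dw", i), model$dense[[i]]$w, dw)
          model$dense[[i]]$b <- upd(paste0("db", i), model$dense[[i]]$b, db)
        }
        dact <- array(delta_flat, fw$cache$flat_in_dim)
        for (i in rev(seq_along(model$conv))) {
          cc <- fw$cache$conv[[i]]
          dr <- .maxpool_backward(dact, cc$argmax, cc$outdim, cc$zdim)
          dz <- dr * cc$relu_mask
          gr <- .conv_backward(cc$x, dim(cc$x), model$conv[[i]]$w, dz,
                               need_dx = (i > 1))
          if (i > 1) dact <- array(gr$dx, dim(cc$x))
          model$conv[[i]]$w <- upd(paste0("cw", i), model$conv[[i]]$w, gr$dw)
          model$conv[[i]]$b <- upd(paste0("cb", i), model$conv[[i]]$b,
                                   as.numeric(gr$db))
        }
      }
      history <- c(history, epoch_loss / max(nb, 1))
      if (verbose && epoch %% 10 == 0)
        message(sprintf("epoch %d: MSE %.5g", epoch, tail(history, 1)))
    }
  })
  model$loss_history <- history
  model$trained <- TRUE
  model
}

#' Predict with a CNN regressor
#'
#' @param object a trained `cnn_model`.
#' @param x input array (H, W, C, N).
#' @param symmetrize average the prediction over the 8 dihedral transforms
#'   of each image (default FALSE). For targets invariant under in-plane
#'   rotations/flips this projects the regressor onto the symmetry-
#'   respecting function class, which cannot increase the expected squared
#'   error.
#' @param ... unused.
#' @return N x n_outputs matrix of predictions in the (normalized) target
#'   space.
#' @export
predict.cnn_model <- function(object, x, symmetrize = FALSE, ...) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!symmetrize)
    return(t(cnn_forward(object, x, train = FALSE)$pred))
  acc <- NULL
  for (tf in 0:7) {
    xt <- x
    for (i in seq_len(dim(x)[4]))
      xt[, , , i] <- dihedral_transform(x[, , , i, drop = FALSE], tf)
    p <- t(cnn_forward(object, xt, train = FALSE)$pred)
    acc <- if (is.null(acc)) p else acc + p
  }
  acc / 8
}

#' Per-target regression report (R-squared and p-values)
#'
#' Computes the squared Pearson correlation between predictions and ground
#' truth per target, with the two-sided correlation-test p-value. Values
#' are denormalized to native units when a normalization is supplied.
#'
#' @param pred N x K matrix of predictions (normalized space).
#' @param truth N x K matrix of true values (normalized space).
#' @param names target names (default from `truth` columns).
#' @param normalization optional list with `min`, `max` to map back to
#'   native units.
#' @return object of class `regression_report`: data.frame with `target`,
#'   `r_squared`, `p_value`, plus matrices `predicted` and `true` in native
#'   units as attributes.
#' @export
evaluate_regression <- function(pred, truth, names = colnames(truth),
                                normalization = NULL) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (nrow(pred) < 2L)
    stop("correlation undefined for fewer than 2 test samples")
  if (is.null(names)) names <- paste0("t", seq_len(ncol(truth)))
  if (!is.null(normalization)) {
    pred <- minmax_denormalize(pred, normalization)
    truth <- minmax_denormalize(truth, normalization)
  }
  r2 <- p <- numeric(ncol(truth))
  for (j in seq_len(ncol(truth))) {
    if (sd(pred[, j]) == 0 || sd(truth[, j]) == 0) {
      r2[j] <- NA_real_; p[j] <- NA_real_
    } else if (nrow(pred) < 3L) {
      # two points determine r = +/-1; the test statistic needs n >= 3
      r2[j] <- cor(pred[, j], truth[, j])^2
      p[j] <- NA_real_
    } else {
      ct <- cor.test(pred[, j], truth[, j])
      r2[j] <- unname(ct$estimate)^2
      p[j] <- ct$p.value
    }
  }
  out <- data.frame(target = names, r_squared = r2, p_value = p)
  attr(out, "predicted") <- pred
  attr(out, "true") <- truth
  class(out) <- c("regression_report", "data.frame")
  out
}

#' Train and evaluate on a split, guarding normalization leakage
#'
#' Normalization statistics are computed on the training split only and
#' reused for the test split.
#'
#' @param images (H, W, C, N) input array.
#' @param targets N x K matrix of native-unit targets.
#' @param config a [cnn_config()].
#' @param split a [split_dataset()] result (default: 80/20 at the config
#'   seed).
#' @return list with `model`, `report` (test-set [evaluate_regression()]),
#'   `split`, `normalization`.
#' @export
evaluate_cnn <- function(images, targets, config, split = NULL) {
  targets <- as.matrix(targets)
  N <- dim(images)[4]
  if (is.null(split)) split <- split_dataset(N, 0.8, config$seed)
  norm <- minmax_normalize(targets[split$train, , drop = FALSE])
  ytr <- norm$values
  yte <- minmax_normalize(targets[split$test, , drop = FALSE], ranges = norm)$values
  # channel-wise input normalization over the training split (test images
  # reuse the training ranges). Projected curvature has unbounded heavy
  # tails (near-pinch-off necks reach |k| of thousands per mm), so each
  # channel is first winsorized at its training 0.5%/99.5% quantiles and
  # then min-max rescaled, the same convention as the targets.
  nch <- dim(images)[3]
  ch_min <- ch_max <- numeric(nch)
  for (ch in seq_len(nch)) {
    tr <- images[, , ch, split$train, drop = FALSE]
    q <- quantile(tr, c(0.005, 0.995), names = FALSE)
    ch_min[ch] <- q[1]; ch_max[ch] <- q[2]
    rng <- ch_max[ch] - ch_min[ch]
    if (rng == 0) rng <- 1
    images[, , ch, ] <- (pmin(pmax(images[, , ch, ], ch_min[ch]),
                              ch_max[ch]) - ch_min[ch]) / rng
  }
  model <- build_cnn(config, dim(images)[1], nch)
  model$normalization <- list(min = norm$min, max = norm$max)
  model$input_normalization <- list(min = ch_min, max = ch_max)
  model <- train_cnn(model, images[, , , split$train, drop = FALSE], ytr)
  pred <- predict(model, images[, , , split$test, drop = FALSE],
                  symmetrize = isTRUE(config$augment))
  report <- evaluate_regression(pred, yte, colnames(targets),
                                normalization = model$normalization)
  list(model = model, report = report, split = split,
       normalization = model$normalization,
       input_normalization = model$input_normalization)
}
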