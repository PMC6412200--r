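#' CNN hyperparameter specification
#'
#' The three investigated input layouts share a common body — three
#' convolutional blocks (convolution, batch normalization, ReLU), a dense
#' ReLU layer with dropout, and a 5-way softmax — and differ in how the 9
#' sensor channels enter the first layer:
#'
#' * `CNN1`: 1-D convolution along time, kernel 5x1, all 9 channels in the
#'   depth dimension (input 68 x 1 x 9);
#' * `CNN2`: 2-D convolution, kernel 5x3, sensors stacked in the height
#'   dimension and the x/y/z axes in depth (input 68 x 3 x 3);
#' * `CNN3`: a 2-D "signal image" of height 12 (accelerometer, gyroscope,
#'   magnetometer, accelerometer again, each as x/y/z rows), kernel 5x6
#'   with stride 1x3 in the first layer so axis bundles stay together
#'   (input 68 x 12 x 1).
#'
#' Defaults per layout are the tuned values: e.g. `CNN1` uses filters
#' 65/100/45, dense size 583, dropout 0.6, learning rate 0.0330, L2
#' regularization 0.0030, batch 100, SGD, 100 epochs.
#'
#' @param layout `"CNN1"`, `"CNN2"`, or `"CNN3"`.
#' @param epochs optionally override the default epoch count.
#' @return list of class `"CnnSpec"`.
#' @export
cnn_spec <- function(layout = c("CNN1", "CNN2", "CNN3"), epochs = NULL) {
  layout <- match.arg(layout)
  defaults <- list(
    CNN1 = list(kernel = c(5L, 1L), stride1 = c(1L, 1L),
                filters = c(65L, 100L, 45L), dense_size = 583L,
                dropout_p = 0.6, learning_rate = 0.0330, l2_reg = 0.0030,
                batch = 100L, epochs = 100L),
    CNN2 = list(kernel = c(5L, 3L), stride1 = c(1L, 1L),
                filters = c(100L, 57L, 10L), dense_size = 1000L,
                dropout_p = 0.39, learning_rate = 0.0480, l2_reg = 0.0001,
                batch = 100L, epochs = 100L),
    CNN3 = list(kernel = c(5L, 6L), stride1 = c(1L, 3L),
                filters = c(59L, 94L, 58L), dense_size = 773L,
                dropout_p = 0.6, learning_rate = 0.1000, l2_reg = 0.0001,
                batch = 59L, epochs = 100L)
  )
  spec <- defaults[[layout]]
  spec$layout <- layout
  spec$optimizer <- "SGD"
  spec$n_classes <- 5L
  if (!is.null(epochs)) spec$epochs <- as.integer(epochs)
  class(spec) <- "CnnSpec"
  spec
}

#' Input tensor shape per layout
#' @param layout `"CNN1"`, `"CNN2"`, or `"CNN3"`.
#' @return integer vector `(width, height, depth)`.
#' @export
layout_shape <- function(layout) {
  switch(layout,
         CNN1 = c(68L, 1L, 9L),
         CNN2 = c(68L, 3L, 3L),
         CNN3 = c(68L, 12L, 1L),
         stop("unknown layout: ", layout))
}

#' Arrange a 9-channel window into a layout's input tensor
#'
#' Pure rearrangement (with row duplication for `CNN3`): no values are
#' altered. `CNN3` stacks the rows accelerometer x/y/z, gyroscope x/y/z,
#' magnetometer x/y/z, then the accelerometer x/y/z again, so every sensor
#' pair is adjacent somewhere in the image.
#'
#' @param window numeric `68 x 9` matrix with columns in
#'   [CANONICAL_CHANNELS] order.
#' @param layout `"CNN1"`, `"CNN2"`, or `"CNN3"`.
#' @return numeric array `width x height x depth`.
#' @export
layout_input <- function(window, layout) {
  window <- as.matrix(window)
  if (ncol(window) != 9) {
    stop("layout error: 9 channels required, got ", ncol(window))
  }
  w <- nrow(window)
  switch(layout,
    CNN1 = array(window, dim = c(w, 1L, 9L)),
    CNN2 = {
      # height = sensor (acc, gyr, mag), depth = axis (x, y, z)
      out <- array(0, dim = c(w, 3L, 3L))
      for (s in 1:3) for (a in 1:3) out[, s, a] <- window[, (s - 1L) * 3L + a]
      out
    },
    CNN3 = {
      rows <- c(1:9, 1:3)
      array(window[, rows], dim = c(w, 12L, 1L))
    },
    stop("unknown layout: ", layout)
  )
}

# stack a list of 68 x 9 windows into an [N, W, H, C] batch tensor
.layout_batch <- function(windows, layout) {
  n <- length(windows)
  sh <- layout_shape(layout)
  x <- array(0, dim = c(n, sh))
  for (i in seq_len(n)) x[i, , , ] <- layout_input(windows[[i]], layout)
  x
}

#' Build a network descriptor from a specification
#'
#' Resolves every layer's kernel, stride, output shape, and parameter count
#' using valid (no-padding) convolution arithmetic. The nominal kernel is
#' shared by the three convolutional layers; when its height exceeds the
#' remaining feature-map height it is clamped to that height (width stays
#' 5), and any height stride reverts to 1 after the first layer. An error
#' is raised if the temporal width underflows.
#'
#' @param spec a [cnn_spec()].
#' @return list of class `"CnnDescriptor"`: `spec`, `input_shape`, and
#'   `layers` (conv blocks, dense, output, each with shapes and `n_params`).
#' @export
build_network <- function(spec) {
  sh <- layout_shape(spec$layout)
  W <- sh[1]; H <- sh[2]; C <- sh[3]
  layers <- list()
  for (l in 1:3) {
    kw <- spec$kernel[1]
    kh <- min(spec$kernel[2], H)
    st <- if (l == 1) spec$stride1 else c(1L, 1L)
    if (W < kw) {
      stop("architecture error: temporal width ", W,
           " underflows kernel width ", kw, " at conv layer ", l)
    }
    Wo <- (W - kw) %/% st[1] + 1L
    Ho <- (H - kh) %/% st[2] + 1L
    Cout <- spec$filters[l]
    layers[[length(layers) + 1L]] <- list(
      type = "conv", kernel = c(kw, kh), stride = st, in_shape = c(W, H, C),
      out_shape = c(Wo, Ho, Cout),
      n_params = kw * kh * C * Cout + Cout)
    layers[[length(layers) + 1L]] <- list(
      type = "batchnorm", out_shape = c(Wo, Ho, Cout), n_params = 2L * Cout)
    layers[[length(layers) + 1L]] <- list(
      type = "relu", out_shape = c(Wo, Ho, Cout), n_params = 0L)
    W <- Wo; H <- Ho; C <- Cout
  }
  flat <- W * H * C
  layers[[length(layers) + 1L]] <- list(
    type = "dense", in_shape = flat, out_shape = spec$dense_size,
    n_params = flat * spec$dense_size + spec$dense_size)
  layers[[length(layers) + 1L]] <- list(
    type = "output", in_shape = spec$dense_size, out_shape = spec$n_classes,
    n_params = spec$dense_size * spec$n_classes + spec$n_classes)
  structure(list(spec = spec, input_shape = sh, layers = layers),
            class = "CnnDescriptor")
}

#' @export
print.CnnDescriptor <- function(x, ...) {
  cat(sprintf("%s: input %s\n", x$spec$layout,
              paste(x$input_shape, collapse = "x")))
  for (l in x$layers) {
    cat(sprintf("  %-10s out %-12s params %d\n", l$type,
                paste(l$out_shape, collapse = "x"), l$n_params))
  }
  cat("  total params:", sum(vapply(x$layers, `[[`, numeric(1), "n_params")),
      "\n")
  invisible(x)
}

# ---- native network engine ------------------------------------------------

.he_init <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))

# initialize parameters for a descriptor (seeded by the caller)
.init_params <- function(desc) {
  params <- list()
  for (l in desc$layers) {
    if (l$type == "conv") {
      kw <- l$kernel[1]; kh <- l$kernel[2]; Cin <- l$in_shape[3]
      Cout <- l$out_shape[3]
      fan_in <- kw * kh * Cin
      params[[length(params) + 1L]] <- list(
        type = "conv",
        W = matrix(.he_init(fan_in, fan_in * Cout), fan_in, Cout),
        b = numeric(Cout), kernel = l$kernel, stride = l$stride,
        in_shape = l$in_shape, out_shape = l$out_shape)
    } else if (l$type == "batchnorm") {
      C <- l$out_shape[3]
      params[[length(params) + 1L]] <- list(
        type = "batchnorm", gamma = rep(1, C), beta = numeric(C),
        run_mean = numeric(C), run_var = rep(1, C), momentum = 0.9)
    } else if (l$type == "relu") {
      params[[length(params) + 1L]] <- list(type = "relu")
    } else if (l$type == "dense") {
      params[[length(params) + 1L]] <- list(
        type = "dense",
        W = matrix(.he_init(l$in_shape, l$in_shape * l$out_shape),
                   l$in_shape, l$out_shape),
        b = numeric(l$out_shape))
    } else if (l$type == "output") {
      params[[length(params) + 1L]] <- list(
        type = "output",
        W = matrix(.he_init(l$in_shape, l$in_shape * l$out_shape),
                   l$in_shape, l$out_shape),
        b = numeric(l$out_shape))
    }
  }
  params
}

# im2col: [N, W, H, C] -> [(N*Wo*Ho), (kw*kh*C)]
.im2col <- function(x, kw, kh, sw, sh) {
  d <- dim(x); N <- d[1]; C <- d[4]
  Wo <- (d[2] - kw) %/% sw + 1L
  Ho <- (d[3] - kh) %/% sh + 1L
  cols <- matrix(0, N * Wo * Ho, kw * kh * C)
  col <- 0L
  for (c_ in seq_len(C)) {
    for (j in seq_len(kh)) {
      for (i in seq_len(kw)) {
        col <- col + 1L
        iw <- (seq_len(Wo) - 1L) * sw + i
        ih <- (seq_len(Ho) - 1L) * sh + j
        cols[, col] <- as.vector(x[, iw, ih, c_, drop = FALSE])
      }
    }
  }
  list(cols = cols, Wo = Wo, Ho = Ho)
}

.col2im <- function(dcols, in_dim, kw, kh, sw, sh, Wo, Ho) {
  N <- in_dim[1]; C <- in_dim[4]
  dx <- array(0, dim = in_dim)
  col <- 0L
  for (c_ in seq_len(C)) {
    for (j in seq_len(kh)) {
      for (i in seq_len(kw)) {
        col <- col + 1L
        iw <- (seq_len(Wo) - 1L) * sw + i
        ih <- (seq_len(Ho) - 1L) * sh + j
        dx[, iw, ih, c_] <- as.vector(dx[, iw, ih, c_]) + dcols[, col]
      }
    }
  }
  dx
}

.forward <- function(params, x, training = FALSE, dropout_p = 0,
                     rng_dropout = NULL) {
  caches <- vector("list", length(params))
  for (k in seq_along(params)) {
    p <- params[[k]]
    if (p$type == "conv") {
      ic <- .im2col(x, p$kernel[1], p$kernel[2], p$stride[1], p$stride[2])
      out_mat <- ic$cols %*% p$W
      out_mat <- sweep(out_mat, 2, p$b, "+")
      N <- dim(x)[1]
      caches[[k]] <- list(cols = ic$cols, in_dim = dim(x), Wo = ic$Wo,
                          Ho = ic$Ho)
      x <- array(out_mat, dim = c(N, ic$Wo, ic$Ho, p$out_shape[3]))
    } else if (p$type == "batchnorm") {
      d <- dim(x); C <- d[4]
      xm <- matrix(x, ncol = C)   # (N*W*H) x C
      if (training) {
        mu <- colMeans(xm)
        v <- colMeans(sweep(xm, 2, mu)^2)
        params[[k]]$run_mean <- p$momentum * p$run_mean + (1 - p$momentum) * mu
        params[[k]]$run_var <- p$momentum * p$run_var + (1 - p$momentum) * v
      } else {
        mu <- p$run_mean; v <- p$run_var
      }
      inv_sd <- 1 / sqrt(v + 1e-5)
      xhat <- sweep(sweep(xm, 2, mu), 2, inv_sd, "*")
      out <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
      caches[[k]] <- list(xhat = xhat, inv_sd = inv_sd, dims = d)
      x <- array(out, dim = d)
    } else if (p$type == "relu") {
      caches[[k]] <- list(mask = x > 0)
      x <- x * (x > 0)
    } else if (p$type == "dense") {
      N <- dim(x)[1]
      xm <- matrix(x, nrow = N)
      a <- sweep(xm %*% p$W, 2, p$b, "+")
      relu_mask <- a > 0
      a <- a * relu_mask
      drop_mask <- NULL
      if (training && dropout_p > 0) {
        drop_mask <- matrix(stats::runif(length(a)) >= dropout_p,
                            nrow(a), ncol(a)) / (1 - dropout_p)
        a <- a * drop_mask
      }
      caches[[k]] <- list(x = xm, relu_mask = relu_mask,
                          drop_mask = drop_mask)
      x <- a
    } else if (p$type == "output") {
      caches[[k]] <- list(x = x)
      logits <- sweep(x %*% p$W, 2, p$b, "+")
      shifted <- logits - apply(logits, 1, max)
      e <- exp(shifted)
      x <- e / rowSums(e)
    }
  }
  list(probs = x, caches = caches, params = params)
}

.sgd_update <- function(params, grads, lr) {
  for (k in seq_along(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    for (nm in names(g)) {
      params[[k]][[nm]] <- params[[k]][[nm]] - lr * g[[nm]]
    }
  }
  params
}

#' Train a convolutional network on labeled windows
#'
#' Plain stochastic gradient descent with a fixed learning rate, mini-batch
#' shuffling seeded per run, L2 weight penalty, batch-normalized
#' convolutions and inverted dropout on the dense layer — all implemented
#' natively on BLAS matrix operations, so training is deterministic for a
#' fixed seed.
#'
#' @param windows list of `68 x 9` matrices (see [segment_windows()]), or an
#'   `N x 68 x 9` array.
#' @param labels character vector of window labels.
#' @param spec a [cnn_spec()].
#' @param epochs number of epochs (defaults to `spec$epochs`).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return list of class `"CnnModel"`: `params`, `desc`, `classes`,
#'   `history` (data.frame epoch/loss/accuracy).
#' @export
train_cnn <- function(windows, labels, spec, epochs = NULL, seed = 1,
                      verbose = FALSE) {
  if (is.array(windows) && length(dim(windows)) == 3) {
    windows <- lapply(seq_len(dim(windows)[1]), function(i) windows[i, , ])
  }
  if (is.null(epochs)) epochs <- spec$epochs
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("training needs at least 2 classes")
  y_idx <- match(as.character(labels), classes)
  x_all <- .layout_batch(windows, spec$layout)
  desc <- build_network(spec)
  set.seed(seed)
  params <- .init_params(desc)
  # output layer must match the number of observed classes
  if (length(classes) != spec$n_classes) {
    l <- length(params)
    fan_in <- nrow(params[[l]]$W)
    params[[l]]$W <- matrix(.he_init(fan_in, fan_in * length(classes)),
                            fan_in, length(classes))
    params[[l]]$b <- numeric(length(classes))
  }
  n <- length(windows)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  flat_dims <- NULL
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    ep_loss <- 0; ep_correct <- 0L; n_batches <- 0L
    for (b_start in seq(1, n, by = spec$batch)) {
      idx <- ord[b_start:min(b_start + spec$batch - 1L, n)]
      xb <- x_all[idx, , , , drop = FALSE]
      yb <- y_idx[idx]
      fw <- .forward(params, xb, training = TRUE,
                     dropout_p = spec$dropout_p)
      params <- fw$params  # running BN stats updated
      probs <- fw$probs
      eps <- 1e-12
      ep_loss <- ep_loss -
        mean(log(probs[cbind(seq_along(yb), yb)] + eps))
      ep_correct <- ep_correct + sum(max.col(probs) == yb)
      n_batches <- n_batches + 1L
      grads <- .backward2(params, fw$caches, probs, yb, spec$l2_reg)
      params <- .sgd_update(params, grads, spec$learning_rate)
    }
    history <- rbind(history, data.frame(
      epoch = ep, loss = ep_loss / n_batches, accuracy = ep_correct / n))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                      ep_loss / n_batches, ep_correct / n))
    }
  }
  structure(list(params = params, desc = desc, classes = classes,
                 history = history, seed = seed),
            class = "CnnModel")
}

# backward pass with the flatten reshape handled between dense and conv
.backward2 <- function(params, caches, probs, y_idx, l2_reg) {
  # find the shape of the last conv block output for the flatten reshape
  last_relu <- max(which(vapply(params, function(p) p$type == "relu",
                                logical(1))))
  grads <- vector("list", length(params))
  N <- nrow(probs)
  delta <- probs
  delta[cbind(seq_len(N), y_idx)] <- delta[cbind(seq_len(N), y_idx)] - 1
  delta <- delta / N
  for (k in rev(seq_along(params))) {
    p <- params[[k]]; cache <- caches[[k]]
    if (p$type == "output") {
      grads[[k]] <- list(W = crossprod(cache$x, delta) + 2 * l2_reg * p$W,
                         b = colSums(delta))
      delta <- delta %*% t(p$W)
    } else if (p$type == "dense") {
      if (!is.null(cache$drop_mask)) delta <- delta * cache$drop_mask
      delta <- delta * cache$relu_mask
      grads[[k]] <- list(W = crossprod(cache$x, delta) + 2 * l2_reg * p$W,
                         b = colSums(delta))
      delta <- delta %*% t(p$W)
      delta <- array(delta, dim = dim(caches[[last_relu]]$mask))
    } else if (p$type == "relu") {
      delta <- delta * cache$mask
    } else if (p$type == "batchnorm") {
      d <- cache$dims; C <- d[4]
      dm <- matrix(delta, ncol = C)
      m <- nrow(dm)
      dgamma <- colSums(dm * cache$xhat)
      dbeta <- colSums(dm)
      t1 <- sweep(dm, 2, dbeta / m)
      t2 <- sweep(cache$xhat, 2, dgamma / m, "*")
      dx <- sweep(t1 - t2, 2, p$gamma * cache$inv_sd, "*")
      grads[[k]] <- list(gamma = dgamma, beta = dbeta)
      delta <- array(dx, dim = d)
    } else if (p$type == "conv") {
      Cout <- p$out_shape[3]
      dmat <- matrix(delta, ncol = Cout)
      grads[[k]] <- list(W = crossprod(cache$cols, dmat) + 2 * l2_reg * p$W,
                         b = colSums(dmat))
      dcols <- dmat %*% t(p$W)
      delta <- .col2im(dcols, cache$in_dim, p$kernel[1], p$kernel[2],
                       p$stride[1], p$stride[2], cache$Wo, cache$Ho)
    }
  }
  grads
}

#' Class probabilities / evaluation of a trained network
#'
#' `predict_cnn` runs the network in inference mode (batch-norm running
#' statistics, no dropout); `evaluate_cnn` additionally compares against
#' ground-truth labels and reports overall accuracy plus the row-normalized
#' confusion matrix in percent (each actual-class row sums to 100).
#'
#' @param model a [train_cnn()] result.
#' @param windows list of `68 x 9` matrices or `N x 68 x 9` array.
#' @param batch evaluation batch size.
#' @return `predict_cnn`: matrix `N x n_classes` of softmax probabilities
#'   (columns named by class). `evaluate_cnn`: list with `accuracy`
#'   (fraction), `confusion` (percent), `predicted`.
#' @export
predict_cnn <- function(model, windows, batch = 256) {
  if (is.array(windows) && length(dim(windows)) == 3) {
    windows <- lapply(seq_len(dim(windows)[1]), function(i) windows[i, , ])
  }
  x_all <- .layout_batch(windows, model$desc$spec$layout)
  n <- dim(x_all)[1]
  out <- NULL
  for (b_start in seq(1, n, by = batch)) {
    idx <- b_start:min(b_start + batch - 1L, n)
    fw <- .forward(model$params, x_all[idx, , , , drop = FALSE],
                   training = FALSE)
    out <- rbind(out, fw$probs)
  }
  colnames(out) <- model$classes
  out
}

#' @rdname predict_cnn
#' @param labels ground-truth labels for `evaluate_cnn`.
#' @export
evaluate_cnn <- function(model, windows, labels) {
  probs <- predict_cnn(model, windows)
  pred <- model$classes[max.col(probs)]
  truth <- as.character(labels)
  lev <- ACTIVITY_LEVELS[ACTIVITY_LEVELS %in% union(truth, model$classes)]
  conf <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  conf_pct <- 100 * prop.table(conf + 0, margin = 1)
  conf_pct[is.nan(conf_pct)] <- 0
  list(accuracy = mean(pred == truth), confusion = conf_pct, predicted = pred)
}
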