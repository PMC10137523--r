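#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth band-pass, the
#' standard conditioning step for high-frequency electrophysiology bands
#' such as 60-600 Hz at a 2000 Hz sampling rate.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order of the underlying low/high sections.
#' @return Filtered signal of the same length.
#' @export
bandpass_filter <- function(x, fs, low = 60, high = 600, order = 4L) {
  if (!(low > 0 && high > low && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(x)))
}

#' CNN architecture configuration
#'
#' Describes the compact 1D CNN used throughout the package: three
#' convolution + ReLU + pooling blocks, a flattening step, a named penultimate
#' dense layer, dropout (training only), and a final linear layer whose two
#' outputs are the pre-softmax class scores (logits). The defaults map a
#' 2000-sample input to a last-convolution feature map of length 236 across
#' 16 filters, coarse enough to summarise the signal but long enough to
#' correlate against it.
#'
#' @param conv_blocks list of integer triples `c(filters, kernel_len, pool)`;
#'   exactly three blocks by default.
#' @param dense_units width of the penultimate dense layer.
#' @param dropout_rate dropout probability on the penultimate layer during
#'   training; in `[0, 1)`.
#' @param n_classes number of output classes (2).
#' @param pool_type `"max"` or `"avg"` pooling in every block.
#' @param penult_activation activation of the penultimate dense layer;
#'   `"leaky_relu"` (default, negative slope 0.01 — keeps the narrow dense
#'   bottleneck trainable), `"relu"`, or `"linear"` (handy for analytically
#'   tractable toy models).
#' @param input_len expected signal length in samples.
#' @param seed integer seed for weight initialisation.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(conv_blocks = list(c(8L, 11L, 4L),
                                            c(16L, 9L, 2L),
                                            c(16L, 9L, 2L)),
                         dense_units = 32L, dropout_rate = 0.2,
                         n_classes = 2L, pool_type = c("max", "avg"),
                         penult_activation = c("leaky_relu", "relu", "linear"),
                         input_len = 2000L, seed = 1L) {
  pool_type <- match.arg(pool_type)
  penult_activation <- match.arg(penult_activation)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  conv_blocks <- lapply(conv_blocks, as.integer)
  if (any(vapply(conv_blocks, length, 1L) != 3L))
    stop("each conv block is c(filters, kernel_len, pool)", call. = FALSE)
  structure(list(conv_blocks = conv_blocks,
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 pool_type = pool_type,
                 penult_activation = penult_activation,
                 input_len = as.integer(input_len),
                 seed = as.integer(seed)),
            class = "model_config")
}

# lengths of every intermediate stage for a given input length
conv_stack_shape <- function(config) {
  L <- config$input_len
  shapes <- list()
  for (b in seq_along(config$conv_blocks)) {
    blk <- config$conv_blocks[[b]]
    Lc <- L - blk[2] + 1L
    if (Lc < 1L) stop("input too short for conv stack", call. = FALSE)
    Lp <- Lc %/% blk[3]
    if (Lp < 1L) stop("pool factor too large", call. = FALSE)
    shapes[[b]] <- c(conv_len = Lc, pool_len = Lp, filters = blk[1])
    L <- Lp
  }
  shapes
}

#' Length and filter count of the last convolutional feature maps
#'
#' @param config a [model_config()].
#' @return Named vector with `length` (feature-map positions) and `filters`.
#' @export
feature_map_shape <- function(config) {
  shapes <- conv_stack_shape(config)
  last <- shapes[[length(shapes)]]
  c(length = unname(last["conv_len"]), filters = unname(last["filters"]))
}

he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

init_params <- function(config) {
  shapes <- conv_stack_shape(config)
  params <- list(conv = list())
  Cin <- 1L
  for (b in seq_along(config$conv_blocks)) {
    blk <- config$conv_blocks[[b]]
    W <- array(he_init(blk[2] * Cin, blk[2] * Cin * blk[1]),
               dim = c(blk[2], Cin, blk[1]))
    # small positive bias keeps ReLU units alive at the start
    params$conv[[b]] <- list(W = W, b = rep(0.05, blk[1]))
    Cin <- blk[1]
  }
  flat <- shapes[[length(shapes)]]["pool_len"] *
    shapes[[length(shapes)]]["filters"]
  params$W1 <- matrix(he_init(flat, flat * config$dense_units),
                      nrow = flat, ncol = config$dense_units)
  params$b1 <- rep(0.1, config$dense_units)
  # zero-initialised output layer: training starts at the uniform
  # predictor (loss log 2) instead of random confident logits, which keeps
  # the first optimisation steps well-scaled
  params$W2 <- matrix(0, nrow = config$dense_units, ncol = config$n_classes)
  params$b2 <- rep(0, config$n_classes)
  params
}

# per-sample standardisation applied before the network
standardize_rows <- function(X) {
  mu <- rowMeans(X)
  s <- sqrt(rowMeans((X - mu)^2))
  s[s == 0] <- 1
  (X - mu) / s
}

# forward pass over a batch; X is an (L x 1 x B) cube. Returns logits plus
# every intermediate needed for backprop / Grad-CAM.
cnn_forward <- function(params, config, X, dropmask = NULL) {
  pool_code <- if (config$pool_type == "max") 0L else 1L
  cache <- list(conv = list())
  A <- X
  for (b in seq_along(config$conv_blocks)) {
    blk <- config$conv_blocks[[b]]
    Z <- .conv1d_forward_cpp(A, params$conv[[b]]$W, params$conv[[b]]$b)
    R <- Z * (Z > 0)
    P <- .pool1d_forward_cpp(R, blk[3], pool_code)
    cache$conv[[b]] <- list(input = A, Z = Z, R = R, argmax = P$argmax)
    A <- P$Y
  }
  B <- dim(A)[3]
  flat <- matrix(A, nrow = dim(A)[1] * dim(A)[2], ncol = B)
  z1 <- crossprod(params$W1, flat) + params$b1
  a1 <- penult_act(z1, config$penult_activation)
  if (!is.null(dropmask)) a1 <- a1 * dropmask
  logits <- crossprod(params$W2, a1) + params$b2
  cache$pool_out <- A; cache$flat <- flat; cache$z1 <- z1; cache$a1 <- a1
  cache$logits <- logits
  cache
}

penult_act <- function(z, kind) {
  switch(kind,
         relu = z * (z > 0),
         leaky_relu = z * (z > 0) + 0.01 * z * (z <= 0),
         linear = z)
}

penult_act_grad <- function(z, kind) {
  switch(kind,
         relu = (z > 0) * 1,
         leaky_relu = (z > 0) + 0.01 * (z <= 0),
         linear = array(1, dim = dim(z)))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# backward pass from dlogits; returns gradients for every parameter
cnn_backward <- function(params, config, cache, dlogits, dropmask = NULL) {
  grads <- list(conv = vector("list", length(config$conv_blocks)))
  grads$W2 <- cache$a1 %*% t(dlogits)
  grads$b2 <- rowSums(dlogits)
  da1 <- params$W2 %*% dlogits
  if (!is.null(dropmask)) da1 <- da1 * dropmask
  dz1 <- da1 * penult_act_grad(cache$z1, config$penult_activation)
  grads$W1 <- cache$flat %*% t(dz1)
  grads$b1 <- rowSums(dz1)
  dflat <- params$W1 %*% dz1
  dims <- dim(cache$pool_out)
  dP <- array(dflat, dim = dims)
  pool_code <- if (config$pool_type == "max") 0L else 1L
  for (b in rev(seq_along(config$conv_blocks))) {
    blk <- config$conv_blocks[[b]]
    cc <- cache$conv[[b]]
    dR <- .pool1d_backward_cpp(dP, cc$argmax, dim(cc$R)[1], blk[3], pool_code)
    dZ <- dR * (cc$Z > 0)
    bk <- .conv1d_backward_cpp(cc$input, params$conv[[b]]$W, dZ)
    grads$conv[[b]] <- list(W = bk$dW, b = bk$db)
    dP <- bk$dX
  }
  grads
}

adam_state <- function(params) rapply(params, function(p) p * 0, how = "replace")

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else upd(p, g, m, v)
  }
  walk(params, grads, state$m, state$v)
}

as_input_cube <- function(X) {
  # X: matrix (n x L) of raw signals -> standardized (L x 1 x n) cube
  Xs <- standardize_rows(X)
  array(t(Xs), dim = c(ncol(X), 1L, nrow(X)))
}

#' Fit the 1D CNN signal classifier
#'
#' Trains the compact convolutional network described by [model_config()]
#' with mini-batch Adam on softmax cross-entropy. Each signal is standardised
#' (zero mean, unit variance) before entering the network. Training is
#' deterministic given `seed`. With `epochs = 0` the randomly initialised
#' network is returned untrained.
#'
#' @param x a `"signal_dataset"` from [synth_generate()], or a numeric matrix
#'   with one signal per row.
#' @param y 0/1 class labels (ignored when `x` is a dataset).
#' @param config a [model_config()]; `input_len` is taken from the data.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param seed integer; controls initialisation, shuffling and dropout.
#' @param verbose print per-epoch loss.
#' @return An object of class `"signal_cnn"` exposing the trained parameters,
#'   the config, and named access points for the last-convolution feature
#'   maps and pre-softmax outputs (see [model_activations()]).
#' @examples
#' \donttest{
#' ds <- synth_generate(synth_config(n_per_class = 30, seed = 7))
#' fit <- signal_cnn(ds, epochs = 3, seed = 7)
#' mean(predict(fit, ds) == ds$y)
#' }
#' @export
signal_cnn <- function(x, y = NULL, config = model_config(), epochs = 6L,
                       batch_size = 32L, lr = 5e-3, seed = config$seed,
                       verbose = FALSE) {
  if (inherits(x, "signal_dataset")) { y <- x$y; x <- x$x }
  if (!is.matrix(x)) stop("`x` must be a matrix or signal_dataset",
                          call. = FALSE)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("label/sample count mismatch", call. = FALSE)
  if (epochs > 0L && length(unique(y)) < 2L)
    stop("training needs at least two classes", call. = FALSE)
  config$input_len <- ncol(x)
  n <- nrow(x)
  with_seed(seed, {
    params <- init_params(config)
    if (epochs > 0L) {
      st <- list(m = adam_state(params), v = adam_state(params))
      t_step <- 0L
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        ep_loss <- 0
        for (start in seq(1L, n, by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1L, n)]
          Xb <- as_input_cube(x[idx, , drop = FALSE])
          dropmask <- if (config$dropout_rate > 0)
            matrix(stats::rbinom(config$dense_units * length(idx), 1L,
                                 1 - config$dropout_rate) /
                     (1 - config$dropout_rate),
                   nrow = config$dense_units)
          else NULL
          cache <- cnn_forward(params, config, Xb, dropmask)
          p <- softmax_cols(cache$logits)
          onehot <- matrix(0, nrow = config$n_classes, ncol = length(idx))
          onehot[cbind(y[idx] + 1L, seq_along(idx))] <- 1
          ep_loss <- ep_loss - sum(log(pmax(p[onehot == 1], 1e-12)))
          dlogits <- (p - onehot) / length(idx)
          grads <- cnn_backward(params, config, cache, dlogits, dropmask)
          t_step <- t_step + 1L
          r <- adam_update(params, grads, st, lr, t_step)
          params <- r$p; st$m <- r$m; st$v <- r$v
        }
        if (verbose)
          message(sprintf("epoch %d: loss %.4f", ep, ep_loss / n))
      }
    }
    structure(list(params = params, config = config, classes = c(0L, 1L),
                   epochs = epochs, seed = seed),
              class = "signal_cnn")
  })
}

#' @export
print.signal_cnn <- function(x, ...) {
  fm <- feature_map_shape(x$config)
  cat("1D CNN signal classifier\n")
  for (b in seq_along(x$config$conv_blocks)) {
    blk <- x$config$conv_blocks[[b]]
    cat(sprintf("  conv%d: %d filters, kernel %d, %s-pool %d\n",
                b, blk[1], blk[2], x$config$pool_type, blk[3]))
  }
  cat(sprintf("  dense(%d, %s) -> dropout(%.2f) -> dense(%d, linear)\n",
              x$config$dense_units, x$config$penult_activation,
              x$config$dropout_rate, x$config$n_classes))
  cat(sprintf("  last-conv feature maps: %d x %d; trained %d epoch(s)\n",
              fm["length"], fm["filters"], x$epochs))
  invisible(x)
}

#' Predict from a fitted CNN
#'
#' @param object a `"signal_cnn"`.
#' @param newdata `"signal_dataset"` or signal matrix (rows = signals).
#' @param type `"class"` (default, 0/1 labels), `"prob"` (softmax
#'   probabilities), or `"logit"` (pre-softmax outputs).
#' @param ... unused.
#' @return Vector of labels, or an n-by-2 matrix for `"prob"`/`"logit"`.
#' @export
predict.signal_cnn <- function(object, newdata,
                               type = c("class", "prob", "logit"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "signal_dataset")) newdata <- newdata$x
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  logits <- matrix(0, nrow = nrow(newdata), ncol = object$config$n_classes)
  chunk <- 64L
  for (start in seq(1L, nrow(newdata), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(newdata))
    Xb <- as_input_cube(newdata[idx, , drop = FALSE])
    cache <- cnn_forward(object$params, object$config, Xb)
    logits[idx, ] <- t(cache$logits)
  }
  switch(type,
         class = max.col(logits, ties.method = "first") - 1L,
         prob = t(softmax_cols(t(logits))),
         logit = logits)
}

#' Named access points: feature maps and pre-softmax outputs
#'
#' Runs one signal through the network and returns the activations of the
#' last convolutional layer (post-ReLU, before its pooling step) together
#' with the pre-softmax outputs — the two quantities Grad-CAM and the
#' certainty index are built from.
#'
#' @param model a `"signal_cnn"`.
#' @param x a single signal (numeric vector) or one-row matrix.
#' @return List with `A` (feature-map matrix, positions x filters), `logits`
#'   (length-2 pre-softmax vector) and the full forward `cache` (internal).
#' @export
model_activations <- function(model, x) {
  if (!is.null(dim(x))) x <- as.numeric(x[1, ])
  Xb <- as_input_cube(matrix(x, nrow = 1))
  cache <- cnn_forward(model$params, model$config, Xb)
  nb <- length(model$config$conv_blocks)
  A <- cache$conv[[nb]]$R[, , 1, drop = FALSE]
  list(A = matrix(A, nrow = dim(A)[1]), logits = as.numeric(cache$logits),
       cache = cache)
}

#' k-fold cross-validated accuracy
#'
#' Shuffles the data once with `seed`, splits it into `k` near-equal
#' contiguous folds, trains on `k - 1` folds and tests on the held-out fold,
#' rotating the test fold; reports the mean accuracy with its standard error
#' over folds.
#'
#' @param x `"signal_dataset"` or signal matrix.
#' @param y labels (ignored for datasets).
#' @param config a [model_config()].
#' @param k number of folds (>= 2).
#' @param seed integer; controls the single shuffle and per-fold training.
#' @param shuffle shuffle before splitting (default). `FALSE` keeps the
#'   input order, giving deterministic fold contents.
#' @param ... passed on to [signal_cnn()] (e.g. `epochs`, `lr`).
#' @return List of class `"cv_result"`: `mean_accuracy`, `se`,
#'   `fold_accuracy`, `k`.
#' @export
kfold_cv <- function(x, y = NULL, config = model_config(), k = 10L,
                     seed = 1L, shuffle = TRUE, ...) {
  if (inherits(x, "signal_dataset")) { y <- x$y; x <- x$x }
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (k > n) stop("`k` exceeds the number of samples", call. = FALSE)
  ord <- if (shuffle) with_seed(seed, sample.int(n)) else seq_len(n)
  # contiguous near-equal blocks over the (shuffled) order
  rank_in_ord <- match(seq_len(n), ord)
  fold_sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  fold_of <- rep(seq_len(k), times = fold_sizes)[rank_in_ord]
  acc <- numeric(k)
  train_seed <- child_seed(seed, 17L)
  for (f in seq_len(k)) {
    test <- which(fold_of == f)
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[train])) < 2L)
      stop(sprintf("fold %d leaves a single-class training set", f),
           call. = FALSE)
    fit <- signal_cnn(x[train, , drop = FALSE], y[train], config,
                      seed = train_seed, ...)
    acc[f] <- mean(predict(fit, x[test, , drop = FALSE]) == y[test])
  }
  structure(list(mean_accuracy = mean(acc),
                 se = stats::sd(acc) / sqrt(k),
                 fold_accuracy = acc, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV accuracy: %.1f%% +/- %.1f%% (SE)\n",
              x$k, 100 * x$mean_accuracy, 100 * x$se))
  invisible(x)
}
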