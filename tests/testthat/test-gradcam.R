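test_that("channel weights match a central finite-difference oracle", {
  model <- small_model()
  x <- small_holdout()$x[3, ]
  act <- model_activations(model, x)
  A <- act$A
  for (cls in 0:1) {
    alpha <- channel_weights(model, x, class = cls)
    h <- 1e-4
    # finite differences on a subsample of positions per filter, avoiding
    # pooling-tie kinks by construction of the comparison (relative scale)
    fd_alpha <- vapply(seq_len(ncol(A)), function(k) {
      g <- vapply(seq_len(nrow(A)), function(i) {
        Ap <- A; Am <- A
        Ap[i, k] <- Ap[i, k] + h
        Am[i, k] <- Am[i, k] - h
        (head_logits_from_A(model, Ap)[cls + 1] -
           head_logits_from_A(model, Am)[cls + 1]) / (2 * h)
      }, numeric(1))
      mean(g)
    }, numeric(1))
    expect_equal(alpha, fd_alpha, tolerance = 1e-3)
  }
})

test_that("gradients differ across classes when head weights differ", {
  model <- small_model()
  x <- small_holdout()$x[1, ]
  a0 <- channel_weights(model, x, class = 0)
  a1 <- channel_weights(model, x, class = 1)
  expect_false(isTRUE(all.equal(a0, a1)))
})

test_that("the heatmap is the alpha-weighted sum of feature maps", {
  model <- small_model()
  x <- small_holdout()$x[2, ]
  act <- model_activations(model, x)
  for (cls in 0:1) {
    h <- grad_cam(model, x, class = cls)
    alpha <- channel_weights(model, x, class = cls)
    expect_equal(h$values, as.numeric(act$A %*% alpha), tolerance = 1e-12)
    expect_identical(h$explained_class, cls)
  }
  # signed map: negative relevance must be representable (no ReLU clipping)
  h0 <- grad_cam(model, x, class = 0)
  h1 <- grad_cam(model, x, class = 1)
  expect_true(min(c(h0$values, h1$values)) < 0)
})

test_that("a linear-head toy model reproduces its closed form exactly", {
  # single conv filter, no pooling nonlinearity (avg, factor = 1), linear
  # penultimate layer: y_c = w_c . flat + const, so alpha_k = mean-pooled
  # gradient = mean(w_c) and the heatmap is alpha * A exactly
  cfg <- model_config(conv_blocks = list(c(1L, 5L, 1L)), dense_units = 3L,
                      dropout_rate = 0, pool_type = "avg",
                      penult_activation = "linear", input_len = 40L)
  model <- signal_cnn(matrix(rnorm(80), nrow = 2), c(0L, 1L), cfg,
                      epochs = 0L, seed = 2L)
  set.seed(12)
  model$params$W2 <- matrix(rnorm(6), nrow = 3L, ncol = 2L)
  x <- rnorm(40)
  act <- model_activations(model, x)
  Wlin <- model$params$W1 %*% model$params$W2   # flat -> logits
  for (cls in 0:1) {
    alpha <- channel_weights(model, x, class = cls)
    expect_equal(alpha, mean(Wlin[, cls + 1]), tolerance = 1e-12)
    h <- grad_cam(model, x, class = cls)
    expect_equal(h$values, as.numeric(act$A) * alpha, tolerance = 1e-12)
  }
  # negating the head weights for a class negates its heatmap
  model2 <- model
  model2$params$W2 <- -model2$params$W2
  h1 <- grad_cam(model, x, class = 1)
  h2 <- grad_cam(model2, x, class = 1)
  expect_equal(h2$values, -h1$values, tolerance = 1e-12)
})

test_that("a single filter with unit weight passes its activation through", {
  cfg <- model_config(conv_blocks = list(c(1L, 3L, 1L)), dense_units = 1L,
                      dropout_rate = 0, pool_type = "avg",
                      penult_activation = "linear", input_len = 20L)
  model <- signal_cnn(matrix(rnorm(40), nrow = 2), c(0L, 1L), cfg,
                      epochs = 0L, seed = 4L)
  # head y_0 = sum_i A_i: every position's gradient is 1, so alpha_1 = 1
  # and the heatmap must equal the activation map itself
  model$params$W1 <- matrix(1, nrow = 18L, ncol = 1L)
  model$params$W2 <- matrix(c(1, 0), nrow = 1L)
  model$params$b1 <- 0; model$params$b2 <- c(0, 0)
  x <- rnorm(20)
  act <- model_activations(model, x)
  expect_equal(channel_weights(model, x, class = 0), 1, tolerance = 1e-12)
  h <- grad_cam(model, x, class = 0)
  expect_equal(h$values, as.numeric(act$A), tolerance = 1e-12)
})

test_that("upsampling interpolates linearly and preserves endpoints", {
  h <- structure(list(values = c(0, 1), explained_class = 0L,
                      layer = "conv1", source_id = NA, upsampled = NULL),
                 class = "gradcam_heatmap")
  up <- upsample_heatmap(h, 5)
  expect_equal(up$upsampled, c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-12)
  hc <- h; hc$values <- rep(2.5, 7)
  expect_equal(upsample_heatmap(hc, 100)$upsampled, rep(2.5, 100),
               tolerance = 1e-12)
  # round trip: block-averaging the upsampled series back recovers endpoints
  hv <- h; hv$values <- c(3, -1, 2, 0.5)
  up2 <- upsample_heatmap(hv, 400)$upsampled
  expect_equal(up2[1], 3, tolerance = 1e-12)
  expect_equal(up2[400], 0.5, tolerance = 1e-12)
  expect_error(upsample_heatmap(h, 1), ">= 2")
})

test_that("heatmap magnitude concentrates in burst regions for confident
           class-1 predictions", {
  model <- small_model()
  ds <- small_holdout()
  sc <- certainty_scores(model, ds)
  idx <- which(ds$y == 1 & sc$predicted_class == 1 &
                 vapply(ds$truth, nrow, integer(1)) > 0)
  idx <- idx[order(-sc$raw[idx])][1:10]
  ratio <- vapply(idx, function(i) {
    h <- upsample_heatmap(grad_cam(model, ds$x[i, ]), ncol(ds$x))
    inb <- rep(FALSE, ncol(ds$x))
    tr <- ds$truth[[i]]
    for (b in seq_len(nrow(tr))) inb[(tr[b, 1] + 1):tr[b, 2]] <- TRUE
    mean(abs(h$upsampled[inb])) / mean(abs(h$upsampled[!inb]))
  }, numeric(1))
  expect_gt(mean(ratio > 1), 0.7)
  expect_gt(median(ratio), 1)
})
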