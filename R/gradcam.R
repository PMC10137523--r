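# Signed 1D Grad-CAM from the last convolutional layer.
#
# The gradient of the class score (pre-softmax) with respect to the
# last-conv activations is obtained by running the dense head backwards
# analytically: d y_c / d a1 = W2[, c] (through the penultimate activation),
# d y_c / d flat = W1 %*% dz1, then un-pooling back to the feature-map
# positions. No ReLU is applied to the map: negative relevance is kept.

# gradient of logit c w.r.t. the post-ReLU last-conv activations A
grad_wrt_last_conv <- function(model, cache, class_idx) {
  config <- model$config
  nb <- length(config$conv_blocks)
  dlogits <- matrix(0, nrow = config$n_classes, ncol = 1)
  dlogits[class_idx, 1] <- 1
  da1 <- model$params$W2 %*% dlogits
  dz1 <- da1 * penult_act_grad(cache$z1, config$penult_activation)
  dflat <- model$params$W1 %*% dz1
  dP <- array(dflat, dim = dim(cache$pool_out))
  blk <- config$conv_blocks[[nb]]
  pool_code <- if (config$pool_type == "max") 0L else 1L
  dA <- .pool1d_backward_cpp(dP, cache$conv[[nb]]$argmax,
                             dim(cache$conv[[nb]]$R)[1], blk[3], pool_code)
  matrix(dA[, , 1], nrow = dim(dA)[1])   # positions x filters
}

#' Grad-CAM channel weights
#'
#' The importance weight of each last-conv filter for class `c`: the global
#' average pool of the gradient of the pre-softmax class score with respect
#' to that filter's feature map,
#' \deqn{\alpha_k^c = \frac{1}{N} \sum_i \partial y^c / \partial A_i^k.}
#'
#' @param model a fitted [signal_cnn()].
#' @param x a single signal (numeric vector).
#' @param class class to explain, 0-based (default: the predicted class).
#' @return Numeric vector of length `filters`.
#' @export
channel_weights <- function(model, x, class = NULL) {
  act <- model_activations(model, x)
  class_idx <- resolve_class(model, act, class)
  dA <- grad_wrt_last_conv(model, act$cache, class_idx)
  colMeans(dA)
}

resolve_class <- function(model, act, class) {
  if (is.null(class)) return(which.max(act$logits))
  class <- as.integer(class)
  if (is.na(class) || class < 0L || class >= model$config$n_classes)
    stop("`class` out of range", call. = FALSE)
  class + 1L
}

#' Signed 1D Grad-CAM heatmap
#'
#' Weights the last convolutional layer's feature maps by their channel
#' weights and sums over filters: `g_i^c = sum_k alpha_k^c A_i^k`. The map is
#' signed — no ReLU rectification — so regions arguing against the class
#' carry negative relevance, which matters when correlating the map against
#' information measures of the signal.
#'
#' @inheritParams channel_weights
#' @param source_id identifier recorded on the heatmap.
#' @return An object of class `"gradcam_heatmap"`: list with `values`
#'   (feature-map resolution), `explained_class` (0-based), `layer`,
#'   `source_id`, `upsampled` (`NULL` until [upsample_heatmap()]).
#' @export
grad_cam <- function(model, x, class = NULL, source_id = NA_character_) {
  act <- model_activations(model, x)
  class_idx <- resolve_class(model, act, class)
  dA <- grad_wrt_last_conv(model, act$cache, class_idx)
  alpha <- colMeans(dA)
  values <- as.numeric(act$A %*% alpha)
  structure(list(values = values, explained_class = class_idx - 1L,
                 layer = sprintf("conv%d", length(model$config$conv_blocks)),
                 source_id = source_id, upsampled = NULL),
            class = "gradcam_heatmap")
}

#' Linearly upsample a heatmap to signal length
#'
#' Interpolates the feature-map-resolution relevance values onto
#' `target_len` equally spaced positions spanning the signal extent, filling
#' the `upsampled` field. Kept as an explicit step so correlations can be
#' run either at native feature-map resolution or at signal length.
#'
#' @param h a `"gradcam_heatmap"`.
#' @param target_len desired length (>= 2).
#' @return The heatmap with `upsampled` set.
#' @export
upsample_heatmap <- function(h, target_len) {
  stopifnot(inherits(h, "gradcam_heatmap"))
  target_len <- as.integer(target_len)
  if (is.na(target_len) || target_len < 2L)
    stop("`target_len` must be >= 2", call. = FALSE)
  nv <- length(h$values)
  if (nv < 2L) stop("heatmap too short to interpolate", call. = FALSE)
  pos <- seq(1, target_len, length.out = nv)
  h$upsampled <- stats::approx(pos, h$values, xout = seq_len(target_len))$y
  h
}

#' @export
print.gradcam_heatmap <- function(x, ...) {
  cat(sprintf(
    "Grad-CAM heatmap (%s, class %d): %d positions, range [%.3g, %.3g]%s\n",
    x$layer, x$explained_class, length(x$values), min(x$values),
    max(x$values),
    if (is.null(x$upsampled)) "" else
      sprintf(", upsampled to %d", length(x$upsampled))))
  invisible(x)
}

#' @export
plot.gradcam_heatmap <- function(x, ...) {
  v <- if (is.null(x$upsampled)) x$values else x$upsampled
  graphics::plot(v, type = "l", xlab = "position", ylab = "relevance", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
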