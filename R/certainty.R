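#' Certainty index of one prediction
#'
#' For a vector of pre-softmax outputs (logits) `y` and a chosen node `i`,
#' the certainty index is the chosen output minus the mean of all the
#' others:
#' \deqn{C_i = y_i - \frac{1}{N-1} \sum_{j \ne i} y_j}
#' With two classes this reduces to the logit margin `y_i - y_j`. The index
#' is translation-invariant (adding a constant to every output leaves it
#' unchanged) and, for `i` the argmax, non-negative in the two-class case.
#'
#' @param outputs numeric vector of pre-softmax outputs; length at least 2.
#' @param i node index (1-based).
#' @return A single number in the units of the outputs.
#' @examples
#' certainty_index(c(5, 2), 1)       # 3
#' certainty_index(c(4, 1, -2), 1)   # 4 - (1 - 2)/2 = 4.5
#' @export
certainty_index <- function(outputs, i) {
  outputs <- as.numeric(outputs)
  n <- length(outputs)
  if (n < 2L) stop("need at least two output nodes", call. = FALSE)
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > n) stop("`i` out of range", call. = FALSE)
  outputs[i] - mean(outputs[-i])
}

#' Certainty scores for a set of signals
#'
#' Runs each signal through the model, takes the predicted class (argmax of
#' the pre-softmax outputs, ties broken toward class 0) and computes the raw
#' certainty index at the penultimate-layer outputs. The `normalized` column
#' is `NA` until [normalize_certainties()] is applied.
#'
#' @param model a fitted [signal_cnn()].
#' @param x `"signal_dataset"` or signal matrix (rows = signals).
#' @return A data frame of class `"certainty_scores"` with columns
#'   `sample_id`, `predicted_class`, `raw`, `normalized`.
#' @export
certainty_scores <- function(model, x) {
  ids <- if (inherits(x, "signal_dataset")) x$sample_id else
    sprintf("s%04d", seq_len(if (is.null(dim(x))) 1L else nrow(x)))
  logits <- predict(model, x, type = "logit")
  pred <- max.col(logits, ties.method = "first") - 1L
  raw <- vapply(seq_len(nrow(logits)),
                function(i) certainty_index(logits[i, ], pred[i] + 1L),
                numeric(1))
  structure(data.frame(sample_id = ids, predicted_class = pred, raw = raw,
                       normalized = NA_real_, stringsAsFactors = FALSE),
            class = c("certainty_scores", "data.frame"))
}

#' Normalize certainty scores by per-group standard deviation
#'
#' Divides each raw certainty by the sample standard deviation of its group
#' (a separate SD for either class), making scores comparable across models
#' and layers. Groups are the predicted classes by default; pass `labels` to
#' group by true class instead.
#'
#' @param scores a `"certainty_scores"` data frame.
#' @param labels optional true labels to group by instead of
#'   `predicted_class`.
#' @return The input with the `normalized` column filled.
#' @export
normalize_certainties <- function(scores, labels = NULL) {
  grp <- if (is.null(labels)) scores$predicted_class else as.integer(labels)
  if (!is.null(labels) && length(labels) != nrow(scores))
    stop("`labels` length mismatch", call. = FALSE)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L)
      stop(sprintf("group %s has fewer than 2 scores", g), call. = FALSE)
    s <- stats::sd(scores$raw[idx])
    if (!is.finite(s) || s == 0)
      stop(sprintf("group %s has zero standard deviation", g), call. = FALSE)
    scores$normalized[idx] <- scores$raw[idx] / s
  }
  scores
}

#' @export
print.certainty_scores <- function(x, ...) {
  cat(sprintf("Certainty scores for %d predictions\n", nrow(x)))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
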