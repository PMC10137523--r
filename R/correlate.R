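#' Lagged cross-correlation with zero extension
#'
#' Computes the full set of lagged inner products
#' `z(lag) = sum_t a[t] * b[t + lag]` with `b` extended by zeros outside its
#' range, for every lag from `-(length(a) - 1)` to `length(b) - 1`.
#'
#' Lag sign convention: a positive lag means the first series leads — its
#' features occur `lag` samples earlier than the matching features of the
#' second. If `b` is `a` delayed by `d` samples, the peak sits at `lag = +d`.
#'
#' In `"raw"` mode the inner products are returned as-is (the literal
#' zero-padded lagged sum). In `"normalized"` mode both series are first
#' standardized (zero mean, unit population variance) and `z` is divided by
#' the length of the shorter series, so perfectly aligned identical shapes
#' score exactly 1 and values are comparable across samples.
#'
#' @param a,b non-empty numeric vectors.
#' @param mode `"normalized"` (default) or `"raw"`.
#' @return List with `z` (length `length(a) + length(b) - 1`) and `lags`.
#' @export
cross_correlation <- function(a, b, mode = c("normalized", "raw")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both sequences must be non-empty", call. = FALSE)
  if (mode == "normalized") {
    sa <- pop_sd(a); sb <- pop_sd(b)
    if (sa == 0 || sb == 0)
      stop("constant sequence in normalized mode (zero variance)",
           call. = FALSE)
    a <- (a - mean(a)) / sa
    b <- (b - mean(b)) / sb
  }
  z <- as.numeric(.xcorr_cpp(a, b))
  if (mode == "normalized") z <- z / min(length(a), length(b))
  list(z = z, lags = seq.int(-(length(a) - 1L), length(b) - 1L), mode = mode)
}

#' Maximal cross-correlation
#'
#' The signed maximum of the lagged cross-correlation (the largest `z`, not
#' the largest `|z|`), with ties broken toward the smallest `|lag|` (and
#' toward the negative lag if both signs tie).
#'
#' @inheritParams cross_correlation
#' @param series_a_id,series_b_id identifiers recorded on the result.
#' @return An object of class `"corr_max"`: `max_value`, `lag_at_max`,
#'   `mode`, `series_a_id`, `series_b_id`.
#' @export
max_correlation <- function(a, b, mode = c("normalized", "raw"),
                            series_a_id = NA_character_,
                            series_b_id = NA_character_) {
  cc <- cross_correlation(a, b, mode)
  best <- order(-cc$z, abs(cc$lags), cc$lags)[1]
  structure(list(max_value = cc$z[best], lag_at_max = cc$lags[best],
                 mode = cc$mode, series_a_id = series_a_id,
                 series_b_id = series_b_id),
            class = "corr_max")
}

#' @export
print.corr_max <- function(x, ...) {
  cat(sprintf("max cross-correlation: %.4f at lag %d (%s mode)\n",
              x$max_value, x$lag_at_max, x$mode))
  invisible(x)
}

#' Maximal correlation between a heatmap and its signal
#'
#' Upsamples the heatmap to the signal's length and extracts the maximal
#' lagged correlation, the per-sample similarity score plotted against the
#' certainty index.
#'
#' @param h a `"gradcam_heatmap"`.
#' @param s the signal: numeric vector.
#' @inheritParams cross_correlation
#' @return A `"corr_max"`.
#' @export
heatmap_vs_signal <- function(h, s, mode = c("normalized", "raw")) {
  stopifnot(inherits(h, "gradcam_heatmap"))
  s <- as.numeric(s)
  h <- upsample_heatmap(h, length(s))
  max_correlation(h$upsampled, s, mode,
                  series_a_id = paste0("heatmap:", h$source_id),
                  series_b_id = "signal")
}

#' Maximal correlation between a heatmap and a sample-entropy series
#'
#' As [heatmap_vs_signal()], with the signal replaced by its sliding-window
#' sample-entropy series (same length as the signal).
#'
#' @param h a `"gradcam_heatmap"`.
#' @param e an [entropy_series()].
#' @inheritParams cross_correlation
#' @return A `"corr_max"`.
#' @export
heatmap_vs_entropy <- function(h, e, mode = c("normalized", "raw")) {
  stopifnot(inherits(h, "gradcam_heatmap"), inherits(e, "entropy_series"))
  h <- upsample_heatmap(h, length(e$values))
  max_correlation(h$upsampled, e$values, mode,
                  series_a_id = paste0("heatmap:", h$source_id),
                  series_b_id = paste0("entropy:", e$source_id))
}
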