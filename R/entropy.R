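#' Sample-entropy parameters
#'
#' Bundle of the three parameters controlling sample-entropy estimation: the
#' embedding dimension `m` (template length, in samples), the tolerance
#' multiplier `r_mult` (the match tolerance is `r_mult` standard deviations of
#' a reference signal), and the window length `window_len` (`N`, samples per
#' entropy window).
#'
#' @param m embedding dimension; positive integer, `m < window_len - 1` so at
#'   least two templates of length `m + 1` exist.
#' @param r_mult tolerance multiplier, in units of signal standard deviations;
#'   positive.
#' @param window_len samples per entropy window (`N`); integer, at least 4.
#' @return An object of class `"entropy_params"`.
#' @examples
#' entropy_params()            # the defaults: m = 8, r = 2 SD, N = 100
#' entropy_params(4, 2.5, 200)
#' @export
entropy_params <- function(m = 8L, r_mult = 2, window_len = 100L) {
  m <- as.integer(m); window_len <- as.integer(window_len)
  stopifnot_scalar_num(r_mult, "r_mult")
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer", call. = FALSE)
  if (is.na(window_len) || window_len < 4L)
    stop("`window_len` must be an integer >= 4", call. = FALSE)
  if (r_mult <= 0) stop("`r_mult` must be positive", call. = FALSE)
  if (m >= window_len - 1L)
    stop("`m` must satisfy m < window_len - 1", call. = FALSE)
  structure(list(m = m, r_mult = r_mult, window_len = window_len),
            class = "entropy_params")
}

#' @export
print.entropy_params <- function(x, ...) {
  cat(sprintf("Sample-entropy parameters: m = %d, r = %g x SD, N = %d\n",
              x$m, x$r_mult, x$window_len))
  invisible(x)
}

#' Sample entropy of a single window
#'
#' Computes `SampEn(m, r, N) = -log(A / B)`, where `B` counts ordered pairs of
#' distinct length-`m` templates whose Chebyshev distance is below the
#' tolerance `r`, and `A` the analogous count for length `m + 1`, both over
#' the same `N - m` template start positions (self-matches excluded, strict
#' inequality). The tolerance is `r = r_mult * sd_ref`.
#'
#' Degenerate counts: if no `(m+1)`-length pair matches but some `m`-length
#' pair does (`A = 0 < B`), the maximum attainable value
#' `-log(1 / ((N-m)(N-m-1)))` is returned; if no `m`-length pair matches
#' (`B = 0`) the value is `NA`.
#'
#' @param window numeric vector of length `params$window_len`.
#' @param params an [entropy_params()] object.
#' @param sd_ref standard deviation of the reference signal used to scale the
#'   tolerance. Defaults to `sd(window)` (per-window referencing); pass the SD
#'   of the full signal to share one tolerance across windows.
#' @return A single non-negative number (natural-log units), or `NA` when no
#'   template pair matches at length `m`.
#' @examples
#' p <- entropy_params(m = 2, r_mult = 0.2, window_len = 64)
#' sample_entropy(sin(seq(0, 8 * pi, length.out = 64)), p)
#' @export
sample_entropy <- function(window, params = entropy_params(),
                           sd_ref = stats::sd(window)) {
  window <- as.numeric(window)
  if (length(window) != params$window_len)
    stop(sprintf("`window` must have length window_len = %d, got %d",
                 params$window_len, length(window)), call. = FALSE)
  if (!is.finite(sd_ref) || sd_ref < 0)
    stop("`sd_ref` must be a non-negative number", call. = FALSE)
  if (sd_ref == 0) {
    # constant reference: if the window itself is constant every template
    # pair matches at both lengths (distance 0 < r requires r > 0), so
    # entropy is 0 by the A == B identity; guard r at a tiny positive value
    r <- .Machine$double.eps
  } else {
    r <- params$r_mult * sd_ref
  }
  .sampen_value_cpp(window, params$m, r)
}

#' Template match counts behind a sample-entropy value
#'
#' Exposes the ordered-pair counts `B` (length-`m` matches) and `A`
#' (length-`m+1` matches) used by [sample_entropy()]; useful for checking
#' monotone behaviour in the tolerance.
#'
#' @inheritParams sample_entropy
#' @param r absolute tolerance (same units as the signal).
#' @return Named numeric vector `c(B = , A = )`.
#' @export
sampen_counts <- function(window, m, r) {
  .sampen_counts_cpp(as.numeric(window), as.integer(m), r)
}

#' Sliding-window sample-entropy series
#'
#' Computes one sample-entropy value per signal index: the value at index `t`
#' comes from the window of `window_len` samples centred on `t`, clamped to
#' the signal bounds near the edges, so the output series has exactly the
#' length of the input signal. Windows where no length-`m` template pair
#' matches are filled from the nearest finite neighbour so the series is
#' fully finite (required downstream by the correlation stage).
#'
#' @param signal numeric vector, at least `window_len` long.
#' @param params an [entropy_params()] object.
#' @param r_reference `"global_sd"` (default): one tolerance
#'   `r_mult * sd(signal)` shared by every window, as when a whole one-second
#'   epoch is characterised by a single SD; `"per_window_sd"`: the tolerance
#'   is rescaled to each window's own SD.
#' @param source_id identifier recorded on the result.
#' @return An object of class `"entropy_series"`: a list with `values`
#'   (numeric, same length as `signal`), `params`, `r_reference`, `source_id`
#'   and `n_filled` (count of windows filled from a neighbour).
#' @examples
#' x <- sin(seq(0, 40 * pi, length.out = 600)) + rnorm(600, sd = 0.1)
#' es <- entropy_series(x, entropy_params(m = 2, r_mult = 0.2, window_len = 50))
#' length(es$values)  # 600
#' @export
entropy_series <- function(signal, params = entropy_params(),
                           r_reference = c("global_sd", "per_window_sd"),
                           source_id = NA_character_) {
  r_reference <- match.arg(r_reference)
  signal <- as.numeric(signal)
  if (length(signal) < params$window_len)
    stop("signal shorter than window_len", call. = FALSE)
  if (r_reference == "global_sd") {
    s <- stats::sd(signal)
    r <- if (s > 0) params$r_mult * s else .Machine$double.eps
    values <- .sampen_series_cpp(signal, params$m, params$window_len, r, FALSE)
  } else {
    values <- .sampen_series_cpp(signal, params$m, params$window_len,
                                 params$r_mult, TRUE)
  }
  n_bad <- sum(!is.finite(values))
  if (n_bad > 0L) values <- fill_nearest(values)
  structure(list(values = values, params = params, r_reference = r_reference,
                 source_id = source_id, n_filled = n_bad),
            class = "entropy_series")
}

#' @export
print.entropy_series <- function(x, ...) {
  cat(sprintf(
    "Sample-entropy series: %d points (m = %d, r = %g x SD [%s], N = %d)\n",
    length(x$values), x$params$m, x$params$r_mult, x$r_reference,
    x$params$window_len))
  cat(sprintf("  range [%.3f, %.3f], %d window(s) filled from neighbours\n",
              min(x$values), max(x$values), x$n_filled))
  invisible(x)
}

#' @export
plot.entropy_series <- function(x, ...) {
  graphics::plot(x$values, type = "l", xlab = "sample index",
                 ylab = "sample entropy (nats)", ...)
  invisible(x)
}

#' Histogram plug-in Shannon entropy
#'
#' Plug-in estimate `H = -sum p log p` (natural log) from an equal-width
#' histogram over the data range. Included for comparison with sample
#' entropy; a constant sequence has entropy 0.
#'
#' @param values non-empty numeric vector.
#' @param bins positive integer number of histogram bins.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(values, bins = 16L) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1L) stop("`bins` must be positive", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(cut(values, breaks, include.lowest = TRUE, labels = FALSE),
                     nbins = bins)
  p <- counts[counts > 0] / length(values)
  -sum(p * log(p))
}
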