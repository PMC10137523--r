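#' Simple regression of maximal correlation on certainty
#'
#' Ordinary least squares of `y` (per-sample maximal correlation values) on
#' `x` (certainty indices), reporting the quantities tabulated throughout
#' the analysis: R-squared, the slope F-statistic with (1, n - 2) degrees of
#' freedom, slope, intercept and n. Fitting is delegated to [stats::lm()].
#'
#' @param x predictor values (certainty indices); must not be constant.
#' @param y response values (maximal correlations).
#' @param group_label free-text label for the stratum or grid cell.
#' @return An object of class `"simple_fit"` with fields `r_squared`,
#'   `f_statistic`, `n`, `slope`, `intercept`, `group_label`.
#' @examples
#' f <- fit_simple_regression(1:10, 2 * (1:10) + 1)
#' f$r_squared  # 1
#' @export
fit_simple_regression <- function(x, y, group_label = "") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("`x` is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- if (is.null(sm$fstatistic)) {
    # perfect fit: summary.lm drops the F when the residual SS is 0
    Inf
  } else unname(sm$fstatistic[1])
  structure(list(r_squared = sm$r.squared, f_statistic = fstat,
                 n = length(x),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 group_label = group_label),
            class = "simple_fit")
}

#' @export
print.simple_fit <- function(x, ...) {
  lbl <- if (nzchar(x$group_label)) sprintf(" [%s]", x$group_label) else ""
  cat(sprintf(
    "OLS%s: R^2 = %.3f, F(1, %d) = %.1f, slope = %.4g, intercept = %.4g\n",
    lbl, x$r_squared, x$n - 2L, x$f_statistic, x$slope, x$intercept))
  invisible(x)
}

#' @export
coef.simple_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

# regression rows for whole data + per-class strata
stratified_fits <- function(x, y, strata, prefix = "") {
  out <- list(fit_simple_regression(x, y, paste0(prefix, "whole")))
  for (g in sort(unique(strata))) {
    idx <- strata == g
    out[[length(out) + 1L]] <-
      fit_simple_regression(x[idx], y[idx],
                            paste0(prefix, "class", g))
  }
  out
}

fits_to_frame <- function(fits, extra = NULL) {
  df <- do.call(rbind, lapply(fits, function(f)
    data.frame(group = f$group_label, r_squared = f$r_squared,
               f_statistic = f$f_statistic, n = f$n, slope = f$slope,
               intercept = f$intercept, stringsAsFactors = FALSE)))
  if (!is.null(extra)) df <- cbind(extra, df, row.names = NULL)
  df
}
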