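#' Specification of a full certainty-vs-information experiment
#'
#' Bundles everything needed to run the complete analysis: generate (or
#' accept) a two-class dataset, train the CNN, score each held-out signal's
#' certainty, compute its signed Grad-CAM heatmap, correlate the heatmap
#' with the raw signal and with sample-entropy series across a parameter
#' grid, and regress the maximal correlations on certainty.
#'
#' The entropy grid is swept one parameter at a time around the base point
#' (m = 8, r = 2 SD, N = 100): the `m_grid` with r and N at base, the
#' `r_grid` with m and N at base, and the `n_grid` with m and r at base.
#'
#' @param synth a [synth_config()] describing the data.
#' @param model a [model_config()].
#' @param m_grid embedding dimensions to sweep.
#' @param r_grid tolerance multipliers to sweep.
#' @param n_grid entropy window lengths to sweep.
#' @param base named vector `c(m =, r_mult =, window_len =)`; must lie in the
#'   grids.
#' @param mode correlation mode, `"normalized"` or `"raw"`.
#' @param test_fraction held-out fraction used for scoring (the rest trains).
#' @param epochs,batch_size,lr training hyperparameters.
#' @param stratify_by `"label"` (default, true-class strata in the regression
#'   tables) or `"predicted"`.
#' @param seed master seed; the data seed lives in `synth`.
#' @return An object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(synth = synth_config(),
                            model = model_config(),
                            m_grid = c(4L, 8L, 16L, 32L),
                            r_grid = c(1.5, 2, 2.5),
                            n_grid = c(50L, 100L, 200L, 400L),
                            base = c(m = 8, r_mult = 2, window_len = 100),
                            mode = c("normalized", "raw"),
                            test_fraction = 0.1,
                            epochs = 6L, batch_size = 32L, lr = 5e-3,
                            stratify_by = c("label", "predicted"),
                            seed = 1L) {
  mode <- match.arg(mode)
  stratify_by <- match.arg(stratify_by)
  if (length(m_grid) < 1L || length(r_grid) < 1L || length(n_grid) < 1L)
    stop("entropy grids must be non-empty", call. = FALSE)
  if (!(base["m"] %in% m_grid && base["r_mult"] %in% r_grid &&
        base["window_len"] %in% n_grid))
    stop("base point must be contained in the grids", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(synth = synth, model = model, m_grid = m_grid,
                 r_grid = r_grid, n_grid = n_grid, base = base, mode = mode,
                 test_fraction = test_fraction, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 stratify_by = stratify_by, seed = as.integer(seed)),
            class = "experiment_spec")
}

# one-at-a-time sweep cells around the base point, base first, no duplicates
sweep_cells <- function(spec) {
  b <- spec$base
  cells <- data.frame(m = b[["m"]], r_mult = b[["r_mult"]],
                      window_len = b[["window_len"]])
  add <- function(cells, m, r, N) {
    row <- data.frame(m = m, r_mult = r, window_len = N)
    if (!any(cells$m == m & cells$r_mult == r & cells$window_len == N))
      rbind(cells, row) else cells
  }
  for (m in spec$m_grid) cells <- add(cells, m, b[["r_mult"]], b[["window_len"]])
  for (r in spec$r_grid) cells <- add(cells, b[["m"]], r, b[["window_len"]])
  for (N in spec$n_grid) cells <- add(cells, b[["m"]], b[["r_mult"]], N)
  cells
}

cell_tag <- function(m, r, N) sprintf("m%g_r%g_N%g", m, r, N)

#' Run the full experiment
#'
#' Executes the pipeline described by an [experiment_spec()] and returns the
#' per-sample records together with regression tables per entropy-grid cell
#' and stratum. Deterministic given the spec's seeds.
#'
#' @param spec an [experiment_spec()].
#' @param dataset optional pre-built `"signal_dataset"`; when supplied, the
#'   spec's `synth` config is ignored for generation.
#' @param model optional pre-trained [signal_cnn()]; when supplied together
#'   with `dataset`, every sample of `dataset` is treated as evaluation data
#'   and no training split is made.
#' @return An object of class `"sampen_experiment"`: list with
#'   `records` (data frame: one row per evaluated sample with certainty,
#'   heatmap-signal and per-cell heatmap-entropy maximal correlations),
#'   `regressions` (data frame of R-squared / F rows per cell and stratum,
#'   plus the heatmap-vs-signal rows with `response = "signal"`),
#'   `cells`, `model`, `spec`.
#' @export
run_experiment <- function(spec, dataset = NULL, model = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (is.null(dataset)) dataset <- synth_generate(spec$synth)
  n <- nrow(dataset$x)
  if (is.null(model)) {
    ord <- with_seed(child_seed(spec$seed, 1L), sample.int(n))
    n_test <- max(2L, round(spec$test_fraction * n))
    test_idx <- ord[seq_len(n_test)]
    train_idx <- ord[-seq_len(n_test)]
    model <- signal_cnn(dataset$x[train_idx, , drop = FALSE],
                        dataset$y[train_idx], spec$model,
                        epochs = spec$epochs, batch_size = spec$batch_size,
                        lr = spec$lr, seed = child_seed(spec$seed, 2L))
    eval_ds <- dataset_subset(dataset, test_idx)
  } else {
    eval_ds <- dataset
  }
  n_eval <- nrow(eval_ds$x)
  if (n_eval < 3L) stop("evaluation set too small", call. = FALSE)

  scores <- certainty_scores(model, eval_ds)
  scores <- normalize_certainties(scores)
  heatmaps <- lapply(seq_len(n_eval), function(i)
    grad_cam(model, eval_ds$x[i, ], source_id = eval_ds$sample_id[i]))

  # constant series (a dead heatmap, or an entropy series from perfectly
  # regular windows) have no definable normalized correlation; score them 0
  # (no association) instead of aborting the grid
  flat <- function(v) spec$mode == "normalized" && pop_sd(v) == 0
  corr_signal <- vapply(seq_len(n_eval), function(i) {
    if (flat(heatmaps[[i]]$values)) 0 else
      heatmap_vs_signal(heatmaps[[i]], eval_ds$x[i, ], spec$mode)$max_value
  }, numeric(1))

  cells <- sweep_cells(spec)
  corr_entropy <- matrix(NA_real_, nrow = n_eval, ncol = nrow(cells))
  colnames(corr_entropy) <- cell_tag(cells$m, cells$r_mult, cells$window_len)
  for (j in seq_len(nrow(cells))) {
    par <- entropy_params(cells$m[j], cells$r_mult[j], cells$window_len[j])
    for (i in seq_len(n_eval)) {
      es <- entropy_series(eval_ds$x[i, ], par,
                           source_id = eval_ds$sample_id[i])
      corr_entropy[i, j] <-
        if (flat(es$values) || flat(heatmaps[[i]]$values)) 0 else
          heatmap_vs_entropy(heatmaps[[i]], es, spec$mode)$max_value
    }
  }

  strata <- if (spec$stratify_by == "label") eval_ds$y else
    scores$predicted_class
  records <- data.frame(sample_id = eval_ds$sample_id, label = eval_ds$y,
                        predicted_class = scores$predicted_class,
                        certainty_raw = scores$raw,
                        certainty_normalized = scores$normalized,
                        corr_signal = corr_signal,
                        stringsAsFactors = FALSE)
  records <- cbind(records,
                   as.data.frame(corr_entropy, stringsAsFactors = FALSE))

  reg <- fits_to_frame(
    stratified_fits(scores$raw, corr_signal, strata),
    extra = data.frame(response = "signal", m = NA_real_, r_mult = NA_real_,
                       window_len = NA_real_))
  for (j in seq_len(nrow(cells))) {
    reg <- rbind(reg, fits_to_frame(
      stratified_fits(scores$raw, corr_entropy[, j], strata),
      extra = data.frame(response = "entropy", m = cells$m[j],
                         r_mult = cells$r_mult[j],
                         window_len = cells$window_len[j])))
  }

  structure(list(records = records, regressions = reg, cells = cells,
                 model = model, spec = spec,
                 accuracy = mean(scores$predicted_class == eval_ds$y)),
            class = "sampen_experiment")
}

#' @export
print.sampen_experiment <- function(x, ...) {
  cat(sprintf(
    "Certainty/information experiment: %d evaluated signals, %d grid cells\n",
    nrow(x$records), nrow(x$cells)))
  cat(sprintf("  held-out accuracy: %.1f%%\n", 100 * x$accuracy))
  b <- x$spec$base
  base_tag <- cell_tag(b[["m"]], b[["r_mult"]], b[["window_len"]])
  rs <- subset(x$regressions, response == "signal" & group == "whole")
  re <- subset(x$regressions, response == "entropy" & group == "whole" &
                 m == b[["m"]] & r_mult == b[["r_mult"]] &
                 window_len == b[["window_len"]])
  cat(sprintf("  R^2(certainty vs heatmap-signal corr):   %.3f\n",
              rs$r_squared))
  cat(sprintf("  R^2(certainty vs heatmap-entropy corr):  %.3f  [%s]\n",
              re$r_squared, base_tag))
  invisible(x)
}

#' @export
summary.sampen_experiment <- function(object, ...) {
  reg <- object$regressions
  tab <- reg[reg$group == "whole", ]
  tab$cell <- ifelse(tab$response == "signal", "signal",
                     cell_tag(tab$m, tab$r_mult, tab$window_len))
  out <- tab[, c("cell", "response", "r_squared", "f_statistic", "n")]
  rownames(out) <- NULL
  structure(list(table = out, accuracy = object$accuracy),
            class = "summary.sampen_experiment")
}

#' @export
print.summary.sampen_experiment <- function(x, ...) {
  cat(sprintf("Held-out accuracy: %.1f%%\n", 100 * x$accuracy))
  cat("Whole-data regressions (certainty vs max correlation):\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' @export
plot.sampen_experiment <- function(x, which = c("entropy", "signal"), ...) {
  which <- match.arg(which)
  b <- x$spec$base
  yv <- if (which == "signal") x$records$corr_signal else
    x$records[[cell_tag(b[["m"]], b[["r_mult"]], b[["window_len"]])]]
  graphics::plot(x$records$certainty_raw, yv,
                 col = ifelse(x$records$label == 1, "firebrick", "steelblue"),
                 xlab = "certainty index",
                 ylab = sprintf("max corr (heatmap vs %s)", which), ...)
  graphics::abline(stats::lm(yv ~ x$records$certainty_raw), lty = 2)
  invisible(x)
}
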