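# Delimited-text I/O for signals, entropy series and results.
#
# Signals travel as TSV with one row per signal: sample_id, label, fs, then
# the sample values v1..vL. Entropy series are written one value per line
# under a header comment recording (m, r_mult, N) so a series file is
# self-describing.

#' Write a signal dataset as delimited text
#'
#' @param ds a `"signal_dataset"`.
#' @param path output file; tab-separated, one signal per row.
#' @param truth_path optional path for the burst annotations (0-based,
#'   half-open sample intervals).
#' @return `path`, invisibly.
#' @export
write_signals <- function(ds, path, truth_path = NULL) {
  stopifnot(inherits(ds, "signal_dataset"))
  df <- data.frame(sample_id = ds$sample_id, label = ds$y, fs = ds$fs,
                   ds$x, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", "label", "fs",
                 paste0("v", seq_len(ncol(ds$x))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    rows <- do.call(rbind, lapply(seq_along(ds$truth), function(i) {
      tr <- ds$truth[[i]]
      if (nrow(tr) == 0L) return(NULL)
      data.frame(sample_id = ds$sample_id[i], start = tr[, 1], end = tr[, 2])
    }))
    if (is.null(rows))
      rows <- data.frame(sample_id = character(0), start = integer(0),
                         end = integer(0))
    utils::write.table(rows, truth_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a signal dataset from delimited text
#'
#' @param path file written by [write_signals()].
#' @return A `"signal_dataset"` (without burst annotations).
#' @export
read_signals <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -(1:3), drop = FALSE])
  dimnames(x) <- NULL
  n <- nrow(x)
  structure(list(x = x, y = as.integer(df$label), fs = as.numeric(df$fs[1]),
                 sample_id = as.character(df$sample_id),
                 subject = rep(NA_integer_, n),
                 truth = rep(list(matrix(integer(0), ncol = 2,
                                         dimnames = list(NULL,
                                                         c("start", "end")))),
                             n),
                 config = NULL),
            class = "signal_dataset")
}

#' Write an entropy series with a self-describing header
#'
#' @param e an [entropy_series()].
#' @param path output file; `# m=<m> r_mult=<r> N=<N>` header then one value
#'   per line.
#' @return `path`, invisibly.
#' @export
write_entropy_series <- function(e, path) {
  stopifnot(inherits(e, "entropy_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m=%d r_mult=%g N=%d r_reference=%s", e$params$m,
                     e$params$r_mult, e$params$window_len, e$r_reference),
             con)
  writeLines(format(e$values, digits = 17, trim = TRUE, scientific = FALSE),
             con)
  invisible(path)
}

#' Read an entropy series written by [write_entropy_series()]
#'
#' @param path input file.
#' @return An `"entropy_series"`.
#' @export
read_entropy_series <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  kv <- regmatches(hdr, gregexpr("[A-Za-z_]+=[^ ]+", hdr))[[1]]
  vals <- strsplit(kv, "=")
  get <- function(key) {
    hit <- vals[[which(vapply(vals, `[`, "", 1) == key)]][2]
    hit
  }
  structure(list(values = as.numeric(lines[-1]),
                 params = entropy_params(as.integer(get("m")),
                                         as.numeric(get("r_mult")),
                                         as.integer(get("N"))),
                 r_reference = get("r_reference"),
                 source_id = NA_character_, n_filled = 0L),
            class = "entropy_series")
}
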