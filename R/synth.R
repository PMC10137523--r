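#' Configuration for the two-class synthetic signal generator
#'
#' Describes a corpus of one-second, band-limited signals in two classes that
#' differ only by localized high-frequency oscillatory bursts: class 0 is
#' band-limited Gaussian background noise, class 1 is the same background plus
#' Poisson-placed Tukey-windowed tone bursts. The defaults mirror a 2000 Hz
#' recording band-passed to 60-600 Hz with burst content in the 80-500 Hz
#' range, i.e. the regime where high-frequency-oscillation-like epileptiform
#' transients live.
#'
#' @param fs sampling rate in Hz.
#' @param duration signal duration in seconds; each sample has
#'   `fs * duration` points.
#' @param n_per_class signals per class.
#' @param burst_rate expected bursts per second in class-1 signals (Poisson).
#' @param burst_band two Hz values; burst tone frequencies are drawn
#'   uniformly from this band.
#' @param burst_snr burst amplitude as a multiple of the background RMS;
#'   0 makes the two classes distributionally identical (null generator).
#' @param background_band two Hz values bounding the background noise band.
#' @param n_subjects number of pseudo-subjects; each signal belongs to one,
#'   and subjects differ by a background gain factor, emulating cross-patient
#'   amplitude variability that the training shuffle has to absorb.
#' @param seed integer seed; identical configs generate bitwise-identical
#'   datasets.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(fs = 2000, duration = 1, n_per_class = 100L,
                         burst_rate = 4, burst_band = c(80, 500),
                         burst_snr = 5, background_band = c(60, 600),
                         n_subjects = 5L, seed = 1L) {
  check_band <- function(b, name) {
    if (length(b) != 2L || b[1] <= 0 || b[2] <= b[1] || b[2] >= fs / 2)
      stop(sprintf("`%s` must satisfy 0 < low < high < fs/2", name),
           call. = FALSE)
  }
  check_band(burst_band, "burst_band")
  check_band(background_band, "background_band")
  if (burst_rate < 0) stop("`burst_rate` must be >= 0", call. = FALSE)
  if (n_per_class < 1L) stop("`n_per_class` must be >= 1", call. = FALSE)
  structure(list(fs = fs, duration = duration,
                 n_per_class = as.integer(n_per_class),
                 burst_rate = burst_rate, burst_band = burst_band,
                 burst_snr = burst_snr, background_band = background_band,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# band-limited Gaussian noise via FFT brick-wall masking; exactly length n
bandlimited_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)          # two-sided frequency axis
  spec[freq < band[1] | freq > band[2]] <- 0
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# Tukey (tapered cosine) window, taper fraction alpha
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

#' Generate a synthetic two-class signal dataset
#'
#' Class 0 signals are band-limited Gaussian noise; class 1 signals share the
#' identical background generator and add Poisson-placed oscillatory bursts
#' (Tukey-windowed tones, 50-150 ms, frequency uniform in `burst_band`) at
#' amplitude `burst_snr` times the background RMS. Burst intervals are
#' recorded per sample as 0-based, half-open `[start, end)` sample indices;
#' class-0 samples have none.
#'
#' @param config a [synth_config()].
#' @return An object of class `"signal_dataset"`: list with `x` (matrix,
#'   one signal per row), `y` (0/1 integer labels), `fs`, `sample_id`,
#'   `subject`, and `truth` (per-sample matrix of burst intervals with
#'   columns `start`, `end`).
#' @examples
#' ds <- synth_generate(synth_config(n_per_class = 5, seed = 42))
#' dim(ds$x)    # 10 x 2000
#' table(ds$y)
#' @export
synth_generate <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  L <- as.integer(round(config$fs * config$duration))
  n <- 2L * config$n_per_class
  with_seed(config$seed, {
    subject_gain <- exp(stats::rnorm(config$n_subjects, sd = 0.2))
    x <- matrix(0, nrow = n, ncol = L)
    y <- integer(n)
    subject <- integer(n)
    truth <- vector("list", n)
    # interleave classes across subjects so every subject contributes both
    for (i in seq_len(n)) {
      cls <- if (i <= config$n_per_class) 0L else 1L
      subj <- ((i - 1L) %% config$n_subjects) + 1L
      bg <- bandlimited_noise(L, config$fs, config$background_band) *
        subject_gain[subj]
      bursts <- matrix(integer(0), ncol = 2,
                       dimnames = list(NULL, c("start", "end")))
      if (cls == 1L) {
        k <- stats::rpois(1, config$burst_rate * config$duration)
        if (k > 0 && config$burst_snr > 0) {
          amp <- config$burst_snr * sqrt(mean(bg^2))
          for (b in seq_len(k)) {
            dur_s <- stats::runif(1, 0.05, 0.15)
            len <- max(2L, as.integer(round(dur_s * config$fs)))
            len <- min(len, L)
            start <- sample.int(L - len + 1L, 1L) - 1L   # 0-based
            f <- stats::runif(1, config$burst_band[1], config$burst_band[2])
            ph <- stats::runif(1, 0, 2 * pi)
            tt <- (seq_len(len) - 1) / config$fs
            tone <- amp * sin(2 * pi * f * tt + ph) * tukey_window(len)
            idx <- (start + 1L):(start + len)
            bg[idx] <- bg[idx] + tone
            bursts <- rbind(bursts, c(start, start + len))
          }
        } else if (k > 0) {
          # null generator (snr 0): draw the same randomness so class-1
          # backgrounds stay exchangeable with class 0, but add nothing
          for (b in seq_len(k)) {
            stats::runif(1); sample.int(L, 1L); stats::runif(2)
          }
        }
      }
      x[i, ] <- bg
      y[i] <- cls
      subject[i] <- subj
      truth[[i]] <- bursts
    }
    structure(list(x = x, y = y, fs = config$fs,
                   sample_id = sprintf("s%04d", seq_len(n)),
                   subject = subject, truth = truth, config = config),
              class = "signal_dataset")
  })
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf("Signal dataset: %d signals of %d samples at %g Hz\n",
              nrow(x$x), ncol(x$x), x$fs))
  cat(sprintf("  class balance: %d / %d; %d subjects\n",
              sum(x$y == 0L), sum(x$y == 1L),
              length(unique(x$subject))))
  nb <- vapply(x$truth, nrow, integer(1))
  cat(sprintf("  bursts per class-1 signal: mean %.2f\n",
              mean(nb[x$y == 1L])))
  invisible(x)
}

# subset a signal_dataset by index, keeping all parallel fields aligned
dataset_subset <- function(ds, idx) {
  structure(list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx], fs = ds$fs,
                 sample_id = ds$sample_id[idx], subject = ds$subject[idx],
                 truth = ds$truth[idx], config = ds$config),
            class = "signal_dataset")
}
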