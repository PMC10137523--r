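test_that("parameter validation catches degenerate configurations", {
  expect_error(entropy_params(m = 99, window_len = 100), "m < window_len")
  expect_error(entropy_params(r_mult = 0), "positive")
  expect_error(entropy_params(window_len = 3), ">= 4")
  p <- entropy_params(2, 0.2, 64)
  expect_error(sample_entropy(rnorm(50), p), "length")
  expect_error(entropy_series(rnorm(50), entropy_params(8, 2, 100)),
               "shorter")
})

test_that("constant windows have zero sample entropy", {
  p <- entropy_params(m = 2, r_mult = 0.2, window_len = 32)
  expect_identical(sample_entropy(rep(3.7, 32), p), 0)
  expect_identical(sample_entropy(rep(0, 32), p, sd_ref = 1), 0)
})

test_that("sample entropy equals the brute-force pair-counting oracle", {
  set.seed(42)
  cases <- expand.grid(n = c(50, 120, 400), m = c(2, 4, 8),
                       r_mult = c(0.2, 1.5, 2, 2.5))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; m <- cases$m[i]; rm_ <- cases$r_mult[i]
    w <- rnorm(n)
    r <- rm_ * sd(w)
    expect_identical(unname(sampen_counts(w, m, r)),
                     as.numeric(unname(sampen_oracle_counts(w, m, r))))
    p <- entropy_params(m, rm_, n)
    expect_identical(sample_entropy(w, p), sampen_oracle(w, m, r))
  }
})

test_that("periodic windows are more regular than white noise", {
  p <- entropy_params(m = 2, r_mult = 0.2, window_len = 400)
  sine <- sin(2 * pi * (0:399) / 40)   # period divides the window
  se_sine <- sample_entropy(sine, p)
  expect_identical(se_sine,
                   sampen_oracle(sine, 2, 0.2 * sd(sine)))
  set.seed(7)
  noise <- rnorm(400)
  se_noise <- sample_entropy(noise, p)
  expect_identical(se_noise, sampen_oracle(noise, 2, 0.2 * sd(noise)))
  expect_gt(se_noise, se_sine)
  expect_gte(se_sine, 0)
})

test_that("sample entropy is invariant to positive affine transforms", {
  set.seed(11)
  for (i in 1:20) {
    w <- rnorm(120)
    p <- entropy_params(m = sample(c(2, 4, 8), 1),
                        r_mult = runif(1, 0.2, 2.5), window_len = 120)
    a <- runif(1, 0.1, 50); b <- runif(1, -20, 20)
    v0 <- sample_entropy(w, p)
    v1 <- sample_entropy(a * w + b, p)
    if (is.na(v0)) {
      expect_identical(is.na(v1), TRUE)   # no matches either way
    } else {
      expect_equal(v1, v0, tolerance = 1e-12)
      expect_gte(v0, 0)
    }
  }
})

test_that("match counts grow monotonically with the tolerance", {
  set.seed(3)
  w <- rnorm(150)
  rs <- sd(w) * c(0.1, 0.3, 0.8, 1.5, 2.5)
  cnt <- t(vapply(rs, function(r) sampen_counts(w, 3, r), numeric(2)))
  expect_true(all(diff(cnt[, "B"]) >= 0))
  expect_true(all(diff(cnt[, "A"]) >= 0))
})

test_that("degenerate counts follow the documented conventions", {
  # strongly trending data: no template pair ever matches at small r
  w <- (1:40)^2
  expect_true(is.na(sample_entropy(w, entropy_params(2, 0.001, 40))))
  # one m-match but no (m+1)-match: maximum attainable value
  w <- c(0, 1, 0, 1.004, 2, rep(c(9, -9, 8, -8), 4))
  cnt <- sampen_counts(w, 2, 0.01)
  if (cnt["B"] > 0 && cnt["A"] == 0) {
    nt <- length(w) - 2
    expect_equal(sample_entropy(w, entropy_params(2, 0.01 / sd(w), 21),
                                sd_ref = sd(w)),
                 -log(1 / (nt * (nt - 1))))
  }
})

test_that("entropy series has the length of the signal and clamps edges", {
  p <- entropy_params(m = 2, r_mult = 0.2, window_len = 100)
  x <- rnorm(2000)
  es <- entropy_series(x, p)
  expect_length(es$values, 2000)
  expect_true(all(is.finite(es$values)))
  # the same clamped edge window backs the first half-window of indices
  expect_identical(es$values[1], es$values[50])
  # constant signal: all-zero series
  es0 <- entropy_series(rep(2, 500), p)
  expect_identical(es0$values, rep(0, 500))
})

test_that("entropy series separates noise from a pure tone", {
  set.seed(5)
  fs <- 2000
  noise <- rnorm(1000)
  tone <- sin(2 * pi * 200 * (0:999) / fs) * sd(noise) * sqrt(2)
  x <- c(noise, tone)
  es <- entropy_series(x, entropy_params(m = 2, r_mult = 0.2,
                                         window_len = 100))
  m_noise <- mean(es$values[1:900])
  m_tone <- mean(es$values[1101:2000])
  expect_gt(m_noise, m_tone)
})

test_that("per-window tolerance mode rescales to local variance", {
  set.seed(9)
  x <- c(rnorm(500), 10 * rnorm(500))
  p <- entropy_params(m = 2, r_mult = 0.2, window_len = 100)
  glob <- entropy_series(x, p, r_reference = "global_sd")
  per <- entropy_series(x, p, r_reference = "per_window_sd")
  # under a global tolerance the loud half matches far less (higher entropy);
  # per-window referencing removes that amplitude effect
  expect_gt(mean(glob$values[601:1000]) - mean(glob$values[1:400]),
            abs(mean(per$values[601:1000]) - mean(per$values[1:400])))
})

test_that("shannon entropy matches analytic values", {
  expect_identical(shannon_entropy(rep(1, 100)), 0)
  expect_equal(shannon_entropy(rep(c(0, 1), 50), bins = 2), log(2))
  set.seed(13)
  u <- runif(20000)
  h <- shannon_entropy(u, bins = 16)
  # direct summation oracle on the same histogram
  cnt <- table(cut(u, seq(min(u), max(u), length.out = 17),
                   include.lowest = TRUE))
  p <- as.numeric(cnt) / length(u)
  expect_equal(h, -sum(p[p > 0] * log(p[p > 0])))
  expect_lt(abs(h - log(16)), 0.01)
  expect_error(shannon_entropy(numeric(0)), "non-empty")
})
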