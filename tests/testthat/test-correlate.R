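test_that("raw cross-correlation equals the double-loop oracle exactly", {
  set.seed(23)
  for (i in 1:40) {
    a <- rnorm(sample(1:64, 1))
    b <- rnorm(sample(1:64, 1))
    got <- cross_correlation(a, b, mode = "raw")
    want <- xcorr_oracle(a, b)
    expect_identical(got$z, want$z)
    expect_identical(got$lags, want$lags)
  }
})

test_that("normalized cross-correlation equals the standardized oracle", {
  set.seed(29)
  for (i in 1:40) {
    a <- rnorm(sample(3:64, 1))
    b <- rnorm(sample(3:64, 1))
    got <- cross_correlation(a, b, mode = "normalized")
    want <- xcorr_oracle(standardize_pop(a), standardize_pop(b))
    expect_equal(got$z, want$z / min(length(a), length(b)),
                 tolerance = 1e-12)
  }
})

test_that("an impulse pair produces a single unit spike at the aligning lag", {
  got <- cross_correlation(c(1, 0, 0), c(0, 0, 1), mode = "raw")
  expect_identical(sum(got$z != 0), 1L)
  expect_identical(got$z[got$lags == 2], 1)
})

test_that("identical standardized sequences peak at 1 at lag zero", {
  set.seed(37)
  a <- rnorm(200)
  r <- max_correlation(a, a, mode = "normalized")
  expect_equal(r$max_value, 1, tolerance = 1e-12)
  expect_identical(r$lag_at_max, 0L)
})

test_that("a delayed copy peaks at the documented positive lag", {
  set.seed(41)
  a <- rnorm(100)
  b <- c(rep(0, 7), a)[1:100]        # b is a delayed by 7 samples: a leads
  r <- max_correlation(a, b, mode = "normalized")
  expect_identical(r$lag_at_max, 7L)
  expect_gt(r$max_value, 0.9)
})

test_that("max correlation is the oracle max, with symmetry up to lag sign", {
  set.seed(43)
  for (i in 1:25) {
    a <- rnorm(sample(3:64, 1))
    b <- rnorm(sample(3:64, 1))
    got <- max_correlation(a, b, mode = "raw")
    want <- xcorr_oracle(a, b)
    expect_identical(got$max_value, max(want$z))
    swapped <- max_correlation(b, a, mode = "raw")
    expect_identical(swapped$max_value, got$max_value)
    expect_identical(swapped$lag_at_max, -got$lag_at_max)
  }
})

test_that("ties are broken toward the smallest absolute lag", {
  # symmetric signal: z is symmetric in lag, so +k and -k tie; smallest |lag|
  got <- max_correlation(c(0, 1, 0), c(0, 1, 0), mode = "raw")
  expect_identical(got$lag_at_max, 0L)
  # two equal off-centre peaks at -1 and +1: negative lag preferred on ties
  z2 <- max_correlation(c(1, 0, 1), c(0, 1, 0), mode = "raw")
  expect_identical(abs(z2$lag_at_max), 1L)
  expect_identical(z2$lag_at_max, -1L)
})

test_that("normalized maxima are bounded by 1 on equal-length pairs", {
  # the shared-length standardized form is bounded by Cauchy-Schwarz only
  # when both series have the same length, which is the only configuration
  # the pipeline ever correlates (heatmaps are upsampled to series length)
  set.seed(47)
  worst <- 0
  for (i in 1:10000) {
    n <- sample(3:40, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    worst <- max(worst, abs(max_correlation(a, b, "normalized")$max_value))
  }
  expect_lte(worst, 1 + 1e-9)
})

test_that("constant input in normalized mode raises a variance error", {
  expect_error(cross_correlation(rep(1, 5), rnorm(5), "normalized"),
               "zero variance")
  expect_silent(cross_correlation(rep(1, 5), rnorm(5), "raw"))
  expect_error(cross_correlation(numeric(0), 1:3), "non-empty")
})

test_that("heatmap-vs-series wrappers compose upsampling and correlation", {
  h <- structure(list(values = c(0, 1, 0.5, 0), explained_class = 1L,
                      layer = "conv3", source_id = "t", upsampled = NULL),
                 class = "gradcam_heatmap")
  s <- sin(seq(0, 3, length.out = 40))
  r1 <- heatmap_vs_signal(h, s)
  h40 <- upsample_heatmap(h, 40)
  r2 <- max_correlation(h40$upsampled, s)
  expect_identical(r1$max_value, r2$max_value)
  expect_identical(r1$lag_at_max, r2$lag_at_max)
  es <- entropy_series(rnorm(300), entropy_params(2, 2, 50), source_id = "t")
  r3 <- heatmap_vs_entropy(h, es)
  h300 <- upsample_heatmap(h, 300)
  expect_identical(r3$max_value,
                   max_correlation(h300$upsampled, es$values)$max_value)
})
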