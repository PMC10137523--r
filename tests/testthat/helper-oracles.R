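# Independent brute-force oracles used to validate the compiled paths.

# Sample-entropy oracle: vectorised template-matrix counting, O(N^2 * m),
# written with a completely different mechanism (matrix pmax) than the
# compiled early-abort pair loop.
sampen_oracle_counts <- function(w, m, r) {
  n <- length(w)
  nt <- n - m
  cheb_count <- function(len) {
    Tm <- sapply(seq_len(len), function(k) w[seq_len(nt) + k - 1L])
    Tm <- matrix(Tm, nrow = nt)
    total <- 0L
    for (i in seq_len(nt)) {
      d <- do.call(pmax, lapply(seq_len(len),
                                function(k) abs(Tm[, k] - Tm[i, k])))
      total <- total + sum(d < r) - 1L   # drop the self-match
    }
    total
  }
  c(B = cheb_count(m), A = cheb_count(m + 1L))
}

sampen_oracle <- function(w, m, r) {
  cnt <- sampen_oracle_counts(w, m, r)
  nt <- length(w) - m
  if (cnt["B"] == 0) return(NA_real_)
  if (cnt["A"] == 0) return(-log(1 / (nt * (nt - 1))))
  -log(cnt[["A"]] / cnt[["B"]])
}

# Cross-correlation oracle: explicit loop over every lag, ascending inner
# sum so raw-mode results are bitwise comparable to the compiled path.
xcorr_oracle <- function(a, b) {
  la <- length(a); lb <- length(b)
  lags <- seq.int(-(la - 1L), lb - 1L)
  z <- vapply(lags, function(k) {
    t0 <- max(1L, 1L - k); t1 <- min(la, lb - k)
    if (t0 > t1) 0 else sum(a[t0:t1] * b[(t0:t1) + k])
  }, numeric(1))
  list(z = z, lags = lags)
}

standardize_pop <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# head-only forward pass from a given last-conv activation matrix, used by
# the finite-difference oracle
head_logits_from_A <- function(model, A) {
  config <- model$config
  nb <- length(config$conv_blocks)
  blk <- config$conv_blocks[[nb]]
  cube <- array(A, dim = c(nrow(A), ncol(A), 1L))
  pool_code <- if (config$pool_type == "max") 0L else 1L
  P <- gradentropy:::.pool1d_forward_cpp(cube, blk[3], pool_code)
  flat <- as.numeric(P$Y)
  z1 <- as.numeric(crossprod(model$params$W1, flat)) + model$params$b1
  a1 <- if (config$penult_activation == "linear") z1 else
    pmax(z1, 0) + if (config$penult_activation == "leaky_relu")
      0.01 * pmin(z1, 0) else 0
  as.numeric(crossprod(model$params$W2, a1)) + model$params$b2
}

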