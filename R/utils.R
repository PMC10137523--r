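# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps every exported routine deterministic
# given its seed argument without clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# derive a reproducible child seed (keeps values inside 32-bit integer range)
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}

# replace NA entries by the nearest finite neighbour (ties resolved toward
# the earlier index); errors if nothing is finite
fill_nearest <- function(v) {
  ok <- which(is.finite(v))
  if (length(ok) == 0L) stop("no finite values to fill from", call. = FALSE)
  bad <- which(!is.finite(v))
  if (length(bad) == 0L) return(v)
  for (i in bad) {
    j <- ok[which.min(abs(ok - i))]
    v[i] <- v[j]
  }
  v
}

# population standard deviation (divisor n), used where a standardized
# series must satisfy sum(x^2) == n
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
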