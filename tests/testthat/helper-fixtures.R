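# Lazily built, memoised fixtures shared across test files. Everything is
# generated in code at test time; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(build()), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small separable dataset + briefly trained model, enough for heatmap and
# certainty behaviour without taking minutes
small_dataset <- function() fixture("small_dataset", function() {
  synth_generate(synth_config(n_per_class = 150L, seed = 421L))
})

small_model <- function() fixture("small_model", function() {
  ds <- small_dataset()
  signal_cnn(ds, epochs = 12L, seed = 77L)
})

# held-out data from the same generator family, different seed
small_holdout <- function() fixture("small_holdout", function() {
  synth_generate(synth_config(n_per_class = 30L, seed = 1234L))
})
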