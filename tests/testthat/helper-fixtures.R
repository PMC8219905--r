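# Shared fixtures, computed once per test run and memoized in an environment.
# Everything is small (subdivision levels 1-2) so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

fx_montage <- function() fixture("montage", function() build_montage("standard31"))

fx_space1 <- function() fixture("space1", function() build_source_space(1))
fx_space2 <- function() fixture("space2", function() build_source_space(2))

fx_gm1 <- function() fixture("gm1", function() {
  compute_leadfield(fx_space1(), fx_montage())
})
fx_gm2 <- function() fixture("gm2", function() {
  compute_leadfield(fx_space2(), fx_montage())
})
fx_agm2 <- function() fixture("agm2", function() {
  perturb_to_agm(fx_gm1(), seed = 42)  # level 1 -> finer level 2
})

fx_dataset_small <- function() fixture("dataset_small", function() {
  generate_dataset(fx_gm1(), 30, "train", seed = 7)
})
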