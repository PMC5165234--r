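# shared fixtures: a small arena keeps the chemokine solve cheap; built
# lazily once per test run and reused (fields are also cached by config)

small_config <- function(...) {
  gc_config(arena = list(radius_um = 80, n_fdc = 40, seed = 7L), ...)
}

the_test_env <- new.env(parent = emptyenv())

small_arena <- function() {
  if (is.null(the_test_env$arena))
    the_test_env$arena <- build_arena(small_config())
  the_test_env$arena
}

reference_arena <- function() {
  if (is.null(the_test_env$ref_arena))
    the_test_env$ref_arena <- build_arena(gc_config())
  the_test_env$ref_arena
}
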