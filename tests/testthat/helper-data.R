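# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_dataset <- function() {
  cached("small_dataset", generate_dataset(30, 30, master_seed = 7))
}

small_features <- function() {
  cached("small_features", extract_features(small_dataset()))
}

small_db <- function() {
  cached("small_db",
         build_hash_database(small_features(), k = 4, r = 16, seed = 7))
}

# a constant-gray square test image with full mask
flat_image <- function(value = 0.5, n = 8) {
  nodule_image(matrix(value, n, n), matrix(TRUE, n, n), label = 0L, id = "flat")
}
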