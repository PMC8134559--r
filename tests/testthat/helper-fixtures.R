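# Shared fixtures, built once per test run and cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A clean (noise-free, island-free) phantom and its preprocessed form.
clean_phantom <- function() {
  cached("clean_phantom",
         make_phantom(phantom_spec(seed = 101, age_months = 120,
                                   noise_sd = 0, n_islands = 0)))
}

clean_prep <- function() {
  cached("clean_prep", {
    ph <- clean_phantom()
    preprocess_image(ph$image, labels = ph$labels)
  })
}

# A small deterministic packed image exercised by surrogate tests: the
# packed clean phantom.
fixture_packed <- function() clean_prep()$packed

# A compact square probe region on the 299 grid.
square_region <- function(size = 16L, at = c(140L, 140L)) {
  region <- matrix(FALSE, 299, 299)
  region[at[1]:(at[1] + size - 1L), at[2]:(at[2] + size - 1L)] <- TRUE
  region
}

# Channel-summed grid (the direction the probe perturbs along).
channel_sum <- function(arr) arr[, , 1] + arr[, , 2] + arr[, , 3]
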