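# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so interleaved seeded generators never perturb each other.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Packed model-input grid size (cells per side) and the source grid it packs.
PACKED_SIZE <- 299L
SOURCE_SIZE <- 598L

is_gray_matrix <- function(x) is.matrix(x) && is.numeric(x)

assert_gray <- function(x, what = "image") {
  if (!is_gray_matrix(x)) stop(what, " must be a numeric matrix", call. = FALSE)
  invisible(x)
}

assert_packed <- function(x) {
  if (!(is.array(x) && length(dim(x)) == 3L &&
        all(dim(x) == c(PACKED_SIZE, PACKED_SIZE, 3L)))) {
    stop("packed image must be a ", PACKED_SIZE, "x", PACKED_SIZE,
         "x3 array", call. = FALSE)
  }
  invisible(x)
}

assert_same_dim <- function(a, b, what = "mask") {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("dimension mismatch: image is ", paste(dim(a)[1:2], collapse = "x"),
         ", ", what, " is ", paste(dim(b)[1:2], collapse = "x"), call. = FALSE)
  }
  invisible(TRUE)
}

as_binary <- function(mask) {
  if (is.logical(mask)) return(mask)
  assert_gray(mask, "mask")
  mask > 0.5
}

# Round half away from zero (all quantities here are non-negative, so this
# is round-half-up); base round() rounds half to even.
round_half_up <- function(x) floor(x + 0.5)
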