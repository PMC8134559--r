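#' Black-box regressor contract
#'
#' A `pd_regressor` wraps any model that maps a packed 299x299x3 integer
#' image to a scalar predicted age in months.  The probe only ever calls
#' `predict(image)`, so externally trained networks can be plugged in by
#' wrapping their inference call; the contract requires that
#' \itemize{
#'   \item `predict` is deterministic (identical grids give bit-identical
#'     outputs; stochastic models must be wrapped in a fixed inference mode
#'     by the caller), and
#'   \item `predict` accepts channel intensities in `[0, 255]` — the +1
#'     probe can push a 254 pixel to 255.
#' }
#'
#' @param predict Function taking a 299x299x3 numeric array and returning
#'   one finite numeric scalar (months).
#' @param name Free-form model name/description.
#' @param predict_batch Optional function taking a list of packed images and
#'   returning one scalar per image; used by [batch_pd_map()].
#' @return An object of class `pd_regressor`.
#' @export
new_regressor <- function(predict, name = "black-box regressor",
                          predict_batch = NULL) {
  stopifnot(is.function(predict),
            is.null(predict_batch) || is.function(predict_batch))
  structure(list(predict = predict, predict_batch = predict_batch,
                 name = name),
            class = "pd_regressor")
}

#' @export
print.pd_regressor <- function(x, ...) {
  cat("<pd_regressor>", x$name, "\n")
  if (!is.null(x$spec)) {
    cat("  kind:", x$spec$kind, " seed:", x$spec$seed, "\n")
  }
  invisible(x)
}

#' Surrogate regressors with closed-form gradients
#'
#' Surrogates are fully specified stand-in models used as oracles for the
#' finite-difference probe.  Each has an analytic gradient
#' ([analytic_gradient()]) and a documented curvature bound
#' (`$curvature_bound`): the largest second derivative of the prediction
#' along the probe direction (all three channels of one pixel moving
#' together), so the forward-difference error is at most
#' `step * curvature_bound / 2`.
#'
#' Kinds:
#' \describe{
#'   \item{`constant`}{`f(x) = value` (default 120 months).}
#'   \item{`linear`}{`f(x) = sum(w * x) + intercept`.  Weights default to a
#'     seeded uniform draw of dyadic rationals (integer multiples of
#'     `2^-30`) on `[-1e-4, 1e-4]` — dyadic so that all sums are exact in
#'     double precision and the probe is bitwise exact on this affine
#'     model, and of that magnitude so per-pixel PDs land in the 1e-3 to
#'     1e-2 months-per-intensity range typical of hand-mask probes; pass
#'     `weights` to override.}
#'   \item{`quadratic`}{`f(x) = sum(a * x^2)`, coefficients seeded uniform
#'     on `[-5e-7, 5e-7]`.  Curvature bound `6 * max(|a|)`.}
#'   \item{`radial-bump`}{A smooth, bounded bump of weighted pixel sums:
#'     `f(x) = amp * tanh((u - center) / width)` with
#'     `u = sum_p w_p * (x_p1 + x_p2 + x_p3)` and seeded non-negative
#'     weights `w_p` uniform on `[0, 1e-3]`.  Curvature bound
#'     `9 * max(w)^2 * amp * (4 / (3 * sqrt(3))) / width^2`.}
#'   \item{`regional-sum`}{`f(x) = intercept + sum_r coef_r * S_r(x)` where
#'     `S_r` sums all channel intensities over the pixels of label `r` in a
#'     supplied 299x299 label map; coefficients default to a seeded uniform
#'     draw on `[5e-4, 3e-3]`.}
#' }
#'
#' @param kind One of `"constant"`, `"linear"`, `"quadratic"`,
#'   `"radial-bump"`, `"regional-sum"`.
#' @param seed Integer seed for randomized parameter draws; identical
#'   `(kind, parameters, seed)` reproduce the identical surrogate.
#' @param value Constant prediction (kind `constant`).
#' @param weights Optional 299x299x3 weight array (kind `linear`).
#' @param intercept Additive constant (kinds `linear`, `regional-sum`).
#' @param coef_range Range of the seeded coefficient draw (kinds `linear`,
#'   `quadratic`, `regional-sum`) or of the per-pixel weights
#'   (`radial-bump`).
#' @param amp,center,width Bump amplitude (months), center and width of the
#'   weighted-sum coordinate (kind `radial-bump`).
#' @param labels 299x299 integer label map (kind `regional-sum`).
#' @param coefs Named or positional per-label coefficients (kind
#'   `regional-sum`); defaults to a seeded draw over the labels present.
#' @return A `pd_regressor` with fields `spec` (the reproducible parameter
#'   set) and `curvature_bound`.
#' @examples
#' reg <- make_surrogate("linear", seed = 7)
#' img <- array(0L, c(299, 299, 3))
#' reg$predict(img)  # equals the intercept
#' @export
make_surrogate <- function(kind = c("constant", "linear", "quadratic",
                                    "radial-bump", "regional-sum"),
                           seed = 1L, value = 120, weights = NULL,
                           intercept = 100, coef_range = NULL,
                           amp = 120, center = 5000, width = 2000,
                           labels = NULL, coefs = NULL) {
  kind <- match.arg(kind)
  seed <- as.integer(seed)
  n <- PACKED_SIZE
  spec <- list(kind = kind, seed = seed)

  if (kind == "constant") {
    reg <- new_regressor(function(x) value, name = "constant surrogate",
                         predict_batch = function(xs)
                           rep(value, length(xs)))
    spec$value <- value
    bound <- 0
  } else if (kind == "linear") {
    if (is.null(weights)) {
      # Dyadic weights: integer multiples of 2^-30 uniform on ~[-1e-4, 1e-4].
      # Every product with an integer intensity and every partial sum is then
      # exactly representable in double precision, so the forward difference
      # of this affine model is bitwise exact, not merely exact up to
      # rounding.
      rng <- if (is.null(coef_range)) c(-1e-4, 1e-4) else coef_range
      kmax <- floor(rng[2] * 2^30)
      kmin <- ceiling(rng[1] * 2^30)
      weights <- with_seed(seed, array(
        (sample.int(kmax - kmin + 1L, n * n * 3, replace = TRUE) + kmin - 1L)
        / 2^30, c(n, n, 3)))
    }
    if (!(is.array(weights) && length(dim(weights)) == 3L &&
          all(dim(weights) == c(n, n, 3)))) {
      stop("weights must be a ", n, "x", n, "x3 array", call. = FALSE)
    }
    w <- weights
    b <- intercept
    reg <- new_regressor(function(x) sum(w * x) + b,
                         name = "linear surrogate",
                         predict_batch = function(xs)
                           vapply(xs, function(x) sum(w * x) + b, 0))
    reg$weights <- w
    spec$intercept <- b
    bound <- 0
  } else if (kind == "quadratic") {
    rng <- if (is.null(coef_range)) c(-5e-7, 5e-7) else coef_range
    a <- with_seed(seed, array(stats::runif(n * n * 3, rng[1], rng[2]),
                               c(n, n, 3)))
    reg <- new_regressor(function(x) sum(a * x * x),
                         name = "quadratic surrogate",
                         predict_batch = function(xs)
                           vapply(xs, function(x) sum(a * x * x), 0))
    reg$coef <- a
    # probe direction e has a unit step in each channel of one pixel:
    # d2f/dh2 = 2 * (a1 + a2 + a3) <= 6 * max|a|
    bound <- 6 * max(abs(a))
  } else if (kind == "radial-bump") {
    rng <- if (is.null(coef_range)) c(0, 1e-3) else coef_range
    w <- with_seed(seed, matrix(stats::runif(n * n, rng[1], rng[2]), n, n))
    u_of <- function(x) sum(w * (x[, , 1] + x[, , 2] + x[, , 3]))
    f <- function(x) amp * tanh((u_of(x) - center) / width)
    reg <- new_regressor(f, name = "radial-bump surrogate",
                         predict_batch = function(xs) vapply(xs, f, 0))
    reg$weights <- w
    spec$amp <- amp; spec$center <- center; spec$width <- width
    # along the probe direction u moves by 3*w_p per unit step;
    # |tanh''| <= 4/(3*sqrt(3))
    bound <- 9 * max(w)^2 * amp * (4 / (3 * sqrt(3))) / width^2
  } else { # regional-sum
    if (is.null(labels)) stop("regional-sum surrogate needs a label map",
                              call. = FALSE)
    stopifnot(all(dim(labels) == c(n, n)))
    ids <- sort(setdiff(unique(as.integer(labels)), 0L))
    if (is.null(coefs)) {
      rng <- if (is.null(coef_range)) c(5e-4, 3e-3) else coef_range
      coefs <- with_seed(seed, stats::runif(length(ids), rng[1], rng[2]))
    }
    stopifnot(length(coefs) == length(ids))
    cgrid <- matrix(0, n, n)
    for (k in seq_along(ids)) cgrid[labels == ids[k]] <- coefs[k]
    b <- intercept
    f <- function(x) b + sum(cgrid * (x[, , 1] + x[, , 2] + x[, , 3]))
    reg <- new_regressor(f, name = "regional-sum surrogate",
                         predict_batch = function(xs) vapply(xs, f, 0))
    reg$coef_grid <- cgrid
    spec$intercept <- b
    spec$coefs <- coefs
    bound <- 0
  }
  reg$spec <- spec
  reg$curvature_bound <- bound
  reg
}

#' Closed-form gradient of a surrogate regressor
#'
#' Returns the exact partial derivative of the surrogate's prediction with
#' respect to every pixel and channel, evaluated at `image`.  This is the
#' oracle the finite-difference probe is validated against.
#'
#' @param model A `pd_regressor` created by [make_surrogate()].
#' @param image Packed 299x299x3 image at which to evaluate the gradient.
#' @return A 299x299x3 numeric array of derivatives (months per intensity
#'   unit).
#' @export
analytic_gradient <- function(model, image) {
  stopifnot(inherits(model, "pd_regressor"), !is.null(model$spec))
  assert_packed(image)
  n <- PACKED_SIZE
  kind <- model$spec$kind
  if (kind == "constant") {
    array(0, c(n, n, 3))
  } else if (kind == "linear") {
    model$weights + 0 # copy
  } else if (kind == "quadratic") {
    2 * model$coef * image
  } else if (kind == "radial-bump") {
    u <- sum(model$weights * (image[, , 1] + image[, , 2] + image[, , 3]))
    s <- model$spec
    g2d <- (s$amp / s$width) * (1 / cosh((u - s$center) / s$width))^2 *
      model$weights
    array(rep(g2d, 3), c(n, n, 3))
  } else { # regional-sum
    array(rep(model$coef_grid, 3), c(n, n, 3))
  }
}

#' Save and load surrogate specs as plain-text config
#'
#' Writes the reproducible `(kind, seed, scalar parameters)` spec as a
#' `key = value` text file; `read_surrogate_config()` rebuilds the
#' identical surrogate.  For `regional-sum` the label map is written next
#' to the config as a PNG and referenced by file name.
#'
#' @param model A surrogate `pd_regressor`.
#' @param path Config file path.
#' @param labels For `regional-sum` on read: overrides the referenced
#'   label-map PNG.
#' @return `path` / the rebuilt `pd_regressor`.
#' @export
write_surrogate_config <- function(model, path) {
  stopifnot(inherits(model, "pd_regressor"), !is.null(model$spec))
  spec <- model$spec
  if (spec$kind == "regional-sum") {
    # the per-label coefficients live on a grid; store it flat next to the config
    grid_path <- paste0(sub("\\.[^.]*$", "", path), "_coefgrid.csv")
    utils::write.csv(model$coef_grid, grid_path, row.names = FALSE)
    spec$coef_grid_csv <- basename(grid_path)
  }
  write_kv_config(spec, path)
}

#' @rdname write_surrogate_config
#' @export
read_surrogate_config <- function(path, labels = NULL) {
  spec <- read_kv_config(path)
  kind <- spec$kind
  if (kind == "regional-sum" && is.null(labels)) {
    grid_path <- file.path(dirname(path), spec$coef_grid_csv)
    cgrid <- as.matrix(utils::read.csv(grid_path))
    dimnames(cgrid) <- NULL
    # rebuild via a synthetic label map: one label per distinct coefficient
    vals <- sort(setdiff(unique(as.vector(cgrid)), 0))
    labels <- matrix(0L, nrow(cgrid), ncol(cgrid))
    for (k in seq_along(vals)) labels[cgrid == vals[k]] <- k
    return(make_surrogate("regional-sum", seed = spec$seed,
                          intercept = spec$intercept, labels = labels,
                          coefs = vals))
  }
  args <- spec[setdiff(names(spec), c("kind", "coef_grid_csv"))]
  do.call(make_surrogate, c(list(kind = kind), args, list(labels = labels)))
}
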