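#' PD map container
#'
#' A `pd_map` holds the per-pixel partial derivative of the predicted age
#' with respect to input intensity (months per intensity unit) on the
#' 299x299 model grid, together with a computed-region indicator, the
#' baseline prediction and the perturbation step.  Pixels outside the
#' probed region carry the sentinel `NA`.
#'
#' @param pd Numeric matrix of PD values (`NA` where not computed).
#' @param computed Logical indicator matrix, `TRUE` exactly where a PD was
#'   evaluated.
#' @param baseline Baseline predicted age (months).
#' @param step Perturbation step in intensity units (> 0).
#' @return An object of class `pd_map`.
#' @export
new_pd_map <- function(pd, computed, baseline, step) {
  stopifnot(is.matrix(pd), is.matrix(computed),
            identical(dim(pd), dim(computed)),
            is.logical(computed), step > 0)
  stopifnot(all(is.na(pd[!computed])), !anyNA(pd[computed]))
  structure(list(pd = pd, computed = computed, baseline = baseline,
                 step = step),
            class = "pd_map")
}

#' @export
print.pd_map <- function(x, ...) {
  v <- x$pd[x$computed]
  cat("<pd_map> ", nrow(x$pd), "x", ncol(x$pd), ", ",
      sum(x$computed), " computed pixels\n", sep = "")
  cat("  baseline:", format(x$baseline), "months; step:", x$step, "\n")
  if (length(v)) {
    cat("  PD range: [", format(min(v)), ", ", format(max(v)),
        "] months per intensity unit\n", sep = "")
  }
  invisible(x)
}

#' Finite-difference PD at one pixel
#'
#' Increments the intensities of all three channels of one pixel by `step`,
#' re-runs the model, and returns the forward difference
#' `(predict(perturbed) - predict(image)) / step`.  Every other pixel is
#' left untouched.  The perturbed value is passed through unclamped: on a
#' 0-254 scale input the probe can produce 255, which the regressor
#' contract requires accepting.
#'
#' @param model A `pd_regressor`.
#' @param image Packed 299x299x3 image.
#' @param pixel Length-2 integer `(row, col)`, 1-based.
#' @param step Perturbation step in intensity units (>= 1 for integer
#'   inputs; default 1, the increment the probe is defined with).
#' @param baseline Optional precomputed `model$predict(image)`.
#' @param mode `"forward"` (the default probe definition) or `"central"`,
#'   which uses `(f(x + step) - f(x - step)) / (2 * step)` and halves the
#'   truncation bias at the cost of a second model call per pixel.
#' @return PD value in months per intensity unit.
#' @export
fd_pd_at_pixel <- function(model, image, pixel, step = 1, baseline = NULL,
                           mode = c("forward", "central")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "pd_regressor"))
  assert_packed(image)
  pixel <- as.integer(pixel)
  if (length(pixel) != 2L || any(pixel < 1L) || any(pixel > PACKED_SIZE)) {
    stop("pixel out of bounds", call. = FALSE)
  }
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  perturbed <- image
  perturbed[pixel[1], pixel[2], ] <- perturbed[pixel[1], pixel[2], ] + step
  if (mode == "central") {
    lower <- image
    lower[pixel[1], pixel[2], ] <- lower[pixel[1], pixel[2], ] - step
    return((model$predict(perturbed) - model$predict(lower)) / (2 * step))
  }
  if (is.null(baseline)) baseline <- model$predict(image)
  (model$predict(perturbed) - baseline) / step
}

# Normalize the region argument of compute_pd_map/batch_pd_map to a logical
# 299x299 matrix.
resolve_region <- function(region, labels = NULL) {
  if (is.character(region) && length(region) == 1L) {
    if (region == "all") {
      return(matrix(TRUE, PACKED_SIZE, PACKED_SIZE))
    }
    if (grepl("^labels:", region)) {
      if (is.null(labels)) stop("label region needs a label map", call. = FALSE)
      ids <- as.integer(strsplit(sub("^labels:", "", region), ",")[[1]])
      return(matrix(labels %in% ids, nrow(labels), ncol(labels)))
    }
    stop("unknown region \"", region, "\"", call. = FALSE)
  }
  region <- as_binary(region)
  if (all(dim(region) == SOURCE_SIZE)) region <- reduce_mask_299(region)
  if (!all(dim(region) == PACKED_SIZE)) {
    stop("region must be on the 299 or 598 grid", call. = FALSE)
  }
  region
}

#' Compute a finite-difference PD map over a region
#'
#' Evaluates [fd_pd_at_pixel()] at every pixel of the region.  The baseline
#' prediction is computed once and reused; the evaluation order does not
#' affect the result.  A 598-scale mask is reduced to the 299 model grid by
#' 2x2 majority vote (ties count as inside).
#'
#' @param model A `pd_regressor`.
#' @param image Packed 299x299x3 image.
#' @param region Logical matrix on the 299 or 598 grid, the string
#'   `"all"`, or `"labels:i,j,..."` together with `labels`.
#' @param step Perturbation step (default 1 intensity unit).
#' @param labels Optional 299x299 label map, needed for `"labels:..."`
#'   regions.
#' @param mode `"forward"` (default) or `"central"` differencing; see
#'   [fd_pd_at_pixel()].
#' @return A [pd_map].
#' @export
compute_pd_map <- function(model, image, region, step = 1, labels = NULL,
                           mode = c("forward", "central")) {
  mode <- match.arg(mode)
  if (mode == "central") {
    return(compute_pd_map_central(model, image, region, step, labels))
  }
  stopifnot(inherits(model, "pd_regressor"))
  assert_packed(image)
  region <- resolve_region(region, labels)
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty region", call. = FALSE)
  baseline <- model$predict(image)
  if (!is.finite(baseline)) stop("model returned a non-finite prediction",
                                 call. = FALSE)
  pd <- matrix(NA_real_, PACKED_SIZE, PACKED_SIZE)
  work <- image + 0 # private numeric copy, mutated and restored per pixel
  predict <- model$predict
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    old <- work[i, j, ]
    work[i, j, ] <- old + step
    f1 <- predict(work)
    work[i, j, ] <- old
    if (!is.finite(f1)) stop("model returned a non-finite prediction",
                             call. = FALSE)
    pd[i, j] <- (f1 - baseline) / step
  }
  new_pd_map(pd, region, baseline, step)
}

# Central-difference variant of compute_pd_map (behind the mode flag).
compute_pd_map_central <- function(model, image, region, step, labels) {
  assert_packed(image)
  region <- resolve_region(region, labels)
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty region", call. = FALSE)
  baseline <- model$predict(image)
  if (!is.finite(baseline)) stop("model returned a non-finite prediction",
                                 call. = FALSE)
  pd <- matrix(NA_real_, PACKED_SIZE, PACKED_SIZE)
  for (k in seq_len(nrow(idx))) {
    pd[idx[k, 1], idx[k, 2]] <-
      fd_pd_at_pixel(model, image, idx[k, ], step, mode = "central")
  }
  new_pd_map(pd, region, baseline, step)
}

#' Batched PD map
#'
#' Identical in result to [compute_pd_map()] but groups the perturbed
#' images into batches for regressors that provide `predict_batch`; models
#' without batch support fall back to the sequential path.  Per-pixel
#' arithmetic is unchanged, so the map is bit-identical to the sequential
#' one.
#'
#' @inheritParams compute_pd_map
#' @param batch_size Number of perturbed images per `predict_batch` call.
#' @return A [pd_map].
#' @export
batch_pd_map <- function(model, image, region, step = 1, batch_size = 64L,
                         labels = NULL) {
  stopifnot(inherits(model, "pd_regressor"))
  if (is.null(model$predict_batch)) {
    return(compute_pd_map(model, image, region, step, labels))
  }
  assert_packed(image)
  region <- resolve_region(region, labels)
  idx <- which(region, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty region", call. = FALSE)
  baseline <- model$predict(image)
  if (!is.finite(baseline)) stop("model returned a non-finite prediction",
                                 call. = FALSE)
  pd <- matrix(NA_real_, PACKED_SIZE, PACKED_SIZE)
  n <- nrow(idx)
  for (start in seq(1L, n, by = batch_size)) {
    rows <- start:min(start + batch_size - 1L, n)
    batch <- lapply(rows, function(k) {
      x <- image + 0
      x[idx[k, 1], idx[k, 2], ] <- x[idx[k, 1], idx[k, 2], ] + step
      x
    })
    f1 <- model$predict_batch(batch)
    if (length(f1) != length(rows) || !all(is.finite(f1))) {
      stop("predict_batch violated the contract", call. = FALSE)
    }
    pd[idx[rows, , drop = FALSE]] <- (f1 - baseline) / step
  }
  new_pd_map(pd, region, baseline, step)
}
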