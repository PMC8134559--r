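#' Subtract the background level from a radiograph
#'
#' Estimates a global background intensity and subtracts it, clipping at
#' zero.  The estimator and the level actually used are recorded in the
#' `"background"` attribute of the result.
#'
#' @param image Numeric intensity matrix.
#' @param estimator `"low-percentile"` (default): the background level is
#'   the `value`-th percentile of all intensities; or `"fixed-value"`: the
#'   level is `value` itself.
#' @param value Percentile in `(0, 50]` (default 1) or a non-negative
#'   fixed level.
#' @return The background-subtracted image (non-negative).
#' @export
subtract_background <- function(image,
                                estimator = c("low-percentile", "fixed-value"),
                                value = 1) {
  assert_gray(image)
  if (length(image) == 0) stop("image is empty", call. = FALSE)
  estimator <- match.arg(estimator)
  if (estimator == "low-percentile") {
    if (value <= 0 || value > 50) {
      stop("background percentile must be in (0, 50]", call. = FALSE)
    }
    level <- unname(stats::quantile(image, value / 100))
  } else {
    if (value < 0) stop("fixed background level must be >= 0", call. = FALSE)
    level <- value
  }
  out <- pmax(image - level, 0)
  attr(out, "background") <- list(estimator = estimator, value = value,
                                  level = level)
  out
}

#' Generate a binary hand mask
#'
#' Thresholds the image (Otsu by default), applies a morphological opening
#' (erode then dilate with a disc) to remove small isolated islands, and
#' keeps the largest connected foreground component.
#'
#' @param image Numeric intensity matrix with a nonzero range.
#' @param threshold `"otsu"` or a fixed numeric threshold; pixels strictly
#'   above it are foreground.
#' @param struct_radius Disc radius (pixels) of the opening structuring
#'   element; 0 skips the opening.  Default 5 at the 598-pixel scale.
#' @param keep_largest Keep only the largest connected component after the
#'   opening (default `TRUE`).
#' @return Logical mask matrix, same dimensions as `image`.
#' @export
generate_mask <- function(image, threshold = "otsu", struct_radius = 5,
                          keep_largest = TRUE) {
  assert_gray(image)
  rng <- range(image)
  if (diff(rng) == 0) {
    stop("constant image: no threshold separates foreground", call. = FALSE)
  }
  if (identical(threshold, "otsu")) {
    norm <- (image - rng[1]) / diff(rng)
    th <- EBImage::otsu(norm, range = c(0, 1)) * diff(rng) + rng[1]
  } else if (is.numeric(threshold)) {
    th <- threshold
  } else {
    stop("threshold must be \"otsu\" or a number", call. = FALSE)
  }
  bw <- image > th
  if (!any(bw)) stop("empty mask: nothing above threshold", call. = FALSE)
  if (struct_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(struct_radius) + 1L, "disc")
    bw <- EBImage::opening(ifelse(bw, 1, 0), brush) > 0.5
  }
  if (!any(bw)) stop("empty mask after cleanup", call. = FALSE)
  if (keep_largest) {
    lab <- EBImage::bwlabel(ifelse(bw, 1, 0))
    sizes <- tabulate(as.integer(lab[lab > 0]))
    bw <- lab == which.max(sizes)
  }
  matrix(as.logical(bw), nrow(image), ncol(image))
}

#' Zero the image outside the hand mask
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical mask of the same dimensions.
#' @return The masked image: unchanged inside the mask, exactly 0 outside.
#' @export
apply_mask <- function(image, mask) {
  assert_gray(image)
  mask <- as_binary(mask)
  assert_same_dim(image, mask)
  image * mask
}

#' Crop the hand into a square field of view and resize
#'
#' Crops a square window covering the mask's bounding box (expanded by
#' `margin_frac` of the box side and padded with zeros where it leaves the
#' frame), then resizes the window bilinearly to `out_size` x `out_size`.
#' The mask is transformed identically and re-binarized at 0.5; an optional
#' label map is transformed with nearest-neighbour resampling and clipped
#' to the transformed mask.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical mask (non-empty) on the same grid.
#' @param margin_frac Fractional margin added on every side of the bounding
#'   box (default 0).
#' @param labels Optional integer ROI label map on the same grid.
#' @param out_size Output side length (default 598).
#' @return List with `image`, `mask`, optionally `labels`, and `crop`
#'   (`row0`, `col0`, `side`: the 1-based origin and side of the square
#'   source window, for mapping coordinates back).
#' @export
crop_square_resize <- function(image, mask, margin_frac = 0, labels = NULL,
                               out_size = SOURCE_SIZE) {
  assert_gray(image)
  mask <- as_binary(mask)
  assert_same_dim(image, mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  side <- max(rr[2] - rr[1], cc[2] - cc[1]) + 1L
  side <- side + 2L * as.integer(round(margin_frac * side))
  r0 <- as.integer(floor((rr[1] + rr[2]) / 2) - (side - 1) %/% 2)
  c0 <- as.integer(floor((cc[1] + cc[2]) / 2) - (side - 1) %/% 2)

  window <- function(x, fill = 0) {
    out <- matrix(fill, side, side)
    rs <- max(r0, 1L):min(r0 + side - 1L, nrow(x))
    cs <- max(c0, 1L):min(c0 + side - 1L, ncol(x))
    out[rs - r0 + 1L, cs - c0 + 1L] <- x[rs, cs]
    out
  }
  img_w <- window(image)
  msk_w <- window(ifelse(mask, 1, 0))
  img_out <- EBImage::resize(img_w, w = out_size, h = out_size,
                             filter = "bilinear")
  msk_out <- EBImage::resize(msk_w, w = out_size, h = out_size,
                             filter = "bilinear") >= 0.5
  out <- list(image = matrix(img_out, out_size, out_size),
              mask = matrix(msk_out, out_size, out_size),
              crop = list(row0 = r0, col0 = c0, side = side))
  if (!is.null(labels)) {
    lab_w <- window(labels)
    lab_out <- EBImage::resize(lab_w, w = out_size, h = out_size,
                               filter = "none")
    lab_out <- matrix(as.integer(round(lab_out)), out_size, out_size)
    lab_out[!out$mask] <- 0L
    out$labels <- lab_out
  }
  out
}

#' Pack a 598x598 image into 2x2 cells over 3 channels
#'
#' Divides the image into 299x299 cells of 2x2 pixels.  Within each cell
#' (top row `a b`, bottom row `c d`) the bottom two pixels are copied to
#' channels 1 and 2 (`c` to channel 1, `d` to channel 2, left to right) and
#' the mean of the top two pixels, `(a + b) / 2`, to channel 3.
#'
#' @param image598 Numeric 598x598 matrix.
#' @return Real-valued 299x299x3 array (pre intensity scaling).
#' @export
pack_cells <- function(image598) {
  assert_gray(image598)
  if (!all(dim(image598) == SOURCE_SIZE)) {
    stop("pack_cells needs a ", SOURCE_SIZE, "x", SOURCE_SIZE, " image",
         call. = FALSE)
  }
  top <- seq(1L, SOURCE_SIZE - 1L, 2L)
  bot <- top + 1L
  a <- image598[top, top]
  b <- image598[top, bot]
  cc <- image598[bot, top]
  d <- image598[bot, bot]
  out <- array(0, c(PACKED_SIZE, PACKED_SIZE, 3L))
  out[, , 1] <- cc
  out[, , 2] <- d
  out[, , 3] <- (a + b) / 2
  out
}

#' Scale a packed image to the 0-254 integer range
#'
#' Maps `[min, max]` of the input affinely onto `[0, 254]` and rounds
#' half-up to integers.
#'
#' @param packed Real-valued 299x299x3 array with a nonzero range.
#' @return Integer 299x299x3 array with values in `[0, 254]`.
#' @export
rescale_to_254 <- function(packed) {
  assert_packed(packed)
  rng <- range(packed)
  if (diff(rng) == 0) stop("constant input cannot be rescaled", call. = FALSE)
  out <- round_half_up((packed - rng[1]) / diff(rng) * 254)
  storage.mode(out) <- "integer"
  out
}

#' Preprocessing configuration
#'
#' Collects the tunables of the image-preparation chain.
#'
#' @param background Background estimator (see [subtract_background()]).
#' @param background_value Percentile or fixed level.
#' @param threshold `"otsu"` or a fixed threshold for [generate_mask()].
#' @param struct_radius Opening disc radius (pixels at the input scale).
#' @param margin_frac Crop margin fraction.
#' @param flip Mirror the image left-right before processing (hands are
#'   assumed pre-oriented; this flag is the only orientation control).
#' @return A named list of class `preprocess_config`.
#' @export
preprocess_config <- function(background = "low-percentile",
                              background_value = 1, threshold = "otsu",
                              struct_radius = 5, margin_frac = 0,
                              flip = FALSE) {
  structure(list(background = background,
                 background_value = background_value, threshold = threshold,
                 struct_radius = struct_radius, margin_frac = margin_frac,
                 flip = flip),
            class = "preprocess_config")
}

#' Run the full image-preparation chain
#'
#' Background subtraction, hand masking (or a user-supplied mask), masking
#' to zero outside the hand, square crop + resize to 598x598, 2x2-cell
#' packing into 3 channels and 0-254 integer scaling.  The chain is fully
#' deterministic.
#'
#' @param image Raw grayscale intensity matrix.
#' @param config A [preprocess_config()].
#' @param mask Optional user-supplied logical mask (replaces
#'   [generate_mask()], e.g. for manually traced hands); same grid as
#'   `image`.
#' @param labels Optional ROI label map on the input grid, carried through
#'   the same geometric transform.
#' @return List: `packed` (integer 299x299x3), `image598`, `mask598`,
#'   `mask299` (2x2 majority reduction), optionally `labels598`/`labels299`,
#'   and `crop`.
#' @export
preprocess_image <- function(image, config = preprocess_config(),
                             mask = NULL, labels = NULL) {
  assert_gray(image)
  if (isTRUE(config$flip)) {
    image <- image[, ncol(image):1]
    if (!is.null(mask)) mask <- mask[, ncol(mask):1]
    if (!is.null(labels)) labels <- labels[, ncol(labels):1]
  }
  image <- subtract_background(image, config$background,
                               config$background_value)
  if (is.null(mask)) {
    mask <- generate_mask(image, config$threshold, config$struct_radius)
  } else {
    mask <- as_binary(mask)
    assert_same_dim(image, mask)
  }
  image <- apply_mask(image, mask)
  tr <- crop_square_resize(image, mask, config$margin_frac, labels = labels)
  packed <- rescale_to_254(pack_cells(tr$image))
  out <- list(packed = packed, image598 = tr$image, mask598 = tr$mask,
              mask299 = reduce_mask_299(tr$mask), crop = tr$crop)
  if (!is.null(labels)) {
    out$labels598 <- tr$labels
    out$labels299 <- reduce_labels_299(tr$labels)
    out$labels299[!out$mask299] <- 0L
  }
  out
}

#' Reduce a 598-scale mask or label map to the 299 model grid
#'
#' `reduce_mask_299()` takes a majority vote over each 2x2 cell (ties count
#' as inside).  `reduce_labels_299()` assigns each cell the most frequent
#' label; ties between ROI labels go to the smaller label, and the
#' unassigned label 0 wins only by strict majority (3 or 4 of the 4
#' pixels).
#'
#' @param mask598,labels598 598x598 logical mask / integer label map.
#' @return 299x299 logical mask / integer label map.
#' @export
reduce_mask_299 <- function(mask598) {
  mask598 <- as_binary(mask598)
  stopifnot(all(dim(mask598) == SOURCE_SIZE))
  top <- seq(1L, SOURCE_SIZE - 1L, 2L)
  bot <- top + 1L
  cnt <- mask598[top, top] + mask598[top, bot] +
    mask598[bot, top] + mask598[bot, bot]
  cnt >= 2L
}

#' @rdname reduce_mask_299
#' @export
reduce_labels_299 <- function(labels598) {
  stopifnot(is.matrix(labels598), all(dim(labels598) == SOURCE_SIZE))
  top <- seq(1L, SOURCE_SIZE - 1L, 2L)
  bot <- top + 1L
  cells <- list(labels598[top, top], labels598[top, bot],
                labels598[bot, top], labels598[bot, bot])
  ids <- sort(setdiff(unique(as.integer(labels598)), 0L))
  best_cnt <- matrix(-1L, PACKED_SIZE, PACKED_SIZE)
  best_lab <- matrix(0L, PACKED_SIZE, PACKED_SIZE)
  count_of <- function(id) {
    (cells[[1]] == id) + (cells[[2]] == id) +
      (cells[[3]] == id) + (cells[[4]] == id)
  }
  for (id in ids) { # ascending: ties between ROI labels keep the smaller
    cnt <- count_of(id)
    take <- cnt > best_cnt
    best_cnt[take] <- cnt[take]
    best_lab[take] <- id
  }
  cnt0 <- count_of(0L)
  take0 <- cnt0 > best_cnt # label 0 needs a strict majority
  best_lab[take0] <- 0L
  best_lab
}
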