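#' Sigmoid compression of PD values for display
#'
#' Maps a PD value onto `(-1, 1)` with `tanh(pd / T)`: an odd, strictly
#' monotone transform whose extremes correspond to PD -> +/- infinity, so a
#' diverging colormap's two ends are hit only in the limit.  `T` is the
#' display threshold: the PD magnitude at which the score reaches
#' `tanh(1) ~ 0.76` of the color scale.  With `clamp = TRUE` the smooth
#' saturation is replaced by a hard clamp of `pd / T` to `[-1, 1]`.
#'
#' @param pd PD value(s), months per intensity unit.
#' @param threshold Display threshold `T > 0` (default 4e-3, the in-mask
#'   convention; use 4e-2 for outside-mask maps, whose PDs run an order of
#'   magnitude larger).
#' @param clamp Hard-clamp instead of smooth tanh saturation.
#' @return Scores in `[-1, 1]`.
#' @export
sigmoid_score <- function(pd, threshold = 4e-3, clamp = FALSE) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  if (clamp) pmin(pmax(pd / threshold, -1), 1) else tanh(pd / threshold)
}

#' Overlay display settings
#'
#' @param threshold Display threshold `T` (months per intensity unit).
#' @param opacity Overlay opacity in `[0, 1]` (default 0.5).
#' @param clamp Hard clamp instead of tanh (see [sigmoid_score()]).
#' @param colormap Colormap name; `"blue-red"` (the default) is a diverging
#'   blue-white-red map with a neutral midpoint.
#' @return An `overlay_spec` list.
#' @export
overlay_spec <- function(threshold = 4e-3, opacity = 0.5, clamp = FALSE,
                         colormap = "blue-red") {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (opacity < 0 || opacity > 1) stop("opacity must be in [0, 1]",
                                       call. = FALSE)
  structure(list(threshold = threshold, opacity = opacity, clamp = clamp,
                 colormap = colormap),
            class = "overlay_spec")
}

# Map scores in [-1, 1] to RGB: blue (-1) -> white (0) -> red (+1).
# Midpoint-symmetric: negating the score swaps the R and B channels.
diverging_rgb <- function(score, colormap = "blue-red") {
  if (colormap != "blue-red") stop("unknown colormap", call. = FALSE)
  list(r = pmin(1, 1 + score), g = 1 - abs(score), b = pmin(1, 1 - score))
}

#' Render a PD map as a color overlay on the anatomical image
#'
#' Sigmoid-compresses the PD values, maps them through a diverging
#' colormap, and alpha-composites the colors onto the grayscale anatomy.
#' Pixels without a computed PD show the anatomy only.  A 299-grid PD map
#' is upsampled to a 598-grid anatomy by 2x2 pixel replication.
#'
#' @param pdmap A [pd_map] (299 grid).
#' @param anatomy Grayscale matrix at the 299 or 598 scale, or a packed
#'   299x299x3 image (collapsed to its channel mean).
#' @param spec An [overlay_spec()].
#' @return RGB array (`H x W x 3`, values in `[0, 1]`), ready for
#'   [write_rgb_png()].
#' @export
render_overlay <- function(pdmap, anatomy, spec = overlay_spec()) {
  stopifnot(inherits(pdmap, "pd_map"), inherits(spec, "overlay_spec"))
  if (is.array(anatomy) && length(dim(anatomy)) == 3L) {
    anatomy <- (anatomy[, , 1] + anatomy[, , 2] + anatomy[, , 3]) / 3
  }
  assert_gray(anatomy, "anatomy")
  pd <- pdmap$pd
  computed <- pdmap$computed
  if (!identical(dim(anatomy), dim(pd))) {
    fac <- dim(anatomy)[1] / dim(pd)[1]
    if (fac != 2 || !identical(dim(anatomy), dim(pd) * 2L)) {
      stop("misaligned grids: anatomy ", paste(dim(anatomy), collapse = "x"),
           " vs PD map ", paste(dim(pd), collapse = "x"), call. = FALSE)
    }
    up <- matrix(1, 2, 2)
    pd <- kronecker(pd, up)
    computed <- kronecker(computed, up) > 0
  }
  rng <- range(anatomy)
  gray <- if (diff(rng) > 0) (anatomy - rng[1]) / diff(rng) else anatomy * 0
  score <- sigmoid_score(pd, spec$threshold, spec$clamp)
  col <- diverging_rgb(score, spec$colormap)
  a <- spec$opacity
  out <- array(0, c(dim(gray), 3L))
  for (ch in 1:3) {
    tint <- (1 - a) * gray + a * switch(ch, col$r, col$g, col$b)
    plane <- gray
    plane[computed] <- tint[computed]
    out[, , ch] <- plane
  }
  out
}

#' Render anatomy and overlay side by side
#'
#' @inheritParams render_overlay
#' @return RGB array with the grayscale anatomy on the left and the
#'   overlay on the right.
#' @export
render_panel <- function(pdmap, anatomy, spec = overlay_spec()) {
  right <- render_overlay(pdmap, anatomy, spec)
  h <- dim(right)[1]; w <- dim(right)[2]
  left <- render_overlay(pdmap, anatomy, overlay_spec(spec$threshold,
                                                      opacity = 0))
  out <- array(0, c(h, 2L * w, 3L))
  out[, 1:w, ] <- left
  out[, (w + 1):(2 * w), ] <- right
  out
}

#' Write an RGB array as PNG
#'
#' @param rgb `H x W x 3` array with values in `[0, 1]`.
#' @param path Output path.
#' @export
write_rgb_png <- function(rgb, path) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L)
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}
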