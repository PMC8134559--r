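#' Phantom specification
#'
#' Parameters of the synthetic hand-like radiograph generator.  Identical
#' specs produce bit-identical phantoms (image, mask, labels).
#'
#' @param seed Integer seed driving island placement and noise.
#' @param age_months "Age" parameter in months, within the 15-216 month
#'   range the probe is designed for; it controls the width and contrast of
#'   the bone-like bright cores.
#' @param frame Square frame side in pixels (default 598; minimum 200).
#'   All geometry scales with `frame / 598`.
#' @param background Dark background level (default 10 on the 0-255 scale).
#' @param noise_sd Gaussian intensity noise SD (default 2; the ground-truth
#'   mask is always the noiseless silhouette).
#' @param n_islands Count of small isolated bright background islands
#'   (default 3), placed in the strip above the hand to exercise mask
#'   cleanup.
#' @param island_radius Island disc radius in pixels (default 3, i.e.
#'   diameter 7, below the default opening diameter of 11).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(seed = 1L, age_months = 120, frame = 598L,
                         background = 10, noise_sd = 2, n_islands = 3L,
                         island_radius = 3L) {
  if (age_months < 15 || age_months > 216) {
    stop("age_months must be within [15, 216]", call. = FALSE)
  }
  if (frame < 200L) stop("frame too small for the hand silhouette",
                         call. = FALSE)
  structure(list(seed = as.integer(seed), age_months = age_months,
                 frame = as.integer(frame), background = background,
                 noise_sd = noise_sd, n_islands = as.integer(n_islands),
                 island_radius = as.integer(island_radius)),
            class = "phantom_spec")
}

# Distance from grid points to a line segment (r1,c1)-(r2,c2).
seg_dist <- function(rw, cl, r1, c1, r2, c2) {
  dr <- r2 - r1; dc <- c2 - c1
  len2 <- dr * dr + dc * dc
  t <- pmin(pmax(((rw - r1) * dr + (cl - c1) * dc) / len2, 0), 1)
  sqrt((rw - (r1 + t * dr))^2 + (cl - (c1 + t * dc))^2)
}

#' Generate a synthetic hand phantom
#'
#' Builds a bright hand-shaped silhouette (wrist block, palm ellipse, four
#' finger capsules and a slanted thumb capsule) on a dark background, with
#' bone-like bright cores whose width and contrast increase monotonically
#' with `age_months`, optional isolated bright background islands, and
#' optional Gaussian noise.  The silhouette is constructed as the dilation
#' of a geometric skeleton by the same disc brush (radius
#' `round(5 * frame / 598)`) that [generate_mask()] uses for its opening by
#' default, so on a noise-free phantom the default mask pipeline recovers
#' the ground-truth mask exactly.
#'
#' Ground-truth five-ROI labels mirror the anatomical roles used on real
#' radiographs: 1 = wrist, 2 = five disconnected mid-metacarpal bands,
#' 3 = five metacarpal-phalanx joint patches, 4 = finger regions,
#' 5 = a small thumb-web muscle patch between digits 1 and 2.  Labels are
#' pairwise disjoint and lie inside the mask.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_bundle`: `image` (raw intensities), `mask`
#'   (ground-truth logical), `labels` (ground-truth integer map),
#'   `roi_counts` (declared per-ROI pixel counts), `age_months`, `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  f <- spec$frame
  s <- f / 598
  rw <- .row(c(f, f)); cl <- .col(c(f, f))

  finger_cols <- c(225, 275, 325, 375) * s
  finger_tops <- c(170, 140, 155, 200) * s
  finger_base <- 375 * s # deep enough that every digit merges with the palm

  skel <- (rw >= 460 * s & rw <= 545 * s & cl >= 245 * s & cl <= 355 * s) |
    (((rw - 390 * s) / (65 * s))^2 + ((cl - 300 * s) / (85 * s))^2 <= 1)
  for (k in 1:4) {
    skel <- skel | (rw >= finger_tops[k] & rw <= finger_base &
                      abs(cl - finger_cols[k]) <= 6 * s)
  }
  thumb_d <- seg_dist(rw, cl, 430 * s, 225 * s, 350 * s, 120 * s)
  skel <- skel | (thumb_d <= 7 * s)

  radius <- max(1L, as.integer(round(5 * s)))
  brush <- EBImage::makeBrush(2L * radius + 1L, "disc")
  mask <- EBImage::dilate(ifelse(skel, 1, 0), brush) > 0.5
  mask <- matrix(mask, f, f)

  # bone-like cores: width and contrast grow monotonically with age
  t_age <- (spec$age_months - 15) / 201
  hw <- (1 + 3 * t_age) * s
  boost <- 30 + 60 * t_age
  core <- matrix(FALSE, f, f)
  for (k in 1:4) {
    core <- core | (rw >= finger_tops[k] & rw <= 445 * s &
                      abs(cl - finger_cols[k]) <= hw)
  }
  core <- core | (thumb_d <= hw)
  for (p in list(c(480, 270), c(480, 330), c(510, 300))) {
    core <- core | ((rw - p[1] * s)^2 + (cl - p[2] * s)^2 <=
                      ((4 + 4 * t_age) * s)^2)
  }
  core <- core & mask

  image <- matrix(spec$background, f, f) + 130 * mask + boost * core
  image <- with_seed(spec$seed, {
    if (spec$n_islands > 0) {
      ir <- spec$island_radius
      for (i in seq_len(spec$n_islands)) {
        pr <- stats::runif(1, 25 * s, 85 * s)
        pc <- stats::runif(1, (30 + 180 * (i - 1)) * s, (150 + 180 * (i - 1)) * s)
        image[(rw - pr)^2 + (cl - pc)^2 <= ir^2] <- spec$background + 190
      }
    }
    if (spec$noise_sd > 0) {
      image <- image + matrix(stats::rnorm(f * f, 0, spec$noise_sd), f, f)
    }
    image
  })

  labels <- matrix(0L, f, f)
  assign_roi <- function(labels, sel, id) {
    sel <- sel & mask & labels == 0L
    labels[sel] <- id
    labels
  }
  labels <- assign_roi(labels, rw >= 450 * s, 1L)
  band2 <- matrix(FALSE, f, f)
  for (k in 1:4) {
    band2 <- band2 | (rw >= 368 * s & rw <= 398 * s &
                        abs(cl - finger_cols[k]) <= 10 * s)
  }
  band2 <- band2 | (rw >= 405 * s & rw <= 425 * s &
                      cl >= 230 * s & cl <= 250 * s)
  labels <- assign_roi(labels, band2, 2L)
  joint3 <- matrix(FALSE, f, f)
  for (k in 1:4) {
    joint3 <- joint3 | (rw >= 315 * s & rw <= 340 * s &
                          abs(cl - finger_cols[k]) <= 10 * s)
  }
  joint3 <- joint3 | (rw >= 380 * s & rw <= 400 * s &
                        cl >= 162 * s & cl <= 183 * s)
  labels <- assign_roi(labels, joint3, 3L)
  labels <- assign_roi(labels, rw <= 310 * s, 4L)
  labels <- assign_roi(labels,
                       (rw - 405 * s)^2 + (cl - 210 * s)^2 <= (14 * s)^2, 5L)

  counts <- vapply(1:5, function(id) sum(labels == id), 0L)
  names(counts) <- paste0("roi", 1:5)
  structure(list(image = image, mask = mask, labels = labels,
                 roi_counts = counts, age_months = spec$age_months,
                 spec = spec),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat("<phantom_bundle> frame", x$spec$frame, "age", x$age_months,
      "months, mask px:", sum(x$mask), "\n")
  cat("  ROI px:", paste(names(x$roi_counts), x$roi_counts,
                         collapse = ", "), "\n")
  invisible(x)
}

#' Generate a seeded phantom cohort
#'
#' Draws `n` ages from a uniform distribution on `age_range` under one
#' master seed, derives an independent sub-seed per phantom, and generates
#' the bundles.  Optionally writes each bundle and an `ages.csv`
#' (columns `image_id`, `age_months`) to `dir`.
#'
#' @param n Number of phantoms (>= 1).
#' @param seed Master seed.
#' @param age_range Uniform age range in months (default `c(15, 216)`).
#' @param dir Optional output directory.
#' @param ... Further arguments passed to [phantom_spec()] (e.g.
#'   `noise_sd`, `n_islands`).
#' @return List: `bundles` (named by image id), `ages` (data frame).
#' @export
make_cohort <- function(n, seed = 1L, age_range = c(15, 216), dir = NULL,
                        ...) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  draws <- with_seed(seed, list(
    ages = stats::runif(n, age_range[1], age_range[2]),
    seeds = sample.int(.Machine$integer.max - 1L, n)
  ))
  ids <- sprintf("ph%03d", seq_len(n))
  bundles <- lapply(seq_len(n), function(i) {
    make_phantom(phantom_spec(seed = draws$seeds[i],
                              age_months = draws$ages[i], ...))
  })
  names(bundles) <- ids
  ages <- data.frame(image_id = ids, age_months = draws$ages)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) write_phantom_bundle(bundles[[i]], dir, ids[i])
    utils::write.csv(ages, file.path(dir, "ages.csv"), row.names = FALSE)
  }
  list(bundles = bundles, ages = ages)
}

#' Write a phantom bundle to disk
#'
#' Writes `<id>_image.png`, `<id>_mask.png` and `<id>_labels.png`.
#'
#' @param bundle A `phantom_bundle`.
#' @param dir Output directory.
#' @param id Image id used as the file-name stem.
#' @export
write_phantom_bundle <- function(bundle, dir, id) {
  stopifnot(inherits(bundle, "phantom_bundle"))
  write_gray_png(bundle$image, file.path(dir, paste0(id, "_image.png")))
  write_mask_png(bundle$mask, file.path(dir, paste0(id, "_mask.png")))
  write_label_png(bundle$labels, file.path(dir, paste0(id, "_labels.png")))
  invisible(file.path(dir, id))
}
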