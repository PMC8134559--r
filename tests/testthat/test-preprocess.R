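test_that("background subtraction removes the estimated level and clips at 0", {
  uniform <- matrix(40, 20, 20)
  expect_equal(subtract_background(uniform, "fixed-value", 40),
               matrix(0, 20, 20), ignore_attr = TRUE)

  clean <- matrix(0, 20, 20); clean[5:10, 5:10] <- 100
  out <- subtract_background(clean, "low-percentile", 1)
  expect_equal(out, clean, ignore_attr = TRUE)

  two <- matrix(10, 40, 40); two[11:20, 11:20] <- 200
  out <- subtract_background(two, "low-percentile", 5)
  expect_setequal(unique(as.vector(out)), c(0, 190))
  expect_equal(attr(out, "background")$level, 10)

  expect_error(subtract_background(two, "low-percentile", 60), "\\(0, 50]")
  expect_error(subtract_background(two, "fixed-value", -1), ">= 0")
})

test_that("mask generation thresholds, removes islands, keeps the hand", {
  core <- matrix(0, 598, 598); core[205:394, 205:394] <- 1
  blob <- EBImage::dilate(core, EBImage::makeBrush(11, "disc")) > 0.5
  img <- matrix(5, 598, 598)
  img[blob] <- 200 # ~200x200 blob with disc-rounded corners
  for (at in list(c(30, 30), c(30, 560), c(560, 30))) {
    img[at[1]:(at[1] + 2), at[2]:(at[2] + 2)] <- 220 # 3x3 islands
  }
  mask <- generate_mask(img, struct_radius = 5)
  expect_identical(mask, matrix(blob, 598, 598))

  expect_error(generate_mask(matrix(0, 50, 50)), "constant image")
  dark <- matrix(1, 50, 50); dark[1, 1] <- 2
  expect_error(generate_mask(dark, threshold = 5), "empty mask")
})

test_that("default mask pipeline recovers the phantom ground truth exactly", {
  ph <- clean_phantom()
  expect_identical(generate_mask(ph$image), ph$mask)
  # idempotence: regenerating from the masked image gives the same mask
  masked <- apply_mask(ph$image, ph$mask)
  expect_identical(generate_mask(masked), ph$mask)
})

test_that("masking zeroes the outside and is idempotent", {
  ph <- clean_phantom()
  img <- ph$image
  full <- matrix(TRUE, nrow(img), ncol(img))
  expect_identical(apply_mask(img, full), img)

  masked <- apply_mask(img, ph$mask)
  expect_identical(sum(masked[!ph$mask]), 0)
  expect_identical(masked[ph$mask], img[ph$mask])
  expect_identical(apply_mask(masked, ph$mask), masked)

  expect_error(apply_mask(img, matrix(TRUE, 2, 2)), "dimension mismatch")
})

test_that("square crop-resize has the contracted geometry", {
  ph <- clean_phantom()
  out <- crop_square_resize(ph$image, ph$mask, margin_frac = 0)
  expect_identical(dim(out$image), c(598L, 598L))
  expect_identical(dim(out$mask), c(598L, 598L))

  # an image whose mask fills a square frame needs no crop: pure resize
  sq <- matrix(runif(100 * 100), 100, 100) + 1
  full <- matrix(TRUE, 100, 100)
  pure <- crop_square_resize(sq, full)
  expect_identical(pure$crop, list(row0 = 1L, col0 = 1L, side = 100L))
  expect_equal(pure$image,
               matrix(EBImage::resize(sq, 598, 598, filter = "bilinear"),
                      598, 598))

  # bounding-box corners of the resized mask map back to the original
  # bounding box within 1 source pixel under the inverse affine transform
  rr <- range(which(rowSums(out$mask) > 0))
  cc <- range(which(colSums(out$mask) > 0))
  sc <- out$crop$side / 598
  back_r <- (c(rr[1], rr[2]) - 0.5) * sc + 0.5 + (out$crop$row0 - 1)
  back_c <- (c(cc[1], cc[2]) - 0.5) * sc + 0.5 + (out$crop$col0 - 1)
  orig_r <- range(which(rowSums(ph$mask) > 0))
  orig_c <- range(which(colSums(ph$mask) > 0))
  expect_lt(max(abs(back_r - orig_r)), 1 + sc)
  expect_lt(max(abs(back_c - orig_c)), 1 + sc)

  expect_error(crop_square_resize(ph$image, matrix(FALSE, 598, 598)),
               "empty mask")
})

test_that("cell packing follows the bottom-row / top-mean rule", {
  v <- matrix(7, 598, 598)
  pk <- pack_cells(v)
  expect_equal(pk, array(7, c(299, 299, 3)))

  one <- matrix(0, 598, 598)
  one[1, 1] <- 10; one[1, 2] <- 20; one[2, 1] <- 30; one[2, 2] <- 40
  pk <- pack_cells(one)
  expect_equal(pk[1, 1, ], c(30, 40, 15))

  checker <- matrix(0, 598, 598)
  checker[(row(checker) + col(checker)) %% 2 == 0] <- 100
  expect_equal(pack_cells(checker)[, , 3], matrix(50, 299, 299))

  expect_error(pack_cells(matrix(0, 100, 100)), "598")
})

test_that("packing is lossless for bottom rows and top-row means", {
  set.seed(42)
  for (rep in 1:3) {
    img <- matrix(runif(598 * 598, 0, 255), 598, 598)
    pk <- pack_cells(img)
    bot <- seq(2, 598, 2); top <- seq(1, 597, 2); lft <- seq(1, 597, 2)
    expect_identical(pk[, , 1], img[bot, lft])
    expect_identical(pk[, , 2], img[bot, lft + 1])
    expect_equal(pk[, , 3], (img[top, lft] + img[top, lft + 1]) / 2)
  }
})

test_that("0-254 rescaling maps the range affinely with half-up rounding", {
  base <- array(0, c(299, 299, 3))
  two <- base; two[1] <- 1
  out <- rescale_to_254(two)
  expect_setequal(unique(as.vector(out)), c(0L, 254L))

  set.seed(7)
  r <- base; r[] <- runif(length(base), -3, 17)
  sc <- rescale_to_254(r)
  expect_identical(range(sc), c(0L, 254L))
  expect_true(all(sc == floor((r - min(r)) / diff(range(r)) * 254 + 0.5)))

  expect_error(rescale_to_254(base), "constant")
})

test_that("the preprocessing chain is deterministic and conserves mask area", {
  ph <- clean_phantom()
  a <- preprocess_image(ph$image, labels = ph$labels)
  b <- preprocess_image(ph$image, labels = ph$labels)
  expect_identical(a$packed, b$packed)
  expect_identical(a$mask299, b$mask299)
  expect_identical(a$labels299, b$labels299)

  # area fraction before vs after crop+resize (margin 0): < 5% relative
  frac_before <- sum(ph$mask) / a$crop$side^2
  frac_after <- sum(a$mask598) / 598^2
  expect_lt(abs(frac_after - frac_before) / frac_before, 0.05)
})

test_that("598-grid masks and labels reduce to the 299 grid by majority", {
  m <- matrix(FALSE, 598, 598)
  m[1, 1] <- TRUE                  # 1 of 4: outside
  m[1, 3] <- TRUE; m[2, 4] <- TRUE # 2 of 4 (tie): inside
  m[3:4, 1:2] <- TRUE              # 4 of 4: inside
  red <- reduce_mask_299(m)
  expect_identical(red[1, 1], FALSE)
  expect_identical(red[1, 2], TRUE)
  expect_identical(red[2, 1], TRUE)
  expect_identical(sum(red), 2L)

  lab <- matrix(0L, 598, 598)
  lab[1, 1] <- 2L; lab[2, 1] <- 2L
  lab[1, 2] <- 4L; lab[2, 2] <- 4L                            # 2-2 tie
  lab[3, 1] <- 5L                                             # 1 vs 3 zeros
  lab[5:6, 1:2] <- 3L                                         # unanimous
  red <- reduce_labels_299(lab)
  expect_identical(red[1, 1], 2L) # ROI tie -> smaller label
  expect_identical(red[2, 1], 0L) # zero wins only by strict majority
  expect_identical(red[3, 1], 3L)
})
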