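# Build a pd_map directly from a value grid for ROI-statistics tests.
pdmap_from <- function(values, computed = !is.na(values), baseline = 100,
                       step = 1) {
  values[!computed] <- NA_real_
  new_pd_map(values, computed, baseline, step)
}

test_that("mean APD averages absolute PDs over computed ROI pixels", {
  lab <- matrix(0L, 10, 10)
  lab[1:4, 1:4] <- 1L
  pd <- matrix(NA_real_, 10, 10)

  pd[lab == 1L] <- 0.02
  expect_equal(as.numeric(mean_apd(pdmap_from(pd), lab, 1)), 0.02)

  pd[lab == 1L] <- rep(c(0.02, -0.02), 8)
  expect_equal(as.numeric(mean_apd(pdmap_from(pd), lab, 1)), 0.02)

  set.seed(11)
  pd[lab == 1L] <- rnorm(16, 0, 5e-3)
  m <- mean_apd(pdmap_from(pd), lab, 1)
  expect_equal(as.numeric(m), sum(abs(pd[lab == 1L])) / 16) # brute force
  expect_identical(attr(m, "excluded"), 0L)

  # labeled pixels without a computed PD are excluded and counted
  computed <- !is.na(pd); computed[1, 1:2] <- FALSE
  m <- mean_apd(pdmap_from(pd, computed), lab, 1)
  expect_equal(as.numeric(m), mean(abs(pd[lab == 1L & computed])))
  expect_identical(attr(m, "excluded"), 2L)

  expect_error(mean_apd(pdmap_from(pd), lab, 3), "no pixels")
})

test_that("relative mean APD normalizes over ROIs 1-4 on a shared scale", {
  rec <- data.frame(roi = 1:4, mean_apd = rep(3e-3, 4))
  out <- relative_mean_apd(rec)
  expect_equal(out$rel_mean_apd, rep(0.25, 4))

  rec <- data.frame(roi = 1:5, mean_apd = c(2, 1, 1, 1, 5) * 1e-3)
  out <- relative_mean_apd(rec)
  expect_equal(out$rel_mean_apd, c(0.4, 0.2, 0.2, 0.2, 1.0))
  expect_equal(sum(out$rel_mean_apd[out$roi %in% 1:4]), 1)

  set.seed(3)
  for (i in 1:20) {
    rec <- data.frame(roi = 1:5, mean_apd = runif(5, 1e-4, 1e-2))
    out <- relative_mean_apd(rec)
    expect_lt(abs(sum(out$rel_mean_apd[1:4]) - 1), 1e-12)
  }

  expect_error(relative_mean_apd(data.frame(roi = c(1, 2, 3),
                                            mean_apd = 1:3)), "missing")
  expect_error(relative_mean_apd(data.frame(roi = 1:4, mean_apd = rep(0, 4))),
               "positive")
})

test_that("ROI area fractions are percentages of the mask", {
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  lab <- matrix(0L, 20, 20)
  lab[1:10, 1:10] <- 1L
  expect_equal(area_fraction(lab, mask, 1), 100)
  lab[] <- 0L; lab[1:5, 1:5] <- 2L
  expect_equal(area_fraction(lab, mask, 2), 25)
  expect_error(area_fraction(lab, matrix(FALSE, 20, 20), 2), "empty mask")

  # phantom ground truth: declared counts drive the fractions
  ph <- clean_phantom()
  for (r in 1:5) {
    expect_equal(area_fraction(ph$labels, ph$mask, r),
                 100 * ph$roi_counts[[r]] / sum(ph$mask))
  }
})

test_that("scaling a PD map scales mean APD but not relative mean APD", {
  ph <- clean_phantom()
  lab299 <- clean_prep()$labels299
  set.seed(5)
  pd <- matrix(NA_real_, 299, 299)
  pd[lab299 > 0] <- rnorm(sum(lab299 > 0), 0, 4e-3)
  base <- roi_stats(pdmap_from(pd), lab299, clean_prep()$mask299)
  k <- 7.5
  scaled <- roi_stats(pdmap_from(pd * k), lab299, clean_prep()$mask299)
  expect_equal(scaled$mean_apd, k * base$mean_apd)
  expect_equal(scaled$rel_mean_apd, base$rel_mean_apd)
})

test_that("trend regression matches the closed-form OLS oracle", {
  ages <- seq(10, 100, 10)
  exact <- 0.001 * ages + 0.2
  # exact fits are accepted silently (the affine-surrogate case)
  expect_silent(fit <- trend_regression(exact, ages, roi = 2L))
  expect_equal(fit$slope, 0.001)
  expect_equal(fit$intercept, 0.2)
  expect_identical(fit$n, 10L)

  flat <- trend_regression(rep(0.4, 10), ages)
  expect_equal(flat$slope, 0, tolerance = 1e-12)

  # five-point fixture, frozen from the hand-computed normal equations
  x <- c(12, 60, 120, 180, 216)
  y <- c(0.30, 0.28, 0.24, 0.21, 0.20)
  fit <- trend_regression(y, x, roi = 1L)
  expect_equal(fit$slope, -0.00051505817932922659)
  expect_equal(fit$intercept, 0.30657084188911704)
  expect_equal(fit$p_value, 0.0004535531774923447)

  expect_error(trend_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(trend_regression(c(1, 2, 3), c(5, 5, 5)), "constant ages")
})

test_that("cohort table reports per-ROI mean and sample SD", {
  one <- data.frame(image_id = "a", roi = 1:2,
                    area_pct = c(20, 10), mean_apd = c(4e-3, 6e-3),
                    rel_mean_apd = NA, excluded_px = 0L)
  two <- one; two$image_id <- "b"
  tab <- cohort_table(rbind(one, two))
  expect_equal(tab$area_pct_sd, c(0, 0))
  expect_equal(tab$mean_apd_sd, c(0, 0))

  two$mean_apd <- c(6e-3, 6e-3)
  tab <- cohort_table(rbind(one, two))
  expect_equal(tab$mean_apd_mean[1], 5e-3)
  expect_equal(tab$mean_apd_sd[1], sqrt(sum((c(4, 6) * 1e-3 - 5e-3)^2)))

  expect_error(cohort_table(one), "at least 2")

  # independent aggregation oracle on seeded records
  set.seed(21)
  recs <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(image_id = sprintf("im%02d", i), roi = 1:5,
               area_pct = runif(5, 1, 40), mean_apd = runif(5, 1e-3, 1e-2),
               rel_mean_apd = NA, excluded_px = 0L)
  }))
  tab <- cohort_table(recs)
  for (r in 1:5) {
    v <- recs$mean_apd[recs$roi == r]
    expect_equal(tab$mean_apd_mean[tab$roi == r], sum(v) / length(v))
    expect_equal(tab$mean_apd_sd[tab$roi == r],
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
    expect_identical(tab$n[tab$roi == r], 20L)
  }
})

test_that("slope recovery and test power hold on synthetic trend data", {
  # y = s*age + c + N(0, sigma^2), ages uniform on the probe's design range
  s_true <- -5e-4; c_true <- 0.42; sigma <- 0.03; n <- 100
  cover <- 0L; reject <- 0L
  set.seed(77)
  n_cover <- 500L; n_power <- 200L
  for (i in seq_len(n_cover)) {
    ages <- runif(n, 15, 216)
    y <- s_true * ages + c_true + rnorm(n, 0, sigma)
    fit <- stats::lm(y ~ ages)
    se <- summary(fit)$coefficients["ages", 2]
    if (abs(stats::coef(fit)["ages"] - s_true) <= 3 * se) cover <- cover + 1L
    if (i <= n_power) {
      p <- trend_regression(y, ages)$p_value
      if (p < 0.05) reject <- reject + 1L
    }
  }
  expect_gte(cover / n_cover, 0.99)
  expect_gte(reject / n_power, 0.80)
})
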