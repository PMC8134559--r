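#' Mean absolute PD over one ROI
#'
#' Averages `|PD|` over the pixels of one ROI that carry a computed PD.
#' Labeled pixels without a computed PD (e.g. at the edge of the mask
#' reduction) are excluded; the exclusion count is attached as attribute
#' `"excluded"`.
#'
#' @param pdmap A [pd_map].
#' @param labels Integer ROI label map aligned to the PD grid.
#' @param roi ROI id (1-5).
#' @return Mean APD in months per intensity unit.
#' @export
mean_apd <- function(pdmap, labels, roi) {
  stopifnot(inherits(pdmap, "pd_map"), is.matrix(labels))
  assert_same_dim(pdmap$pd, labels, "labels")
  in_roi <- labels == roi
  usable <- in_roi & pdmap$computed
  if (!any(usable)) {
    stop("ROI ", roi, " has no pixels with a computed PD", call. = FALSE)
  }
  out <- mean(abs(pdmap$pd[usable]))
  attr(out, "excluded") <- sum(in_roi) - sum(usable)
  out
}

#' ROI area as a percentage of the hand mask
#'
#' @param labels Integer ROI label map.
#' @param mask Logical hand mask on the same grid (non-empty).
#' @param roi ROI id.
#' @return `100 * (ROI pixel count) / (mask pixel count)`.
#' @export
area_fraction <- function(labels, mask, roi) {
  stopifnot(is.matrix(labels))
  mask <- as_binary(mask)
  assert_same_dim(labels, mask, "mask")
  if (!any(mask)) stop("empty mask", call. = FALSE)
  100 * sum(labels == roi) / sum(mask)
}

#' Relative mean APD within one image
#'
#' Divides each ROI's mean APD by the sum of the mean APDs of the
#' normalization set (ROIs 1-4 by convention).  ROI 5 is normalized by the
#' same denominator, so its relative values live on the shared scale; the
#' relative values of the normalization set sum to exactly 1.
#'
#' @param records Data frame with one row per ROI of a single image,
#'   columns `roi` and `mean_apd`.
#' @param norm_set ROI ids forming the denominator (default `1:4`).
#' @return `records` with a `rel_mean_apd` column added.
#' @export
relative_mean_apd <- function(records, norm_set = 1:4) {
  stopifnot(is.data.frame(records),
            all(c("roi", "mean_apd") %in% names(records)))
  if (!all(norm_set %in% records$roi)) {
    stop("normalization ROIs ", paste(setdiff(norm_set, records$roi),
                                      collapse = ", "),
         " missing from records", call. = FALSE)
  }
  denom <- sum(records$mean_apd[records$roi %in% norm_set])
  if (!is.finite(denom) || denom <= 0) {
    stop("normalization denominator must be positive", call. = FALSE)
  }
  records$rel_mean_apd <- records$mean_apd / denom
  records
}

#' Per-image ROI statistics
#'
#' Computes, for one image, the area fraction, mean APD and relative mean
#' APD of every ROI present in the label map.
#'
#' @param pdmap A [pd_map].
#' @param labels ROI label map aligned to the PD grid.
#' @param mask Hand mask aligned to the PD grid.
#' @param image_id Identifier copied into the output rows.
#' @param rois ROI ids to report (default all labels present).
#' @param norm_set Normalization ROIs (default `1:4`).
#' @param require_norm If `TRUE` (default) a missing normalization ROI is
#'   an error; if `FALSE` (e.g. when only part of the hand was probed) the
#'   relative column is `NA` instead.
#' @return Data frame: `image_id`, `roi`, `area_pct`, `mean_apd`,
#'   `rel_mean_apd`, `excluded_px`.
#' @export
roi_stats <- function(pdmap, labels, mask, image_id = "image",
                      rois = NULL, norm_set = 1:4, require_norm = TRUE) {
  if (is.null(rois)) rois <- sort(setdiff(unique(as.integer(labels)), 0L))
  rows <- lapply(rois, function(r) {
    m <- mean_apd(pdmap, labels, r)
    data.frame(image_id = image_id, roi = r,
               area_pct = area_fraction(labels, mask, r),
               mean_apd = as.numeric(m),
               excluded_px = attr(m, "excluded"))
  })
  out <- do.call(rbind, rows)
  if (all(norm_set %in% out$roi) || require_norm) {
    out <- relative_mean_apd(out, norm_set)
  } else {
    out$rel_mean_apd <- NA_real_
  }
  out[, c("image_id", "roi", "area_pct", "mean_apd", "rel_mean_apd",
          "excluded_px")]
}

#' Linear trend of relative mean APD against reference age
#'
#' Ordinary least-squares fit `value = slope * age + intercept` with the
#' classical two-sided t-test for a nonzero slope.
#'
#' @param values Relative mean APD, one per image.
#' @param ages Reference ages in months, one per image (not all equal).
#' @param roi Optional ROI id carried into the result.
#' @return Data frame row: `roi`, `slope` (per month), `intercept`,
#'   `p_value`, `n`.
#' @export
trend_regression <- function(values, ages, roi = NA_integer_) {
  stopifnot(length(values) == length(ages))
  keep <- is.finite(values) & is.finite(ages)
  values <- values[keep]; ages <- ages[keep]
  if (length(values) < 3L) stop("need at least 3 points", call. = FALSE)
  if (diff(range(ages)) == 0) stop("degenerate design: constant ages",
                                   call. = FALSE)
  fit <- stats::lm(values ~ ages)
  # exact fits are legitimate here (affine surrogates reproduce their
  # weights exactly), so muffle only the perfect-fit note
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  co <- sm$coefficients
  p <- if (nrow(co) >= 2L && ncol(co) >= 4L) co["ages", 4] else NA_real_
  data.frame(roi = roi, slope = unname(stats::coef(fit)["ages"]),
             intercept = unname(stats::coef(fit)["(Intercept)"]),
             p_value = unname(p), n = length(values))
}

#' Cohort descriptive table
#'
#' Per ROI over a cohort of images: mean and sample SD (n-1 denominator)
#' of the area fraction and of the mean APD.
#'
#' @param records Row-bound [roi_stats()] output for >= 2 images.
#' @return Data frame: `roi`, `n`, `area_pct_mean`, `area_pct_sd`,
#'   `mean_apd_mean`, `mean_apd_sd`.
#' @export
cohort_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("image_id", "roi", "area_pct", "mean_apd") %in%
                  names(records)))
  if (length(unique(records$image_id)) < 2L) {
    stop("cohort statistics need at least 2 images", call. = FALSE)
  }
  rois <- sort(unique(records$roi))
  out <- lapply(rois, function(r) {
    sub <- records[records$roi == r, ]
    data.frame(roi = r, n = nrow(sub),
               area_pct_mean = mean(sub$area_pct),
               area_pct_sd = stats::sd(sub$area_pct),
               mean_apd_mean = mean(sub$mean_apd),
               mean_apd_sd = stats::sd(sub$mean_apd))
  })
  do.call(rbind, out)
}
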