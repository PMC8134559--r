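#' Read a grayscale PNG as an intensity matrix
#'
#' Reads an 8-bit or 16-bit grayscale PNG and returns a numeric matrix of
#' intensities on the 0-255 scale (16-bit files keep their sub-integer
#' precision), row-major with the origin at the top-left.
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @export
read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    # collapse RGB(A) to luminance by channel mean over the first 3 channels
    x <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  }
  x * 255
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' Intensities are clamped to `[0, 255]` and quantized to 8 bits.
#'
#' @param image Numeric matrix on the 0-255 scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  assert_gray(image)
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' Read and write binary masks as PNG
#'
#' Masks are stored as single-channel PNGs with 0 = background and
#' 255 = foreground.
#'
#' @param path PNG path.
#' @return `read_mask_png`: a logical matrix.
#' @export
read_mask_png <- function(path) read_gray_png(path) > 127

#' @rdname read_mask_png
#' @param mask Logical (or 0/1) matrix.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_binary(mask)
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Read and write ROI label maps as PNG
#'
#' Label maps are single-channel PNGs whose 8-bit pixel values are the
#' integer labels themselves (0 = unassigned, 1-5 = ROIs).
#'
#' @param path PNG path.
#' @return `read_label_png`: an integer matrix of labels.
#' @export
read_label_png <- function(path) {
  lab <- round(read_gray_png(path))
  storage.mode(lab) <- "integer"
  lab
}

#' @rdname read_label_png
#' @param labels Integer matrix of labels in `[0, 255]`.
#' @export
write_label_png <- function(labels, path) {
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read and write packed 299x299x3 model-input images as PNG
#'
#' @param path PNG path.
#' @return `read_packed_png`: integer 299x299x3 array on the 0-254 scale.
#' @export
read_packed_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) != 3L || dim(x)[3] < 3L) {
    stop("expected a 3-channel PNG", call. = FALSE)
  }
  x <- round(x[, , 1:3] * 255)
  storage.mode(x) <- "integer"
  assert_packed(x)
}

#' @rdname read_packed_png
#' @param packed Integer 299x299x3 array on the 0-254 scale.
#' @export
write_packed_png <- function(packed, path) {
  assert_packed(packed)
  png::writePNG(packed / 255, path)
  invisible(path)
}

#' Serialize a PD map to flat CSV
#'
#' Writes one row per computed pixel with 1-based `row`, `col` coordinates
#' and the PD value at full precision, plus the baseline prediction and
#' perturbation step as commented header lines.
#'
#' @param pdmap A [pd_map] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pdmap_csv <- function(pdmap, path) {
  stopifnot(inherits(pdmap, "pd_map"))
  idx <- which(pdmap$computed, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# dim = %d %d", nrow(pdmap$computed), ncol(pdmap$computed)),
    sprintf("# step = %.17g", pdmap$step),
    sprintf("# baseline = %.17g", pdmap$baseline),
    "row,col,pd"
  ), con)
  if (nrow(idx)) {
    writeLines(sprintf("%d,%d,%.17g", idx[, 1], idx[, 2],
                       pdmap$pd[idx]), con)
  }
  invisible(path)
}

#' @rdname write_pdmap_csv
#' @return `read_pdmap_csv`: the [pd_map] object round-tripped from `path`.
#' @export
read_pdmap_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, " ="), hdr, value = TRUE)
    strsplit(sub(paste0("^# ", key, " = "), "", ln[1]), " ")[[1]]
  }
  dm <- as.integer(get_hdr("dim"))
  step <- as.numeric(get_hdr("step"))
  baseline <- as.numeric(get_hdr("baseline"))
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  pd <- matrix(NA_real_, dm[1], dm[2])
  computed <- matrix(FALSE, dm[1], dm[2])
  if (nrow(df)) {
    ij <- cbind(df$row, df$col)
    pd[ij] <- df$pd
    computed[ij] <- TRUE
  }
  new_pd_map(pd, computed, baseline, step)
}

#' Serialize a PD map as a 32-bit float grid with a text header
#'
#' A compact binary export: a short text header (grid dimensions, step,
#' baseline) followed by the full grid as little-endian 32-bit floats in
#' column-major order, with uncomputed pixels stored as NaN.
#'
#' @inheritParams write_pdmap_csv
#' @export
write_pdmap_bin <- function(pdmap, path) {
  stopifnot(inherits(pdmap, "pd_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("pdmap %d %d %.17g %.17g\n",
                 nrow(pdmap$pd), ncol(pdmap$pd), pdmap$step, pdmap$baseline)
  writeBin(charToRaw(hdr), con)
  vals <- pdmap$pd
  vals[!pdmap$computed] <- NaN
  writeBin(as.numeric(vals), con, size = 4, endian = "little")
  invisible(path)
}

# Plain-text key = value config files (used for surrogate specs, the
# preprocessing config and the pipeline run echo).
write_kv_config <- function(x, path) {
  fmt <- function(v) {
    if (is.numeric(v)) paste(sprintf("%.17g", v), collapse = " ")
    else paste(as.character(v), collapse = " ")
  }
  writeLines(sprintf("%s = %s", names(x), vapply(x, fmt, "")), path)
  invisible(path)
}

read_kv_config <- function(path) {
  lines <- grep("=", readLines(path), value = TRUE, fixed = TRUE)
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    toks <- strsplit(val, "[[:space:]]+")[[1]]
    num <- suppressWarnings(as.numeric(toks))
    out[[key]] <- if (!anyNA(num)) num else val
  }
  out
}
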