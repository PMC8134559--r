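#' Pipeline run configuration
#'
#' Collects everything a full preprocess -> probe -> ROI stats ->
#' regression -> render run needs.  The configuration is echoed verbatim
#' into the run directory for provenance.
#'
#' @param input_dir Directory of input images named `<id>_image.png`, with
#'   optional `<id>_mask.png` and `<id>_labels.png` companions and an
#'   `ages.csv` (`image_id`, `age_months`).
#' @param out_dir Run output directory (created if missing).
#' @param model A `pd_regressor`, or the path of a surrogate config file.
#' @param preprocess A [preprocess_config()].
#' @param region Probe region: `"mask"` (default), `"outside"`, `"all"`, or
#'   `"labels:i,j,..."`.
#' @param step Probe step in intensity units.
#' @param norm_set Normalization ROIs for relative mean APD.
#' @param overlay An [overlay_spec()].
#' @param seed Master seed recorded in the manifest.
#' @param verbose Print per-stage progress.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, out_dir, model,
                       preprocess = preprocess_config(), region = "mask",
                       step = 1, norm_set = 1:4, overlay = overlay_spec(),
                       seed = 1L, verbose = FALSE) {
  if (!dir.exists(input_dir)) stop("input_dir does not exist", call. = FALSE)
  if (is.character(model) && !file.exists(model)) {
    stop("model config does not exist", call. = FALSE)
  }
  structure(list(input_dir = input_dir, out_dir = out_dir, model = model,
                 preprocess = preprocess, region = region, step = step,
                 norm_set = norm_set, overlay = overlay,
                 seed = as.integer(seed), verbose = verbose),
            class = "run_config")
}

run_log <- function(config, con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  writeLines(msg, con)
  if (isTRUE(config$verbose)) message(msg)
}

#' Run the full probing pipeline over an image directory
#'
#' For every `<id>_image.png` in the input directory: preprocess to the
#' packed model input, compute the PD map over the configured region,
#' render the sigmoid color overlay, and compute per-ROI statistics (when a
#' label map is present).  Afterwards: cohort table and, when `ages.csv`
#' is present and at least 3 images succeeded, per-ROI trend regressions.
#'
#' Images are processed in isolation: a failure is logged in the manifest
#' and skipped, and the run fails only if every image fails.  Re-running on
#' a completed directory reuses per-image artifacts (no recomputation) and
#' reproduces bit-identical CSVs.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly.  Artifacts: per image
#'   `<id>_packed.png`, `<id>_pd.csv`, `<id>_overlay.png`, `<id>_stats.csv`;
#'   cohort `roi_stats.csv`, `cohort_table.csv`, `regression.csv`;
#'   `manifest.json`, `config.txt`, `run.log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(out, "run.log"), "a")
  on.exit(close(logcon))

  model <- config$model
  if (is.character(model)) model <- read_surrogate_config(model)
  stopifnot(inherits(model, "pd_regressor"))

  cfg_echo <- list(input_dir = config$input_dir, out_dir = out,
                   model = model$name, region = config$region,
                   step = config$step,
                   norm_set = paste(config$norm_set, collapse = ","),
                   background = config$preprocess$background,
                   background_value = config$preprocess$background_value,
                   threshold = config$preprocess$threshold,
                   struct_radius = config$preprocess$struct_radius,
                   margin_frac = config$preprocess$margin_frac,
                   overlay_threshold = config$overlay$threshold,
                   overlay_opacity = config$overlay$opacity,
                   seed = config$seed)
  write_kv_config(cfg_echo, file.path(out, "config.txt"))

  imgs <- sort(list.files(config$input_dir, pattern = "_image\\.png$"))
  ids <- sub("_image\\.png$", "", imgs)
  if (length(ids) == 0L) stop("no <id>_image.png inputs found", call. = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    list(config = cfg_echo, images = list())
  }

  ages_path <- file.path(config$input_dir, "ages.csv")
  ages <- if (file.exists(ages_path)) utils::read.csv(ages_path) else NULL

  per_image_files <- function(id) {
    file.path(out, paste0(id, c("_packed.png", "_pd.csv", "_overlay.png",
                                "_stats.csv")))
  }

  for (i in seq_along(ids)) {
    id <- ids[i]
    files <- per_image_files(id)
    prev <- manifest$images[[id]]
    if (!is.null(prev) && identical(prev$status, "complete") &&
        all(file.exists(files))) {
      run_log(config, logcon, id, ": complete, reusing artifacts")
      next
    }
    t0 <- Sys.time()
    res <- tryCatch({
      image <- read_gray_png(file.path(config$input_dir, imgs[i]))
      mask_path <- file.path(config$input_dir, paste0(id, "_mask.png"))
      lab_path <- file.path(config$input_dir, paste0(id, "_labels.png"))
      user_mask <- if (file.exists(mask_path)) read_mask_png(mask_path)
      labels <- if (file.exists(lab_path)) read_label_png(lab_path)
      prep <- preprocess_image(image, config$preprocess, mask = user_mask,
                               labels = labels)
      write_packed_png(prep$packed, files[1])
      region <- switch(config$region,
                       mask = prep$mask299,
                       outside = !prep$mask299,
                       all = "all",
                       config$region)
      pdmap <- compute_pd_map(model, prep$packed, region,
                              step = config$step, labels = prep$labels299)
      write_pdmap_csv(pdmap, files[2])
      write_rgb_png(render_overlay(pdmap, prep$image598, config$overlay),
                    files[3])
      probed <- prep$labels299
      if (!is.null(probed)) {
        probed_ids <- sort(setdiff(unique(as.integer(
          probed[pdmap$computed])), 0L))
      }
      if (!is.null(probed) && length(probed_ids)) {
        stats <- roi_stats(pdmap, prep$labels299, prep$mask299,
                           image_id = id, rois = probed_ids,
                           norm_set = config$norm_set, require_norm = FALSE)
        utils::write.csv(stats, files[4], row.names = FALSE)
      } else {
        empty <- data.frame(image_id = character(), roi = integer(),
                            area_pct = numeric(), mean_apd = numeric(),
                            rel_mean_apd = numeric(),
                            excluded_px = integer())
        utils::write.csv(empty, files[4], row.names = FALSE)
      }
      "complete"
    }, error = function(e) paste("failed:", conditionMessage(e)))
    secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    run_log(config, logcon, id, ": ", res,
            sprintf(" (%.1f s)", secs))
    manifest$images[[id]] <- list(
      status = if (identical(res, "complete")) "complete" else "failed",
      message = res, files = as.list(basename(files)),
      seconds = round(secs, 2))
  }

  done <- names(Filter(function(x) identical(x$status, "complete"),
                       manifest$images))
  done <- intersect(ids, done)
  if (length(done) == 0L) {
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    stop("all images failed", call. = FALSE)
  }

  stats_all <- do.call(rbind, lapply(done, function(id) {
    f <- file.path(out, paste0(id, "_stats.csv"))
    df <- utils::read.csv(f)
    if (nrow(df)) df else NULL
  }))
  if (!is.null(stats_all) && nrow(stats_all)) {
    utils::write.csv(stats_all, file.path(out, "roi_stats.csv"),
                     row.names = FALSE)
    if (length(unique(stats_all$image_id)) >= 2L) {
      utils::write.csv(cohort_table(stats_all),
                       file.path(out, "cohort_table.csv"), row.names = FALSE)
    }
    if (!is.null(ages) && length(unique(stats_all$image_id)) >= 3L) {
      merged <- merge(stats_all, ages, by = "image_id")
      reg <- do.call(rbind, lapply(sort(unique(merged$roi)), function(r) {
        sub <- merged[merged$roi == r, ]
        trend_regression(sub$rel_mean_apd, sub$age_months, roi = r)
      }))
      utils::write.csv(reg, file.path(out, "regression.csv"),
                       row.names = FALSE)
    }
  }

  produced <- sort(union(list.files(out), "manifest.json"))
  manifest$files <- as.list(produced)
  manifest$n_complete <- length(done)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  run_log(config, logcon, "run complete: ", length(done), "/", length(ids),
          " images")
  invisible(out)
}
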