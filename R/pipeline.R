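## End-to-end orchestration: images -> per-image physical measurements ->
## area-weight model selection -> weight prediction -> validation against
## hand-weighed values, with a reproducible run manifest.

#' Build a run configuration
#'
#' Defaults reproduce the study protocol: 6x6_250 dictionary, marker id 1,
#' 10 cm marker side, 5 cm2 minimum object area, alpha 0.05.
#'
#' @param ... overrides for any configuration key (see Details).
#' @param file optional YAML file read first; `...` overrides file keys.
#' @details Keys: `marker.dictionary`, `marker.id`, `marker.side_cm`,
#'   `segmentation.backend`, `segmentation.min_area_cm2`,
#'   `segmentation.marker_mask_margin_px`, `modeling.families`,
#'   `modeling.species`, `validation.alpha`, `seed`.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(
    marker.dictionary = "6x6_250",
    marker.id = 1L,
    marker.side_cm = 10,
    segmentation.backend = "threshold",
    segmentation.min_area_cm2 = 5,
    segmentation.marker_mask_margin_px = 3,
    modeling.families = WEIGHT_MODEL_FAMILIES,
    modeling.species = "",
    validation.alpha = 0.05,
    seed = 1L)
  if (!is.null(file)) {
    y <- yaml::read_yaml(file)
    flat <- unlist(lapply(names(y), function(k) {
      if (is.list(y[[k]])) setNames(y[[k]], paste(k, names(y[[k]]), sep = "."))
      else setNames(list(y[[k]]), k)
    }), recursive = FALSE)
    cfg <- modifyList(cfg, flat)
  }
  cfg <- modifyList(cfg, list(...))
  structure(cfg, class = "run_config")
}

#' Measure one image
#'
#' Applies the image-analysis stages in order: background removal, marker
#' detection and scale calibration, Otsu binarization, marker-region
#' suppression, contour measurement with the physical-area filter.
#'
#' @param image grayscale matrix, colour array, or a PNG path.
#' @param config a [run_config()].
#' @param image_name label for errors and the measurement table.
#' @return list with `row` (one-row data frame: image, marker_id,
#'   pixels_per_cm, pixel_area, area_cm2, width_cm, height_cm, n_objects),
#'   `objects`, `calibration`, `clean` (background-removed image).
#' @export
measure_image <- function(image, config = run_config(), image_name = NULL) {
  if (is.character(image)) {
    if (is.null(image_name)) image_name <- basename(image)
    image <- read_image(image)
  }
  if (is.null(image_name)) image_name <- "image"
  clean <- remove_background(image, backend = config$segmentation.backend)
  obs <- detect_marker(clean, config$marker.dictionary, config$marker.id,
                       image_name = image_name)
  cal <- compute_scale(obs, config$marker.side_cm)
  mask <- binarize(clean)
  mask <- mask_marker_region(mask, obs, config$segmentation.marker_mask_margin_px)
  objs <- measure_objects(mask, cal, config$segmentation.min_area_cm2)
  if (length(objs) == 0L)
    stop("no object of at least ", config$segmentation.min_area_cm2,
         " cm2 found in ", image_name)
  if (length(objs) > 1L)
    message(image_name, ": ", length(objs),
            " objects pass the area filter; using the largest")
  top <- objs[[1]]
  row <- data.frame(image = image_name, marker_id = obs$marker_id,
                    pixels_per_cm = cal$pixels_per_cm,
                    pixel_area = top$pixel_area, area_cm2 = top$area_cm2,
                    width_cm = top$width_cm, height_cm = top$height_cm,
                    n_objects = length(objs))
  list(row = row, objects = objs, calibration = cal, clean = clean,
       observation = obs)
}

#' Measure every image in a directory
#'
#' Images that fail (no marker, no valid object) are logged and skipped.
#'
#' @param images_dir directory of PNG images.
#' @param config a [run_config()].
#' @param annotated_dir if non-`NULL`, annotated copies are written here.
#' @return list: `measurements` (data frame), `skipped` (named character
#'   vector of error messages).
#' @export
measure_images <- function(images_dir, config = run_config(),
                           annotated_dir = NULL) {
  paths <- sort(list.files(images_dir, pattern = "\\.png$", full.names = TRUE,
                           ignore.case = TRUE))
  rows <- list(); skipped <- character(0)
  for (p in paths) {
    res <- tryCatch(measure_image(p, config), error = function(e) conditionMessage(e))
    if (is.character(res)) {
      message("skipping ", basename(p), ": ", res)
      skipped[[basename(p)]] <- res
      next
    }
    rows[[length(rows) + 1L]] <- res$row
    if (!is.null(annotated_dir)) {
      dir.create(annotated_dir, showWarnings = FALSE, recursive = TRUE)
      ann <- annotate(res$clean, res$objects[1], res$calibration)
      write_image(ann, file.path(annotated_dir, basename(p)))
    }
  }
  list(measurements = if (length(rows)) do.call(rbind, rows) else
         data.frame(),
       skipped = skipped)
}

#' Run the full weight-estimation workflow
#'
#' Measures all images, joins the hand-weighed values, fits and selects
#' the area-weight model, predicts weights from the measured areas, and
#' validates predictions against the actual weights. Outputs
#' (`measurements.csv`, `model.json`, `report.json`, `manifest.json`) are
#' written to `out_dir` and are byte-identical across reruns with the same
#' configuration and seed.
#'
#' @param config a [run_config()].
#' @param images_dir directory of PNG images (one organism + one marker each).
#' @param weights_csv CSV with columns `image`, `weight_g`.
#' @param out_dir output directory (created if needed).
#' @return list: `measurements`, `selection` (a `model_selection`),
#'   `report` (a `validation_report`), `manifest`.
#' @export
run_pipeline <- function(config, images_dir, weights_csv, out_dir) {
  stopifnot(dir.exists(images_dir), file.exists(weights_csv))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mr <- measure_images(images_dir, config)
  meas <- mr$measurements
  if (nrow(meas) == 0L) stop("no image could be measured; nothing to fit")
  weights <- read.csv(weights_csv)
  stopifnot(all(c("image", "weight_g") %in% names(weights)))
  merged <- merge(meas, weights, by = "image", sort = TRUE)
  if (nrow(merged) == 0L) stop("no measured image matches the weights table")

  pairs <- aw_pairs(merged$area_cm2, merged$weight_g)
  sel <- select_best_model(pairs, config$modeling.families,
                           species_label = config$modeling.species)
  est <- predict_weight(sel$best, merged$area_cm2, quiet = TRUE)
  report <- validate_weights(est, merged$weight_g, config$validation.alpha)

  manifest <- list(
    tool = paste0("holoweigh ", as.character(packageVersion("holoweigh"))),
    config = unclass(config), seed = config$seed,
    n_input = nrow(meas) + length(mr$skipped),
    n_measured = nrow(meas), n_skipped = length(mr$skipped),
    skipped = as.list(mr$skipped))

  write.csv(meas, file.path(out_dir, "measurements.csv"), row.names = FALSE)
  write_weight_model(sel$best, file.path(out_dir, "model.json"))
  write_validation_report(report, file.path(out_dir, "report.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(measurements = merged, selection = sel, report = report,
       manifest = manifest)
}
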