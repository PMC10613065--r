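#' Pipeline configuration
#'
#' Bundles the stage parameters for the end-to-end analysis. When
#' `remap` is a [remap_spec()], the input is treated as a raw line-scan
#' capture and restored first; with `remap = NULL` (default) the input
#' is already planar.
#'
#' @param remap `NULL` or a [remap_spec()].
#' @param preprocess a [preprocess_params()].
#' @param watershed a [watershed_params()].
#' @param classifier a [classifier_params()].
#' @param overlay write an annotated overlay PNG when an output
#'   directory is given (filled grains outlined red, unfilled blue).
#' @param to_gray accept color input, converting to luminance.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(remap = NULL,
                            preprocess = preprocess_params(),
                            watershed = watershed_params(),
                            classifier = classifier_params(),
                            overlay = FALSE, to_gray = FALSE) {
  if (!is.null(remap)) stopifnot(inherits(remap, "remap_spec"))
  stopifnot(inherits(preprocess, "preprocess_params"),
            inherits(watershed, "watershed_params"),
            inherits(classifier, "classifier_params"))
  structure(list(remap = remap, preprocess = preprocess,
                 watershed = watershed, classifier = classifier,
                 overlay = isTRUE(overlay), to_gray = isTRUE(to_gray)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value file mirroring the stage parameters; recognized keys
#' are `width_px`, `scan_lines`, `interp`, `fill_value` (remap; remap is
#' enabled iff `width_px` is present), `median_kernel`, `bin_threshold`,
#' `close_kernel`, `min_area`, `otsu`, `fg_fraction`, `bg_dilate`,
#' `global_fraction`, `keep_border`, `dr_threshold`, `resolution`,
#' `overlay`, `to_gray`. Missing keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- function(key, default) if (is.null(y[[key]])) default else y[[key]]
  remap <- NULL
  if (!is.null(y$width_px)) {
    remap <- remap_spec(y$width_px,
                        scan_lines_per_rev = g("scan_lines", y$width_px),
                        interpolation = g("interp", "bilinear"),
                        fill_value = g("fill_value", 255))
  }
  pipeline_config(
    remap = remap,
    preprocess = preprocess_params(
      median_kernel = g("median_kernel", 5),
      bin_threshold = g("bin_threshold", 220),
      close_kernel = g("close_kernel", 5),
      min_object_area = g("min_area", 500),
      otsu = g("otsu", FALSE)),
    watershed = watershed_params(
      bg_dilate_iters = g("bg_dilate", 3),
      fg_dist_fraction = g("fg_fraction", 0.4),
      per_component_fraction = !isTRUE(g("global_fraction", FALSE)),
      exclude_border = !isTRUE(g("keep_border", FALSE))),
    classifier = classifier_params(
      dark_ratio_threshold = g("dr_threshold", 0.6),
      resolution_mm_per_px = g("resolution", 0.086)),
    overlay = g("overlay", FALSE),
    to_gray = g("to_gray", FALSE))
}

#' Analyze one backlight image
#'
#' Runs the full pipeline: optional line-scan restoration, median
#' filter, binarization, hole closing, small-object removal, watershed
#' segmentation, per-grain dark-ratio classification and size
#' measurement, and the panicle summary. The pipeline has no stochastic
#' stage, so a fixed input and configuration give identical output.
#'
#' @param input a [backlight_image()] or a path to a PNG/TIFF file.
#' @param config a [pipeline_config()].
#' @param out_dir when given, writes `<name>_grains.csv`,
#'   `<name>_summary.json` and (if `config$overlay`)
#'   `<name>_overlay.png` there.
#' @param name basename for output files (defaults to the input filename
#'   or `"image"`).
#' @param verbose log per-stage timings to stderr.
#' @return An object of class `analysis_result`: list with `summary`
#'   (a `panicle_summary`), `phenotypes` (per-grain data.frame),
#'   `labels` (integer label raster), `provenance` (config echo,
#'   package version, input checksum).
#' @export
analyze_image <- function(input, config = pipeline_config(), out_dir = NULL,
                          name = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  checksum <- NA_character_
  if (is.character(input)) {
    if (is.null(name)) name <- tools::file_path_sans_ext(basename(input))
    checksum <- unname(tools::md5sum(input))
    img <- read_backlight_image(
      input,
      resolution_mm_per_px = config$classifier$resolution_mm_per_px,
      remapped = is.null(config$remap), to_gray = config$to_gray)
  } else if (is_backlight_image(input)) {
    img <- input
  } else {
    stop("'input' must be a file path or a backlight_image", call. = FALSE)
  }
  if (is.null(name)) name <- "image"
  tic <- function() proc.time()[["elapsed"]]
  log_stage <- function(msg, t0) {
    if (verbose) message(sprintf("[grainscan] %-12s %6.2f s", msg, tic() - t0))
  }

  t0 <- tic()
  if (!is.null(config$remap)) {
    img <- remap_image(img, config$remap)
    log_stage("remap", t0)
  }
  t0 <- tic()
  pre <- preprocess(img, config$preprocess)
  log_stage("preprocess", t0)
  t0 <- tic()
  regions <- segment_grains(pre$filtered, pre$mask, config$watershed)
  log_stage("segment", t0)
  t0 <- tic()
  phen <- phenotype_grains(regions, config$classifier)
  log_stage("phenotype", t0)
  summary <- summarize_panicle(phen, attr(regions, "excluded_border"))

  result <- structure(
    list(summary = summary, phenotypes = phen,
         labels = attr(regions, "labels"),
         image = img,
         provenance = list(name = name, input_checksum = checksum,
                           package_version = as.character(
                             utils::packageVersion("grainscan")),
                           config = config)),
    class = "analysis_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_phenotype_csv(result, file.path(out_dir, paste0(name, "_grains.csv")))
    write_summary_json(result, file.path(out_dir, paste0(name, "_summary.json")))
    if (config$overlay) {
      write_overlay_png(result, file.path(out_dir, paste0(name, "_overlay.png")))
    }
  }
  result
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("<analysis_result>", x$provenance$name, "\n")
  print(x$summary)
  invisible(x)
}

#' Write the per-grain CSV
#'
#' Columns: `label`, `centroid_x`, `centroid_y`, `area_px`,
#' `dark_ratio`, `filled`, `length_mm`, `width_mm`, `rect_angle_deg`.
#'
#' @param result an `analysis_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(result, path) {
  cols <- c("label", "centroid_x", "centroid_y", "area_px", "dark_ratio",
            "filled", "length_mm", "width_mm", "rect_angle_deg")
  utils::write.csv(result$phenotypes[, cols, drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write the summary JSON
#'
#' Panicle counts plus full provenance (effective configuration, package
#' version, input checksum), so a run is reproducible from its artifacts.
#'
#' @inheritParams write_phenotype_csv
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(result, path) {
  s <- result$summary
  out <- list(total_count = s$total_count, filled_count = s$filled_count,
              unfilled_count = s$unfilled_count,
              filled_fraction = s$filled_fraction,
              excluded_border_count = s$excluded_border_count,
              provenance = list(
                name = result$provenance$name,
                input_checksum = result$provenance$input_checksum,
                package_version = result$provenance$package_version,
                config = unclass_config(result$provenance$config)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_config <- function(config) {
  rapply(list(remap = if (!is.null(config$remap)) unclass(config$remap),
              preprocess = unclass(config$preprocess),
              watershed = unclass(config$watershed),
              classifier = unclass(config$classifier),
              overlay = config$overlay, to_gray = config$to_gray),
         identity, how = "replace")
}

#' Write an annotated overlay image
#'
#' Grayscale scene with grain outlines: red = filled, blue = unfilled.
#' Per-grain sizes are in the accompanying CSV.
#'
#' @inheritParams write_phenotype_csv
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(result, path) {
  lab <- result$labels
  g <- img_data(result$image) / 255
  rgb <- array(g, c(nrow(g), ncol(g), 3))
  if (nrow(result$phenotypes)) {
    nr <- nrow(lab); nc <- ncol(lab)
    shift <- function(m, dr, dc) {
      out <- matrix(0L, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs - dr, cs - dc] <- m[rs, cs]
      out
    }
    edge <- lab > 0L & (lab != shift(lab, 1, 0) | lab != shift(lab, -1, 0) |
                        lab != shift(lab, 0, 1) | lab != shift(lab, 0, -1))
    filled_ids <- result$phenotypes$label[result$phenotypes$filled]
    efill <- edge & matrix(lab %in% filled_ids, nr, nc)
    eunf <- edge & !efill
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[efill] <- if (ch == 1) 1 else 0
      plane[eunf] <- if (ch == 3) 1 else 0
      rgb[, , ch] <- plane
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Analyze a batch of images
#'
#' One [analyze_image()] per path; per-file failures are logged to
#' stderr and skipped rather than aborting the batch.
#'
#' @param paths character vector of image paths (or a list mixing paths
#'   and [backlight_image()]s).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory passed through to
#'   [analyze_image()]; the aggregate CSV `batch_counts.csv` is written
#'   there too.
#' @return List with `results` (per-image `analysis_result`s, `NULL`
#'   where failed), `counts` (aggregate data.frame: `image`, `total`,
#'   `filled`, `unfilled`, `excluded_border`, `ok`) and `n_failed`.
#' @export
analyze_batch <- function(paths, config = pipeline_config(), out_dir = NULL) {
  if (length(paths) < 1) stop("need at least one input", call. = FALSE)
  results <- vector("list", length(paths))
  rows <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    input <- if (is.list(paths)) paths[[i]] else paths[i]
    nm <- if (is.character(input)) {
      tools::file_path_sans_ext(basename(input))
    } else {
      sprintf("image_%03d", i)
    }
    res <- tryCatch(
      analyze_image(input, config, out_dir = out_dir, name = nm),
      error = function(e) {
        message(sprintf("[grainscan] skipping %s: %s", nm, conditionMessage(e)))
        NULL
      })
    results[[i]] <- res
    rows[[i]] <- if (is.null(res)) {
      data.frame(image = nm, total = NA_integer_, filled = NA_integer_,
                 unfilled = NA_integer_, excluded_border = NA_integer_,
                 ok = FALSE)
    } else {
      data.frame(image = nm, total = res$summary$total_count,
                 filled = res$summary$filled_count,
                 unfilled = res$summary$unfilled_count,
                 excluded_border = res$summary$excluded_border_count,
                 ok = TRUE)
    }
  }
  counts <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(counts, file.path(out_dir, "batch_counts.csv"),
                     row.names = FALSE)
  }
  list(results = results, counts = counts, n_failed = sum(!counts$ok))
}
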