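#' Backlight image container
#'
#' A `backlight_image` is a plain numeric matrix of 8-bit grayscale values
#' (0 = opaque, 255 = fully transmitting) with acquisition metadata attached:
#' the spatial resolution in mm per pixel, whether the raster has already
#' been restored from line-scan (turntable) geometry, and the nominal
#' backlight intensity scale. Matrix rows are image rows (y), columns are
#' image columns (x); pixel centers sit at 0-based integer coordinates
#' `(column, row)` with the origin at the top-left.
#'
#' @param data numeric matrix of grayscale values in `[0, 255]`.
#' @param resolution_mm_per_px spatial resolution, mm per pixel.
#' @param remapped logical; `TRUE` if the raster is already planar
#'   (either captured planar or restored by [remap_image()]).
#' @param intensity nominal backlight intensity scale (1 = reference).
#'
#' @return An object of class `backlight_image`.
#' @export
backlight_image <- function(data, resolution_mm_per_px = 0.086,
                            remapped = TRUE, intensity = 1) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("'data' must be a numeric matrix", call. = FALSE)
  }
  if (length(data) == 0L) stop("image is empty", call. = FALSE)
  if (anyNA(data) || min(data) < 0 || max(data) > 255) {
    stop("grayscale values must lie in [0, 255] and contain no NA",
         call. = FALSE)
  }
  if (!is.numeric(resolution_mm_per_px) || resolution_mm_per_px <= 0) {
    stop("'resolution_mm_per_px' must be > 0", call. = FALSE)
  }
  structure(data,
            resolution_mm_per_px = resolution_mm_per_px,
            remapped = isTRUE(remapped),
            intensity = intensity,
            class = c("backlight_image", "matrix", "array"))
}

#' @export
print.backlight_image <- function(x, ...) {
  cat(sprintf("<backlight_image> %d x %d px, %.3f mm/px, remapped=%s\n",
              nrow(x), ncol(x), attr(x, "resolution_mm_per_px"),
              attr(x, "remapped")))
  cat(sprintf("  gray range [%d, %d], mean %.1f\n",
              round(min(x)), round(max(x)), mean(x)))
  invisible(x)
}

#' Test for backlight_image
#' @param x object.
#' @return logical.
#' @export
is_backlight_image <- function(x) inherits(x, "backlight_image")

# strip class/attrs, keep plain matrix
img_data <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  m
}

# rebuild a backlight_image from a matrix, copying metadata from a template
img_like <- function(data, template, ...) {
  args <- list(data = data,
               resolution_mm_per_px = attr(template, "resolution_mm_per_px"),
               remapped = attr(template, "remapped"),
               intensity = attr(template, "intensity"))
  args[names(list(...))] <- list(...)
  do.call(backlight_image, args)
}

#' Read an 8-bit grayscale image
#'
#' Reads a PNG or TIFF file into a [backlight_image()]. Multi-channel
#' inputs are rejected unless `to_gray = TRUE`, in which case they are
#' converted by the Rec. 601 luminance weights (the acquisition rig is a
#' monochrome line-scan camera, so color inputs usually indicate a
#' mistake).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param resolution_mm_per_px resolution metadata to attach.
#' @param remapped whether the stored raster is already planar.
#' @param to_gray allow color input, converting to luminance.
#'
#' @return A [backlight_image()].
#' @export
read_backlight_image <- function(path, resolution_mm_per_px = 0.086,
                                 remapped = TRUE, to_gray = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L && to_gray) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else if (dim(arr)[3] == 1L) {
      arr <- arr[, , 1]
    } else {
      stop("image is not grayscale (pass to_gray = TRUE to convert)",
           call. = FALSE)
    }
  }
  backlight_image(round(arr * 255), resolution_mm_per_px = resolution_mm_per_px,
                  remapped = remapped)
}

#' Write an 8-bit grayscale image
#'
#' @param img a [backlight_image()] or numeric matrix in `[0, 255]`.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_backlight_image <- function(img, path) {
  m <- pmin(pmax(round(img_data(img)), 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(m, path),
    tif  = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}
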