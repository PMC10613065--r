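#' Preprocessing parameters
#'
#' Stage order is fixed: median filter, fixed-threshold binarization,
#' morphological closing, small-object removal. Under backlight the
#' background is near-saturated while grain interiors — even translucent
#' unfilled ones — stay bounded below it, so a fixed grayscale cut just
#' below saturation separates foreground from background.
#'
#' @param median_kernel odd median window size in px (default 5).
#' @param bin_threshold grayscale cut in (0, 255); pixels strictly below
#'   it are foreground (default 220). The rig's backlight is assumed
#'   uniform, so no local thresholding is applied.
#' @param close_kernel odd size of the elliptical closing element
#'   (default 5), sized to fill the 1--3 px glume-gap holes without
#'   bridging neighboring grains.
#' @param min_object_area components smaller than this many px^2 are
#'   discarded as debris (default 500; a grain at 0.086 mm/px is roughly
#'   3000 px^2, a 6x margin).
#' @param otsu if `TRUE`, ignore `bin_threshold` and derive the cut with
#'   Otsu's method (off by default; the fixed threshold is the reference
#'   behavior).
#'
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(median_kernel = 5, bin_threshold = 220,
                              close_kernel = 5, min_object_area = 500,
                              otsu = FALSE) {
  for (k in c(median_kernel, close_kernel)) {
    if (k < 1 || k %% 2 != 1) {
      stop("kernel sizes must be odd and >= 1", call. = FALSE)
    }
  }
  if (bin_threshold <= 0 || bin_threshold >= 255) {
    stop("'bin_threshold' must lie in (0, 255)", call. = FALSE)
  }
  if (min_object_area < 0) stop("'min_object_area' must be >= 0", call. = FALSE)
  structure(list(median_kernel = median_kernel,
                 bin_threshold = bin_threshold,
                 close_kernel = close_kernel,
                 min_object_area = min_object_area,
                 otsu = isTRUE(otsu)),
            class = "preprocess_params")
}

#' Median filter
#'
#' Each pixel is replaced by the median of its `kernel x kernel`
#' neighborhood; borders are handled by edge replication (constant
#' padding would darken borders and create false foreground).
#'
#' @param img a [backlight_image()] or numeric matrix in `[0, 255]`.
#' @param kernel odd window size, at most the smaller image dimension.
#' @return Filtered image of the same class and shape.
#' @export
median_filter <- function(img, kernel = 5) {
  if (kernel %% 2 != 1 || kernel < 1) {
    stop("'kernel' must be odd and >= 1", call. = FALSE)
  }
  m <- img_data(img)
  if (kernel > min(dim(m))) {
    stop("'kernel' exceeds image dimensions", call. = FALSE)
  }
  if (kernel == 1) return(img)
  r <- (kernel - 1) / 2
  # replicate-pad, filter, crop: pins down the border semantics
  ri <- c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1, r), seq_len(ncol(m)), rep(ncol(m), r))
  padded <- m[ri, ci]
  f <- EBImage::medianFilter(padded / 255, r) * 255
  out <- round(f[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))])
  if (is_backlight_image(img)) img_like(out, img) else out
}

#' Binarize a backlight image
#'
#' Grains attenuate the backlight, so foreground is the dark phase:
#' pixels with grayscale strictly below the threshold.
#'
#' @inheritParams median_filter
#' @param threshold grayscale cut in (0, 255).
#' @return Logical matrix (`TRUE` = grain foreground), same shape.
#' @export
binarize <- function(img, threshold = 220) {
  if (threshold <= 0 || threshold >= 255) {
    stop("'threshold' must lie in (0, 255)", call. = FALSE)
  }
  img_data(img) < threshold
}

#' Otsu threshold of an 8-bit image
#'
#' Convenience for [preprocess_params()]'s `otsu` switch.
#'
#' @inheritParams median_filter
#' @return A single grayscale threshold.
#' @export
otsu_threshold <- function(img) {
  EBImage::otsu(EBImage::Image(img_data(img) / 255), range = c(0, 1)) * 255
}

#' Close small holes in a binary mask
#'
#' Morphological closing (dilation then erosion) with an elliptical
#' structuring element. The glume gap between a grain's shell and its
#' empty glume transmits light and punches a small hole in the mask;
#' closing fills holes smaller than the element. The output is forced to
#' be a superset of the input foreground, so closing never erodes grains
#' clipped by the raster border.
#'
#' @param mask logical matrix, `TRUE` = foreground.
#' @param kernel odd element size (default 5).
#' @return Logical matrix, superset of `mask`.
#' @export
close_holes <- function(mask, kernel = 5) {
  if (kernel %% 2 != 1 || kernel < 1) {
    stop("'kernel' must be odd and >= 1", call. = FALSE)
  }
  if (kernel == 1) return(mask)
  brush <- EBImage::makeBrush(kernel, shape = "disc")
  closed <- EBImage::closing(mask * 1, brush) > 0
  closed | mask
}

#' Remove small connected components
#'
#' Drops 8-connected foreground components with area below `min_area`
#' (clastic debris, dust); all other components pass untouched.
#'
#' @param mask logical matrix.
#' @param min_area area cut in px^2 (`0` = identity).
#' @return Logical matrix, subset of `mask`.
#' @export
remove_small_objects <- function(mask, min_area = 500) {
  if (min_area < 0) stop("'min_area' must be >= 0", call. = FALSE)
  if (min_area == 0 || !any(mask)) return(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= min_area)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Label connected components (8-connectivity)
#'
#' Integer labeling of foreground components where diagonal contact
#' counts as connected. Labels are renumbered 1..n in raster order.
#'
#' @param mask logical matrix.
#' @return Integer matrix, 0 = background.
#' @export
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)  # 4-connected
  storage.mode(lab) <- "integer"
  dim(lab) <- dim(mask)
  n <- max(lab)
  if (n <= 1L) return(lab)
  # merge labels that touch diagonally (union-find over label pairs)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Run the full preprocessing chain
#'
#' Median filter, binarize, close holes, remove small objects — in that
#' fixed order. Every stage preserves the raster shape.
#'
#' @param img a [backlight_image()].
#' @param params a [preprocess_params()].
#' @return A list with `mask` (logical matrix), `filtered` (the
#'   median-filtered [backlight_image()]) and `threshold` (the grayscale
#'   cut actually used).
#' @export
preprocess <- function(img, params = preprocess_params()) {
  stopifnot(inherits(params, "preprocess_params"))
  filtered <- median_filter(img, params$median_kernel)
  thr <- if (params$otsu) otsu_threshold(filtered) else params$bin_threshold
  mask <- binarize(filtered, thr)
  mask <- close_holes(mask, params$close_kernel)
  mask <- remove_small_objects(mask, params$min_object_area)
  list(mask = mask, filtered = filtered, threshold = thr)
}
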