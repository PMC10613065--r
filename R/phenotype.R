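#' Classifier and measurement parameters
#'
#' @param dark_ratio_threshold dark-ratio cut in (0, 1); a grain whose
#'   dark ratio strictly exceeds it is filled (default 0.6).
#' @param resolution_mm_per_px pixel pitch used to convert rectangle
#'   sides to millimeters (default 0.086).
#' @param degenerate_gray_span gray-level span at or below which a grain
#'   is treated as a single cluster (default 2): two-cluster structure is
#'   absent in a uniform grain, so classification falls back to absolute
#'   darkness.
#' @param uniform_dark_cut grayscale below which a degenerate (uniform)
#'   grain counts as fully dark, dark ratio 1 (default 110, half the
#'   default binarization threshold); at or above it the dark ratio is 0.
#'
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(dark_ratio_threshold = 0.6,
                              resolution_mm_per_px = 0.086,
                              degenerate_gray_span = 2,
                              uniform_dark_cut = 110) {
  if (dark_ratio_threshold <= 0 || dark_ratio_threshold >= 1) {
    stop("'dark_ratio_threshold' must lie in (0, 1)", call. = FALSE)
  }
  if (resolution_mm_per_px <= 0) {
    stop("'resolution_mm_per_px' must be > 0", call. = FALSE)
  }
  structure(list(dark_ratio_threshold = dark_ratio_threshold,
                 resolution_mm_per_px = resolution_mm_per_px,
                 degenerate_gray_span = degenerate_gray_span,
                 uniform_dark_cut = uniform_dark_cut),
            class = "classifier_params")
}

#' Two-cluster partition of grayscale values
#'
#' Splits a grain's pixel grays into "dark" and "light" clusters at the
#' globally optimal 1-D 2-means partition: the split minimizing total
#' within-cluster squared deviation. In one dimension the optimum is a
#' contiguous split of the sorted values, so it is found by an exact scan
#' over the n-1 split points (prefix sums) rather than iterative
#' refinement — no seeding, no convergence tolerance, deterministic.
#' The cluster with the lower centroid is "dark". If the gray span is at
#' or below `degenerate_span` the values form a single cluster and
#' `degenerate = TRUE` is returned (callers apply the uniform-grain
#' rule).
#'
#' @param gray_values numeric vector of grayscale values (length >= 1).
#' @param degenerate_span span cut for the single-cluster fallback
#'   (default 2).
#' @return List with `dark_indices`, `light_indices` (indices into
#'   `gray_values`), `centroids` (dark, light) and `degenerate`.
#' @export
cluster_gray_levels <- function(gray_values, degenerate_span = 2) {
  n <- length(gray_values)
  if (n == 0L) stop("no grayscale values supplied", call. = FALSE)
  if (anyNA(gray_values)) stop("grayscale values contain NA", call. = FALSE)
  if (max(gray_values) - min(gray_values) <= degenerate_span) {
    return(list(dark_indices = seq_len(n), light_indices = integer(0),
                centroids = c(mean(gray_values), NA_real_),
                degenerate = TRUE))
  }
  ord <- order(gray_values)
  x <- gray_values[ord]
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  k <- seq_len(n - 1)
  # within-cluster SS of x[1..k] and x[(k+1)..n]
  ss_lo <- cs2[k] - cs[k]^2 / k
  ss_hi <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  cost <- ss_lo + ss_hi
  kbest <- which.min(cost)
  dark <- ord[seq_len(kbest)]
  light <- ord[(kbest + 1):n]
  list(dark_indices = sort(dark), light_indices = sort(light),
       centroids = c(mean(gray_values[dark]), mean(gray_values[light])),
       degenerate = FALSE)
}

#' Dark ratio
#'
#' The per-grain statistic `DR = N_d / N_t`: the fraction of a grain's
#' pixels assigned to the darker cluster. Filled grains are largely
#' opaque under backlight (class mean 0.87); unfilled grains transmit
#' light through the empty hull (class mean 0.25).
#'
#' @param n_dark dark pixel count.
#' @param n_total total pixel count (>= 1).
#' @return `n_dark / n_total`.
#' @export
dark_ratio <- function(n_dark, n_total) {
  if (any(n_total < 1)) stop("'n_total' must be >= 1", call. = FALSE)
  if (any(n_dark < 0) || any(n_dark > n_total)) {
    stop("'n_dark' must lie in [0, n_total]", call. = FALSE)
  }
  n_dark / n_total
}

#' Classify a grain from its dark ratio
#'
#' A grain is filled iff its dark ratio strictly exceeds the threshold
#' (a dark ratio exactly at the threshold is unfilled).
#'
#' @param dr dark ratio(s) in `[0, 1]`.
#' @param threshold cut in (0, 1) (default 0.6).
#' @return Character vector, `"filled"` or `"unfilled"`.
#' @export
classify_grain <- function(dr, threshold = 0.6) {
  if (any(dr < 0 | dr > 1)) stop("'dr' must lie in [0, 1]", call. = FALSE)
  ifelse(dr > threshold, "filled", "unfilled")
}

# Min-area enclosing rectangle of a point set by rotating calipers over
# the convex hull edges. Returns sides (long, short), center, angle of
# the long side in degrees.
min_area_rect <- function(pts) {
  hull <- grDevices::chull(pts)
  h <- pts[hull, , drop = FALSE]
  nh <- nrow(h)
  if (nh == 1L) {
    return(list(long = 0, short = 0, center = h[1, ], angle = 0))
  }
  edges <- rbind(h[-1, , drop = FALSE], h[1, , drop = FALSE]) - h
  ang <- unique(round(atan2(edges[, 2], edges[, 1]) %% pi, 12))
  best <- NULL
  for (a in ang) {
    ca <- cos(a); sa <- sin(a)
    rx <- h[, 1] * ca + h[, 2] * sa
    ry <- -h[, 1] * sa + h[, 2] * ca
    wdt <- max(rx) - min(rx); hgt <- max(ry) - min(ry)
    if (is.null(best) || wdt * hgt < best$area - 1e-12) {
      cx <- (max(rx) + min(rx)) / 2; cy <- (max(ry) + min(ry)) / 2
      best <- list(area = wdt * hgt, w = wdt, h = hgt, a = a,
                   center = c(cx * ca - cy * sa, cx * sa + cy * ca))
    }
  }
  if (best$w >= best$h) {
    long <- best$w; short <- best$h; la <- best$a
  } else {
    long <- best$h; short <- best$w; la <- (best$a + pi / 2) %% pi
  }
  list(long = long, short = short, center = best$center,
       angle = la * 180 / pi)
}

#' Measure grain size via the minimum-area enclosing rectangle
#'
#' Computes the smallest-area rotated rectangle enclosing the grain's
#' pixel set (rotating calipers over the convex hull) and converts its
#' sides to millimeters. Sides are measured in pixel-center units — the
#' span between outermost pixel centers — with no +1 footprint
#' correction: under backlight the fixed binarization threshold sits
#' high on the grain-to-background edge ramp and already captures
#' partially covered boundary pixels, so the center span is the less
#' biased estimate of the true silhouette extent.
#'
#' @param region a `grain_region` from [extract_regions()] with area
#'   >= 3.
#' @param resolution mm per pixel (default 0.086).
#' @return List with `length_mm`, `width_mm`, `length_px`, `width_px`,
#'   `center` (planar px, 0-based), `angle_deg` (orientation of the long
#'   side, in `[0, 180)`).
#' @export
measure_size <- function(region, resolution = 0.086) {
  stopifnot(inherits(region, "grain_region"))
  if (region$area < 3) {
    stop("degenerate region: area < 3 px cannot support a rectangle",
         call. = FALSE)
  }
  pts <- region$pixels[, c("col", "row"), drop = FALSE]
  storage.mode(pts) <- "double"
  rect <- min_area_rect(pts)
  list(length_mm = rect$long * resolution,
       width_mm = rect$short * resolution,
       length_px = rect$long, width_px = rect$short,
       center = rect$center, angle_deg = rect$angle)
}

#' Phenotype a list of grain regions
#'
#' For each segmented grain: partition its grays with
#' [cluster_gray_levels()], compute the dark ratio, classify
#' filled/unfilled at the threshold, and measure length/width. Degenerate
#' uniform grains get dark ratio 1 if their mean gray is below
#' `uniform_dark_cut` (an opaque uniform grain), else 0.
#'
#' @param regions list of `grain_region`s from [extract_regions()].
#' @param params a [classifier_params()].
#' @return A data.frame with one row per grain: `label`, `centroid_x`,
#'   `centroid_y`, `area_px`, `n_dark`, `n_total`, `dark_ratio`,
#'   `filled`, `length_mm`, `width_mm`, `rect_cx`, `rect_cy`,
#'   `rect_angle_deg`.
#' @export
phenotype_grains <- function(regions, params = classifier_params()) {
  stopifnot(inherits(params, "classifier_params"))
  rows <- lapply(regions, function(rg) {
    cl <- cluster_gray_levels(rg$gray_values, params$degenerate_gray_span)
    if (cl$degenerate) {
      nd <- if (mean(rg$gray_values) < params$uniform_dark_cut) rg$area else 0L
    } else {
      nd <- length(cl$dark_indices)
    }
    dr <- dark_ratio(nd, rg$area)
    sz <- measure_size(rg, params$resolution_mm_per_px)
    data.frame(label = rg$label,
               centroid_x = mean(rg$pixels[, "col"]),
               centroid_y = mean(rg$pixels[, "row"]),
               area_px = rg$area,
               n_dark = nd, n_total = rg$area,
               dark_ratio = dr,
               filled = dr > params$dark_ratio_threshold,
               length_mm = sz$length_mm, width_mm = sz$width_mm,
               rect_cx = sz$center[1], rect_cy = sz$center[2],
               rect_angle_deg = sz$angle_deg)
  })
  if (!length(rows)) {
    return(data.frame(label = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area_px = integer(0),
                      n_dark = integer(0), n_total = integer(0),
                      dark_ratio = numeric(0), filled = logical(0),
                      length_mm = numeric(0), width_mm = numeric(0),
                      rect_cx = numeric(0), rect_cy = numeric(0),
                      rect_angle_deg = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Summarize a panicle
#'
#' Total, filled and unfilled counts plus the filled fraction for one
#' analyzed image (one panicle's worth of grains).
#'
#' @param phenotypes data.frame from [phenotype_grains()].
#' @param excluded_border_count grains dropped at the raster border.
#' @return An object of class `panicle_summary`: list with
#'   `total_count`, `filled_count`, `unfilled_count`, `filled_fraction`
#'   (`NA` when empty), `excluded_border_count`.
#' @export
summarize_panicle <- function(phenotypes, excluded_border_count = 0L) {
  total <- nrow(phenotypes)
  filled <- sum(phenotypes$filled)
  structure(list(total_count = total,
                 filled_count = filled,
                 unfilled_count = total - filled,
                 filled_fraction = if (total > 0) filled / total else NA_real_,
                 excluded_border_count = as.integer(excluded_border_count)),
            class = "panicle_summary")
}

#' @export
print.panicle_summary <- function(x, ...) {
  cat(sprintf("<panicle_summary> total %d | filled %d | unfilled %d",
              x$total_count, x$filled_count, x$unfilled_count))
  if (!is.na(x$filled_fraction)) {
    cat(sprintf(" | filled fraction %.3f", x$filled_fraction))
  }
  if (x$excluded_border_count > 0) {
    cat(sprintf(" | %d excluded at border", x$excluded_border_count))
  }
  cat("\n")
  invisible(x)
}
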