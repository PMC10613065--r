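#' Watershed segmentation parameters
#'
#' Grains spread on the turntable frequently touch; marker-based
#' watershed flooding splits those clumps. Markers are derived from the
#' Euclidean distance transform: pixels whose distance to background
#' exceeds a fraction of the (per-component) distance maximum form the
#' sure-foreground seeds, the dilated mask bounds the sure-background,
#' and the band between them is the unknown region the flooding assigns.
#'
#' @param bg_dilate_iters dilation iterations (3x3 box element) used to
#'   grow the mask into the sure-background bound (default 3) — enough to
#'   guarantee an unknown band around every grain without bridging
#'   distant grains.
#' @param fg_dist_fraction fraction of the distance-transform maximum
#'   used to threshold sure-foreground, in (0, 1) (default 0.55: high
#'   enough that the cores of tangent grains separate across the
#'   contact weld, while isolated grains keep a single connected core).
#' @param per_component_fraction apply the fraction per 8-connected
#'   component (default `TRUE`) rather than globally; a global fraction
#'   starves small grains lying next to large ones.
#' @param exclude_border drop regions touching the raster edge (default
#'   `TRUE`): a clipped grain would bias both size and dark-ratio
#'   statistics.
#' @param min_seed_area sure-foreground components smaller than this
#'   many pixels are dissolved into the unknown region instead of
#'   seeding a grain (default 10). The discrete distance transform
#'   zig-zags by a fraction of a pixel along diagonal ridges, so an
#'   isolated pixel can cross the threshold on its own; a genuine grain
#'   core at these scales is hundreds of pixels.
#'
#' @return An object of class `watershed_params`.
#' @export
watershed_params <- function(bg_dilate_iters = 3, fg_dist_fraction = 0.55,
                             per_component_fraction = TRUE,
                             exclude_border = TRUE, min_seed_area = 10) {
  if (fg_dist_fraction <= 0 || fg_dist_fraction >= 1) {
    stop("'fg_dist_fraction' must lie in (0, 1)", call. = FALSE)
  }
  if (bg_dilate_iters < 1) stop("'bg_dilate_iters' must be >= 1", call. = FALSE)
  if (min_seed_area < 1) stop("'min_seed_area' must be >= 1", call. = FALSE)
  structure(list(bg_dilate_iters = bg_dilate_iters,
                 fg_dist_fraction = fg_dist_fraction,
                 per_component_fraction = isTRUE(per_component_fraction),
                 exclude_border = isTRUE(exclude_border),
                 min_seed_area = min_seed_area),
            class = "watershed_params")
}

#' Euclidean distance transform
#'
#' Distance of each foreground pixel to the nearest background pixel,
#' in pixels; background pixels get 0.
#'
#' @param mask logical matrix.
#' @return Numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(mask * 1, metric = "euclidean")
  m <- EBImage::imageData(d)
  dim(m) <- dim(mask)
  m
}

#' Compute watershed markers
#'
#' Builds the three marker classes from a cleaned binary mask:
#' sure-background bound = iterated dilation of the mask;
#' sure-foreground = distance-transform pixels at or above
#' `fg_dist_fraction` of the (per-component or global) distance maximum;
#' unknown = the difference. The marker raster labels sure-foreground
#' components starting at 2, background as 1, unknown as 0.
#'
#' @param mask logical matrix from [preprocess()] (holes closed, specks
#'   removed).
#' @param params a [watershed_params()].
#' @return An object of class `marker_set`: list with `sure_background`,
#'   `sure_foreground`, `unknown`, `markers` (integer raster), `mask`
#'   (the input mask) and `n_seeds`.
#' @export
compute_markers <- function(mask, params = watershed_params()) {
  stopifnot(inherits(params, "watershed_params"))
  box3 <- matrix(1, 3, 3)
  sure_bg <- mask
  for (i in seq_len(params$bg_dilate_iters)) {
    sure_bg <- EBImage::dilate(sure_bg * 1, box3) > 0
  }
  d <- distance_transform(mask)
  if (!any(mask)) {
    sure_fg <- mask
  } else if (params$per_component_fraction) {
    comp <- label_components(mask)
    fg <- which(comp > 0L)
    gv <- comp[fg]; dv <- d[fg]
    o <- order(gv, dv)
    last <- o[!duplicated(gv[o], fromLast = TRUE)]
    cmax <- numeric(max(gv))
    cmax[gv[last]] <- dv[last]
    sure_fg <- mask
    sure_fg[fg] <- dv >= params$fg_dist_fraction * cmax[gv]
  } else {
    sure_fg <- d >= params$fg_dist_fraction * max(d) & mask
  }
  # drop speckle seeds (distance-quantization artifacts, not cores)
  seeds0 <- label_components(sure_fg)
  if (max(seeds0) > 0L) {
    areas <- tabulate(seeds0[seeds0 > 0L], nbins = max(seeds0))
    small <- which(areas < params$min_seed_area)
    if (length(small)) {
      sure_fg <- sure_fg &
        !matrix(seeds0 %in% small, nrow(mask), ncol(mask))
    }
  }
  unknown <- sure_bg & !sure_fg
  seeds <- label_components(sure_fg)
  markers <- matrix(0L, nrow(mask), ncol(mask))
  markers[!sure_bg] <- 1L
  markers[seeds > 0L] <- seeds[seeds > 0L] + 1L
  structure(list(sure_background = sure_bg, sure_foreground = sure_fg,
                 unknown = unknown, markers = markers, mask = mask,
                 n_seeds = max(seeds), distance = d),
            class = "marker_set")
}

#' Marker-based watershed segmentation
#'
#' Floods the unknown region from the sure-foreground seeds over the
#' inverted distance transform (backlight grains are near-uniformly dark
#' inside clumps, so the intensity gradient carries no boundary
#' information; the distance geometry does). Every foreground pixel of
#' the mask is assigned to exactly one seed label; unknown pixels outside
#' the mask remain background. Seed labels are conserved: the number of
#' final grain labels equals the number of seeds.
#'
#' @param img the (remapped, median-filtered) [backlight_image()] —
#'   shape reference and gray source for downstream region extraction.
#' @param markers a `marker_set` from [compute_markers()].
#' @return Integer label raster (0 = background, 1..n = grains).
#' @export
watershed_segment <- function(img, markers) {
  stopifnot(inherits(markers, "marker_set"))
  m <- img_data(img)
  if (!all(dim(m) == dim(markers$mask))) {
    stop("image and marker shapes differ", call. = FALSE)
  }
  if (markers$n_seeds == 0L) {
    return(matrix(0L, nrow(m), ncol(m)))
  }
  seeds <- markers$markers
  seeds[seeds == 1L] <- 0L
  seeds[seeds > 1L] <- seeds[seeds > 1L] - 1L
  d <- if (!is.null(markers$distance)) {
    markers$distance
  } else {
    distance_transform(markers$mask)
  }
  relief <- max(d) - d           # flood the inverted distance transform
  mr <- max(relief)
  if (mr > 0) relief <- relief / mr
  lab <- EBImage::propagate(relief, EBImage::Image(seeds),
                            mask = markers$mask * 1)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"
  dim(lab) <- dim(m)
  lab
}

#' Extract per-grain regions
#'
#' Materializes each labeled grain into a `grain_region`: its 0-based
#' pixel coordinates, the grayscale values those pixels take in `img`,
#' its area, and whether it touches the raster border. Border-touching
#' regions are omitted when `params$exclude_border` (their count is
#' reported in the `excluded_border` attribute).
#'
#' @param labels integer label raster from [watershed_segment()].
#' @param img the [backlight_image()] supplying grayscale values.
#' @param params a [watershed_params()].
#' @return List of `grain_region` objects sorted by label, with
#'   attribute `excluded_border`.
#' @export
extract_regions <- function(labels, img, params = watershed_params()) {
  m <- img_data(img)
  stopifnot(all(dim(m) == dim(labels)))
  idx <- which(labels > 0L)
  out <- list()
  excluded <- 0L
  if (length(idx)) {
    nr <- nrow(labels)
    rows0 <- (idx - 1L) %% nr          # 0-based row (y)
    cols0 <- (idx - 1L) %/% nr         # 0-based col (x)
    labv <- labels[idx]
    ord <- order(labv)
    sp <- split(seq_along(idx)[ord], labv[ord])
    for (nm in names(sp)) {
      sel <- sp[[nm]]
      r0 <- rows0[sel]; c0 <- cols0[sel]
      touches <- any(r0 == 0L) || any(c0 == 0L) ||
        any(r0 == nr - 1L) || any(c0 == ncol(labels) - 1L)
      if (touches && params$exclude_border) {
        excluded <- excluded + 1L
        next
      }
      out[[length(out) + 1L]] <- structure(
        list(label = as.integer(nm),
             pixels = cbind(col = c0, row = r0),
             gray_values = m[idx[sel]],
             area = length(sel),
             touches_border = touches),
        class = "grain_region")
    }
  }
  attr(out, "excluded_border") <- excluded
  out
}

#' Segment grains in one call
#'
#' Convenience chain: [compute_markers()], [watershed_segment()],
#' [extract_regions()].
#'
#' @inheritParams watershed_segment
#' @param mask cleaned binary mask from [preprocess()].
#' @param params a [watershed_params()].
#' @return List of `grain_region`s (attribute `excluded_border`), plus
#'   attributes `labels` (the raster) and `markers`.
#' @export
segment_grains <- function(img, mask, params = watershed_params()) {
  mk <- compute_markers(mask, params)
  lab <- watershed_segment(img, mk)
  regions <- extract_regions(lab, img, params)
  attr(regions, "labels") <- lab
  attr(regions, "markers") <- mk
  regions
}
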