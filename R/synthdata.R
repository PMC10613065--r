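#' Synthetic backlight scene parameters
#'
#' The generator emulates what the turntable rig photographs: a bright,
#' lightly noisy background (transmitted backlight) carrying opaque
#' (filled) and translucent (unfilled) ellipse-shaped grains, small
#' bright glume-gap holes inside grains, dark debris specks, and —
#' optionally — touching grain pairs that exercise watershed splitting.
#' Grain dimensions default to the 8.0--11.0 mm x 2.0--3.0 mm range of
#' mature indica rice at the rig's 0.086 mm/px resolution. Within each
#' grain a contiguous dark sub-region grown from one end (emulating
#' endosperm fill) occupies the grain's target dark fraction; unfilled
#' grains additionally carry a thin dark outline ring so that they
#' survive binarization, as translucent grains do in real backlight
#' images.
#'
#' Class dark-fraction targets are drawn from truncated normals with
#' means 0.87 (filled) and 0.25 (unfilled). The spread (sd 0.08) is
#' chosen so that the upper tail of the unfilled class crosses 0.4 at a
#' low rate and the lower tail of the filled class crosses 0.7 at a low
#' rate, while essentially no mass of either class crosses 0.6 — the
#' regime in which threshold choice shows the documented over/under
#' estimation directions yet 0.6 remains near-perfect.
#'
#' @param n_filled,n_unfilled grain counts (defaults 150 / 50).
#' @param canvas `(height, width)` px, or `NULL` to size automatically
#'   from a jittered grid that guarantees `min_gap`.
#' @param background_gray mean background level (default 235).
#' @param background_sigma Gaussian pixel noise sd (default 3).
#' @param length_range_mm,width_range_mm grain size ranges (mm).
#' @param resolution_mm_per_px pixel pitch (default 0.086).
#' @param filled_dr_mean,filled_dr_sd,filled_dr_range dark-fraction
#'   target distribution for filled grains (truncated normal).
#' @param unfilled_dr_mean,unfilled_dr_sd,unfilled_dr_range same for
#'   unfilled grains.
#' @param dark_gray,light_gray per-grain base gray ranges for the dark
#'   and light phases.
#' @param ring_width_px outline ring width for unfilled grains.
#' @param gap_hole_prob probability a grain carries a glume-gap hole.
#' @param gap_hole_size_px hole diameter range, px (1--3: small enough
#'   for the closing element to fill).
#' @param n_specks background debris speck count (default 15).
#' @param speck_size_px speck diameter range, px.
#' @param speck_gray speck gray range.
#' @param placement `"separated"`, `"touching_pairs"` or `"mixed"`.
#' @param touching_frac fraction of grains placed as touching pairs in
#'   `"mixed"` mode (default 0.3).
#' @param min_gap minimum clearance between distinct grains/units, px.
#' @param intensity_scale multiplicative brightness factor emulating
#'   backlight intensity (klux) changes; mean scene gray increases
#'   strictly with it.
#' @param supersample subpixel sampling factor for edge rendering
#'   (default 4).
#' @param seed RNG seed; identical seed gives bit-identical output.
#'
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(n_filled = 150, n_unfilled = 50, canvas = NULL,
                         background_gray = 235, background_sigma = 3,
                         length_range_mm = c(8, 11),
                         width_range_mm = c(2, 3),
                         resolution_mm_per_px = 0.086,
                         filled_dr_mean = 0.87, filled_dr_sd = 0.08,
                         filled_dr_range = c(0.55, 0.98),
                         unfilled_dr_mean = 0.25, unfilled_dr_sd = 0.08,
                         unfilled_dr_range = c(0.12, 0.50),
                         dark_gray = c(40, 80), light_gray = c(180, 215),
                         ring_width_px = 3.5,
                         gap_hole_prob = 0.25, gap_hole_size_px = c(1, 3),
                         n_specks = 15, speck_size_px = c(2, 8),
                         speck_gray = c(60, 120),
                         placement = c("separated", "touching_pairs", "mixed"),
                         touching_frac = 0.3, min_gap = 8,
                         intensity_scale = 1, supersample = 4,
                         seed = NULL) {
  placement <- match.arg(placement)
  if (n_filled < 0 || n_unfilled < 0) stop("grain counts must be >= 0", call. = FALSE)
  chk01 <- function(x, nm) {
    if (any(x <= 0) || any(x >= 1)) stop("'", nm, "' must lie in (0, 1)", call. = FALSE)
  }
  chk01(filled_dr_mean, "filled_dr_mean"); chk01(unfilled_dr_mean, "unfilled_dr_mean")
  chk01(filled_dr_range, "filled_dr_range"); chk01(unfilled_dr_range, "unfilled_dr_range")
  if (max(dark_gray) >= min(light_gray) || max(light_gray) >= background_gray) {
    stop("gray ranges must satisfy dark < light < background", call. = FALSE)
  }
  rm(chk01)
  structure(as.list(environment()), class = "scene_params")
}

# truncated-normal draw by rejection (bounded retries, then clamp)
rtruncnorm1 <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x < range[1] | x > range[2]
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, range[1]), range[2])
}

# Center separation along direction 'dir' (radians) at which two
# rotated ellipses (semi-axes a/b, orientations in degrees) just touch.
# Bisection on an overlap test over sampled boundary points.
tangent_separation <- function(a1, b1, phi1, a2, b2, phi2, dir) {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  bnd <- function(a, b, phi_deg) {
    ph <- phi_deg * pi / 180
    x <- a * cos(th); y <- b * sin(th)
    cbind(x * cos(ph) - y * sin(ph), x * sin(ph) + y * cos(ph))
  }
  inside <- function(p, a, b, phi_deg) {
    ph <- phi_deg * pi / 180
    t <- p[, 1] * cos(ph) + p[, 2] * sin(ph)
    n <- -p[, 1] * sin(ph) + p[, 2] * cos(ph)
    any((t / a)^2 + (n / b)^2 < 1)
  }
  b1p <- bnd(a1, b1, phi1); b2p <- bnd(a2, b2, phi2)
  d <- c(cos(dir), sin(dir))
  overlaps <- function(s) {
    off <- matrix(s * d, nrow(b2p), 2, byrow = TRUE)
    inside(sweep(b2p + off, 2, c(0, 0)), a1, b1, phi1) ||
      inside(sweep(b1p - off, 2, c(0, 0)), a2, b2, phi2)
  }
  lo <- 0; hi <- a1 + a2 + 2
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (overlaps(mid)) lo <- mid else hi <- mid
  }
  hi
}

# Contact-lens area (px^2) of two rotated ellipses inflated by 1 px on
# each semi-axis, with centers offset by s along dir. Osculating
# (curvature-matched) contacts give a long thin lens; point contacts a
# small one.
contact_lens_area <- function(a1, b1, phi1, a2, b2, phi2, dir, s) {
  c2 <- s * c(cos(dir), sin(dir))
  half <- max(a1, a2) + 2
  xs <- seq(c2[1] / 2 - half, c2[1] / 2 + half, by = 0.5)
  ys <- seq(c2[2] / 2 - half, c2[2] / 2 + half, by = 0.5)
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  inel <- function(cx, cy, a, b, phi_deg) {
    ph <- phi_deg * pi / 180
    tt <- (gx - cx) * cos(ph) + (gy - cy) * sin(ph)
    nn <- -(gx - cx) * sin(ph) + (gy - cy) * cos(ph)
    (tt / (a + 1))^2 + (nn / (b + 1))^2 <= 1
  }
  sum(inel(0, 0, a1, b1, phi1) & inel(c2[1], c2[2], a2, b2, phi2)) * 0.25
}

# block-mean downsample of an (ny*s) x (nx*s) matrix to ny x nx
block_mean <- function(m, s) {
  ny <- nrow(m) / s; nx <- ncol(m) / s
  v1 <- colMeans(array(m, c(s, ny * s * nx)))          # over sub-rows
  a <- array(v1, c(ny, s, nx))
  a <- aperm(a, c(2, 1, 3))                            # sub-cols first
  matrix(colMeans(array(a, c(s, ny * nx))), ny, nx)
}

# Render one grain into the canvas (modified in place by the caller).
# Returns the patch and its 1-based canvas row/col ranges, or NULL if the
# grain does not intersect the canvas.
render_grain <- function(canvas_dim, cx, cy, a, b, phi_deg, dr_target,
                         dark_val, light_val, ring_w, hole, bg, s) {
  phi <- phi_deg * pi / 180
  cp <- cos(phi); sp <- sin(phi)
  ex <- sqrt((a * cp)^2 + (b * sp)^2) + 1
  ey <- sqrt((a * sp)^2 + (b * cp)^2) + 1
  x0 <- max(floor(cx - ex), 0); x1 <- min(ceiling(cx + ex), canvas_dim[2] - 1)
  y0 <- max(floor(cy - ey), 0); y1 <- min(ceiling(cy + ey), canvas_dim[1] - 1)
  if (x1 < x0 || y1 < y0) return(NULL)
  nx <- x1 - x0 + 1; ny <- y1 - y0 + 1
  sub <- ((seq_len(s) - 0.5) / s) - 0.5
  xs <- rep(x0:x1, each = s) + sub          # length nx*s
  ys <- rep(y0:y1, each = s) + sub          # length ny*s
  X <- matrix(xs, ny * s, nx * s, byrow = TRUE)
  Y <- matrix(ys, ny * s, nx * s)
  tt <- (X - cx) * cp + (Y - cy) * sp
  nn <- -(X - cx) * sp + (Y - cy) * cp
  inside <- (tt / a)^2 + (nn / b)^2 <= 1
  if (!any(inside)) return(NULL)
  vals <- matrix(bg, ny * s, nx * s)
  if (ring_w > 0 && a > ring_w && b > ring_w) {
    inner <- (tt / (a - ring_w))^2 + (nn / (b - ring_w))^2 <= 1
    ring <- inside & !inner
  } else {
    ring <- inside & FALSE
  }
  n_in <- sum(inside)
  k_dark <- round(dr_target * n_in)
  n_ring <- sum(ring)
  dark <- ring
  if (k_dark <= n_ring) {
    if (k_dark < n_ring) {           # keep only the k darkest-end ring px
      rt <- tt[ring]
      cut <- sort(rt)[k_dark]
      dark <- ring & tt <= cut
      if (k_dark == 0) dark <- ring & FALSE
    }
  } else {
    core <- inside & !ring
    rt <- tt[core]
    cut <- sort(rt)[k_dark - n_ring]
    dark <- ring | (core & tt <= cut)
  }
  vals[inside] <- light_val
  vals[dark] <- dark_val
  if (!is.null(hole)) {
    # bright interior hole on the light (glume) end
    ht <- hole$t_frac * a; hn <- 0
    hx <- cx + ht * cp - hn * sp
    hy <- cy + ht * sp + hn * cp
    inhole <- (X - hx)^2 + (Y - hy)^2 <= hole$radius^2
    vals[inhole & inside] <- bg
  }
  list(patch = block_mean(vals, s), rows = (y0 + 1):(y1 + 1),
       cols = (x0 + 1):(x1 + 1))
}

#' Generate a synthetic backlight scene with ground truth
#'
#' Renders grains as rotated ellipses with 4x supersampled (antialiased)
#' edges onto a bright background, composites debris specks, and adds
#' Gaussian pixel noise scaled by the backlight intensity factor. Grains
#' (or touching pairs, depending on `placement`) are placed on a
#' jittered grid that guarantees the configured minimum clearance.
#'
#' @param params a [scene_params()].
#' @param seed overrides `params$seed` when given.
#' @return A list with `image` (a [backlight_image()]) and `manifest`
#'   (data.frame: `id`, `cx`, `cy` 0-based planar px, `a_px`, `b_px`
#'   semi-axes, `orientation_deg`, `filled`, `target_dark_fraction`,
#'   `length_mm`, `width_mm`, `pair_id`).
#' @export
generate_scene <- function(params = scene_params(), seed = NULL) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  if (is.null(seed)) seed <- p$seed
  if (!is.null(seed)) set.seed(seed)
  n <- p$n_filled + p$n_unfilled
  res <- p$resolution_mm_per_px
  maxlen_px <- p$length_range_mm[2] / res
  maxwid_px <- p$width_range_mm[2] / res
  jitter <- 3

  # --- units: singles and touching pairs -------------------------------
  n_pair_grains <- switch(p$placement,
    separated = 0L,
    touching_pairs = n - (n %% 2L),
    mixed = { k <- floor(p$touching_frac * n / 2) * 2L; k })
  n_pairs <- n_pair_grains %/% 2L
  n_single <- n - n_pair_grains
  n_units <- n_single + n_pairs

  # two grid bands: touching pairs need roomier cells than singles
  cell_s <- ceiling(maxlen_px + p$min_gap + 2 * jitter)
  cell_p <- ceiling(2 * maxlen_px + p$min_gap + 2 * jitter)
  margin <- ceiling(maxwid_px / 2) + 12
  pcols <- if (n_pairs > 0) ceiling(sqrt(n_pairs)) else 0L
  prows <- if (n_pairs > 0) ceiling(n_pairs / pcols) else 0L
  scols <- if (n_single > 0) ceiling(sqrt(n_single)) else 0L
  srows <- if (n_single > 0) ceiling(n_single / scols) else 0L
  need <- c(prows * cell_p + srows * cell_s + 2 * margin,
            max(pcols * cell_p, scols * cell_s) + 2 * margin)
  canvas_dim <- if (is.null(p$canvas)) need else p$canvas
  if (any(canvas_dim < need)) {
    stop(sprintf(paste0("placement infeasible: %d units need a canvas of ",
                        "at least %d x %d px (got %d x %d); enlarge the ",
                        "canvas or reduce the grain count"),
                 n_units, need[1], need[2], canvas_dim[1], canvas_dim[2]),
         call. = FALSE)
  }

  # --- per-grain truth -------------------------------------------------
  if (n > 0) {
    filled <- sample(rep(c(TRUE, FALSE), c(p$n_filled, p$n_unfilled)))
    len_mm <- stats::runif(n, p$length_range_mm[1], p$length_range_mm[2])
    wid_mm <- stats::runif(n, p$width_range_mm[1], p$width_range_mm[2])
    drt <- numeric(n)
    if (any(filled)) {
      drt[filled] <- rtruncnorm1(sum(filled), p$filled_dr_mean,
                                 p$filled_dr_sd, p$filled_dr_range)
    }
    if (any(!filled)) {
      drt[!filled] <- rtruncnorm1(sum(!filled), p$unfilled_dr_mean,
                                  p$unfilled_dr_sd, p$unfilled_dr_range)
    }
  } else {
    filled <- logical(0); len_mm <- wid_mm <- drt <- numeric(0)
  }

  # --- placement on a jittered grid ------------------------------------
  cx <- cy <- phi <- numeric(n); pair_id <- rep(NA_integer_, n)
  if (n > 0) {
    ucx <- ucy <- numeric(n_units)
    if (n_pairs > 0) {
      cells <- sample(prows * pcols, n_pairs)
      ccol <- (cells - 1L) %% pcols; crow <- (cells - 1L) %/% pcols
      ucx[seq_len(n_pairs)] <- margin + ccol * cell_p + cell_p / 2 +
        stats::runif(n_pairs, -jitter, jitter)
      ucy[seq_len(n_pairs)] <- margin + crow * cell_p + cell_p / 2 +
        stats::runif(n_pairs, -jitter, jitter)
    }
    if (n_single > 0) {
      y_off <- margin + prows * cell_p
      cells <- sample(srows * scols, n_single)
      ccol <- (cells - 1L) %% scols; crow <- (cells - 1L) %/% scols
      ucx[n_pairs + seq_len(n_single)] <- margin + ccol * cell_s +
        cell_s / 2 + stats::runif(n_single, -jitter, jitter)
      ucy[n_pairs + seq_len(n_single)] <- y_off + crow * cell_s +
        cell_s / 2 + stats::runif(n_single, -jitter, jitter)
    }
    uphi <- stats::runif(n_units, 0, 180)
    gi <- 1L
    a_px <- len_mm / (2 * res); b_px <- wid_mm / (2 * res)
    for (u in seq_len(n_units)) {
      if (u <= n_pairs) {
        # two grains touching tangentially: contact roughly flank-on,
        # with angular scatter so the contact zone stays narrow (grains
        # are convex ovals; they meet at a point, not along a side)
        i1 <- gi; i2 <- gi + 1L
        phi[i1] <- uphi[u]
        # Convex 3-D grains meet at point contacts, predominantly tip
        # against tip when lying in loose chains; a 2-D ellipse pair
        # lying flank-to-flank instead osculates (boundary curvatures
        # match), welding the silhouettes into one blob no segmenter
        # could split. Contacts are therefore tip-to-tip with angular
        # scatter, resampled until the 1 px-inflated contact lens is
        # small, i.e. the gap opens promptly away from the contact.
        for (try in 1:40) {
          dir <- (uphi[u] + stats::runif(1, -20, 20)) * pi / 180
          phi[i2] <- (dir * 180 / pi + stats::runif(1, -35, 35)) %% 180
          sep <- tangent_separation(a_px[i1], b_px[i1], phi[i1],
                                    a_px[i2], b_px[i2], phi[i2], dir)
          sep <- sep - stats::runif(1, 0, 1)  # -1..0 px gap: slight contact
          lens <- contact_lens_area(a_px[i1], b_px[i1], phi[i1],
                                    a_px[i2], b_px[i2], phi[i2], dir, sep)
          if (lens <= 14) break
        }
        ox <- cos(dir) * sep / 2; oy <- sin(dir) * sep / 2
        cx[i1] <- ucx[u] - ox; cy[i1] <- ucy[u] - oy
        cx[i2] <- ucx[u] + ox; cy[i2] <- ucy[u] + oy
        pair_id[c(i1, i2)] <- u
        gi <- gi + 2L
      } else {
        cx[gi] <- ucx[u]; cy[gi] <- ucy[u]; phi[gi] <- uphi[u]
        gi <- gi + 1L
      }
    }
  }

  # --- render ----------------------------------------------------------
  canvas <- matrix(p$background_gray, canvas_dim[1], canvas_dim[2])
  a_px <- len_mm / (2 * res); b_px <- wid_mm / (2 * res)
  for (i in seq_len(n)) {
    hole <- NULL
    if (stats::runif(1) < p$gap_hole_prob) {
      hole <- list(t_frac = stats::runif(1, 0.5, 0.85),
                   radius = stats::runif(1, p$gap_hole_size_px[1],
                                         p$gap_hole_size_px[2]) / 2)
    }
    rw <- if (filled[i]) 0 else p$ring_width_px
    g <- render_grain(canvas_dim, cx[i], cy[i], a_px[i], b_px[i], phi[i],
                      drt[i],
                      dark_val = stats::runif(1, p$dark_gray[1], p$dark_gray[2]),
                      light_val = stats::runif(1, p$light_gray[1], p$light_gray[2]),
                      ring_w = rw, hole = hole, bg = p$background_gray,
                      s = p$supersample)
    if (!is.null(g)) {
      canvas[g$rows, g$cols] <- pmin(canvas[g$rows, g$cols], g$patch)
    }
  }

  # --- debris specks ---------------------------------------------------
  if (p$n_specks > 0) {
    placed <- 0L; tries <- 0L
    while (placed < p$n_specks && tries < 200L * p$n_specks) {
      tries <- tries + 1L
      sx <- stats::runif(1, 6, canvas_dim[2] - 7)
      sy <- stats::runif(1, 6, canvas_dim[1] - 7)
      sr <- stats::runif(1, p$speck_size_px[1], p$speck_size_px[2]) / 2
      if (n > 0) {
        dmin <- min(sqrt((cx - sx)^2 + (cy - sy)^2) - a_px)
        if (dmin < sr + p$min_gap + 2) next
      }
      xr <- max(floor(sx - sr - 1), 0):min(ceiling(sx + sr + 1), canvas_dim[2] - 1)
      yr <- max(floor(sy - sr - 1), 0):min(ceiling(sy + sr + 1), canvas_dim[1] - 1)
      gx <- matrix(xr, length(yr), length(xr), byrow = TRUE)
      gy <- matrix(yr, length(yr), length(xr))
      insp <- (gx - sx)^2 + (gy - sy)^2 <= sr^2
      sv <- stats::runif(1, p$speck_gray[1], p$speck_gray[2])
      blk <- canvas[yr + 1, xr + 1]
      blk[insp] <- pmin(blk[insp], sv)
      canvas[yr + 1, xr + 1] <- blk
      placed <- placed + 1L
    }
    if (placed < p$n_specks) {
      stop("speck placement infeasible; enlarge the canvas", call. = FALSE)
    }
  }

  # --- noise and intensity ---------------------------------------------
  canvas <- canvas + stats::rnorm(length(canvas), 0, p$background_sigma)
  canvas <- canvas * p$intensity_scale
  canvas <- round(pmin(pmax(canvas, 0), 255))

  manifest <- data.frame(
    id = seq_len(n), cx = cx, cy = cy, a_px = a_px, b_px = b_px,
    orientation_deg = phi, filled = filled, target_dark_fraction = drt,
    length_mm = len_mm, width_mm = wid_mm, pair_id = pair_id)
  attr(manifest, "seed") <- seed
  attr(manifest, "params") <- p
  list(image = backlight_image(canvas, resolution_mm_per_px = res,
                               remapped = TRUE, intensity = p$intensity_scale),
       manifest = manifest)
}

#' Rasterize ground-truth grain masks
#'
#' Label raster of the manifest's analytic ellipses (pixel centers
#' inside), for mask-level comparisons such as segmentation IoU.
#'
#' @param manifest manifest from [generate_scene()].
#' @param dim raster `(height, width)`; defaults to the scene's.
#' @return Integer matrix; 0 = background, otherwise the grain `id`.
#' @export
manifest_masks <- function(manifest, dim) {
  out <- matrix(0L, dim[1], dim[2])
  for (i in seq_len(nrow(manifest))) {
    g <- manifest[i, ]
    phi <- g$orientation_deg * pi / 180
    cp <- cos(phi); sp <- sin(phi)
    ex <- sqrt((g$a_px * cp)^2 + (g$b_px * sp)^2) + 1
    ey <- sqrt((g$a_px * sp)^2 + (g$b_px * cp)^2) + 1
    xr <- max(floor(g$cx - ex), 0):min(ceiling(g$cx + ex), dim[2] - 1)
    yr <- max(floor(g$cy - ey), 0):min(ceiling(g$cy + ey), dim[1] - 1)
    gx <- matrix(xr, length(yr), length(xr), byrow = TRUE)
    gy <- matrix(yr, length(yr), length(xr))
    tt <- (gx - g$cx) * cp + (gy - g$cy) * sp
    nn <- -(gx - g$cx) * sp + (gy - g$cy) * cp
    inside <- (tt / g$a_px)^2 + (nn / g$b_px)^2 <= 1
    blk <- out[yr + 1, xr + 1]
    blk[inside] <- g$id
    out[yr + 1, xr + 1] <- blk
  }
  out
}

# bilinear sample of a planar raster at fractional 0-based (x, y),
# clamped to the raster
sample_planar <- function(src, x, y) {
  nr <- nrow(src); nc <- ncol(src)
  x <- pmin(pmax(x, 0), nc - 1); y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0)
  fx <- x - x0; fy <- y - y0
  p00 <- src[cbind(y0 + 1, x0 + 1)]; p01 <- src[cbind(y0 + 1, x0 + 2)]
  p10 <- src[cbind(y0 + 2, x0 + 1)]; p11 <- src[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * p00 + fx * p01) + fy * ((1 - fx) * p10 + fx * p11)
}

#' Embed a scene in a turntable frame
#'
#' Pastes a planar scene into the center of the `(2w+1)`-square frame
#' that [distort_to_linescan()] expects, padding with the background
#' level.
#'
#' @param img a [backlight_image()].
#' @param spec a [remap_spec()].
#' @param background fill level for the frame.
#' @return A `(2w+1)`-square [backlight_image()].
#' @export
embed_in_turntable <- function(img, spec, background = 235) {
  n <- 2 * spec$w + 1
  m <- img_data(img)
  if (nrow(m) > n || ncol(m) > n) {
    stop("scene larger than the turntable frame; increase spec$w", call. = FALSE)
  }
  out <- matrix(background, n, n)
  r0 <- floor((n - nrow(m)) / 2); c0 <- floor((n - ncol(m)) / 2)
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  img_like(out, img)
}

#' Forward-distort a planar scene into line-scan geometry
#'
#' Simulates what the line-scan camera records of a planar scene on the
#' turntable: source pixel `(v, u)` samples the scene (bilinearly) at
#' the forward-mapped planar position. [remap_image()] of the output
#' restores the scene.
#'
#' @param scene a `(2w+1)`-square planar [backlight_image()] centered on
#'   the turntable axis (see [embed_in_turntable()]).
#' @param spec a [remap_spec()].
#' @return A [backlight_image()] of `scan_lines_per_rev` rows by `w`
#'   columns, flagged `remapped = FALSE`.
#' @export
distort_to_linescan <- function(scene, spec) {
  stopifnot(inherits(spec, "remap_spec"))
  m <- img_data(scene)
  n <- 2 * spec$w + 1
  if (nrow(m) != n || ncol(m) != n) {
    stop(sprintf("scene must be %d x %d for spec$w = %g (got %d x %d)",
                 n, n, spec$w, nrow(m), ncol(m)), call. = FALSE)
  }
  w <- spec$w; s <- spec$scan_lines_per_rev
  u <- rep(0:(w - 1), each = s)
  v <- rep(0:(s - 1), times = w)
  fw <- forward_remap_point(u, v, spec)
  vals <- sample_planar(m, fw$x, fw$y)
  out <- matrix(vals, nrow = s, ncol = w)   # row v, col u
  img_like(out, scene, remapped = FALSE)
}

#' Generate a synthetic validation set
#'
#' The synthetic analogue of a multi-panicle validation experiment: each
#' scene stands for one panicle, with a total grain count drawn from
#' `total_range` (the 130--290 grains a rice panicle typically bears)
#' and a filled fraction drawn from `filled_frac_range`.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param params a [scene_params()] template; per-scene counts and seeds
#'   override its `n_filled`, `n_unfilled`, `seed`.
#' @param seed master seed; scene `i` uses `seed + i`.
#' @param total_range inclusive range for per-scene total grain counts.
#' @param filled_frac_range range for the per-scene filled fraction.
#' @param out_dir when given, writes `scene_###.png` images and
#'   `truth.csv` (per-scene counts) plus `grains.csv` (per-grain truth)
#'   into it.
#' @return List with `scenes` (list of [generate_scene()] results) and
#'   `truth` (data.frame: `scene`, `total`, `filled`, `unfilled`,
#'   `seed`).
#' @export
generate_validation_set <- function(n_scenes, params = scene_params(),
                                    seed = 1, total_range = c(130, 290),
                                    filled_frac_range = c(0.6, 0.9),
                                    out_dir = NULL) {
  if (n_scenes < 1) stop("'n_scenes' must be >= 1", call. = FALSE)
  set.seed(seed)
  totals <- sample(seq(total_range[1], total_range[2]), n_scenes,
                   replace = TRUE)
  fracs <- stats::runif(n_scenes, filled_frac_range[1], filled_frac_range[2])
  filled <- round(totals * fracs)
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    p <- params
    p$n_filled <- filled[i]
    p$n_unfilled <- totals[i] - filled[i]
    p$canvas <- NULL
    scenes[[i]] <- generate_scene(p, seed = seed + i)
  }
  truth <- data.frame(scene = seq_len(n_scenes), total = totals,
                      filled = filled, unfilled = totals - filled,
                      seed = seed + seq_len(n_scenes))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_scenes)) {
      write_backlight_image(scenes[[i]]$image,
                            file.path(out_dir, sprintf("scene_%03d.png", i)))
    }
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    grains <- do.call(rbind, lapply(seq_len(n_scenes), function(i) {
      cbind(scene = i, scenes[[i]]$manifest)
    }))
    utils::write.csv(grains, file.path(out_dir, "grains.csv"),
                     row.names = FALSE)
  }
  list(scenes = scenes, truth = truth)
}
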