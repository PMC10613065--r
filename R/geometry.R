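#' Remapping specification for line-scan turntable captures
#'
#' A line-scan camera over a rotating turntable records one pixel row per
#' encoder pulse, so the raw capture is indexed by `(u, v)` where `u` is
#' the radial pixel position along the scan line and `v` the scan-line
#' (angle) index. The restoration maps source coordinates to planar
#' coordinates through a log-polar transform:
#' \deqn{\rho = e^{u \ln(w)/w},\quad \theta = 2\pi v / S,\quad
#'       x = w + \rho\cos\theta,\quad y = w + \rho\sin\theta}
#' with `w` the source width in pixels and `S` the number of scan lines
#' per full revolution. The radius therefore spans exactly `[1, w]` and
#' the restored raster is `(2w+1)` pixels square, centered on the
#' turntable axis at `(w, w)`.
#'
#' @param w source image width in pixels along the u-axis (>= 2).
#' @param scan_lines_per_rev scan lines covering one revolution
#'   (defaults to `w`, matching a rig tuned for square sampling).
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @param fill_value grayscale 0--255 used outside the valid annulus.
#'
#' @return An object of class `remap_spec`.
#' @export
remap_spec <- function(w, scan_lines_per_rev = w,
                       interpolation = c("bilinear", "nearest"),
                       fill_value = 255) {
  interpolation <- match.arg(interpolation)
  if (!is.numeric(w) || length(w) != 1L || w < 2 || w != round(w)) {
    stop("'w' must be a single integer >= 2", call. = FALSE)
  }
  s <- scan_lines_per_rev
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != round(s)) {
    stop("'scan_lines_per_rev' must be a single integer >= 1", call. = FALSE)
  }
  if (fill_value < 0 || fill_value > 255) {
    stop("'fill_value' must lie in [0, 255]", call. = FALSE)
  }
  structure(list(w = as.numeric(w), scan_lines_per_rev = as.numeric(s),
                 interpolation = interpolation,
                 fill_value = as.numeric(fill_value)),
            class = "remap_spec")
}

#' Forward map: line-scan (u, v) to planar (x, y)
#'
#' Applies the log-polar restoration transform (see [remap_spec()]) to
#' source coordinates. All arguments are vectorized; coordinates are
#' 0-based `(column, row)` with theta measured counterclockwise (in image
#' axes) from the +x direction.
#'
#' @param u radial source coordinate(s), in `[0, w]`.
#' @param v scan-line coordinate(s), in `[0, scan_lines_per_rev)`.
#' @param spec a [remap_spec()].
#'
#' @return A list with components `x`, `y`, `rho`, `theta`.
#' @export
forward_remap_point <- function(u, v, spec) {
  stopifnot(inherits(spec, "remap_spec"))
  w <- spec$w; s <- spec$scan_lines_per_rev
  if (any(u < 0 | u > w)) {
    stop(sprintf("u out of range [0, %g]: %g", w, u[which(u < 0 | u > w)[1]]),
         call. = FALSE)
  }
  if (any(v < 0 | v >= s)) {
    stop(sprintf("v out of range [0, %g): %g", s, v[which(v < 0 | v >= s)[1]]),
         call. = FALSE)
  }
  rho <- exp(u * log(w) / w)
  theta <- 2 * pi * v / s
  list(x = w + rho * cos(theta), y = w + rho * sin(theta),
       rho = rho, theta = theta)
}

# Vectorized analytic inverse; coordinates outside the annulus come back NA.
# Returns u in [0, w], v in [0, S).
inverse_remap_vec <- function(x, y, spec) {
  w <- spec$w; s <- spec$scan_lines_per_rev
  dx <- x - w; dy <- y - w
  rho <- sqrt(dx * dx + dy * dy)
  inside <- rho >= 1 & rho <= w
  u <- v <- rep(NA_real_, length(rho))
  if (any(inside)) {
    u[inside] <- w * log(rho[inside]) / log(w)
    th <- atan2(dy[inside], dx[inside]) %% (2 * pi)
    vv <- s * th / (2 * pi)
    vv[vv >= s] <- 0        # guard against 2*pi rounding
    v[inside] <- vv
  }
  list(u = u, v = v, rho = rho, inside = inside)
}

#' Inverse map: planar (x, y) to line-scan (u, v)
#'
#' Analytic inverse of [forward_remap_point()]. Points with radius
#' `rho < 1` (the center exclusion zone) or `rho > w` are outside the
#' valid annulus; for those the function signals a condition of class
#' `grainscan_out_of_annulus`, which image resampling catches to
#' substitute the fill value.
#'
#' @inheritParams forward_remap_point
#' @param x,y planar coordinate(s) in the `(2w+1)`-square restored frame.
#'
#' @return A list with components `u`, `v`, `rho`.
#' @export
inverse_remap_point <- function(x, y, spec) {
  stopifnot(inherits(spec, "remap_spec"))
  r <- inverse_remap_vec(x, y, spec)
  if (!all(r$inside)) {
    bad <- which(!r$inside)[1]
    cond <- structure(
      class = c("grainscan_out_of_annulus", "error", "condition"),
      list(message = sprintf(
             "point (%g, %g) outside annulus: rho = %g not in [1, %g]",
             x[bad], y[bad], r$rho[bad], spec$w),
           call = sys.call(-1)))
    stop(cond)
  }
  list(u = r$u, v = r$v, rho = r$rho)
}

# Bilinear / nearest sampling of a source raster at fractional (u, v).
# u is clamped to the column range (edge replication at the outer radius),
# v wraps cyclically across the scan seam.
sample_linescan <- function(src, u, v, interpolation) {
  nl <- nrow(src)   # scan lines (v)
  w  <- ncol(src)   # radial samples (u)
  if (interpolation == "nearest") {
    ui <- pmin(pmax(round(u), 0), w - 1)
    vi <- round(v) %% nl
    return(src[cbind(vi + 1, ui + 1)])
  }
  u0 <- floor(u); fu <- u - u0
  u0 <- pmin(pmax(u0, 0), w - 1); u1 <- pmin(u0 + 1, w - 1)
  fu[u0 == u1] <- 0
  v0 <- floor(v); fv <- v - v0
  v0i <- v0 %% nl; v1i <- (v0 + 1) %% nl
  p00 <- src[cbind(v0i + 1, u0 + 1)]
  p01 <- src[cbind(v0i + 1, u1 + 1)]
  p10 <- src[cbind(v1i + 1, u0 + 1)]
  p11 <- src[cbind(v1i + 1, u1 + 1)]
  (1 - fv) * ((1 - fu) * p00 + fu * p01) + fv * ((1 - fu) * p10 + fu * p11)
}

#' Restore a distorted line-scan image to planar geometry
#'
#' Resamples a raw line-scan capture into the planar `(2w+1)`-square
#' frame by inverse mapping: each destination pixel inside the annulus is
#' sampled from the source at its analytically inverted `(u, v)`
#' coordinate (bilinear by default), which avoids the holes and aliasing
#' a forward splat would produce. Destination pixels outside the annulus
#' take `spec$fill_value`. Interpolation wraps cyclically across the
#' `v = 0` scan seam.
#'
#' @param img a [backlight_image()] whose width equals `spec$w` and whose
#'   height is the number of captured scan lines.
#' @param spec a [remap_spec()].
#'
#' @return A [backlight_image()] of size `(2w+1) x (2w+1)` flagged
#'   `remapped = TRUE`.
#' @export
remap_image <- function(img, spec) {
  stopifnot(inherits(spec, "remap_spec"))
  src <- img_data(img)
  if (length(src) == 0L) stop("image is empty", call. = FALSE)
  if (ncol(src) != spec$w) {
    stop(sprintf("image width %d does not match spec$w = %g",
                 ncol(src), spec$w), call. = FALSE)
  }
  w <- spec$w
  n <- 2 * w + 1
  xs <- rep(0:(n - 1), each = n)   # column-major: y fastest
  ys <- rep(0:(n - 1), times = n)
  inv <- inverse_remap_vec(xs, ys, spec)
  out <- matrix(spec$fill_value, nrow = n, ncol = n)
  if (any(inv$inside)) {
    vals <- sample_linescan(src, inv$u[inv$inside], inv$v[inv$inside],
                            spec$interpolation)
    out[cbind(ys[inv$inside] + 1, xs[inv$inside] + 1)] <- round(vals)
  }
  img_like(out, img, remapped = TRUE)
}
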