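make_region <- function(pix, gray = rep(60, nrow(pix))) {
  structure(list(label = 1L,
                 pixels = cbind(col = pix[, 1], row = pix[, 2]),
                 gray_values = gray, area = nrow(pix),
                 touches_border = FALSE),
            class = "grain_region")
}

rect_pixels <- function(wpx, hpx, angle_deg = 0, ox = 0, oy = 0) {
  # the pixel centers of an exact wpx x hpx rectangle, rotated as a
  # point set (the rectangle oracle: spans between centers are
  # wpx-1 and hpx-1 regardless of angle)
  g <- expand.grid(x = 0:(wpx - 1), y = 0:(hpx - 1))
  a <- angle_deg * pi / 180
  cbind(g$x * cos(a) - g$y * sin(a) + ox,
        g$x * sin(a) + g$y * cos(a) + oy)
}

test_that("two-cluster partition matches the hand-worked examples", {
  cl <- cluster_gray_levels(c(10, 12, 200, 210))
  expect_equal(cl$dark_indices, c(1L, 2L))
  expect_equal(cl$light_indices, c(3L, 4L))
  expect_equal(cl$centroids, c(11, 205))
  expect_false(cl$degenerate)

  cl2 <- cluster_gray_levels(c(0, 255))
  expect_equal(cl2$dark_indices, 1L)
  expect_equal(cl2$light_indices, 2L)

  cl3 <- cluster_gray_levels(c(100, 100, 100))
  expect_true(cl3$degenerate)
  expect_equal(cl3$dark_indices, 1:3)
  expect_error(cluster_gray_levels(numeric(0)), "no grayscale")
})

test_that("split-scan clustering attains the exhaustive-split optimum", {
  set.seed(41)
  for (rep in 1:300) {
    n <- sample(3:12, 1)
    x <- sample(0:255, n, replace = TRUE)
    if (max(x) - min(x) <= 2) next
    cl <- cluster_gray_levels(x)
    got <- sum((x[cl$dark_indices] - cl$centroids[1])^2) +
      sum((x[cl$light_indices] - cl$centroids[2])^2)
    expect_equal(got, oracle_split_cost(x)$cost, tolerance = 1e-9)
    expect_lt(cl$centroids[1], cl$centroids[2])
  }
})

test_that("contiguous split equals the unrestricted 2-partition optimum", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    x <- sample(0:255, n, replace = TRUE)
    if (max(x) - min(x) <= 2) next
    cl <- cluster_gray_levels(x)
    got <- sum((x[cl$dark_indices] - cl$centroids[1])^2) +
      sum((x[cl$light_indices] - cl$centroids[2])^2)
    expect_equal(got, oracle_partition_cost(x), tolerance = 1e-9)
  }
})

test_that("dark ratio is the exact pixel-count quotient", {
  expect_identical(dark_ratio(3, 4), 0.75)
  expect_identical(dark_ratio(7, 7), 1)
  expect_identical(dark_ratio(0, 5), 0)
  # scale invariance: duplicating every pixel leaves DR unchanged
  expect_equal(dark_ratio(13, 29), dark_ratio(26, 58))
  expect_error(dark_ratio(1, 0), "n_total")
  expect_error(dark_ratio(5, 4), "n_dark")
})

test_that("classification exceeds strictly and is monotone", {
  expect_equal(classify_grain(0.87), "filled")
  expect_equal(classify_grain(0.25), "unfilled")
  expect_equal(classify_grain(0.6), "unfilled")       # strict "exceeds"
  expect_equal(classify_grain(0.6 + 1e-9), "filled")
  drs <- seq(0, 1, by = 0.05)
  cls <- classify_grain(drs, 0.6)
  expect_true(all(diff(cls == "filled") >= 0))        # monotone in dr
  expect_equal(classify_grain(0.5, 0.4), "filled")    # monotone in -threshold
  expect_error(classify_grain(1.2), "dr")
})

test_that("enclosing rectangle measures center spans exactly on rectangles", {
  # 100 x 30 px axis-aligned rectangle: spans of 99 x 29 px between centers
  pix <- rect_pixels(100, 30)
  sz <- measure_size(make_region(pix), 0.086)
  expect_equal(sz$length_px, 99)
  expect_equal(sz$width_px, 29)
  expect_equal(sz$length_mm, 99 * 0.086)
  expect_equal(sz$width_mm, 29 * 0.086)

  # rotated by 37 degrees: within 2 px of the same spans
  pix37 <- rect_pixels(100, 30, angle_deg = 37)
  sz37 <- measure_size(make_region(pix37), 0.086)
  expect_lt(abs(sz37$length_px - 99), 2)
  expect_lt(abs(sz37$width_px - 29), 2)
})

test_that("enclosing rectangle is translation-invariant and rotation-stable", {
  pix <- rect_pixels(60, 20, angle_deg = 13)
  a <- measure_size(make_region(pix))
  b <- measure_size(make_region(cbind(pix[, 1] + 57, pix[, 2] + 1031)))
  expect_equal(a$length_px, b$length_px)
  expect_equal(a$width_px, b$width_px)
  for (ang in c(0, 22, 45, 68, 90)) {
    s <- measure_size(make_region(rect_pixels(60, 20, angle_deg = ang)))
    expect_lt(abs(s$length_px - 59), 2)
    expect_lt(abs(s$width_px - 19), 2)
  }
  expect_error(measure_size(make_region(cbind(1:2, 1:2))), "degenerate")
})

test_that("phenotyping a scene recovers class, size and dark ratio", {
  sc <- generate_scene(tiny_params(n_filled = 6, n_unfilled = 4, seed = 43))
  res <- analyze_image(sc$image)
  ph <- res$phenotypes
  m <- sc$manifest
  expect_equal(nrow(ph), nrow(m))
  idx <- match_regions_to_manifest(ph, m)
  expect_equal(sort(idx), 1:nrow(m))                 # bijective matching
  expect_equal(ph$filled, m$filled[idx])
  expect_equal(ph$dark_ratio, m$target_dark_fraction[idx], tolerance = 0.08)
  expect_true(all(abs(ph$length_mm - m$length_mm[idx]) / 0.086 <= 2))
  expect_true(all(abs(ph$width_mm - m$width_mm[idx]) / 0.086 <= 2))
  expect_true(all(ph$length_mm >= ph$width_mm))
  expect_equal(ph$dark_ratio, ph$n_dark / ph$n_total)
})

test_that("degenerate uniform grains fall back to absolute darkness", {
  dark_uniform <- make_region(rect_pixels(20, 10), gray = rep(60, nrow(rect_pixels(20, 10))))
  light_uniform <- make_region(rect_pixels(20, 10), gray = rep(200, nrow(rect_pixels(20, 10))))
  phd <- phenotype_grains(list(dark_uniform))
  phl <- phenotype_grains(list(light_uniform))
  expect_equal(phd$dark_ratio, 1)
  expect_true(phd$filled)
  expect_equal(phl$dark_ratio, 0)
  expect_false(phl$filled)
})

test_that("panicle summary counts add up", {
  drs <- c(rep(0.85, 7), rep(0.2, 8))
  ph <- data.frame(filled = classify_grain(drs) == "filled")
  s <- summarize_panicle(ph)
  expect_equal(s$total_count, 15)
  expect_equal(s$filled_count, 7)
  expect_equal(s$unfilled_count, 8)
  expect_equal(s$filled_fraction, 7 / 15)
  s0 <- summarize_panicle(data.frame(filled = logical(0)))
  expect_equal(s0$total_count, 0)
  expect_true(is.na(s0$filled_fraction))
  s1 <- summarize_panicle(data.frame(filled = rep(TRUE, 4)))
  expect_equal(s1$filled_fraction, 1)
})
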