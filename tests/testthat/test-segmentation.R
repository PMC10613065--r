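disc_mask <- function(h, w, cx, cy, r) {
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  yy <- matrix(seq_len(h), h, w)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

test_that("distance transform equals the exhaustive nearest-background search", {
  set.seed(31)
  for (rep in 1:3) {
    mask <- matrix(FALSE, 48, 48)
    for (k in 1:3) {
      mask <- mask | disc_mask(48, 48, sample(10:38, 1), sample(10:38, 1),
                               sample(4:9, 1))
    }
    d <- distance_transform(mask)
    expect_equal(d, oracle_distmap(mask), tolerance = 1e-6)
  }
})

test_that("markers: one seed per convex object, spec'd marker algebra", {
  mask <- disc_mask(64, 64, 32, 32, 20)
  mk <- compute_markers(mask)
  expect_equal(mk$n_seeds, 1L)
  expect_true(mk$markers[32, 32] >= 2L)          # seed contains the center
  # marker algebra
  expect_equal(mk$unknown, mk$sure_background & !mk$sure_foreground)
  expect_true(all(mask | !mk$sure_foreground))   # sure-fg inside mask
  expect_true(all(mk$sure_background | !mask))   # mask inside sure-bg bound

  # two circles overlapping by 15% of the radius: two seeds
  r <- 20; overlap <- 0.15 * r
  mask2 <- disc_mask(64, 100, 35, 32, r) | disc_mask(64, 100, 35 + 2 * r - overlap, 32, r)
  expect_equal(max(label_components(mask2)), 1L)  # genuinely touching
  mk2 <- compute_markers(mask2)
  expect_equal(mk2$n_seeds, 2L)

  # empty mask: zero seeds, empty unknown, not an error
  mk0 <- compute_markers(matrix(FALSE, 20, 20))
  expect_equal(mk0$n_seeds, 0L)
  expect_false(any(mk0$unknown & !mk0$sure_background))
})

test_that("watershed on separated grains reduces to component labeling", {
  sc <- generate_scene(tiny_params(n_filled = 6, n_unfilled = 3, seed = 32))
  pre <- preprocess(sc$image)
  mk <- compute_markers(pre$mask)
  lab <- watershed_segment(pre$filtered, mk)
  comp <- label_components(pre$mask)
  expect_equal(max(lab), max(comp))
  # label partition: every mask pixel labeled, labels disjoint by construction
  expect_true(all(lab[pre$mask] > 0L))
  expect_true(all(lab[!pre$mask] == 0L))
  # same partition as plain labeling (up to label numbering)
  expect_equal(length(unique(paste(lab[pre$mask], comp[pre$mask]))),
               max(comp))
  # total segmented area equals mask area exactly
  expect_equal(sum(lab > 0L), sum(pre$mask))
})

test_that("watershed conserves seeds and splits a touching pair", {
  sc <- generate_scene(tiny_params(n_filled = 2, n_unfilled = 0, seed = 33,
                                   placement = "touching_pairs",
                                   n_specks = 0))
  pre <- preprocess(sc$image)
  expect_equal(max(label_components(pre$mask)), 1L)   # merged in the mask
  mk <- compute_markers(pre$mask)
  expect_equal(mk$n_seeds, 2L)
  lab <- watershed_segment(pre$filtered, mk)
  expect_equal(max(lab), 2L)                          # seed conservation
  m <- sc$manifest
  for (i in 1:2) {
    li <- lab[round(m$cy[i]) + 1, round(m$cx[i]) + 1]
    area <- sum(lab == li)
    truth <- pi * m$a_px[i] * m$b_px[i]
    expect_lt(abs(area - truth) / truth, 0.10)
  }
})

test_that("single-seed flooding claims all foreground; shapes validated", {
  mask <- disc_mask(40, 40, 20, 20, 12)
  mk <- compute_markers(mask)
  img <- backlight_image(matrix(100, 40, 40))
  lab <- watershed_segment(img, mk)
  expect_true(all(lab[mask] == 1L))
  img_bad <- backlight_image(matrix(100, 30, 40))
  expect_error(watershed_segment(img_bad, mk), "shape")
})

test_that("region extraction partitions labels and honors the border policy", {
  lab <- matrix(0L, 20, 20)
  lab[5:8, 5:9] <- 1L
  lab[1:3, 12:15] <- 2L     # touches the top border
  img <- backlight_image(matrix(seq(0, 255, length.out = 400), 20, 20))
  keep <- extract_regions(lab, img, watershed_params(exclude_border = FALSE))
  expect_length(keep, 2)
  expect_equal(attr(keep, "excluded_border"), 0L)
  expect_true(keep[[2]]$touches_border)
  expect_false(keep[[1]]$touches_border)
  expect_equal(sum(vapply(keep, `[[`, numeric(1), "area")), sum(lab > 0L))
  # pixel sets disjoint and aligned with gray values
  r1 <- keep[[1]]
  expect_equal(r1$gray_values,
               unclass(img)[cbind(r1$pixels[, "row"] + 1, r1$pixels[, "col"] + 1)])
  drop <- extract_regions(lab, img, watershed_params(exclude_border = TRUE))
  expect_length(drop, 1)
  expect_equal(attr(drop, "excluded_border"), 1L)
  expect_equal(drop[[1]]$label, 1L)
})

test_that("watershed parameter validation", {
  expect_error(watershed_params(fg_dist_fraction = 0), "fg_dist_fraction")
  expect_error(watershed_params(fg_dist_fraction = 1), "fg_dist_fraction")
  expect_error(watershed_params(bg_dilate_iters = 0), "bg_dilate_iters")
})
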