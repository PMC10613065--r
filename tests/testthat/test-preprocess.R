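test_that("median filter matches the brute-force sliding-window oracle", {
  set.seed(11)
  m <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  img <- backlight_image(m)
  out <- median_filter(img, 5)
  expect_equal(unclass(out)[, ], oracle_median(m, 5), ignore_attr = TRUE)
  out3 <- median_filter(img, 3)
  expect_equal(unclass(out3)[, ], oracle_median(m, 3), ignore_attr = TRUE)
})

test_that("median filter basics: constants, outliers, validation", {
  img <- backlight_image(matrix(88, 20, 20))
  expect_equal(unclass(median_filter(img, 5))[, ], matrix(88, 20, 20),
               ignore_attr = TRUE)
  m <- matrix(240, 21, 21); m[11, 11] <- 5
  out <- median_filter(backlight_image(m), 5)
  expect_equal(unclass(out)[11, 11], 240)
  expect_error(median_filter(img, 4), "odd")
  expect_error(median_filter(img, 25), "dimensions")
})

test_that("binarization selects the dark phase and is threshold-monotone", {
  m <- matrix(255, 10, 10)
  expect_false(any(binarize(m, 220)))
  m2 <- matrix(240, 8, 8); m2[3:4, 5] <- 50
  mask <- binarize(m2, 220)
  expect_equal(which(mask), which(m2 == 50))
  set.seed(12)
  r <- matrix(sample(0:255, 400, TRUE), 20, 20)
  for (i in 1:20) {
    t1 <- sample(1:253, 1); t2 <- t1 + sample(1:(254 - t1), 1)
    expect_true(all(binarize(r, t2) | !binarize(r, t1)))  # t2 superset
  }
  expect_error(binarize(m, 0), "threshold")
})

test_that("closing fills small holes and never shrinks the foreground", {
  # solid ellipse: unchanged
  xx <- matrix(1:40, 40, 40, byrow = TRUE); yy <- matrix(1:40, 40, 40)
  ell <- ((xx - 20) / 14)^2 + ((yy - 20) / 8)^2 <= 1
  expect_equal(close_holes(ell, 5), ell)
  # 2 px interior hole: filled
  holed <- ell; holed[20, 20:21] <- FALSE
  expect_equal(close_holes(holed, 5), ell)
  # random blobs: superset property + brute-force oracle equality
  set.seed(13)
  for (rep in 1:3) {
    mask <- matrix(FALSE, 40, 40)
    pts <- cbind(sample(12:28, 30, TRUE), sample(12:28, 30, TRUE))
    mask[pts] <- TRUE
    out <- close_holes(mask, 5)
    expect_true(all(out[mask]))
    brush <- EBImage::makeBrush(5, "disc")
    oracle <- oracle_erode(oracle_dilate(mask, brush), brush) | mask
    expect_equal(out, oracle)
  }
})

test_that("small-object removal drops specks and keeps grains", {
  mask <- matrix(FALSE, 80, 80)
  mask[10:60, 10:60] <- TRUE              # 2601 px grain
  mask[70:74, 70:73] <- TRUE              # 20 px speck
  out <- remove_small_objects(mask, 500)
  expect_true(all(out[10:60, 10:60]))
  expect_false(any(out[70:74, 70:73]))
  expect_equal(remove_small_objects(mask, 0), mask)
  expect_true(all(mask | !out))           # subset property
  expect_error(remove_small_objects(mask, -1), "min_area")
})

test_that("component labeling uses 8-connectivity", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE   # diagonal chain
  m[5, 5] <- TRUE                                      # separate
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[1, 1])
})

test_that("preprocess chain recovers the scene's foreground", {
  sc <- generate_scene(tiny_params(n_filled = 6, n_unfilled = 4, seed = 21,
                                   n_specks = 15, speck_size_px = c(2, 8)))
  pre <- preprocess(sc$image)
  expect_equal(dim(pre$mask), dim(sc$image))
  # exactly the 10 grains survive; all 15 specks are removed
  expect_equal(max(label_components(pre$mask)), 10L)
  # foreground area within 5% of the summed truth ellipse areas
  truth_area <- sum(pi * sc$manifest$a_px * sc$manifest$b_px)
  expect_lt(abs(sum(pre$mask) - truth_area) / truth_area, 0.05)
})

test_that("preprocess parameter validation and Otsu fallback", {
  expect_error(preprocess_params(median_kernel = 4), "odd")
  expect_error(preprocess_params(bin_threshold = 256), "bin_threshold")
  # Otsu splits dark grains from bright background; use an all-filled
  # scene (translucent unfilled interiors sit above the bimodal cut)
  sc <- generate_scene(tiny_params(n_filled = 6, n_unfilled = 0, seed = 22))
  pre <- preprocess(sc$image, preprocess_params(otsu = TRUE))
  expect_true(pre$threshold > 80 && pre$threshold < 235)
  expect_equal(max(label_components(pre$mask)), 6L)
})
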