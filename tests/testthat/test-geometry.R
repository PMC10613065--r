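test_that("forward map hits the analytic anchor points", {
  spec <- remap_spec(100)
  p <- forward_remap_point(0, 0, spec)
  expect_equal(p$rho, 1)
  expect_equal(c(p$x, p$y), c(101, 100))

  p <- forward_remap_point(100, 0, spec)
  expect_equal(p$rho, 100)
  expect_equal(c(p$x, p$y), c(200, 100))

  p <- forward_remap_point(100, 25, spec)   # quarter revolution
  expect_equal(p$theta, pi / 2)
  expect_equal(c(p$x, p$y), c(100, 200))
})

test_that("forward map rejects out-of-range coordinates, naming them", {
  spec <- remap_spec(100)
  expect_error(forward_remap_point(-1, 0, spec), "u out of range")
  expect_error(forward_remap_point(101, 0, spec), "u out of range")
  expect_error(forward_remap_point(0, 100, spec), "v out of range")
})

test_that("inverse map inverts the anchors and flags the center zone", {
  spec <- remap_spec(100)
  p <- inverse_remap_point(200, 100, spec)
  expect_equal(p$u, 100)
  expect_equal(p$v, 0)
  err <- tryCatch(inverse_remap_point(100, 100, spec), condition = identity)
  expect_s3_class(err, "grainscan_out_of_annulus")
  err2 <- tryCatch(inverse_remap_point(500, 100, spec), condition = identity)
  expect_s3_class(err2, "grainscan_out_of_annulus")
})

test_that("forward and inverse maps are mutual inverses", {
  spec <- remap_spec(640, scan_lines_per_rev = 900)
  set.seed(101)
  u <- runif(1000, 0, 640)
  v <- runif(1000, 0, 900 - 1e-9)
  fw <- forward_remap_point(u, v, spec)
  bk <- inverse_remap_point(fw$x, fw$y, spec)
  expect_lt(max(abs(bk$u - u)), 1e-6)
  expect_lt(max(abs(bk$v - v)), 1e-6)
  # and the other direction, starting from annulus points
  rho <- runif(500, 1, 640); th <- runif(500, 0, 2 * pi)
  x <- 640 + rho * cos(th); y <- 640 + rho * sin(th)
  bk2 <- inverse_remap_point(x, y, spec)
  fw2 <- forward_remap_point(bk2$u, bk2$v, spec)
  expect_lt(max(abs(fw2$x - x)), 1e-9 * 640)
  expect_lt(max(abs(fw2$y - y)), 1e-9 * 640)
})

test_that("rho is monotone in u and theta monotone in v", {
  spec <- remap_spec(300)
  u <- seq(0, 300, length.out = 50)
  rho <- forward_remap_point(u, 0, spec)$rho
  expect_true(all(diff(rho) > 0))
  v <- seq(0, 299, length.out = 50)
  th <- forward_remap_point(0, v, spec)$theta
  expect_true(all(diff(th) > 0))
})

test_that("remapping a constant image gives a constant annulus", {
  w <- 80
  spec <- remap_spec(w, fill_value = 17)
  img <- backlight_image(matrix(123, w, w))
  out <- remap_image(img, spec)
  expect_equal(dim(out), c(2 * w + 1, 2 * w + 1))
  expect_true(attr(out, "remapped"))
  vals <- unique(as.vector(unclass(out)))
  expect_setequal(vals, c(123, 17))
  # center pixel is outside the annulus
  expect_equal(unclass(out)[w + 1, w + 1], 17)
  # a point at radius w/2 is inside
  expect_equal(unclass(out)[w + 1, w + 1 + round(w / 2)], 123)
})

test_that("nearest and bilinear interpolation agree on a smooth gradient", {
  w <- 120
  src <- matrix(rep(seq(40, 200, length.out = w), each = w), w, w)
  img <- backlight_image(src)
  near <- remap_image(img, remap_spec(w, interpolation = "nearest"))
  bil <- remap_image(img, remap_spec(w, interpolation = "bilinear"))
  # gradient spans 160 gray over 120 columns: < 2 gray per px, and
  # nearest vs bilinear differ by at most one sample spacing
  expect_lte(max(abs(unclass(near) - unclass(bil))), 1.5)
})

test_that("remap_image validates its input", {
  spec <- remap_spec(100)
  img <- backlight_image(matrix(200, 50, 99))
  expect_error(remap_image(img, spec), "width")
  expect_error(backlight_image(matrix(numeric(0), 0, 0)), "empty")
})

test_that("remap specification validates its fields", {
  expect_error(remap_spec(1), "w")
  expect_error(remap_spec(100, scan_lines_per_rev = 0), "scan_lines")
  expect_error(remap_spec(100, fill_value = 300), "fill_value")
  expect_error(remap_spec(100, interpolation = "cubic"))
})
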