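test_that("the principal axis hits the ground at elevation * tan(axis)", {
  cam <- camera_model()
  ctr <- pixel_to_ground(cam, c((cam$width - 1) / 2, (cam$height - 1) / 2))
  expect_equal(unname(ctr[1, 1]), 0, tolerance = 1e-12)
  expect_equal(unname(ctr[1, 2]), cam$elevation * tan(cam$axis * pi / 180),
               tolerance = 1e-9)
})

test_that("projection round-trips a 5x5 ground grid to < 1e-6 relative error", {
  cam <- camera_model()
  spacing <- 40
  g <- as.matrix(expand.grid(x = seq(-80, 80, spacing),
                             y = seq(200, 360, spacing)))
  uv <- ground_to_pixel(cam, g)
  back <- pixel_to_ground(cam, uv)
  expect_lt(max(abs(back - g)) / spacing, 1e-6)

  # and the other way: pixels -> ground -> pixels
  px <- as.matrix(expand.grid(x = seq(100, 1800, length.out = 5),
                              y = seq(100, 1000, length.out = 5)))
  rt <- ground_to_pixel(cam, pixel_to_ground(cam, px))
  expect_lt(max(abs(rt - px)), 1e-6)
})

test_that("a nadir-pointing axis reduces the mapping to a similarity", {
  hfov <- 40; w <- 800; h <- 600
  vfov <- 2 * atan(tan(hfov / 2 * pi / 180) * h / w) * 180 / pi
  cam <- camera_model(elevation = 50, inclination = -vfov / 2, hfov = hfov,
                      width = w, height = h)
  expect_equal(cam$axis, 0)
  px <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(200.5, 321.25),
              c(399.5, 299.5))
  g <- pixel_to_ground(cam, px)
  # affine with equal isotropic scales and no shear: x ~ u, y ~ -v
  sx <- unname((g[2, 1] - g[1, 1]) / (px[2, 1] - px[1, 1]))
  sy <- unname((g[3, 2] - g[1, 2]) / (px[3, 2] - px[1, 2]))
  expect_equal(sx, -sy, tolerance = 1e-12)
  pred_x <- g[1, 1] + sx * px[, 1]
  pred_y <- g[1, 2] + sy * px[, 2]
  expect_equal(g[, 1], pred_x, tolerance = 1e-9)
  expect_equal(g[, 2], pred_y, tolerance = 1e-9)
})

test_that("rays at or above the horizon and horizon-crossing views error", {
  cam <- camera_model()
  expect_error(pixel_to_ground(cam, c(960, -1e6)), "horizon")
  expect_error(camera_model(inclination = 85, hfov = 30), "horizon")
})

test_that("camera heading rotates the ground frame consistently", {
  cam0 <- camera_model(heading = 0)
  cam90 <- camera_model(heading = 90)
  p <- c(12, 250)
  p_rot <- c(-p[2], p[1])  # the same physical point in the rotated frame
  expect_equal(ground_to_pixel(cam0, p), ground_to_pixel(cam90, p_rot),
               tolerance = 1e-9)
})
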