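disk_fixture <- make_label_fixture(
  data.frame(type = "disk", cx = 60, cy = 60, a = 50, b = NA),
  dim = c(120L, 120L))

test_that("a digital disk has circularity near 1 and analytic area", {
  m <- shape_metrics(disk_fixture$labels, pixel_pitch = 1e-6)
  expect_gte(m$circularity, 0.95)
  expect_lte(m$circularity, 1.05)
  expect_equal(m$area, pi * 50^2 * 1e-12, tolerance = 0.01)
  expect_equal(m$perimeter, 2 * pi * 50 * 1e-6, tolerance = 0.01)
  expect_false(m$border)
})

test_that("a 100 x 50 rectangle has aspect ratio 2.00 within 0.02", {
  fx <- make_label_fixture(data.frame(type = "rect", cx = 60, cy = 35,
                                      a = 100, b = 50))
  m <- shape_metrics(fx$labels)
  expect_equal(m$aspect_ratio, 2, tolerance = 0.01)
  expect_equal(m$area, 5000 * 1e-12)
})

test_that("the Crofton estimator's square response matches its closed form", {
  # four-direction Crofton quadrature gives an axis-aligned a x a square
  # P = (pi/8) (4a + (8a - 4)/sqrt(2)); corners bias it ~5% below 4a, so
  # square circularity sits near 0.88, above the continuum pi/4
  a <- 100
  fx <- make_label_fixture(data.frame(type = "rect", cx = 60, cy = 60,
                                      a = a, b = a))
  m <- shape_metrics(fx$labels)
  p_pred <- (pi / 8) * (4 * a + (8 * a - 4) / sqrt(2))
  expect_equal(m$perimeter, p_pred * 1e-6)
  expect_equal(m$circularity, 4 * pi * a^2 / p_pred^2, tolerance = 1e-6)
  expect_gt(m$circularity, pi / 4)
})

test_that("an ellipse's aspect ratio and circularity match the closed forms", {
  fx <- make_label_fixture(data.frame(type = "ellipse", cx = 80, cy = 40,
                                      a = 60, b = 20))
  m <- shape_metrics(fx$labels)
  expect_equal(m$aspect_ratio, 3, tolerance = 0.02)
  expect_equal(m$circularity, fx$truth$circularity, tolerance = 0.05)
})

test_that("area and perimeter scale with pixel pitch; shape factors do not", {
  m1 <- shape_metrics(disk_fixture$labels, pixel_pitch = 1e-6)
  m2 <- shape_metrics(disk_fixture$labels, pixel_pitch = 2e-6)
  expect_equal(m2$area, 4 * m1$area)
  expect_equal(m2$perimeter, 2 * m1$perimeter)
  expect_equal(m2$aspect_ratio, m1$aspect_ratio)
  expect_equal(m2$circularity, m1$circularity)
})

test_that("metrics are invariant under 90-degree rotation", {
  fx <- make_label_fixture(data.frame(type = "rect", cx = 60, cy = 35,
                                      a = 100, b = 50))
  m <- shape_metrics(fx$labels)
  rot <- t(fx$labels)[ncol(fx$labels):1, ]     # 90-degree rotation
  mr <- shape_metrics(rot)
  for (col in c("area", "perimeter", "aspect_ratio", "circularity"))
    expect_equal(mr[[col]], m[[col]])
})

test_that("border-touching and degenerate labels are flagged", {
  lab <- matrix(0L, 20, 20)
  lab[1, 1:5] <- 1L                            # touches the border
  lab[10, 10] <- 2L                            # single pixel
  m <- shape_metrics(lab)
  expect_true(m$border[m$label == 1])
  expect_true(m$degenerate[m$label == 2])
  expect_gt(m$perimeter[m$label == 2], 0)      # perimeter floor applies
  s <- summarize_shapes(m, include_border = TRUE)
  expect_equal(s$n_cells, 1L)                  # degenerate still excluded
  expect_error(shape_metrics(matrix(0L, 4, 4)), "no labels")
})

test_that("mean 3D cell area follows pi*r*h/n", {
  expect_equal(mean_cell_area_3d(1, 1, 1), pi)
  expect_equal(mean_cell_area_3d(117.5e-6, 1e-2, 1000),
               pi * 117.5e-6 * 1e-2 / 1000)
  expect_equal(mean_cell_area_3d(1, 1, 2), mean_cell_area_3d(1, 1, 1) / 2)
  expect_error(mean_cell_area_3d(1, 1, 0), "positive integer")
  expect_error(mean_cell_area_3d(-1, 1, 1), "'r'")
})
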