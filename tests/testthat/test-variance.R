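test_that("directional variance hits its closed-form anchors", {
  expect_equal(directional_variance(c(30, 30, 30), c(1, 5, 2)), 0,
               tolerance = 1e-12)
  expect_equal(directional_variance(c(0, 90)), 1, tolerance = 1e-12)
  expect_equal(directional_variance(c(45, 135), c(2, 2)), 1,
               tolerance = 1e-12)
  expect_error(directional_variance(c(0, 10), c(1, 2, 3)), "length")
  expect_error(directional_variance(c(0, 10), c(1, -1)), "nonnegative")
  expect_warning(v <- directional_variance(c(0, 10), c(0, 0)), "undefined")
  expect_true(is.na(v))
})

test_that("sampled axial von Mises matches the Bessel closed form", {
  # oracle: 1 - I1(k)/I0(k); 1e5 draws at kappa = 2
  th <- scarkit:::sample_axial_deg(1e5, 40, 2)
  expect_lt(abs(directional_variance(th) - vm_directional_variance(2)), 0.01)
})

test_that("local variance is small everywhere on an aligned phantom", {
  ph <- generate_fiber_phantom(phantom_spec(
    image_height_px = 128, image_width_px = 128, n_fibers = 2000,
    kappa = 1e6, mean_orientation_deg = 20, target_density = 0.15,
    fiber_length_px = 40, seed = 3))
  cm <- segment_collagen(ph$image)
  f <- estimate_orientation_field(cm, 8)
  loc <- local_directional_variance(f, 50)
  expect_lt(loc$mean, 0.05)
  expect_lt(max(loc$map, na.rm = TRUE), 0.25)
  # mean local cannot exceed overall by more than sampling slack
  expect_lte(loc$mean, overall_directional_variance(f) + 0.05)
})

test_that("uniform random orientations give near-unit local variance", {
  set.seed(7)
  H <- 80; W <- 80
  theta <- matrix(runif(H * W, 0, 180), H, W)
  field <- structure(list(theta_deg = theta,
                          certainty = matrix(1, H, W),
                          defined = matrix(TRUE, H, W),
                          weight = matrix(1, H, W), window_radius_px = 8),
                     class = "orientation_field")
  loc <- local_directional_variance(field, 20)
  expect_gt(loc$mean, 0.9)
  expect_gt(overall_directional_variance(field), 0.95)
})

test_that("undefined fields are signalled distinctly", {
  field <- structure(list(theta_deg = matrix(NA_real_, 8, 8),
                          certainty = matrix(NA_real_, 8, 8),
                          defined = matrix(FALSE, 8, 8),
                          weight = matrix(0, 8, 8), window_radius_px = 2),
                     class = "orientation_field")
  expect_warning(loc <- local_directional_variance(field, 5), "undefined")
  expect_true(is.na(loc$mean))
  expect_warning(v <- overall_directional_variance(field), "undefined")
  expect_true(is.na(v))
})

test_that("region restriction of the overall variance works", {
  # left half aligned at 0, right half aligned at 90
  H <- 60; W <- 120
  theta <- matrix(0, H, W); theta[, 61:120] <- 90
  field <- structure(list(theta_deg = theta, certainty = matrix(1, H, W),
                          defined = matrix(TRUE, H, W),
                          weight = matrix(1, H, W), window_radius_px = 8),
                     class = "orientation_field")
  expect_equal(overall_directional_variance(field, region_rect(0, 0, 60, 60)),
               0, tolerance = 1e-12)
  expect_equal(overall_directional_variance(field), 1, tolerance = 1e-12)
})

test_that("fiber density and blue intensity anchors", {
  m <- matrix(TRUE, 32, 32)
  expect_equal(fiber_density(make_cmap(m)), 1)
  expect_equal(fiber_density(make_cmap(matrix(FALSE, 32, 32))), 0)
  px <- array(0, dim = c(32, 32, 3)); px[, , 3] <- 0.72
  img <- trichrome_image(px)
  expect_equal(blue_intensity(img, make_cmap(m)), 0.72)
  px[, , 3] <- 1
  expect_equal(blue_intensity(trichrome_image(px), make_cmap(m)), 1)
  expect_error(blue_intensity(img, make_cmap(matrix(FALSE, 32, 32))),
               "collagen")
})

test_that("phantom density and blue level are recovered", {
  ph <- generate_fiber_phantom(phantom_spec(
    image_height_px = 128, image_width_px = 128, n_fibers = 4000, kappa = 0,
    target_density = 0.6, fiber_length_px = 30, seed = 12))
  cm <- segment_collagen(ph$image)
  expect_lt(abs(fiber_density(cm) - 0.6), 0.03)
  expect_lt(abs(blue_intensity(ph$image, cm) - 0.8), 0.05)
})
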