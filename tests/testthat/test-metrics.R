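ratio_from <- function(values, geometry = scan_geometry(3, nrow(values))) {
  structure(list(values = values, max_fd = 2, geometry = geometry),
            class = "fractal_ratio_map")
}

test_that("pixels are classified by the declared band partition", {
  v <- matrix(c(0.85, 0.15, 0.30, 0.70, 0, 1, 0.299999, 0.699999, 0.5), 3)
  cl <- classify_pixels(ratio_from(v))
  lv <- attr(cl$labels, "levels")
  expect_equal(lv[cl$labels[1, 1]], "vessel")        # 0.85
  expect_equal(lv[cl$labels[2, 1]], "large_spacing") # 0.15
  expect_equal(lv[cl$labels[3, 1]], "small_spacing") # 0.30 boundary
  expect_equal(lv[cl$labels[1, 2]], "vessel")        # 0.70 boundary
  expect_equal(lv[cl$labels[2, 2]], "large_spacing") # 0
  expect_equal(lv[cl$labels[3, 2]], "vessel")        # 1
  expect_equal(lv[cl$labels[1, 3]], "large_spacing") # just below 0.3
  expect_equal(lv[cl$labels[2, 3]], "small_spacing") # just below 0.7
  expect_error(classify_pixels(ratio_from(matrix(1.2, 2, 2))), "outside")
  expect_error(class_bands(0.7, 0.3))
})

test_that("band percentages partition to 100 over any region", {
  v <- matrix(0, 10, 10)
  v[, 1:5] <- 0.9 # half vessel, half large spacing
  cl <- classify_pixels(ratio_from(v))
  m <- band_percentages(cl)
  expect_equal(m$vessel_density_pct, 50)
  expect_equal(m$small_spacing_pct, 0)
  expect_equal(m$large_spacing_pct, 50)

  zero <- band_percentages(classify_pixels(ratio_from(matrix(0, 10, 10))))
  expect_equal(zero$large_spacing_pct, 100)
  expect_equal(zero$vessel_density_pct, 0)

  set.seed(31)
  for (k in 1:10) {
    vv <- matrix(runif(400), 20)
    region <- matrix(runif(400) < 0.5, 20)
    if (!any(region)) next
    mm <- band_percentages(classify_pixels(ratio_from(vv)), region)
    expect_equal(mm$vessel_density_pct + mm$small_spacing_pct +
                   mm$large_spacing_pct, 100, tolerance = 1e-9)
  }
  expect_error(
    band_percentages(cl, matrix(FALSE, 10, 10)), "empty")
})

test_that("the parafoveal ring is the analytic annulus", {
  g <- scan_geometry(3, 304)
  ring <- parafoveal_ring(g)
  ctr <- round(g$center_px) + 1
  expect_false(ring[ctr[1], ctr[2]])
  analytic <- pi * (1.25^2 - 0.5^2) / pixel_area_mm2(g)
  expect_lt(abs(sum(ring) - analytic) / analytic, 0.01)
  # circular symmetry: invariant under quarter rotations
  rot90 <- function(m) t(m)[, nrow(m):1]
  expect_identical(ring, rot90(ring))
  expect_error(parafoveal_ring(g, 1, 3.5), "exceeds")
})

test_that("FAZ measurement recovers carved areas and handles degenerate fields", {
  areas <- c(0.2, 0.42, 0.8)
  measured <- vapply(areas, function(a) {
    ph <- generate_phantom(phantom_spec(faz_area_mm2 = a, seed = 7))
    as.numeric(measure_faz(binarize(ph$scp)))
  }, numeric(1))
  expect_true(all(abs(measured - areas) / areas < 0.1))
  expect_true(all(diff(measured) > 0))

  g <- scan_geometry(3, 64)
  open_field <- binary_mask(matrix(FALSE, 64, 64), g)
  expect_equal(as.numeric(measure_faz(open_field)),
               64 * 64 * pixel_area_mm2(g))

  walled <- binary_mask(matrix(TRUE, 64, 64), g)
  expect_warning(absent <- measure_faz(walled), "absent")
  expect_true(is.na(absent))
})

test_that("FAZ can be seeded off-center and read from a class map", {
  g <- scan_geometry(3, 64)
  vessel <- matrix(FALSE, 64, 64)
  vessel[30:34, 30:34] <- TRUE # small island on the fovea center
  m <- binary_mask(vessel, g)
  a <- measure_faz(m, closing_radius_px = 0)
  expect_equal(as.numeric(a), (64 * 64 - 25) * pixel_area_mm2(g))

  labels <- matrix(1L, 64, 64)
  cl <- structure(list(labels = labels, bands = class_bands(), geometry = g),
                  class = "pixel_class_map")
  expect_equal(as.numeric(measure_faz(cl)), 64 * 64 * pixel_area_mm2(g))
})
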