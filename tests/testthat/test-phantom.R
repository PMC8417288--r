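test_that("identical spec and seed give bit-identical phantoms", {
  s <- phantom_spec(seed = 11, dropout_fraction = 0.2, projection_scale = 0.4)
  p1 <- generate_phantom(s)
  p2 <- generate_phantom(s)
  expect_identical(p1$scp$pixels, p2$scp$pixels)
  expect_identical(p1$dcp$pixels, p2$dcp$pixels)
  expect_identical(p1$truth$scp_mask$pixels, p2$truth$scp_mask$pixels)
  # and a different seed gives a different phantom
  p3 <- generate_phantom(phantom_spec(seed = 12, dropout_fraction = 0.2,
                                      projection_scale = 0.4))
  expect_false(identical(p1$scp$pixels, p3$scp$pixels))
})

test_that("the carved FAZ disc has the requested area and no vessels", {
  spec <- phantom_spec(seed = 3)
  m <- generate_vessel_layer(spec, "SCP")
  faz <- attr(m, "faz")
  g <- spec$geometry
  # discretized disc area within one boundary pixel-ring of the target
  r_px <- sqrt(0.42 / pi) / pixel_pitch_mm(g)
  ring_area <- 2 * pi * r_px * pixel_area_mm2(g)
  expect_lt(abs(sum(faz) * pixel_area_mm2(g) - 0.42), ring_area)
  expect_false(any(m$pixels & faz))
  # too large a disc is rejected
  expect_error(
    generate_vessel_layer(phantom_spec(faz_area_mm2 = 10, seed = 1), "SCP"),
    "larger than"
  )
})

test_that("capillary coverage tracks its target outside the FAZ", {
  for (target in c(0.2, 0.35)) {
    spec <- phantom_spec(capillary_density_target = target, seed = 8)
    m <- generate_vessel_layer(spec, "SCP")
    faz <- attr(m, "faz")
    cov <- sum(attr(m, "capillaries") & !faz) / sum(!faz)
    expect_lt(abs(cov - target) / target, 0.1)
  }
  # degenerate: no mesh, no large vessels, no FAZ ring
  empty <- generate_vessel_layer(
    phantom_spec(capillary_density_target = 0, n_large_vessels = 0,
                 faz_area_mm2 = 0, seed = 1), "SCP")
  expect_false(any(empty$pixels))
})

test_that("dropout erases the requested capillary fraction, sparing large vessels", {
  spec <- phantom_spec(seed = 5)
  m <- generate_vessel_layer(spec, "SCP")
  ncap <- sum(attr(m, "capillaries"))

  expect_identical(apply_dropout(m, 0, seed = 1)$pixels, m$pixels)

  all_gone <- apply_dropout(m, 1, seed = 1)
  expect_equal(sum(attr(all_gone, "capillaries")), 0)
  expect_identical(all_gone$pixels, attr(m, "large_vessels") & m$pixels)

  d <- apply_dropout(m, 0.3, patch_radius_px = 6, seed = 2)
  erased <- ncap - sum(attr(d, "capillaries"))
  expect_equal(erased, round(0.3 * ncap))
  expect_identical(d$pixels & attr(m, "large_vessels"),
                   attr(m, "large_vessels"))

  # coverage strictly decreases along a nested dropout sequence
  cover <- vapply(seq(0, 0.5, 0.1), function(f) {
    mean(apply_dropout(m, f, patch_radius_px = 6, seed = 2)$pixels)
  }, numeric(1))
  expect_true(all(diff(cover) < 0))
})

test_that("rendering maps masks to two intensity levels plus calibrated noise", {
  g <- scan_geometry(3, 128)
  m <- binary_mask(matrix(rep(c(TRUE, FALSE), length.out = 128 * 128), 128), g)
  two <- render_angiogram(m, noise_sd = 0, seed = 1)
  expect_setequal(unique(as.vector(two$pixels)), c(0.1, 0.8))

  flat <- render_angiogram(binary_mask(matrix(FALSE, 128, 128), g), 0)
  expect_equal(unique(as.vector(flat$pixels)), 0.1)

  noisy <- render_angiogram(binary_mask(matrix(FALSE, 128, 128), g),
                            noise_sd = 0.05, seed = 9)
  s <- sd(noisy$pixels)
  expect_gt(s, 0.04)
  expect_lt(s, 0.06)
})

test_that("projection injection behaves as scaled addition of the SCP", {
  ph <- default_phantom(seed = 6)
  g <- ph$scp$geometry
  bg <- render_angiogram(binary_mask(matrix(FALSE, g$grid_size_px,
                                            g$grid_size_px), g),
                         noise_sd = 0.02, layer = "DCP", seed = 13)
  expect_identical(inject_projection_artifact(ph$scp, bg, 0)$pixels,
                   bg$pixels)
  # scale 0.5 onto a background-only DCP: nothing clips, slope recovers 0.5
  out <- inject_projection_artifact(ph$scp, bg, 0.5)
  delta <- as.vector(out$pixels - bg$pixels)
  x <- as.vector(ph$scp$pixels)
  expect_equal(unname(coef(lm(delta ~ x))[2]), 0.5, tolerance = 1e-6)
  # scale 1: the deep pattern is the superficial one
  out1 <- inject_projection_artifact(ph$scp, bg, 1)
  expect_gt(cor(as.vector(out1$pixels), x), 0.8)
  # geometry mismatch rejected
  small <- render_angiogram(
    binary_mask(matrix(FALSE, 16, 16), scan_geometry(3, 16)), 0)
  expect_error(inject_projection_artifact(ph$scp, small, 0.5), "geometr")
})
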