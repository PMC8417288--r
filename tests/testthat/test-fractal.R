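test_that("binarization recovers the phantom vessel mask and flags oddities", {
  ph <- default_phantom(seed = 2)
  mask <- binarize(ph$scp)
  expect_identical(mask$pixels, ph$truth$scp_mask$pixels)
  expect_true(attr(mask, "threshold") > 0.1 && attr(mask, "threshold") < 0.8)

  g <- scan_geometry(3, 32)
  flat <- en_face_angiogram(matrix(0.5, 32, 32), "SCP", g)
  expect_warning(m <- binarize(flat), "constant")
  expect_false(any(m$pixels))

  # inverted contrast (sparse vessels dark on bright ground): the
  # foreground-fraction sanity check fires
  sparse <- generate_vessel_layer(
    phantom_spec(capillary_density_target = 0.15, n_large_vessels = 2,
                 seed = 2), "SCP")
  inv <- en_face_angiogram(1 - render_angiogram(sparse, 0.02, seed = 2)$pixels,
                           "SCP", sparse$geometry)
  expect_warning(binarize(inv), "inverted")
})

test_that("local dimension matches a brute-force box-count oracle", {
  set.seed(77)
  for (k in 1:3) {
    mask <- matrix(runif(64 * 64) < runif(1, 0.1, 0.5), 64)
    fd <- local_fractal_dimension(binary_mask(mask, scan_geometry(3, 64)))
    for (ij in list(c(32, 32), c(5, 60), c(1, 1))) {
      expect_equal(fd$values[ij[1], ij[2]],
                   fd_oracle(mask, ij[1], ij[2]), tolerance = 1e-9)
    }
  }
})

test_that("canonical shapes get their theoretical dimensions", {
  filled <- matrix(TRUE, 33, 33)
  fd_f <- local_fractal_dimension(binary_mask(filled, scan_geometry(3, 33)))
  expect_gte(fd_f$values[17, 17], 1.9)
  expect_lte(fd_f$values[17, 17], 2.0)
  expect_equal(fd_f$values[17, 17], fd_oracle(filled, 17, 17),
               tolerance = 1e-9)

  line <- matrix(FALSE, 33, 33)
  line[17, ] <- TRUE
  fd_l <- local_fractal_dimension(binary_mask(line, scan_geometry(3, 33)))
  expect_gte(fd_l$values[17, 17], 0.9)
  expect_lte(fd_l$values[17, 17], 1.1)

  empty <- matrix(FALSE, 33, 33)
  fd_e <- local_fractal_dimension(binary_mask(empty, scan_geometry(3, 33)))
  expect_true(all(fd_e$values == 0))
})

test_that("fractal map values stay within [0, 2] and shift with the mask", {
  set.seed(5)
  mask <- matrix(runif(80 * 80) < 0.3, 80)
  fd <- local_fractal_dimension(binary_mask(mask, scan_geometry(3, 80)))
  expect_true(all(fd$values >= 0 & fd$values <= 2))

  # translation equivariance away from borders
  k <- 7
  shifted <- matrix(FALSE, 80, 80)
  shifted[(1 + k):80, ] <- mask[1:(80 - k), ]
  fd_s <- local_fractal_dimension(binary_mask(shifted, scan_geometry(3, 80)))
  interior <- 25:55
  expect_equal(fd_s$values[interior + k, interior],
               fd$values[interior, interior])
})

test_that("window and box-size preconditions are enforced", {
  m <- binary_mask(matrix(TRUE, 33, 33), scan_geometry(3, 33))
  expect_error(local_fractal_dimension(m, window_px = 32), "odd")
  expect_error(local_fractal_dimension(m, box_sizes_px = c(8, 4)), "3 box")
  expect_error(local_fractal_dimension(m, box_sizes_px = c(4, 8, 2)),
               "decreasing")
  expect_error(local_fractal_dimension(m, window_px = 9,
                                       box_sizes_px = c(16, 8, 4, 2)),
               "largest box")
})

test_that("ratio map self-normalizes to [0, 1] with max 1", {
  ph <- default_phantom(seed = 4)
  fd <- local_fractal_dimension(binarize(ph$scp))
  ratio <- normalized_ratio_map(fd)
  expect_true(all(ratio$values >= 0 & ratio$values <= 1))
  expect_equal(max(ratio$values), 1)
  expect_equal(ratio$max_fd, max(fd$values))
  # every pixel is its dimension divided by the image maximum
  expect_equal(ratio$values, fd$values / max(fd$values))

  empty <- local_fractal_dimension(
    binary_mask(matrix(FALSE, 33, 33), scan_geometry(3, 33)))
  expect_warning(r0 <- normalized_ratio_map(empty), "all zero")
  expect_true(all(r0$values == 0))
})
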