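test_that("self- and independent-pair estimates hit their theoretical values", {
  ph <- default_phantom(seed = 21)
  est_self <- estimate_projection(ph$scp, ph$scp)
  expect_equal(est_self$correlation_r, 1)
  expect_equal(est_self$scale_alpha, 1, tolerance = 1e-6)

  # independent layers: no shared signal, alpha near zero
  est_ind <- estimate_projection(ph$scp, ph$dcp_clean)
  expect_lt(abs(est_ind$scale_alpha), 0.05)
  expect_lt(abs(est_ind$correlation_r), 0.2)

  g <- scan_geometry(3, 32)
  flat <- en_face_angiogram(matrix(0.4, 32, 32), "SCP", g)
  expect_error(estimate_projection(flat, flat), "constant")
})

test_that("an injected contamination scale is recovered", {
  ph <- generate_phantom(phantom_spec(projection_scale = 0.5, seed = 31))
  est <- estimate_projection(ph$scp, ph$dcp)
  expect_lt(abs(est$scale_alpha - 0.5), 0.05)
  # OLS is reported too, and is attenuated by detector saturation
  expect_true(is.finite(est$slope_ls))
})

test_that("removal subtracts the scaled superficial pattern", {
  ph <- default_phantom(seed = 9)
  est0 <- structure(list(scale_alpha = 0, correlation_r = 0, slope_ls = 0,
                         method = "quantile", clamped = FALSE),
                    class = "projection_estimate")
  expect_identical(remove_projection(ph$scp, ph$dcp_clean, est0)$pixels,
                   ph$dcp_clean$pixels)

  # pure projection with no intrinsic deep signal cancels to ~0
  pure <- en_face_angiogram(0.5 * ph$scp$pixels, "DCP", ph$scp$geometry)
  corrected <- remove_projection(ph$scp, pure)
  expect_lt(max(corrected$pixels), 0.02)

  # contaminated phantom: removal decorrelates from the SCP
  phc <- generate_phantom(phantom_spec(projection_scale = 0.5, seed = 9))
  fixed <- remove_projection(phc$scp, phc$dcp)
  r_before <- abs(cor(as.vector(phc$dcp$pixels), as.vector(phc$scp$pixels)))
  r_after <- abs(cor(as.vector(fixed$pixels), as.vector(phc$scp$pixels)))
  expect_lt(r_after, r_before)
  expect_true(attr(fixed, "pa_removed"))
})

test_that("removal is idempotent at the vessel-density level", {
  ph <- generate_phantom(phantom_spec(projection_scale = 0.5, seed = 14))
  once <- remove_projection(ph$scp, ph$dcp)
  # the residual scale is ~0 (possibly clamped at 0 with a warning)
  twice <- suppressWarnings(remove_projection(ph$scp, once))
  expect_lt(abs(vessel_density_of(twice) - vessel_density_of(once)), 1)
})
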