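# Synthetic en face angiogram phantoms with known ground truth.
#
# The generator emulates the structure the vessel metrics assume: a central
# avascular disc (FAZ), a space-filling capillary mesh, a handful of smooth
# large vessels crossing the field, optional capillary-dropout patches
# (disease), and optional contamination of the deep layer by the superficial
# pattern (projection artifact).

#' Phantom specification
#'
#' Parameters of a synthetic SCP/DCP angiogram pair. Defaults describe a
#' healthy 3 x 3 mm macular scan: a 0.42 mm^2 foveal avascular zone, a
#' capillary mesh covering about a third of the perifoveal field, and six
#' large vessels of ~70 um calibre, with mild acquisition noise.
#'
#' @param geometry A [scan_geometry()].
#' @param n_large_vessels Number of large vessels crossing the field.
#' @param large_vessel_width_px Large-vessel calibre in pixels.
#' @param capillary_density_target Fraction of the non-FAZ area covered by
#'   the capillary mesh, in (0, 1) (0 disables the mesh).
#' @param faz_area_mm2 Area of the carved central avascular disc, mm^2.
#' @param capillary_scale_px Correlation length of the mesh-generating
#'   random field, in pixels; sets the capillary spacing (~2-3x this value).
#' @param capillary_heterogeneity Strength of coarse-scale lognormal
#'   modulation of the mesh density (the exponent applied to a unit-variance
#'   coarse random field). Real plexuses are not uniformly dense:
#'   perivascular and watershed regions are sparser, which is what spreads
#'   the fractal-ratio histogram over its three bands. 0 gives a spatially
#'   uniform mesh; the default reproduces roughly the normal band split of
#'   healthy 3 x 3 mm scans (~half vessel, ~a third small spacing).
#' @param heterogeneity_scale_px Correlation length of the density
#'   modulation field, in pixels.
#' @param faz_irregularity Relative sd of a smooth random radial
#'   perturbation of the FAZ outline; 0 gives an exact disc (the default,
#'   so the area ground truth is exact), positive values emulate the broken,
#'   irregular perifoveal network seen in disease.
#' @param dropout_fraction Fraction of capillary pixels erased by disease
#'   patches, in [0, 1].
#' @param dropout_patch_radius_px Radius of each dropout patch.
#' @param projection_scale Strength of superficial-vessel contamination
#'   added to the deep layer, in [0, 1].
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed; identical spec + seed gives identical phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = scan_geometry(),
                         n_large_vessels = 6,
                         large_vessel_width_px = 7,
                         capillary_density_target = 0.35,
                         faz_area_mm2 = 0.42,
                         capillary_scale_px = 3,
                         capillary_heterogeneity = 2.5,
                         heterogeneity_scale_px = 40,
                         faz_irregularity = 0,
                         dropout_fraction = 0,
                         dropout_patch_radius_px = 6,
                         projection_scale = 0,
                         noise_sd = 0.05,
                         seed = 1L) {
  stopifnot(inherits(geometry, "scan_geometry"),
            n_large_vessels >= 0,
            large_vessel_width_px >= 1,
            capillary_density_target >= 0, capillary_density_target < 1,
            faz_area_mm2 >= 0,
            capillary_scale_px > 0,
            capillary_heterogeneity >= 0,
            heterogeneity_scale_px > 0,
            faz_irregularity >= 0,
            dropout_fraction >= 0, dropout_fraction <= 1,
            dropout_patch_radius_px >= 1,
            projection_scale >= 0, projection_scale <= 1,
            noise_sd >= 0)
  structure(
    list(geometry = geometry,
         n_large_vessels = as.integer(n_large_vessels),
         large_vessel_width_px = as.integer(large_vessel_width_px),
         capillary_density_target = capillary_density_target,
         faz_area_mm2 = faz_area_mm2,
         capillary_scale_px = capillary_scale_px,
         capillary_heterogeneity = capillary_heterogeneity,
         heterogeneity_scale_px = heterogeneity_scale_px,
         faz_irregularity = faz_irregularity,
         dropout_fraction = dropout_fraction,
         dropout_patch_radius_px = as.integer(dropout_patch_radius_px),
         projection_scale = projection_scale,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# FAZ region for a spec: disc of the requested area, optionally with a
# smooth radial perturbation (area ground truth then only approximate).
faz_region <- function(spec) {
  g <- spec$geometry
  if (spec$faz_area_mm2 == 0) {
    return(matrix(FALSE, g$grid_size_px, g$grid_size_px))
  }
  r_px <- sqrt(spec$faz_area_mm2 / pi) / pixel_pitch_mm(g)
  if (r_px > g$grid_size_px / 2) {
    stop("FAZ disc larger than the scanned field")
  }
  d <- dist_from_center_px(g)
  if (spec$faz_irregularity > 0) {
    n <- g$grid_size_px
    rr <- outer((seq_len(n) - 1) - g$center_px[1], rep(1, n))
    cc <- outer(rep(1, n), (seq_len(n) - 1) - g$center_px[2])
    ang <- atan2(cc, rr)
    k <- 2:4
    amp <- stats::rnorm(length(k), 0, spec$faz_irregularity / sqrt(length(k)))
    phs <- stats::runif(length(k), 0, 2 * pi)
    pert <- Reduce(`+`, Map(function(ki, ai, pi_) ai * cos(ki * ang + pi_),
                            k, amp, phs))
    d <= r_px * (1 + pert)
  } else {
    d <= r_px
  }
}

#' Generate one phantom vessel layer
#'
#' Builds a binary vessel mask containing `n_large_vessels` smooth
#' curvilinear vessels of the stated calibre crossing the field plus a
#' space-filling capillary mesh, with a central avascular disc of the
#' requested area carved out. The mesh is the set of pixels where a
#' Gaussian-smoothed random field is closest to its zero level — its level
#' curves give the curvilinear, anastomosing look of a capillary plexus —
#' with the admission threshold modulated by a second, coarser random
#' field so that mesh density varies across the image as it does across a
#' real plexus; the overall threshold is set so the mesh covers
#' `capillary_density_target` of the non-FAZ area (exact by construction,
#' up to ties). A terminal capillary ring is laid along the FAZ boundary,
#' the synthetic counterpart of the perifoveal arcade that delimits the
#' anatomical FAZ. Large-vessel paths are steered around the FAZ.
#'
#' @param spec A [phantom_spec()].
#' @param layer Layer label for bookkeeping (`"SCP"` or `"DCP"`).
#' @param seed Seed for this layer's randomness; defaults to `spec$seed`.
#' @return A [binary_mask()] with logical attributes `"capillaries"` and
#'   `"large_vessels"` splitting the mask into its two components, and
#'   `"faz"` marking the carved region.
#' @export
generate_vessel_layer <- function(spec, layer = c("SCP", "DCP"),
                                  seed = spec$seed) {
  layer <- match.arg(layer)
  g <- spec$geometry
  n <- g$grid_size_px
  with_seed_(seed, {
    faz <- faz_region(spec)
    caps <- matrix(FALSE, n, n)
    if (spec$capillary_density_target > 0) {
      field <- EBImage::gblur(matrix(stats::rnorm(n * n), n, n),
                              sigma = spec$capillary_scale_px)
      # rank of |field|: 0 on the mesh skeleton (zero level set), 1 far away
      a <- abs(field)
      score <- matrix(rank(a, ties.method = "first") / length(a), n, n)
      if (spec$capillary_heterogeneity > 0) {
        coarse <- EBImage::gblur(matrix(stats::rnorm(n * n), n, n),
                                 sigma = spec$heterogeneity_scale_px)
        coarse <- coarse / stats::sd(coarse)
        score <- score / exp(spec$capillary_heterogeneity * coarse)
      }
      thr <- stats::quantile(score[!faz],
                             probs = spec$capillary_density_target,
                             names = FALSE)
      caps <- score <= thr & !faz
      # terminal capillary ring delimiting the FAZ
      if (any(faz)) {
        ring <- (EBImage::dilate(faz * 1, EBImage::makeBrush(5, "disc")) >
                   0) & !faz
        caps <- caps | ring
      }
    }
    large <- matrix(FALSE, n, n)
    if (spec$n_large_vessels > 0) {
      r_faz_px <- if (spec$faz_area_mm2 > 0) {
        sqrt(spec$faz_area_mm2 / pi) / pixel_pitch_mm(g)
      } else 0
      path <- large_vessel_paths(spec$n_large_vessels, n, g$center_px,
                                 r_faz_px + spec$large_vessel_width_px)
      w <- spec$large_vessel_width_px
      if (w %% 2 == 0) w <- w + 1L
      if (w > 1) {
        kern <- EBImage::makeBrush(w, shape = "disc")
        path <- EBImage::dilate(path * 1, kern) > 0
      }
      large <- path & !faz
    }
    out <- binary_mask(caps | large, g)
    attr(out, "capillaries") <- caps & !large
    attr(out, "large_vessels") <- large
    attr(out, "faz") <- faz
    out
  })
}

# Random smooth paths across an n x n grid, steered away from a central
# exclusion disc. Returns a logical matrix of 1-px path traces.
large_vessel_paths <- function(n_vessels, n, center, avoid_r) {
  mask <- matrix(FALSE, n, n)
  for (v in seq_len(n_vessels)) {
    side <- sample.int(4, 1)
    t <- stats::runif(1, 0.1, 0.9) * (n - 1)
    pos <- switch(side, c(0, t), c(n - 1, t), c(t, 0), c(t, n - 1))
    target <- stats::runif(2, 0.3, 0.7) * (n - 1)
    theta <- atan2(target[2] - pos[2], target[1] - pos[1])
    for (s in seq_len(3 * n)) {
      theta <- theta + stats::rnorm(1, 0, 0.06)
      dvec <- pos - center
      dist <- sqrt(sum(dvec^2))
      if (dist < avoid_r + 8) {
        away <- atan2(dvec[2], dvec[1])
        delta <- atan2(sin(away - theta), cos(away - theta))
        theta <- theta + 0.3 * delta
      }
      pos <- pos + c(cos(theta), sin(theta))
      if (any(pos < 0) || any(pos > n - 1)) break
      mask[round(pos[1]) + 1, round(pos[2]) + 1] <- TRUE
    }
  }
  mask
}

#' Erase capillary patches to emulate capillary dropout
#'
#' Removes capillary pixels inside randomly placed discs until the erased
#' fraction of the original capillary pixels equals `dropout_fraction`
#' (exact to the pixel: the last patch is trimmed at random). Large-vessel
#' pixels are never erased; they are taken from the mask's
#' `"large_vessels"` attribute when present, otherwise identified by
#' morphological opening (capillaries, being ~1-3 px wide, vanish under a
#' 5-px disc while large vessels survive).
#'
#' @param mask A [binary_mask()], typically from [generate_vessel_layer()].
#' @param dropout_fraction Fraction of capillary pixels to erase, in [0, 1].
#' @param patch_radius_px Radius of each dropout disc.
#' @param seed Seed for patch placement.
#' @return A [binary_mask()] with the same attributes, updated.
#' @export
apply_dropout <- function(mask, dropout_fraction, patch_radius_px = 10,
                          seed = NULL) {
  stopifnot(inherits(mask, "binary_mask"),
            dropout_fraction >= 0, dropout_fraction <= 1)
  if (dropout_fraction == 0) return(mask)
  px <- mask$pixels
  caps <- attr(mask, "capillaries")
  if (is.null(caps)) {
    survives <- EBImage::opening(px * 1, EBImage::makeBrush(5, "disc")) > 0
    caps <- px & !survives
  }
  ncap <- sum(caps)
  if (ncap == 0) return(mask)
  target <- round(dropout_fraction * ncap)
  with_seed_(seed, {
    erased <- matrix(FALSE, nrow(px), ncol(px))
    if (dropout_fraction >= 1) {
      erased <- caps
    } else {
      r <- patch_radius_px
      off <- which(outer((-r):r, (-r):r, function(a, b) a^2 + b^2) <= r^2,
                   arr.ind = TRUE) - (r + 1)
      n <- nrow(px)
      done <- 0L
      iter <- 0L
      while (done < target) {
        iter <- iter + 1L
        if (iter > 5000L) {
          # patches keep landing on already-erased ground; finish directly
          pool <- which(caps & !erased)
          pick <- sample(pool, target - done)
          erased[pick] <- TRUE
          break
        }
        ctr <- sample.int(n, 2, replace = TRUE)
        rr <- off[, 1] + ctr[1]
        cc <- off[, 2] + ctr[2]
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
        cells <- cbind(rr[ok], cc[ok])
        hit <- cells[caps[cells] & !erased[cells], , drop = FALSE]
        if (nrow(hit) == 0) next
        need <- target - done
        if (nrow(hit) > need) {
          hit <- hit[sample.int(nrow(hit), need), , drop = FALSE]
        }
        erased[hit] <- TRUE
        done <- done + nrow(hit)
      }
    }
    out <- binary_mask(px & !erased, mask$geometry)
    attr(out, "capillaries") <- caps & !erased
    attr(out, "large_vessels") <- attr(mask, "large_vessels")
    attr(out, "faz") <- attr(mask, "faz")
    attr(out, "erased_fraction") <- sum(erased) / ncap
    out
  })
}

#' Render a binary vessel mask as a noisy angiogram
#'
#' Vessel pixels receive a high decorrelation-like intensity and background
#' a low one, with additive zero-mean Gaussian noise, clipped to [0, 1].
#'
#' @param mask A [binary_mask()].
#' @param noise_sd Noise standard deviation (0 gives a two-level image).
#' @param layer Layer label for the output angiogram.
#' @param seed Seed for the noise.
#' @param vessel_level,background_level Noise-free intensities of vessel
#'   and background pixels.
#' @return An [en_face_angiogram()].
#' @export
render_angiogram <- function(mask, noise_sd = 0.05, layer = "SCP",
                             seed = NULL, vessel_level = 0.8,
                             background_level = 0.1) {
  stopifnot(inherits(mask, "binary_mask"), noise_sd >= 0)
  with_seed_(seed, {
    px <- ifelse(mask$pixels, vessel_level, background_level)
    if (noise_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, noise_sd)
    }
    px <- matrix(pmin(pmax(px, 0), 1), nrow(mask$pixels), ncol(mask$pixels))
    en_face_angiogram(px, layer = layer, geometry = mask$geometry)
  })
}

#' Contaminate a deep-layer angiogram with superficial projection artifact
#'
#' Adds `projection_scale` times the superficial image to the deep image,
#' clipped to [0, 1] — the generative counterpart of the subtraction-based
#' removal in [remove_projection()]. Decorrelation tails of flowing blood in
#' superficial vessels replicate their pattern into deeper slabs; a single
#' global scale is the model used both here and by the removal stage.
#'
#' @param scp,dcp [en_face_angiogram()]s sharing one geometry.
#' @param projection_scale Contamination strength in [0, 1].
#' @return The contaminated DCP angiogram.
#' @export
inject_projection_artifact <- function(scp, dcp, projection_scale) {
  stopifnot(inherits(scp, "en_face_angiogram"),
            inherits(dcp, "en_face_angiogram"),
            projection_scale >= 0, projection_scale <= 1)
  if (!same_geometry(scp$geometry, dcp$geometry)) {
    stop("SCP and DCP geometries differ")
  }
  px <- pmin(pmax(dcp$pixels + projection_scale * scp$pixels, 0), 1)
  out <- en_face_angiogram(px, layer = dcp$layer, geometry = dcp$geometry,
                           signal_strength_index = dcp$signal_strength_index)
  attr(out, "injected_projection_scale") <- projection_scale
  out
}

#' Generate a paired SCP/DCP phantom with ground truth
#'
#' Orchestrates the full generator: independent vessel layers for the two
#' plexuses, dropout applied to the requested layers, rendering with noise,
#' and projection contamination of the deep layer. All randomness derives
#' from `spec$seed`, so identical specs give bit-identical phantoms.
#'
#' @param spec A [phantom_spec()].
#' @param dropout_layers Layers that receive the dropout lesions when
#'   `spec$dropout_fraction > 0` (deep-layer-only dropout emulates the
#'   typical deep-plexus predilection of capillary nonperfusion).
#' @return An object of class `octa_phantom`: fields `scp` and `dcp`
#'   (the observable pair, `dcp` contaminated when `projection_scale > 0`),
#'   `dcp_clean` (deep layer before contamination), and `truth` (a list
#'   with `scp_mask`, `dcp_mask`, `faz_area_mm2`, `dropout_fraction`,
#'   `projection_scale`).
#' @export
generate_phantom <- function(spec, dropout_layers = c("SCP", "DCP")) {
  stopifnot(inherits(spec, "phantom_spec"))
  base <- spec$seed %% 2147480000L
  scp_mask <- generate_vessel_layer(spec, "SCP", seed = base + 101L)
  dcp_mask <- generate_vessel_layer(spec, "DCP", seed = base + 202L)
  if (spec$dropout_fraction > 0) {
    if ("SCP" %in% dropout_layers) {
      scp_mask <- apply_dropout(scp_mask, spec$dropout_fraction,
                                spec$dropout_patch_radius_px,
                                seed = base + 303L)
    }
    if ("DCP" %in% dropout_layers) {
      dcp_mask <- apply_dropout(dcp_mask, spec$dropout_fraction,
                                spec$dropout_patch_radius_px,
                                seed = base + 404L)
    }
  }
  scp <- render_angiogram(scp_mask, spec$noise_sd, layer = "SCP",
                          seed = base + 505L)
  dcp_clean <- render_angiogram(dcp_mask, spec$noise_sd, layer = "DCP",
                                seed = base + 606L)
  dcp <- if (spec$projection_scale > 0) {
    inject_projection_artifact(scp, dcp_clean, spec$projection_scale)
  } else {
    dcp_clean
  }
  structure(
    list(scp = scp, dcp = dcp, dcp_clean = dcp_clean,
         truth = list(scp_mask = scp_mask, dcp_mask = dcp_mask,
                      faz_area_mm2 = spec$faz_area_mm2,
                      dropout_fraction = spec$dropout_fraction,
                      projection_scale = spec$projection_scale),
         spec = spec),
    class = "octa_phantom"
  )
}

#' @export
print.octa_phantom <- function(x, ...) {
  cat(sprintf(paste0(
    "<octa_phantom> %d px, FAZ %.2f mm^2, dropout %.0f%%, ",
    "projection %.2f, seed %d\n"),
    x$spec$geometry$grid_size_px, x$spec$faz_area_mm2,
    100 * x$spec$dropout_fraction, x$spec$projection_scale, x$spec$seed))
  invisible(x)
}
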