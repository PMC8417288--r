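# Whole-eye analysis pipeline: binarize -> local fractal dimension ->
# normalized ratio -> classification -> metrics, with projection-artifact
# removal applied to the deep layer before its quantification.

#' Analysis configuration
#'
#' @param window_px,box_sizes_px Fractal-analysis settings; see
#'   [local_fractal_dimension()].
#' @param bands Ratio [class_bands()].
#' @param remove_projection Remove the superficial projection artifact from
#'   the DCP before quantifying it (default TRUE).
#' @param ring_inner_d_mm,ring_outer_d_mm Parafoveal ring diameters.
#' @param faz_closing_radius_px Closing radius for [measure_faz()].
#' @param normative A [normative_reference()], or NULL to skip z-scores.
#' @param min_ssi Signal-strength index below which a quality flag is
#'   raised (never a hard error).
#' @return A list of class `octa_config`.
#' @export
octa_config <- function(window_px = 33, box_sizes_px = c(16L, 8L, 4L, 2L),
                        bands = class_bands(), remove_projection = TRUE,
                        ring_inner_d_mm = 1.0, ring_outer_d_mm = 2.5,
                        faz_closing_radius_px = 5,
                        normative = normative_reference(),
                        min_ssi = 40) {
  structure(
    list(window_px = window_px, box_sizes_px = box_sizes_px, bands = bands,
         remove_projection = remove_projection,
         ring_inner_d_mm = ring_inner_d_mm,
         ring_outer_d_mm = ring_outer_d_mm,
         faz_closing_radius_px = faz_closing_radius_px,
         normative = normative, min_ssi = min_ssi),
    class = "octa_config"
  )
}

# One layer through the fractal pipeline. Returns maps + metrics.
analyze_layer <- function(angiogram, config, ring) {
  mask <- binarize(angiogram)
  fd <- local_fractal_dimension(mask, config$window_px, config$box_sizes_px)
  ratio <- normalized_ratio_map(fd)
  classes <- classify_pixels(ratio, config$bands)
  whole <- band_percentages(classes, layer = angiogram$layer,
                            region_label = "whole_image")
  ring_m <- band_percentages(classes, region = ring,
                             layer = angiogram$layer,
                             region_label = "parafoveal_ring")
  faz <- withCallingHandlers(
    measure_faz(mask, closing_radius_px = config$faz_closing_radius_px),
    warning = function(w) invokeRestart("muffleWarning")
  )
  whole$faz_area_mm2 <- as.numeric(faz)
  list(mask = mask, ratio = ratio, classes = classes,
       metrics = list(whole_image = whole, parafoveal_ring = ring_m),
       faz_area_mm2 = as.numeric(faz))
}

#' Analyze a superficial/deep angiogram pair
#'
#' Runs the full quantification for one eye in fixed stage order:
#' projection-artifact estimation (and, when enabled, removal from the
#' DCP), then per layer binarization, local fractal dimension, normalized
#' ratio, band classification, whole-image and parafoveal-ring band
#' percentages, and FAZ measurement; finally z-scores against the
#' normative reference. DCP metrics are computed on the artifact-corrected
#' image when removal is enabled.
#'
#' @param scp,dcp [en_face_angiogram()]s of the two plexuses, same
#'   geometry.
#' @param config An [octa_config()].
#' @return An object of class `eye_report`: per-layer `metrics` (whole
#'   image and parafoveal ring), `faz_area_mm2`, maps (`ratio`, `classes`,
#'   `mask`), the `projection` estimate, z-score tables, and quality
#'   `flags` (low SSI, absent FAZ, clamped projection scale).
#' @export
analyze_eye <- function(scp, dcp, config = octa_config()) {
  stopifnot(inherits(scp, "en_face_angiogram"),
            inherits(dcp, "en_face_angiogram"),
            inherits(config, "octa_config"))
  if (!same_geometry(scp$geometry, dcp$geometry)) {
    stop("SCP and DCP geometries differ")
  }
  flags <- character(0)
  for (a in list(scp, dcp)) {
    if (!is.null(a$signal_strength_index) &&
        a$signal_strength_index < config$min_ssi) {
      flags <- c(flags, paste0("low_ssi_", tolower(a$layer)))
    }
  }
  projection <- estimate_projection(scp, dcp)
  if (projection$clamped) flags <- c(flags, "clamped_projection_scale")
  dcp_used <- if (config$remove_projection) {
    remove_projection(scp, dcp, projection)
  } else {
    dcp
  }
  ring <- parafoveal_ring(scp$geometry, config$ring_inner_d_mm,
                          config$ring_outer_d_mm)
  layers <- list(SCP = analyze_layer(scp, config, ring),
                 DCP = analyze_layer(dcp_used, config, ring))
  for (ly in names(layers)) {
    if (is.na(layers[[ly]]$faz_area_mm2)) {
      flags <- c(flags, paste0("faz_absent_", tolower(ly)))
    }
  }
  zscores <- NULL
  if (!is.null(config$normative)) {
    zscores <- lapply(layers, function(l) {
      compare_to_normative(l$metrics$whole_image, config$normative)
    })
  }
  structure(
    list(layers = layers, projection = projection, zscores = zscores,
         flags = flags, geometry = scp$geometry, config = config,
         pa_removed = isTRUE(config$remove_projection)),
    class = "eye_report"
  )
}

#' @export
print.eye_report <- function(x, ...) {
  cat("<eye_report>\n")
  cat(sprintf("  projection: alpha %.3f, r %.3f%s\n",
              x$projection$scale_alpha, x$projection$correlation_r,
              if (x$pa_removed) " (removed from DCP)" else ""))
  for (ly in names(x$layers)) {
    m <- x$layers[[ly]]$metrics$whole_image
    faz <- x$layers[[ly]]$faz_area_mm2
    cat(sprintf(
      "  %s: vessel %.2f%%, small spacing %.2f%%, large spacing %.2f%%, FAZ %s\n",
      ly, m$vessel_density_pct, m$small_spacing_pct, m$large_spacing_pct,
      if (is.na(faz)) "absent" else sprintf("%.3f mm^2", faz)))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.eye_report <- function(x, ...) {
  rows <- lapply(names(x$layers), function(ly) {
    l <- x$layers[[ly]]
    do.call(rbind, lapply(l$metrics, function(m) {
      d <- as.data.frame(m)
      d$faz_area_mm2 <- l$faz_area_mm2
      d
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize an eye report to JSON
#'
#' Deterministic JSON (fixed key order, full precision) with the metrics,
#' projection estimate, z-scores and flags; the pixel maps are omitted.
#'
#' @param report An [analyze_eye()] report.
#' @param path Optional output file; when NULL the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "eye_report"))
  payload <- list(
    metrics = lapply(report$layers, function(l) {
      lapply(l$metrics, function(m) {
        list(vessel_density_pct = m$vessel_density_pct,
             small_spacing_pct = m$small_spacing_pct,
             large_spacing_pct = m$large_spacing_pct,
             n_pixels = m$n_pixels)
      })
    }),
    faz_area_mm2 = lapply(report$layers, function(l) l$faz_area_mm2),
    projection = list(scale_alpha = report$projection$scale_alpha,
                      correlation_r = report$projection$correlation_r,
                      method = report$projection$method,
                      pa_removed = report$pa_removed),
    zscores = report$zscores,
    flags = as.list(report$flags)
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
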