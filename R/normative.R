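#' Normative reference values for vascular metrics
#'
#' Loads per-layer reference means and standard deviations for FAZ area,
#' spacing percentages and vessel density, used to express a measured eye
#' as z-scores. The shipped default encodes published normative values for
#' healthy adults on 3 x 3 mm scans; it is an editable YAML
#' (`system.file("extdata", "normative_reference.yaml", package =
#' "octafract")`) and should be replaced by a device- and
#' population-matched cohort for any real use.
#'
#' @param path YAML file with layers as top-level keys and
#'   `{mean, sd}` pairs per metric. Defaults to the shipped reference.
#' @return An object of class `normative_reference` (a named list per
#'   layer).
#' @export
normative_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "normative_reference.yaml",
                        package = "octafract")
  }
  ref <- yaml::read_yaml(path)
  for (layer in names(ref)) {
    for (metric in names(ref[[layer]])) {
      m <- ref[[layer]][[metric]]
      if (!is.numeric(m$mean) || !is.numeric(m$sd) || m$sd <= 0) {
        stop(sprintf("invalid reference for %s/%s: sd must be > 0",
                     layer, metric))
      }
    }
  }
  structure(ref, class = "normative_reference")
}

#' Compare measured metrics to a normative reference
#'
#' Computes `z = (measured - mean) / sd` for each metric with a reference
#' entry in the matching layer, flagging |z| > 2 as outside the normal
#' range. The printed reference spread is used as the SD as printed.
#'
#' @param metrics A [vascular_metrics()] (its `layer` field selects the
#'   reference row).
#' @param ref A [normative_reference()].
#' @param faz_area_mm2 Optional FAZ area to score together with the band
#'   percentages (overrides the field in `metrics`).
#' @return A data frame with columns `metric`, `measured`, `ref_mean`,
#'   `ref_sd`, `z`, `outside_normal`.
#' @export
compare_to_normative <- function(metrics, ref = normative_reference(),
                                 faz_area_mm2 = NULL) {
  stopifnot(inherits(metrics, "vascular_metrics"),
            inherits(ref, "normative_reference"))
  layer <- metrics$layer
  if (is.na(layer) || is.null(ref[[layer]])) {
    stop("no normative reference for layer '", layer, "'")
  }
  faz <- faz_area_mm2 %||% metrics$faz_area_mm2
  measured <- c(vessel_density_pct = metrics$vessel_density_pct,
                small_spacing_pct = metrics$small_spacing_pct,
                large_spacing_pct = metrics$large_spacing_pct,
                faz_area_mm2 = as.numeric(faz))
  rows <- lapply(names(measured), function(metric) {
    entry <- ref[[layer]][[metric]]
    if (is.null(entry) || is.na(measured[[metric]])) return(NULL)
    z <- (measured[[metric]] - entry$mean) / entry$sd
    data.frame(metric = metric, measured = measured[[metric]],
               ref_mean = entry$mean, ref_sd = entry$sd, z = z,
               outside_normal = abs(z) > 2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
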