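#' En face angiogram container
#'
#' A single-channel en face OCTA flow image together with the vascular layer
#' it was segmented from, its scan geometry, and the device-reported signal
#' strength index (SSI). Intensities are decorrelation-like values in [0, 1].
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param layer One of `"SCP"`, `"DCP"`, `"OR"`, `"CC"` (superficial / deep
#'   capillary plexus, outer retina, choriocapillaris).
#' @param geometry A [scan_geometry()]; the matrix must match
#'   `grid_size_px` on both axes.
#' @param signal_strength_index Optional scan-quality scalar. Values below 40
#'   are flagged in reports but never rejected: low SSI is an acquisition
#'   problem, not an analysis error.
#' @return An object of class `en_face_angiogram`.
#' @export
en_face_angiogram <- function(pixels, layer = c("SCP", "DCP", "OR", "CC"),
                              geometry = scan_geometry(),
                              signal_strength_index = NULL) {
  layer <- match.arg(layer)
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            inherits(geometry, "scan_geometry"))
  if (nrow(pixels) != geometry$grid_size_px ||
      ncol(pixels) != geometry$grid_size_px) {
    stop(sprintf("image is %d x %d but geometry expects %d x %d",
                 nrow(pixels), ncol(pixels),
                 geometry$grid_size_px, geometry$grid_size_px))
  }
  if (!all(is.finite(pixels))) stop("intensities must be finite")
  if (any(pixels < 0)) stop("intensities must be non-negative")
  if (!is.null(signal_strength_index)) {
    stopifnot(is.numeric(signal_strength_index),
              length(signal_strength_index) == 1,
              signal_strength_index >= 0)
  }
  structure(
    list(pixels = pixels, layer = layer, geometry = geometry,
         signal_strength_index = signal_strength_index),
    class = "en_face_angiogram"
  )
}

#' @export
print.en_face_angiogram <- function(x, ...) {
  cat(sprintf("<en_face_angiogram> layer %s, %d x %d px, %g mm FOV",
              x$layer, nrow(x$pixels), ncol(x$pixels),
              x$geometry$field_of_view_mm))
  if (!is.null(x$signal_strength_index)) {
    cat(sprintf(", SSI %g", x$signal_strength_index))
  }
  cat(sprintf(", intensity [%.3g, %.3g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary vessel mask
#'
#' @param pixels Logical matrix (TRUE = vessel / foreground).
#' @param geometry A [scan_geometry()] matching the matrix shape.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, geometry = scan_geometry()) {
  stopifnot(is.matrix(pixels), is.logical(pixels),
            inherits(geometry, "scan_geometry"))
  if (nrow(pixels) != geometry$grid_size_px ||
      ncol(pixels) != geometry$grid_size_px) {
    stop("mask shape does not match geometry")
  }
  structure(list(pixels = pixels, geometry = geometry),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.1f%% foreground\n",
              nrow(x$pixels), ncol(x$pixels), 100 * mean(x$pixels)))
  invisible(x)
}

#' Read an en face angiogram from a PNG or TIFF file
#'
#' Reads a single-channel 8- or 16-bit raster, rescales intensities to
#' [0, 1] by the dtype maximum (so images from the same device remain
#' comparable regardless of their individual dynamic range), and validates
#' the pixel grid against the supplied geometry. A JSON sidecar written by
#' [write_angiogram()] (same path plus `.json`) supplies layer, field of
#' view and SSI when present; explicit arguments override it.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param layer Vascular layer label; see [en_face_angiogram()].
#' @param geometry A [scan_geometry()]. Defaults to the sidecar geometry if
#'   available, else the package default.
#' @param signal_strength_index Optional SSI override.
#' @return An [en_face_angiogram()].
#' @export
read_angiogram <- function(path, layer = NULL, geometry = NULL,
                           signal_strength_index = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::fromJSON(sidecar)
  } else {
    list()
  }
  if (is.null(layer)) layer <- meta$layer %||% "SCP"
  if (is.null(geometry)) {
    geometry <- if (!is.null(meta$field_of_view_mm)) {
      scan_geometry(meta$field_of_view_mm, meta$grid_size_px)
    } else {
      scan_geometry()
    }
  }
  if (is.null(signal_strength_index)) {
    signal_strength_index <- meta$signal_strength_index
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (expected PNG or TIFF)")
  )
  if (length(dim(img)) == 3) {
    if (dim(img)[3] != 1) {
      stop("expected a single-channel image, got ", dim(img)[3], " channels")
    }
    img <- img[, , 1]
  }
  # readPNG/readTIFF already divide integer samples by the dtype maximum,
  # giving the [0,1] convention used throughout.
  en_face_angiogram(img, layer = layer, geometry = geometry,
                    signal_strength_index = signal_strength_index)
}

#' Write an en face angiogram to a PNG or TIFF file
#'
#' Writes intensities quantized to the requested bit depth (PNG is always
#' 8-bit; TIFF may be 8 or 16) plus a JSON metadata sidecar at
#' `<path>.json` holding layer, geometry and SSI.
#'
#' @param angiogram An [en_face_angiogram()].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Bits per sample for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_angiogram <- function(angiogram, path, bits = 8) {
  stopifnot(inherits(angiogram, "en_face_angiogram"), bits %in% c(8, 16))
  px <- pmin(pmax(angiogram$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = bits),
    stop("unsupported image format '.", ext, "'")
  )
  meta <- list(layer = angiogram$layer,
               field_of_view_mm = angiogram$geometry$field_of_view_mm,
               grid_size_px = angiogram$geometry$grid_size_px,
               signal_strength_index = angiogram$signal_strength_index)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
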