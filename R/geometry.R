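#' Scan geometry of an en face angiogram
#'
#' Describes the physical footprint of a square en face OCTA scan: the field
#' of view in millimetres, the pixel grid size, and the pixel position of the
#' fovea. The default corresponds to a 3 x 3 mm macular scan sampled on a
#' 304 x 304 grid, the common acquisition for plexus-level quantification.
#'
#' Coordinates are 0-based and row-major with the origin at the top-left
#' pixel; the fovea defaults to the grid centre `((n - 1) / 2, (n - 1) / 2)`,
#' i.e. the exact centre of an n-pixel grid measured in pixel centres.
#'
#' @param field_of_view_mm Side length of the scanned square, in mm.
#' @param grid_size_px Number of pixels per axis (square grid).
#' @param center_px Numeric length-2 (row, col), 0-based pixel coordinates of
#'   the fovea. Defaults to the grid centre.
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(3, 304)
#' pixel_pitch_mm(g)
#' @export
scan_geometry <- function(field_of_view_mm = 3, grid_size_px = 304L,
                          center_px = NULL) {
  stopifnot(is.numeric(field_of_view_mm), length(field_of_view_mm) == 1,
            is.finite(field_of_view_mm), field_of_view_mm > 0)
  grid_size_px <- as.integer(grid_size_px)
  stopifnot(length(grid_size_px) == 1, !is.na(grid_size_px), grid_size_px >= 1)
  if (is.null(center_px)) {
    center_px <- rep((grid_size_px - 1) / 2, 2)
  }
  stopifnot(is.numeric(center_px), length(center_px) == 2,
            all(is.finite(center_px)))
  if (any(center_px < 0) || any(center_px > grid_size_px - 1)) {
    stop("fovea center must lie inside the pixel grid")
  }
  structure(
    list(field_of_view_mm = as.numeric(field_of_view_mm),
         grid_size_px = grid_size_px,
         center_px = as.numeric(center_px)),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %g x %g mm on %d x %d px (pitch %.4g mm/px)\n",
              x$field_of_view_mm, x$field_of_view_mm,
              x$grid_size_px, x$grid_size_px, pixel_pitch_mm(x)))
  invisible(x)
}

#' Pixel pitch in millimetres
#'
#' @param geometry A [scan_geometry()].
#' @return Pixel side length in mm (`field_of_view_mm / grid_size_px`).
#' @export
pixel_pitch_mm <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  geometry$field_of_view_mm / geometry$grid_size_px
}

#' Area of one pixel in square millimetres
#'
#' Conversion factor between pixel counts and physical areas (used e.g. to
#' express the foveal avascular zone in mm^2).
#'
#' @param geometry A [scan_geometry()].
#' @return `(field_of_view_mm / grid_size_px)^2`, in mm^2.
#' @examples
#' pixel_area_mm2(scan_geometry(3, 304)) # ~9.74e-5
#' @export
pixel_area_mm2 <- function(geometry) {
  pixel_pitch_mm(geometry)^2
}

# Squared-distance-from-fovea matrix in px^2, 1-based matrix indexing but
# 0-based geometry coordinates (row i maps to coordinate i - 1).
dist_from_center_px <- function(geometry) {
  n <- geometry$grid_size_px
  rr <- (seq_len(n) - 1) - geometry$center_px[1]
  cc <- (seq_len(n) - 1) - geometry$center_px[2]
  sqrt(outer(rr^2, cc^2, `+`))
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$field_of_view_mm, b$field_of_view_mm)) &&
    a$grid_size_px == b$grid_size_px &&
    isTRUE(all.equal(a$center_px, b$center_px))
}
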