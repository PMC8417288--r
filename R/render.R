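# Pictorial outputs: colored contour of the normalized ratio map and a
# fixed-palette rendering of the class map (vessel = red, small-vessel
# spacing = yellow, large-vessel spacing = blue).

ratio_palette <- function(n_levels) {
  grDevices::colorRampPalette(
    c("#000004", "#3B0F70", "#8C2981", "#DE4968", "#FE9F6D", "#FCFDBF")
  )(n_levels)
}

class_palette <- c(large_spacing = "#0000FF", small_spacing = "#FFFF00",
                   vessel = "#FF0000")

rgb_array <- function(idx, palette) {
  co <- grDevices::col2rgb(palette) / 255
  arr <- array(0, c(nrow(idx), ncol(idx), 3))
  for (ch in 1:3) {
    arr[, , ch] <- matrix(co[ch, idx], nrow(idx), ncol(idx))
  }
  arr
}

#' Render ratio and class maps to PNG files
#'
#' Writes a filled-contour rendering of the normalized ratio map (the
#' ratio quantized into `n_levels` equal bands of a fixed dark-to-light
#' palette, an apparent probability index of vessel presence) and an
#' indexed-color rendering of the class map with the fixed palette red =
#' vessel, yellow = small-vessel spacing, blue = large-vessel spacing.
#' Output bytes are deterministic for fixed inputs.
#'
#' @param ratio A `fractal_ratio_map` (or NULL to skip).
#' @param classes A `pixel_class_map` (or NULL to skip).
#' @param out_dir Output directory (created if missing).
#' @param basename Stem for the output files.
#' @param n_levels Number of contour bands for the ratio map.
#' @return Named character vector of the files written.
#' @export
render_maps <- function(ratio = NULL, classes = NULL, out_dir = ".",
                        basename = "octa", n_levels = 10) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory '", out_dir, "'")
  }
  files <- c()
  if (!is.null(ratio)) {
    stopifnot(inherits(ratio, "fractal_ratio_map"))
    idx <- pmin(floor(ratio$values * n_levels) + 1, n_levels)
    path <- file.path(out_dir, paste0(basename, "_ratio.png"))
    png::writePNG(rgb_array(idx, ratio_palette(n_levels)), path)
    files["ratio"] <- path
  }
  if (!is.null(classes)) {
    stopifnot(inherits(classes, "pixel_class_map"))
    path <- file.path(out_dir, paste0(basename, "_classes.png"))
    png::writePNG(rgb_array(classes$labels, class_palette), path)
    files["classes"] <- path
  }
  files
}
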