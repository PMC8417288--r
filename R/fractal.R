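#' Binarize an angiogram by between-class-variance maximization
#'
#' Thresholds the intensity histogram with Otsu's criterion (maximal
#' between-class variance), yielding the binary foreground the box-counting
#' stage operates on. A constant image produces an all-background mask with
#' a warning, and a foreground fraction above 60% triggers a warning since
#' en face angiograms are majority-background: such a result usually means
#' inverted contrast or gross artifact.
#'
#' @param angiogram An [en_face_angiogram()].
#' @param levels Number of histogram bins for the threshold search.
#' @return A [binary_mask()], with the threshold used stored in attribute
#'   `"threshold"`.
#' @export
binarize <- function(angiogram, levels = 256) {
  stopifnot(inherits(angiogram, "en_face_angiogram"))
  px <- angiogram$pixels
  if (diff(range(px)) == 0) {
    warning("constant image: no foreground found")
    out <- binary_mask(matrix(FALSE, nrow(px), ncol(px)), angiogram$geometry)
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  thr <- EBImage::otsu(pmin(px, 1), range = c(0, 1), levels = levels)
  fg <- px > thr
  if (mean(fg) > 0.6) {
    warning(sprintf(
      "foreground covers %.0f%% of the image; check for inverted contrast",
      100 * mean(fg)))
  }
  out <- binary_mask(fg, angiogram$geometry)
  attr(out, "threshold") <- as.numeric(thr)
  out
}

#' Local box-counting fractal dimension map
#'
#' Computes, for every pixel, the box-counting dimension of the binary
#' foreground inside a square window centred on it: boxes of each size tile
#' the window from its top-left corner and the dimension is the
#' least-squares slope of log(occupied boxes) versus log(1/box size),
#' clamped to [0, 2]. The local dimension is near 2 over filled vessel
#' lumina, near 1 along thin capillaries, and 0 where the window holds no
#' foreground, so the map acts as a vessel-presence index. Windows are
#' clipped (not padded) at the image borders and tiled over their clipped
#' extent; box sizes whose complete tiles capture no foreground are dropped
#' from the regression.
#'
#' The defaults (33 px window, box sizes 16/8/4/2) span several capillary
#' spacings at 3 mm / 304 px sampling while staying local; both are
#' configurable and metric values should always be read relative to the
#' window convention in force.
#'
#' @param mask A [binary_mask()] (or logical matrix).
#' @param window_px Odd window side, at least the largest box size.
#' @param box_sizes_px Strictly decreasing positive box sizes, length >= 3.
#' @return An object of class `fractal_map`: fields `values` (matrix in
#'   [0, 2]), `window_px`, `box_sizes_px`, `geometry`.
#' @export
local_fractal_dimension <- function(mask, window_px = 33,
                                    box_sizes_px = c(16L, 8L, 4L, 2L)) {
  geometry <- NULL
  if (inherits(mask, "binary_mask")) {
    geometry <- mask$geometry
    mask <- mask$pixels
  }
  stopifnot(is.matrix(mask), is.logical(mask))
  window_px <- as.integer(window_px)
  box_sizes_px <- as.integer(box_sizes_px)
  if (window_px < 1 || window_px %% 2 == 0) {
    stop("window_px must be a positive odd integer")
  }
  if (length(box_sizes_px) < 3) {
    stop("at least 3 box sizes are needed for a reliable log-log slope")
  }
  if (any(box_sizes_px < 1) || any(diff(box_sizes_px) >= 0)) {
    stop("box_sizes_px must be strictly decreasing positive integers")
  }
  if (max(box_sizes_px) > window_px) {
    stop("window_px must be at least the largest box size")
  }
  values <- local_fd_cpp(mask, window_px, box_sizes_px)
  structure(
    list(values = values, window_px = window_px,
         box_sizes_px = box_sizes_px, geometry = geometry),
    class = "fractal_map"
  )
}

#' @export
print.fractal_map <- function(x, ...) {
  cat(sprintf(
    "<fractal_map> %d x %d px, window %d px, boxes {%s}, FD range [%.3f, %.3f]\n",
    nrow(x$values), ncol(x$values), x$window_px,
    paste(x$box_sizes_px, collapse = ","), min(x$values), max(x$values)))
  invisible(x)
}

#' Normalized fractal-ratio map
#'
#' Divides every local fractal dimension by the maximum dimension observed
#' in the same image, giving a per-pixel vessel-presence index in [0, 1]
#' that is comparable across scans regardless of window convention. The
#' maximum is the image's own (not the theoretical 2), so a vessel-bearing
#' image always attains ratio 1 somewhere. An all-zero map (no foreground
#' anywhere) yields all-zero ratios with a warning.
#'
#' @param fd A `fractal_map` from [local_fractal_dimension()].
#' @return An object of class `fractal_ratio_map`: fields `values` (matrix
#'   in [0, 1]), `max_fd`, `geometry`.
#' @export
normalized_ratio_map <- function(fd) {
  stopifnot(inherits(fd, "fractal_map"))
  max_fd <- max(fd$values)
  if (max_fd == 0) {
    warning("fractal map is all zero (no foreground); ratios set to 0")
    values <- fd$values
  } else {
    values <- fd$values / max_fd
  }
  structure(
    list(values = values, max_fd = max_fd, geometry = fd$geometry),
    class = "fractal_ratio_map"
  )
}

#' @export
print.fractal_ratio_map <- function(x, ...) {
  cat(sprintf("<fractal_ratio_map> %d x %d px, max FD %.3f\n",
              nrow(x$values), ncol(x$values), x$max_fd))
  invisible(x)
}
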