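# Brute-force box-counting oracle, written independently of the package's
# integral-image kernel: extracts the clipped window as a submatrix and
# scans every complete box with any()/submatrix indexing.
fd_oracle <- function(mask, i, j, window = 33, sizes = c(16, 8, 4, 2)) {
  h <- window %/% 2
  rows <- max(1, i - h):min(nrow(mask), i + h)
  cols <- max(1, j - h):min(ncol(mask), j + h)
  w <- mask[rows, cols, drop = FALSE]
  if (!any(w)) return(0)
  xs <- c()
  ys <- c()
  for (s in sizes) {
    nr <- nrow(w) %/% s
    nc <- ncol(w) %/% s
    if (nr == 0 || nc == 0) next
    cnt <- 0
    for (a in seq_len(nr)) {
      for (b in seq_len(nc)) {
        block <- w[((a - 1) * s + 1):(a * s), ((b - 1) * s + 1):(b * s)]
        if (any(block)) cnt <- cnt + 1
      }
    }
    if (cnt > 0) {
      xs <- c(xs, -log(s))
      ys <- c(ys, log(cnt))
    }
  }
  if (length(xs) < 2) return(0)
  slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  min(max(slope, 0), 2)
}

# Small test phantom: full generator on a coarser grid is not needed; most
# tests use the default 304-px spec with a fixed seed.
default_phantom <- function(seed = 1, ...) {
  generate_phantom(phantom_spec(seed = seed, ...))
}

vessel_density_of <- function(angiogram, ...) {
  mask <- suppressWarnings(binarize(angiogram))
  ratio <- normalized_ratio_map(local_fractal_dimension(mask, ...))
  band_percentages(classify_pixels(ratio))$vessel_density_pct
}
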