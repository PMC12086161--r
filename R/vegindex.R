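#' Excess Green (ExG) vegetation index
#'
#' Computes the per-pixel Excess Green map. The default is the classical
#' un-normalized Woebbecke index `ExG = 2G - R - B` on raw 8-bit channels;
#' `variant = "chromaticity"` uses the chromaticity-normalized form
#' `2g - r - b` with `r = R/(R+G+B)` etc. (defined as 0 where
#' `R + G + B = 0`). Higher values indicate green-dominant pixels; gray
#' pixels score exactly 0 under the raw convention, which is also
#' invariant to adding a constant to all three channels.
#'
#' @param image an [rgb_image()] (or bare `H x W x 3` array in `[0, 255]`).
#' @param variant `"raw"` (default, `2G - R - B`) or `"chromaticity"`.
#' @return numeric `H x W` matrix.
#' @examples
#' img <- rgb_image(array(c(50, 200, 30), dim = c(1, 1, 3)))
#' excess_green(img)  # 2*200 - 50 - 30 = 320
#' @export
excess_green <- function(image, variant = c("raw", "chromaticity")) {
  variant <- match.arg(variant)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("`image` must have exactly three channels", call. = FALSE)
  }
  d <- dim(image)
  r <- matrix(image[, , 1], d[1], d[2])
  g <- matrix(image[, , 2], d[1], d[2])
  b <- matrix(image[, , 3], d[1], d[2])
  if (variant == "raw") return(2 * g - r - b)
  s <- r + g + b
  out <- (2 * g - r - b) / s
  out[s == 0] <- 0
  out
}

#' Otsu threshold of a real-valued map
#'
#' Classical histogram Otsu: the map is linearly rescaled to `[0, 255]`,
#' rounded to 256 integer levels, and the integer level maximizing the
#' between-class variance of the (level <= t) / (level > t) split is
#' selected (ties broken toward the lowest level, which is deterministic).
#' The returned threshold is mapped back to the original scale so that
#' `map > threshold` reproduces the quantized split exactly.
#'
#' @param map numeric matrix (e.g. an Excess-Green map).
#' @return scalar threshold on the scale of `map`, or `NA` for a constant
#'   map (with a warning): callers treat that as an all-background mask.
#' @export
otsu_threshold <- function(map) {
  rng <- range(map)
  if (rng[2] <= rng[1]) {
    warning("constant map: no Otsu threshold exists; returning NA")
    return(NA_real_)
  }
  q <- as.integer(round((map - rng[1]) * (255 / (rng[2] - rng[1]))))
  counts <- tabulate(q + 1L, nbins = 256L)
  n <- length(q)
  p <- counts / n
  omega <- cumsum(p)                       # P(class 0) for t = 0..255
  mu <- cumsum(p * (0:255))                # partial means
  mu_t <- mu[256]
  # between-class variance for t = 0..254 (t = 255 puts everything in class 0)
  w0 <- omega[1:255]; m0 <- mu[1:255]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[w0 == 0 | w0 == 1] <- -Inf
  t_star <- which.max(sigma_b) - 1L        # lowest argmax
  # map back: q > t_star  <=>  map > rng[1] + (t_star + 0.5) * step
  rng[1] + (t_star + 0.5) * (rng[2] - rng[1]) / 255
}

#' Binarize an image into a vegetation mask via ExG + Otsu
#'
#' Applies [excess_green()] to the whole image and [otsu_threshold()] to
#' the resulting map (computed once, globally); the mask is
#' `exg > threshold`. A constant ExG map (no vegetation/background
#' contrast) yields an all-zero mask with a warning rather than an error,
#' so pipelines degrade gracefully on pathological inputs.
#'
#' @inheritParams excess_green
#' @return an object of class `"vegetation_mask"`: a list with `mask`
#'   (logical `H x W`), `otsu_threshold`, and `exg` (the ExG map).
#' @examples
#' scene <- generate_scene(scene_config(n_plants = 2, seed = 1))
#' vm <- vegetation_mask(scene$image)
#' mean(vm$mask)
#' @export
vegetation_mask <- function(image, variant = c("raw", "chromaticity")) {
  exg <- excess_green(image, variant)
  thr <- suppressWarnings(otsu_threshold(exg))
  if (is.na(thr)) {
    warning("constant ExG map: returning an all-zero vegetation mask")
    mask <- matrix(FALSE, nrow(exg), ncol(exg))
  } else {
    mask <- exg > thr
  }
  structure(list(mask = mask, otsu_threshold = thr, exg = exg),
            class = "vegetation_mask")
}

#' Raw cover-green count within a bounding box
#'
#' Counts vegetation-mask foreground pixels inside the box under the
#' half-open pixel convention. Boxes extending beyond the image are
#' clipped first; a zero-area (or fully clipped) box counts 0, with a
#' warning for genuinely degenerate input.
#'
#' @param mask a [vegetation_mask()] (or bare logical matrix).
#' @param box a single-row box tibble.
#' @return nonnegative integer count.
#' @export
ncgi_raw <- function(mask, box) {
  m <- if (inherits(mask, "vegetation_mask")) mask$mask else mask
  if (nrow(box) != 1L) stop("`box` must be a single-row box tibble", call. = FALSE)
  if (box$x_max <= box$x_min || box$y_max <= box$y_min) {
    warning("zero-area box: NCGI_raw = 0")
    return(0L)
  }
  box <- clip_boxes(box, nrow(m), ncol(m))
  rows <- seq.int(ceiling(box$y_min) + 1L, ceiling(box$y_max))
  cols <- seq.int(ceiling(box$x_min) + 1L, ceiling(box$x_max))
  rows <- rows[rows >= 1L & rows <= nrow(m)]
  cols <- cols[cols >= 1L & cols <= ncol(m)]
  if (!length(rows) || !length(cols)) return(0L)
  sum(m[rows, cols])
}

#' Normalized Cover Green Index (NCGI) for a set of boxes
#'
#' `add_ncgi()` appends `ncgi_raw` and `ncgi` columns to a box tibble.
#' Each box's raw green-pixel count is normalized by the maximum raw count
#' over its overlap set — the box itself together with every box whose
#' intersection area with it is positive — so NCGI is always in `[0, 1]`,
#' an isolated green box scores 1, and within every overlap cluster at
#' least one box attains 1 (unless all counts are 0, in which case the
#' whole cluster scores 0).
#'
#' @param b a box tibble (see [boxes()]).
#' @param mask a [vegetation_mask()] (or logical matrix).
#' @param graph optional precomputed [overlap_graph()] for `b`.
#' @return `b` with columns `ncgi_raw` (integer) and `ncgi` (in `[0, 1]`).
#' @export
add_ncgi <- function(b, mask, graph = NULL) {
  graph <- graph %||% overlap_graph(b)
  raw <- vapply(seq_len(nrow(b)), function(i) as.numeric(ncgi_raw(mask, b[i, ])),
                numeric(1))
  n <- nrow(b)
  norm <- numeric(n)
  for (i in seq_len(n)) {
    cluster_max <- max(raw[i], raw[graph$adjacency[i, ]])
    norm[i] <- if (cluster_max > 0) raw[i] / cluster_max else 0
  }
  dplyr::mutate(b, ncgi_raw = raw, ncgi = norm)
}
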