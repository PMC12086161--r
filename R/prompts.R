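#' Select the reference box for similarity-map prompting
#'
#' The box with the highest composite NCGI value (`y_n`) becomes the
#' reference: its cropped image and ExG/Otsu foreground define the
#' reference feature vector every other box region is compared against.
#' Ties break toward larger area, then lower id.
#'
#' @param b a box tibble of final (post-NMS) boxes.
#' @param y_n composite NCGI values, one per box; defaults to `b$score`
#'   (the working score VC-NMS reports).
#' @return the selected single-row box tibble.
#' @export
select_reference <- function(b, y_n = b$score) {
  if (nrow(b) == 0) stop("no boxes to select a reference from", call. = FALSE)
  ord <- order(-y_n, -box_area(b), b$id)
  b[ord[1], , drop = FALSE]
}

# cosine of each grid cell against a reference vector; zero norms -> 0
cell_cosines <- function(grid, ref_vec) {
  gh <- dim(grid)[1]; gw <- dim(grid)[2]
  flat <- matrix(grid, gh * gw, dim(grid)[3])
  num <- flat %*% ref_vec
  den <- sqrt(rowSums(flat^2)) * sqrt(sum(ref_vec^2))
  out <- as.numeric(num) / den
  out[den == 0] <- 0
  matrix(out, gh, gw)
}

# bilinear upsample of a grid (cell centers at (i - 0.5) * stride) to pixels
bilinear_upsample <- function(grid, height, width) {
  gh <- nrow(grid); gw <- ncol(grid)
  sy <- height / gh; sx <- width / gw
  gi <- pmin(gh, pmax(1, (seq_len(height) - 0.5) / sy + 0.5))
  gj <- pmin(gw, pmax(1, (seq_len(width) - 0.5) / sx + 0.5))
  i0 <- pmin(gh - 1L, pmax(1L, floor(gi))); if (gh == 1) i0 <- rep(1L, height)
  j0 <- pmin(gw - 1L, pmax(1L, floor(gj))); if (gw == 1) j0 <- rep(1L, width)
  wi <- gi - i0; wj <- gj - j0
  i1 <- pmin(gh, i0 + 1L); j1 <- pmin(gw, j0 + 1L)
  a <- grid[i0, j0, drop = FALSE]; bq <- grid[i0, j1, drop = FALSE]
  cc <- grid[i1, j0, drop = FALSE]; d <- grid[i1, j1, drop = FALSE]
  WI <- matrix(wi, height, width); WJ <- matrix(wj, height, width, byrow = TRUE)
  a * (1 - WI) * (1 - WJ) + bq * (1 - WI) * WJ + cc * WI * (1 - WJ) + d * WI * WJ
}

#' Cosine similarity map of a box region against a reference plant
#'
#' The reference vector is the mean of the reference embedding's grid
#' cells whose centers fall in the reference vegetation foreground
#' (masked mean pooling; if no cell center hits the foreground, all cells
#' are pooled). Each cell of the region embedding is scored by cosine
#' similarity against that vector, and the cell grid is bilinearly
#' upsampled to the region's pixel size.
#'
#' @param region_embed embedding of the target box region (`grid`
#'   `h x w x c` array plus `stride`), as produced by [mock_embedder()].
#' @param ref_embed embedding of the reference region.
#' @param ref_mask a [vegetation_mask()] of the reference region (or bare
#'   logical matrix).
#' @param height,width pixel size of the target region (defaults to the
#'   grid size times the stride).
#' @return numeric matrix of cosines in `[-1, 1]` at region pixel size.
#' @export
similarity_map <- function(region_embed, ref_embed, ref_mask,
                           height = NULL, width = NULL) {
  m <- if (inherits(ref_mask, "vegetation_mask")) ref_mask$mask else ref_mask
  g <- ref_embed$grid
  gh <- dim(g)[1]; gw <- dim(g)[2]
  sy <- ref_embed$stride[1]; sx <- ref_embed$stride[2]
  rows <- pmin(nrow(m), pmax(1L, ceiling((seq_len(gh) - 0.5) * sy)))
  cols <- pmin(ncol(m), pmax(1L, ceiling((seq_len(gw) - 0.5) * sx)))
  infg <- outer(rows, cols, function(r, c) m[cbind(r, c)])
  if (!any(infg)) infg <- matrix(TRUE, gh, gw)
  flat <- matrix(g, gh * gw, dim(g)[3])
  ref_vec <- colMeans(flat[as.vector(infg), , drop = FALSE])
  cells <- cell_cosines(region_embed$grid, ref_vec)
  h <- height %||% round(dim(region_embed$grid)[1] * region_embed$stride[1])
  w <- width %||% round(dim(region_embed$grid)[2] * region_embed$stride[2])
  bilinear_upsample(cells, h, w)
}

# smallest row-major (y * W + x) index attaining the extreme value
argext_rowmajor <- function(m, which = c("max", "min")) {
  which <- match.arg(which)
  target <- if (which == "max") max(m) else min(m)
  hits <- which(m == target, arr.ind = TRUE)
  rm_idx <- (hits[, 1] - 1) * ncol(m) + (hits[, 2] - 1)
  best <- which.min(rm_idx)
  c(x = unname(hits[best, 2] - 1), y = unname(hits[best, 1] - 1))
}

#' Base point prompts from a similarity map
#'
#' The pixel with the highest similarity becomes the positive base point
#' and the lowest the negative base point (ties toward the smallest
#' row-major index). A constant map is flagged degenerate and the caller
#' falls back to the box center / corner.
#'
#' @param simmap numeric matrix (a [similarity_map()]).
#' @return a list with `positive` and `negative` (each `c(x =, y =)` in
#'   0-based region coordinates) and `degenerate` (logical).
#' @export
base_points <- function(simmap) {
  if (max(simmap) == min(simmap)) {
    return(list(positive = NULL, negative = NULL, degenerate = TRUE))
  }
  list(positive = argext_rowmajor(simmap, "max"),
       negative = argext_rowmajor(simmap, "min"),
       degenerate = FALSE)
}

#' Farthest allowed pixel from a base point (max-distance criterion)
#'
#' Returns the pixel of `allowed_region` maximizing the Euclidean
#' distance (on pixel indices) to the base point; ties break toward the
#' smallest row-major index. With a set of base points the minimum
#' distance to the set is maximized (iterated farthest-point sampling).
#'
#' @param base `c(x =, y =)` 0-based point, or a 2-column matrix of
#'   points (x, y per row).
#' @param allowed_region logical matrix of candidate pixels.
#' @return `c(x =, y =)` of the selected pixel (0-based).
#' @export
max_distance_point <- function(base, allowed_region) {
  cand <- which(allowed_region, arr.ind = TRUE)
  if (nrow(cand) == 0) stop("empty allowed region for max-distance point",
                            call. = FALSE)
  cx <- cand[, 2] - 1; cy <- cand[, 1] - 1
  if (is.null(dim(base))) base <- matrix(base, 1, 2)
  d2 <- rep(Inf, nrow(cand))
  for (k in seq_len(nrow(base))) {
    d2 <- pmin(d2, (cx - base[k, 1])^2 + (cy - base[k, 2])^2)
  }
  rm_idx <- cy * ncol(allowed_region) + cx
  best <- order(-d2, rm_idx)[1]
  c(x = unname(cx[best]), y = unname(cy[best]))
}

#' Build the point-prompt set for one final bounding box
#'
#' Implements the two-step augmentation: base positive/negative points
#' from the similarity map of the box region against the reference
#' plant, then enhanced points by the max-distance criterion inside the
#' region's ExG/Otsu foreground (positives) and background (negatives).
#' With `n_pos = n_neg = 1` only the base points are produced; beyond one
#' enhanced point, iterated farthest-point sampling from the selected
#' set is used. Degenerate cases fall back deterministically: a constant
#' similarity map yields the box center (positive) and box corner
#' (negative); an empty foreground makes positives fall back to the box
#' center and similarity argmax; an empty background reduces the
#' negative count with a warning.
#'
#' @param image the full [rgb_image()].
#' @param box a single-row box tibble (a kept VC-NMS box).
#' @param y_n the box's composite NCGI value.
#' @param embedder an embedder function, e.g. [mock_embedder()].
#' @param reference list with `embed` and `mask` for the reference
#'   region; computed from the box itself when `NULL`.
#' @param n_pos,n_neg number of positive / negative points (default 2/2,
#'   the configuration found optimal for promptable plant segmentation).
#' @return an object of class `"prompt_set"`: list with `box`, `points`
#'   (tibble `x`, `y`, `label`, `kind` in full-image 0-based pixel
#'   coordinates) and `y_n`.
#' @export
build_prompt_set <- function(image, box, y_n, embedder = mock_embedder(),
                             reference = NULL, n_pos = 2, n_neg = 2) {
  h <- dim(image)[1]; w <- dim(image)[2]
  box <- clip_boxes(box, h, w)
  region <- crop_pixels(unclass(image), box)
  x_off <- ceiling(box$x_min); y_off <- ceiling(box$y_min)
  rh <- dim(region)[1]; rw <- dim(region)[2]
  reg_mask <- suppressWarnings(vegetation_mask(region))
  if (is.null(reference)) {
    reference <- list(embed = embedder(region), mask = reg_mask)
  }
  simmap <- similarity_map(embedder(region), reference$embed, reference$mask,
                           height = rh, width = rw)
  bp <- base_points(simmap)
  if (bp$degenerate) {
    bp$positive <- c(x = floor((rw - 1) / 2), y = floor((rh - 1) / 2))
    bp$negative <- c(x = 0, y = 0)
  }
  fg <- reg_mask$mask
  bg <- !reg_mask$mask
  pos <- matrix(bp$positive, 1, 2)
  if (n_pos > 1) {
    allowed <- if (any(fg)) fg else NULL
    for (k in seq_len(n_pos - 1)) {
      nxt <- if (is.null(allowed)) {
        if (k == 1) c(x = floor((rw - 1) / 2), y = floor((rh - 1) / 2))
        else max_distance_point(pos, matrix(TRUE, rh, rw))
      } else max_distance_point(pos, allowed)
      pos <- rbind(pos, nxt)
    }
  }
  neg <- matrix(bp$negative, 1, 2)
  n_neg_eff <- n_neg
  if (n_neg > 1) {
    if (any(bg)) {
      for (k in seq_len(n_neg - 1)) neg <- rbind(neg, max_distance_point(neg, bg))
    } else {
      warning("region has no background pixels: reducing negative points to 1")
      n_neg_eff <- 1
    }
  }
  pts <- dplyr::bind_rows(
    tibble::tibble(x = pos[, 1] + x_off, y = pos[, 2] + y_off,
                   label = "positive",
                   kind = c("base", rep("enhanced", nrow(pos) - 1))),
    if (n_neg_eff > 0) tibble::tibble(
      x = neg[seq_len(n_neg_eff), 1] + x_off,
      y = neg[seq_len(n_neg_eff), 2] + y_off,
      label = "negative",
      kind = c("base", rep("enhanced", n_neg_eff - 1))))
  structure(list(box = box, points = pts, y_n = y_n), class = "prompt_set")
}

#' Build prompt sets for all final boxes of an image
#'
#' Selects the reference box ([select_reference()]), computes its
#' embedding and vegetation mask once, and builds a [build_prompt_set()]
#' for every box against that shared reference.
#'
#' @param image the full [rgb_image()].
#' @param b box tibble of final boxes; `score` is used as `y_n`.
#' @inheritParams build_prompt_set
#' @return a list of `"prompt_set"` objects, one per row of `b`.
#' @export
build_prompt_sets <- function(image, b, embedder = mock_embedder(),
                              n_pos = 2, n_neg = 2) {
  if (nrow(b) == 0) return(list())
  h <- dim(image)[1]; w <- dim(image)[2]
  ref_box <- clip_boxes(select_reference(b), h, w)
  ref_region <- crop_pixels(unclass(image), ref_box)
  reference <- list(embed = embedder(ref_region),
                    mask = suppressWarnings(vegetation_mask(ref_region)))
  lapply(seq_len(nrow(b)), function(i) {
    build_prompt_set(image, b[i, ], y_n = b$score[i], embedder = embedder,
                     reference = reference, n_pos = n_pos, n_neg = n_neg)
  })
}

#' Serialize prompt sets to JSON
#'
#' Layout consumed by promptable-segmenter adapters:
#' `{box: [x, y, w, h], score, points: [{x, y, label, kind}]}`.
#'
#' @param prompt_sets a list of `"prompt_set"` objects.
#' @param path output file path.
#' @export
write_prompt_sets <- function(prompt_sets, path) {
  recs <- lapply(prompt_sets, function(ps) {
    list(box = c(ps$box$x_min, ps$box$y_min,
                 ps$box$x_max - ps$box$x_min, ps$box$y_max - ps$box$y_min),
         score = ps$y_n,
         points = purrr::pmap(ps$points, function(x, y, label, kind)
           list(x = x, y = y, label = label, kind = kind)))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
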