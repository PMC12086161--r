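#' Synthetic vertical-farm scene configuration
#'
#' The generator emulates the visual pathologies of overhead hydroponic
#' imagery: green plant rosettes of varying scale on a granular non-green
#' substrate (clay-pebble-like), an uneven illumination gradient, and a
#' global red/purple colour cast such as auto-white-balance shifts
#' produce. Every random choice is driven by `seed`, and rendering is
#' integer-valued, so scenes are byte-identical across runs and
#' platforms.
#'
#' @param width,height canvas size in pixels.
#' @param n_plants number of plants.
#' @param plant_radius length-2 range of plant radii (px).
#' @param leaves_per_plant length-2 range of leaf-ellipse counts.
#' @param separation tray-hole spacing as a multiple of twice the maximum
#'   plant radius; plants sit on a jittered regular grid (hydroponic
#'   holes), with occupied holes forming a connected patch so adjacent
#'   plant pairs always exist.
#' @param gradient logical: apply a linear illumination gradient
#'   (intensity 0.75 to 1.25 across a random direction).
#' @param tint `"none"`, `"red"` or `"purple"` global channel gain.
#' @param seed integer seed fixing all randomness.
#' @return a list of class `"scene_config"`.
#' @export
scene_config <- function(width = 192, height = 192, n_plants = 8,
                         plant_radius = c(9, 14), leaves_per_plant = c(4, 8),
                         separation = 1.05, gradient = TRUE,
                         tint = c("none", "red", "purple"), seed = 1) {
  tint <- match.arg(tint)
  stopifnot(width >= 16, height >= 16, n_plants >= 0,
            plant_radius[1] >= 2, plant_radius[2] >= plant_radius[1])
  structure(list(width = width, height = height, n_plants = n_plants,
                 plant_radius = plant_radius,
                 leaves_per_plant = leaves_per_plant,
                 separation = separation, gradient = gradient, tint = tint,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# rasterize a rotated ellipse onto 0-based pixel indices within the canvas
ellipse_pixels <- function(ex, ey, a, b, theta, height, width) {
  x0 <- max(0L, floor(ex - a)); x1 <- min(width - 1L, ceiling(ex + a))
  y0 <- max(0L, floor(ey - a)); y1 <- min(height - 1L, ceiling(ey + a))
  if (x1 < x0 || y1 < y0) return(cbind(integer(0), integer(0)))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(ys * 0, xs - ex, `+`)
  dy <- outer(ys - ey, xs * 0, `+`)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  w <- which(inside, arr.ind = TRUE)
  cbind(row = ys[w[, 1]] + 1L, col = xs[w[, 2]] + 1L)  # 1-based matrix indices
}

#' Generate a synthetic vertical-farm scene with exact ground truth
#'
#' Plants are rendered as clusters of overlapping green ellipses whose
#' channel statistics keep their Excess-Green values well above anything
#' the background can reach (the granular background noise is mostly
#' luminance-correlated, to which ExG is invariant), so Otsu separation
#' of the vegetation is a construction guarantee. Ground-truth masks
#' record, per pixel, the last plant painted (visible ownership); boxes
#' are the tight bounding boxes of the masks.
#'
#' @param config a [scene_config()].
#' @return a list of class `"synthetic_scene"`: `image` ([rgb_image()]),
#'   `gt_masks` (list of logical matrices, one per plant), `gt_boxes`
#'   (box tibble, `score = 1`), `config`.
#' @examples
#' sc <- generate_scene(scene_config(n_plants = 4, seed = 42))
#' sc$gt_boxes
#' @export
generate_scene <- function(config = scene_config()) {
  with_seed(config$seed, {
    h <- config$height; w <- config$width
    # granular background: coarse 4-px luminance blotches + small chroma noise
    base <- c(95, 85, 70)
    ch <- ceiling(h / 4); cw <- ceiling(w / 4)
    coarse <- matrix(sample(-25:25, ch * cw, replace = TRUE), ch, cw)
    lum <- coarse[rep(seq_len(ch), each = 4)[1:h], rep(seq_len(cw), each = 4)[1:w]]
    img <- array(0, dim = c(h, w, 3))
    for (k in 1:3) {
      img[, , k] <- base[k] + lum +
        matrix(sample(-8:8, h * w, replace = TRUE), h, w)
    }
    # place plants on a jittered tray grid; occupied holes form a
    # connected patch (plants fill neighbouring holes in a tray)
    n <- config$n_plants
    radii <- if (n) round(stats::runif(n, config$plant_radius[1],
                                       config$plant_radius[2])) else numeric(0)
    centers <- matrix(0, n, 2)
    if (n > 0) {
      spacing <- config$separation * 2 * config$plant_radius[2]
      margin <- ceiling(1.25 * config$plant_radius[2]) + 2
      gx <- floor((w - 2 * margin) / spacing) + 1
      gy <- floor((h - 2 * margin) / spacing) + 1
      if (gx * gy < n) stop("canvas too small for ", n,
                            " plants at this spacing", call. = FALSE)
      # grow a connected set of grid cells
      cell <- matrix(FALSE, gy, gx)
      cur <- c(sample.int(gy, 1), sample.int(gx, 1))
      cell[cur[1], cur[2]] <- TRUE
      occupied <- list(cur)
      while (length(occupied) < n) {
        anchor <- occupied[[sample.int(length(occupied), 1)]]
        step <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))[[sample.int(4, 1)]]
        nxt <- anchor + step
        if (nxt[1] >= 1 && nxt[1] <= gy && nxt[2] >= 1 && nxt[2] <= gx &&
            !cell[nxt[1], nxt[2]]) {
          cell[nxt[1], nxt[2]] <- TRUE
          occupied[[length(occupied) + 1]] <- nxt
        }
      }
      for (i in seq_len(n)) {
        jit <- stats::runif(2, -0.12, 0.12) * spacing
        centers[i, 1] <- margin + (occupied[[i]][2] - 0.5) * spacing + jit[1]
        centers[i, 2] <- margin + (occupied[[i]][1] - 0.5) * spacing + jit[2]
      }
    }
    # render plants; ownership records the last plant painted per pixel
    ownership <- matrix(0L, h, w)
    for (i in seq_len(n)) {
      r <- radii[i]
      green <- c(sample(25:55, 1), sample(150:200, 1), sample(30:60, 1))
      k_leaves <- sample(config$leaves_per_plant[1]:config$leaves_per_plant[2], 1)
      angles <- stats::runif(k_leaves, 0, 2 * pi)
      # one central ellipse keeps each plant a single connected blob
      parts <- list(ellipse_pixels(centers[i, 1], centers[i, 2],
                                   0.55 * r, 0.45 * r,
                                   stats::runif(1, 0, pi), h, w))
      for (l in seq_len(k_leaves)) {
        d <- stats::runif(1, 0.15 * r, 0.45 * r)
        a <- stats::runif(1, 0.45 * r, 0.75 * r)
        b <- a * stats::runif(1, 0.5, 0.8)
        parts[[l + 1]] <- ellipse_pixels(centers[i, 1] + d * cos(angles[l]),
                                         centers[i, 2] + d * sin(angles[l]),
                                         a, b, angles[l], h, w)
      }
      px <- unique(do.call(rbind, parts))
      if (nrow(px) == 0) next
      idx <- (px[, 2] - 1L) * h + px[, 1]
      jit <- matrix(sample(-12:12, 3 * nrow(px), replace = TRUE), ncol = 3)
      for (k in 1:3) img[idx + (k - 1L) * h * w] <- green[k] + jit[, k]
      ownership[idx] <- i
    }
    # illumination gradient and colour cast
    if (config$gradient) {
      theta <- stats::runif(1, 0, 2 * pi)
      gx <- outer(rep(1, h), (0:(w - 1)) / max(1, w - 1))
      gy <- outer((0:(h - 1)) / max(1, h - 1), rep(1, w))
      t <- gx * cos(theta)^2 + gy * sin(theta)^2
      gain <- 0.75 + 0.5 * (t - min(t)) / max(1e-12, diff(range(t)))
      for (k in 1:3) img[, , k] <- img[, , k] * gain
    }
    gains <- switch(config$tint, none = c(1, 1, 1), red = c(1.25, 1, 1),
                    purple = c(1.2, 1, 1.25))
    for (k in 1:3) img[, , k] <- pmax(0, pmin(255, round(img[, , k] * gains[k])))

    gt_masks <- lapply(seq_len(n), function(i) ownership == i)
    gt_boxes <- if (n) purrr::map_dfr(seq_len(n), function(i) {
      m <- gt_masks[[i]]
      rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
      tibble::tibble(id = i, x_min = cc[1] - 1, y_min = rr[1] - 1,
                     x_max = cc[2], y_max = rr[2], score = 1)
    }) else empty_boxes()
    structure(list(image = rgb_image(img), gt_masks = gt_masks,
                   gt_boxes = gt_boxes, ownership = ownership,
                   config = config),
              class = "synthetic_scene")
  })
}

#' Detector-proposal pathology configuration
#'
#' Reproduces the redundancy patterns of open-set text-prompted plant
#' detection: jittered near-duplicate boxes around each plant, strictly
#' nested sub-boxes, multi-plant union boxes over adjacent plant pairs,
#' and confidence scores biased upward with box area so that union boxes
#' tend to outscore tight single-plant boxes.
#'
#' @param jitter_scale edge jitter as a fraction of box size (normal,
#'   truncated at 1.6 sd so a jittered copy always keeps IoU >= 0.7 with
#'   its ground-truth box at the default scale).
#' @param n_jitter_per_gt extra jittered duplicates per ground-truth box
#'   (one jittered base copy is always produced).
#' @param n_nested_per_gt strictly nested sub-boxes per ground-truth box.
#' @param n_union_boxes union boxes over the closest plant pairs.
#' @param score_base,area_bias,noise_sd score model:
#'   `clip01(score_base + area_bias * area/max_area + N(0, noise_sd))`.
#' @param seed integer seed.
#' @export
proposal_config <- function(jitter_scale = 0.05, n_jitter_per_gt = 0,
                            n_nested_per_gt = 1, n_union_boxes = 3,
                            score_base = 0.2, area_bias = 0.45,
                            noise_sd = 0.04, seed = 1) {
  structure(list(jitter_scale = jitter_scale, n_jitter_per_gt = n_jitter_per_gt,
                 n_nested_per_gt = n_nested_per_gt,
                 n_union_boxes = n_union_boxes, score_base = score_base,
                 area_bias = area_bias, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "proposal_config")
}

clip01 <- function(x) pmax(0, pmin(1, x))

#' Generate a pathological detector-proposal set for a scene
#'
#' @param scene a [generate_scene()] result.
#' @param config a [proposal_config()].
#' @return a box tibble with area-biased scores; with all pathology
#'   counts and the jitter scale at zero it reduces exactly to the
#'   ground-truth boxes.
#' @export
generate_proposals <- function(scene, config = proposal_config()) {
  gt <- scene$gt_boxes
  h <- scene$config$height; w <- scene$config$width
  with_seed(config$seed, {
    jitter_box <- function(b) {
      bw <- b$x_max - b$x_min; bh <- b$y_max - b$y_min
      lim <- 1.6 * config$jitter_scale
      j <- function(s) pmax(-lim, pmin(lim, stats::rnorm(1, 0, config$jitter_scale))) * s
      tibble::tibble(x_min = max(0, b$x_min + j(bw)), y_min = max(0, b$y_min + j(bh)),
                     x_max = min(w, b$x_max + j(bw)), y_max = min(h, b$y_max + j(bh)))
    }
    rows <- list()
    for (i in seq_len(nrow(gt))) {
      b <- gt[i, ]
      for (r in seq_len(1 + config$n_jitter_per_gt)) rows[[length(rows) + 1]] <- jitter_box(b)
      bw <- b$x_max - b$x_min; bh <- b$y_max - b$y_min
      for (r in seq_len(config$n_nested_per_gt)) {
        fw <- stats::runif(1, 0.25, 0.45) * bw; fh <- stats::runif(1, 0.25, 0.45) * bh
        ox <- stats::runif(1, 0, bw - fw); oy <- stats::runif(1, 0, bh - fh)
        rows[[length(rows) + 1]] <- tibble::tibble(
          x_min = b$x_min + ox, y_min = b$y_min + oy,
          x_max = b$x_min + ox + fw, y_max = b$y_min + oy + fh)
      }
    }
    if (nrow(gt) >= 2 && config$n_union_boxes > 0) {
      ctr <- cbind((gt$x_min + gt$x_max) / 2, (gt$y_min + gt$y_max) / 2)
      pairs <- utils::combn(nrow(gt), 2)
      d <- apply(pairs, 2, function(p) sqrt(sum((ctr[p[1], ] - ctr[p[2], ])^2)))
      # closest *adjacent* pairs (multi-plant detections arise between
      # neighbouring plants only), each plant in at most one union
      diag_gt <- box_diagonal(gt)
      take <- integer(0); used <- logical(nrow(gt))
      for (t in order(d)) {
        p <- pairs[, t]
        if (d[t] > 0.75 * (diag_gt[p[1]] + diag_gt[p[2]])) next
        if (!used[p[1]] && !used[p[2]]) {
          take <- c(take, t); used[p] <- TRUE
          if (length(take) >= config$n_union_boxes) break
        }
      }
      for (t in take) {
        p <- pairs[, t]
        grow <- stats::runif(1, 0.08, 0.18)
        uw <- max(gt$x_max[p]) - min(gt$x_min[p])
        uh <- max(gt$y_max[p]) - min(gt$y_min[p])
        rows[[length(rows) + 1]] <- tibble::tibble(
          x_min = max(0, min(gt$x_min[p]) - grow * uw),
          y_min = max(0, min(gt$y_min[p]) - grow * uh),
          x_max = min(w, max(gt$x_max[p]) + grow * uw),
          y_max = min(h, max(gt$y_max[p]) + grow * uh))
      }
    }
    if (!length(rows)) return(empty_boxes())
    b <- dplyr::bind_rows(rows)
    area <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
    score <- clip01(config$score_base + config$area_bias * area / max(area) +
                      stats::rnorm(nrow(b), 0, config$noise_sd))
    boxes(b$x_min, b$y_min, b$x_max, b$y_max, score = score)
  })
}

#' Standard synthetic study battery: scenes plus proposal sets
#'
#' The package's reference evaluation conditions: `n_scenes` default-config
#' scenes whose plant counts cycle over 5 to 12 and whose colour casts
#' cycle over none/red/purple, each with a seeded pathological proposal
#' set. All seeds derive from `seed`, so the battery is fully
#' reproducible.
#'
#' @param n_scenes number of scenes.
#' @param seed master seed.
#' @return a list with `scenes` (list of [generate_scene()] results) and
#'   `proposals` (parallel list of box tibbles).
#' @export
synthetic_battery <- function(n_scenes = 50, seed = 1) {
  seed <- as.integer(seed)
  tints <- c("none", "red", "purple")
  scenes <- lapply(seq_len(n_scenes), function(i) {
    generate_scene(scene_config(n_plants = 5L + (i + seed) %% 8L,
                                tint = tints[1L + (i + seed) %% 3L],
                                seed = seed + i))
  })
  proposals <- lapply(scenes, function(s)
    generate_proposals(s, proposal_config(seed = s$config$seed + 1000L)))
  list(scenes = scenes, proposals = proposals)
}

#' Deterministic mock backends for the segmentation pipeline
#'
#' Stand-ins for the three foundation-model roles, defined purely in
#' terms of image statistics so the whole pipeline is testable offline:
#'
#' * `mock_detector(scene, config)` returns a detector function
#'   `(image, text_prompt, box_threshold)` that replays the seeded
#'   pathological proposal set for the scene.
#' * `mock_embedder(stride)` returns an embedder `(region) -> embedding`:
#'   per grid cell the smoothed feature vector
#'   `(ExG, R, G, B, x_norm, y_norm)` averaged over the cell, so green
#'   cells of different plants are mutually similar and background cells
#'   dissimilar.
#' * `mock_segmenter()` returns a segmenter `(image, prompt_set)` that
#'   selects the vegetation-mask connected components inside the prompt
#'   box that contain at least one positive point and no negative point;
#'   confidence is the fraction of in-box vegetation covered. Exactly one
#'   mask is returned per call.
#'
#' @param scene a [generate_scene()] result.
#' @param config a [proposal_config()].
#' @name mock_backends
#' @export
mock_detector <- function(scene, config = proposal_config()) {
  proposals <- generate_proposals(scene, config)
  function(image, text_prompt = "single vegetable", box_threshold = 0.1) {
    proposals[proposals$score >= box_threshold, , drop = FALSE]
  }
}

#' @rdname mock_backends
#' @param stride target region-pixels per embedding grid cell.
#' @export
mock_embedder <- function(stride = 8) {
  function(region) {
    h <- dim(region)[1]; w <- dim(region)[2]
    gh <- max(1L, floor(h / stride)); gw <- max(1L, floor(w / stride))
    row_cell <- pmin(gh, 1L + ((seq_len(h) - 1L) * gh) %/% h)
    col_cell <- pmin(gw, 1L + ((seq_len(w) - 1L) * gw) %/% w)
    exg <- excess_green(region)
    feats <- array(0, dim = c(gh, gw, 6))
    pool <- function(m) {
      t(vapply(seq_len(gh), function(i)
        vapply(seq_len(gw), function(j)
          mean(m[row_cell == i, col_cell == j]), numeric(1)),
        numeric(gw)))
    }
    feats[, , 1] <- pool(exg)
    for (k in 1:3) feats[, , k + 1] <- pool(region[, , k])
    feats[, , 5] <- outer(rep(1, gh), (seq_len(gw) - 0.5) / gw)
    feats[, , 6] <- outer((seq_len(gh) - 0.5) / gh, rep(1, gw))
    # light 3x3 smoothing across the grid
    if (gh > 1 || gw > 1) {
      for (k in 1:6) feats[, , k] <- box_blur3(matrix(feats[, , k], gh, gw))
    }
    structure(list(grid = feats, stride = c(h / gh, w / gw)),
              class = "embedding")
  }
}

box_blur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[c(1, seq_len(h - 1)), , drop = FALSE]
  dn <- m[c(seq_len(h)[-1], h), , drop = FALSE]
  v <- (up + m + dn) / 3
  lf <- v[, c(1, seq_len(w - 1)), drop = FALSE]
  rt <- v[, c(seq_len(w)[-1], w), drop = FALSE]
  (lf + v + rt) / 3
}

#' @rdname mock_backends
#' @export
mock_segmenter <- function() {
  cache <- new.env(parent = emptyenv())
  function(image, prompt_set) {
    key <- paste0("m", sum(image[, , 2]))   # per-image vegetation-mask cache
    if (is.null(cache[[key]])) cache[[key]] <- vegetation_mask(image)$mask
    veg <- cache[[key]]
    h <- nrow(veg); w <- ncol(veg)
    box <- clip_boxes(prompt_set$box, h, w)
    inbox <- matrix(FALSE, h, w)
    rows <- (ceiling(box$y_min) + 1L):ceiling(box$y_max)
    cols <- (ceiling(box$x_min) + 1L):ceiling(box$x_max)
    inbox[rows, cols] <- TRUE
    region <- veg & inbox
    empty <- list(mask = matrix(FALSE, h, w), confidence = 0)
    if (!sum(region)) return(empty)
    pts <- prompt_set$points
    if (nrow(pts) == 0) return(list(mask = region, confidence = 1))  # box-only
    labels <- EBImage::bwlabel(region)
    pos <- pts[pts$label == "positive", , drop = FALSE]
    neg <- pts[pts$label == "negative", , drop = FALSE]
    lab_at <- function(p) labels[cbind(pmin(h, pmax(1, round(p$y) + 1L)),
                                       pmin(w, pmax(1, round(p$x) + 1L)))]
    if (nrow(pos) == 0) return(empty)
    pos_labs <- setdiff(unique(lab_at(pos)), 0)
    neg_labs <- if (nrow(neg)) setdiff(unique(lab_at(neg)), 0) else integer(0)
    take <- setdiff(pos_labs, neg_labs)
    if (!length(take)) return(empty)
    mask <- matrix(labels %in% take, h, w)
    list(mask = mask, confidence = sum(mask) / sum(region))
  }
}
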