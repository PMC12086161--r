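# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / direct definitions so they share no code path with the
# package implementations they check.

# exhaustive Otsu: try every split of the 256-level quantized map and
# maximize between-class variance computed directly from the pixel vector
oracle_otsu_mask <- function(map) {
  rng <- range(map)
  q <- as.integer(round((map - rng[1]) * (255 / (rng[2] - rng[1]))))
  best_var <- -Inf
  best_t <- NA_integer_
  for (t in 0:254) {
    lo <- q[q <= t]
    hi <- q[q > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(q)
    v <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (v > best_var + 1e-12) { best_var <- v; best_t <- t }
  }
  matrix(q > best_t, nrow(map), ncol(map))
}

# exhaustive farthest point: loop over every allowed pixel
oracle_max_distance <- function(base, allowed) {
  best <- NULL; best_d <- -1; best_rm <- Inf
  if (is.null(dim(base))) base <- matrix(base, 1, 2)
  for (r in seq_len(nrow(allowed))) {
    for (cc in seq_len(ncol(allowed))) {
      if (!allowed[r, cc]) next
      x <- cc - 1; y <- r - 1
      d <- Inf
      for (k in seq_len(nrow(base))) {
        d <- min(d, sqrt((x - base[k, 1])^2 + (y - base[k, 2])^2))
      }
      rm_idx <- y * ncol(allowed) + x
      if (d > best_d + 1e-12 || (abs(d - best_d) <= 1e-12 && rm_idx < best_rm)) {
        best_d <- d; best <- c(x = x, y = y); best_rm <- rm_idx
      }
    }
  }
  best
}

# naive pairwise overlap graph (interval arithmetic per pair)
oracle_overlap_counts <- function(b) {
  n <- nrow(b)
  oven <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      iw <- min(b$x_max[i], b$x_max[j]) - max(b$x_min[i], b$x_min[j])
      ih <- min(b$y_max[i], b$y_max[j]) - max(b$y_min[i], b$y_min[j])
      if (iw > 0 && ih > 0) oven[i] <- oven[i] + 1L
    }
  }
  oven
}

# naive 101-point AP: greedy matching at every score cutoff, recomputed
# from scratch, then max-precision-at-recall>=r sampling
oracle_ap <- function(pred, gt, thr) {
  iou_pair <- function(p, g) {
    iw <- max(0, min(p$x_max, g$x_max) - max(p$x_min, g$x_min))
    ih <- max(0, min(p$y_max, g$y_max) - max(p$y_min, g$y_min))
    inter <- iw * ih
    a1 <- (p$x_max - p$x_min) * (p$y_max - p$y_min)
    a2 <- (g$x_max - g$x_min) * (g$y_max - g$y_min)
    inter / (a1 + a2 - inter)
  }
  match_topk <- function(k) {
    ord <- order(-pred$score, pred$id)
    taken <- rep(FALSE, nrow(gt))
    tp <- 0
    for (i in ord[seq_len(k)]) {
      best <- 0; bj <- 0
      for (j in seq_len(nrow(gt))) {
        if (taken[j]) next
        v <- iou_pair(pred[i, ], gt[j, ])
        if (v >= thr && v > best) { best <- v; bj <- j }
      }
      if (bj > 0) { taken[bj] <- TRUE; tp <- tp + 1 }
    }
    tp
  }
  n <- nrow(pred)
  if (n == 0) return(0)
  prec <- numeric(n); rec <- numeric(n)
  for (k in seq_len(n)) {
    tp <- match_topk(k)
    prec[k] <- tp / k
    rec[k] <- tp / nrow(gt)
  }
  mean(vapply(seq(0, 1, by = 0.01), function(r) {
    ok <- rec >= r - 1e-12
    if (any(ok)) max(prec[ok]) else 0
  }, numeric(1)))
}

# naive structure measure, written directly from the metric's definition
oracle_s_measure <- function(pred, gt, alpha = 0.5) {
  eps <- .Machine$double.eps
  y <- mean(gt)
  if (y == 0) return(1 - mean(pred))
  if (y == 1) return(mean(pred))
  obj <- function(x) {
    m <- mean(x); s <- if (length(x) > 1) stats::sd(x) else 0
    2 * m / (m^2 + 1 + s + eps)
  }
  so <- mean(gt) * obj(pred[gt]) + (1 - mean(gt)) * obj((1 - pred)[!gt])
  idx <- which(gt, arr.ind = TRUE)
  cy <- floor(mean(idx[, 1]) + 0.5); cx <- floor(mean(idx[, 2]) + 0.5)
  h <- nrow(gt); w <- ncol(gt)
  ssim_naive <- function(x, y2) {
    x <- as.numeric(x); y2 <- as.numeric(y2); n <- length(x)
    mx <- mean(x); my <- mean(y2)
    vx <- 0; vy <- 0; vxy <- 0
    if (n > 1) {
      for (i in seq_len(n)) {
        vx <- vx + (x[i] - mx)^2; vy <- vy + (y2[i] - my)^2
        vxy <- vxy + (x[i] - mx) * (y2[i] - my)
      }
      vx <- vx / (n - 1); vy <- vy / (n - 1); vxy <- vxy / (n - 1)
    }
    a <- 4 * mx * my * vxy; b <- (mx^2 + my^2) * (vx + vy)
    if (a != 0) a / (b + eps) else if (b == 0) 1 else 0
  }
  sr <- 0
  for (bl in list(list(1:cy, 1:cx), list(1:cy, setdiff(1:w, 1:cx)),
                  list(setdiff(1:h, 1:cy), 1:cx),
                  list(setdiff(1:h, 1:cy), setdiff(1:w, 1:cx)))) {
    rr <- bl[[1]]; cc <- bl[[2]]
    if (!length(rr) || !length(cc)) next
    sr <- sr + (length(rr) * length(cc)) / (h * w) *
      ssim_naive(pred[rr, cc], gt[rr, cc])
  }
  max(0, alpha * so + (1 - alpha) * sr)
}

# naive weighted F-measure: per-pixel loops for the nearest-foreground
# transform and an explicit 7x7 Gaussian correlation with zero padding
oracle_weighted_fmeasure <- function(pred, gt, beta2 = 1) {
  eps <- .Machine$double.eps
  h <- nrow(gt); w <- ncol(gt)
  e <- abs(pred - gt)
  fg <- which(gt, arr.ind = TRUE)
  dst <- matrix(0, h, w); et <- e
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      if (gt[r, cc]) next
      bd <- Inf; bi <- 0
      for (k in seq_len(nrow(fg))) {
        d <- sqrt((r - fg[k, 1])^2 + (cc - fg[k, 2])^2)
        if (d < bd) { bd <- d; bi <- k }
      }
      dst[r, cc] <- bd
      et[r, cc] <- e[fg[bi, 1], fg[bi, 2]]
    }
  }
  kern <- outer(exp(-(-3:3)^2 / 50), exp(-(-3:3)^2 / 50))
  kern <- kern / sum(kern)
  ea <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      acc <- 0
      for (dr in -3:3) {
        for (dc in -3:3) {
          rr <- r + dr; c2 <- cc + dc
          if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w) {
            acc <- acc + kern[dr + 4, dc + 4] * et[rr, c2]
          }
        }
      }
      ea[r, cc] <- acc
    }
  }
  mea <- e
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (gt[r, cc] && ea[r, cc] < e[r, cc]) mea[r, cc] <- ea[r, cc]
  }
  b <- matrix(1, h, w)
  b[!gt] <- 2 - exp(log(0.5) / 5 * dst[!gt])
  ew <- mea * b
  tpw <- sum(gt) - sum(ew[gt]); fpw <- sum(ew[!gt])
  r <- 1 - mean(ew[gt]); p <- tpw / (eps + tpw + fpw)
  (1 + beta2) * r * p / (eps + r + beta2 * p)
}

# random valid box tibble on an integer grid (guarantees every positive
# overlap has RIoU at least 1 / max box area)
random_boxes <- function(n, extent = 60, min_side = 5, max_side = 20,
                         min_score = 0.2) {
  x0 <- sample.int(extent - max_side, n, replace = TRUE)
  y0 <- sample.int(extent - max_side, n, replace = TRUE)
  wd <- sample(min_side:max_side, n, replace = TRUE)
  ht <- sample(min_side:max_side, n, replace = TRUE)
  boxes(x0, y0, x0 + wd, y0 + ht,
        score = stats::runif(n, min_score, 1))
}

# small flat test image with a green patch (for pipelines that need one)
flat_green_image <- function(h = 24, w = 24) {
  img <- array(100, dim = c(h, w, 3))
  img[5:12, 5:12, 1] <- 50; img[5:12, 5:12, 2] <- 200; img[5:12, 5:12, 3] <- 30
  rgb_image(img)
}

# rectangle plants scene used by the hand-traced VC-NMS fixture
two_plant_rect_scene <- function() {
  img <- array(100, dim = c(40, 60, 3))
  paint <- function(img, rows, cols) {
    img[rows, cols, 1] <- 50; img[rows, cols, 2] <- 200; img[rows, cols, 3] <- 30
    img
  }
  img <- paint(img, 11:20, 6:15)    # plant A: box [5,10,15,20)
  img <- paint(img, 11:20, 31:40)   # plant B: box [30,10,40,20)
  rgb_image(img)
}
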