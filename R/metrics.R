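#' Greedy one-to-one matching of detections to ground truth
#'
#' Predictions are taken in descending score order (ties toward lower id)
#' and each is matched to the unmatched ground-truth box of highest IoU
#' among those with IoU at or above the threshold. At most `max_det`
#' predictions are considered. TP + FN equals the number of ground-truth
#' boxes and TP + FP the number of considered predictions.
#'
#' @param pred,gt box tibbles (see [boxes()]); `pred` must carry scores.
#' @param iou_threshold matching threshold.
#' @param max_det cap on the number of predictions considered.
#' @return a list of class `"match_table"`: `matches` (tibble `pred_id`,
#'   `gt_id`, `iou`, `score`; `gt_id` is `NA` for false positives),
#'   `tp`, `fp`, `fn`.
#' @export
match_detections <- function(pred, gt, iou_threshold = 0.5, max_det = Inf) {
  ord <- nms_order(pred)
  pred <- pred[ord[seq_len(min(nrow(pred), max_det))], , drop = FALSE]
  gt_free <- rep(TRUE, nrow(gt))
  iou_mat <- if (nrow(pred) && nrow(gt)) box_iou(pred, gt) else
    matrix(0, nrow(pred), nrow(gt))
  rows <- vector("list", nrow(pred))
  for (i in seq_len(nrow(pred))) {
    cand <- which(gt_free & iou_mat[i, ] >= iou_threshold)
    if (length(cand)) {
      j <- cand[which.max(iou_mat[i, cand])]
      gt_free[j] <- FALSE
      rows[[i]] <- tibble::tibble(pred_id = pred$id[i], gt_id = gt$id[j],
                                  iou = iou_mat[i, j], score = pred$score[i])
    } else {
      rows[[i]] <- tibble::tibble(pred_id = pred$id[i], gt_id = NA_integer_,
                                  iou = NA_real_, score = pred$score[i])
    }
  }
  matches <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(pred_id = integer(), gt_id = integer(),
                   iou = numeric(), score = numeric())
  tp <- sum(!is.na(matches$gt_id))
  structure(list(matches = matches, tp = tp, fp = nrow(matches) - tp,
                 fn = nrow(gt) - tp),
            class = "match_table")
}

#' Precision and recall from a match table
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; both defined as 0 when
#' their denominator is 0.
#'
#' @param table a [match_detections()] result.
#' @return named numeric vector `c(precision =, recall =)`.
#' @export
precision_recall <- function(table) {
  p_den <- table$tp + table$fp
  r_den <- table$tp + table$fn
  c(precision = if (p_den > 0) table$tp / p_den else 0,
    recall = if (r_den > 0) table$tp / r_den else 0)
}

# per-image greedy TP flags for a prediction set sorted by global score order
tp_flags <- function(pred, gt, iou_threshold, max_det = Inf) {
  img_p <- pred[["image_id"]] %||% rep(1L, nrow(pred))
  img_g <- gt[["image_id"]] %||% rep(1L, nrow(gt))
  flags <- logical(nrow(pred))
  for (im in unique(img_g)) {
    pi <- which(img_p == im)
    if (is.finite(max_det)) pi <- pi[seq_len(min(length(pi), max_det))]
    gi <- which(img_g == im)
    if (!length(pi)) next
    mt <- match_detections(
      dplyr::mutate(pred[pi, ], id = seq_along(pi)),
      dplyr::mutate(gt[gi, ], id = seq_along(gi)),
      iou_threshold = iou_threshold)
    # match_detections preserves score order, which is the order of pi here
    flags[pi] <- !is.na(mt$matches$gt_id[order(mt$matches$pred_id)])
  }
  # predictions on images with no GT are false positives; drop those beyond
  # max_det entirely
  keep <- rep(TRUE, nrow(pred))
  if (is.finite(max_det)) {
    for (im in unique(img_p)) {
      pi <- which(img_p == im)
      if (length(pi) > max_det) keep[pi[-seq_len(max_det)]] <- FALSE
    }
  }
  list(flags = flags[keep], n_gt = nrow(gt), keep = keep)
}

#' Average precision of a detection set
#'
#' AP is the area under the score-swept precision-recall curve, computed
#' with 101-point interpolation (the COCO convention): precision is
#' replaced by its monotone envelope and sampled at recalls
#' `0, 0.01, ..., 1`. `average_precision()` returns one AP per IoU
#' threshold plus their mean (`ap_range`, the usual AP 0.5:0.95 when the
#' default threshold grid is used). Predictions and ground truth may span
#' several images via an optional `image_id` column.
#'
#' @param pred,gt box tibbles, optionally with an `image_id` column.
#' @param thresholds IoU thresholds; default `seq(0.5, 0.95, by = 0.05)`.
#' @param interpolation `"101pt"` (COCO) or `"all"` (exact area under the
#'   envelope at every recall step).
#' @return a list with `ap_at` (named vector per threshold) and
#'   `ap_range` (their mean).
#' @export
average_precision <- function(pred, gt, thresholds = seq(0.5, 0.95, by = 0.05),
                              interpolation = c("101pt", "all"),
                              max_det = Inf) {
  interpolation <- match.arg(interpolation)
  if (nrow(gt) == 0) {
    warning("no ground-truth boxes: AP undefined (NaN)")
    ap <- rep(NaN, length(thresholds))
    names(ap) <- sprintf("ap_%g", thresholds)
    return(list(ap_at = ap, ap_range = NaN))
  }
  ord <- order(-pred$score, pred$id)
  pred <- pred[ord, , drop = FALSE]
  ap <- vapply(thresholds, function(thr) {
    fl <- tp_flags(pred, gt, thr, max_det)
    if (!length(fl$flags)) return(0)
    ctp <- cumsum(fl$flags)
    rec <- ctp / fl$n_gt
    prec <- ctp / seq_along(ctp)
    env <- rev(cummax(rev(prec)))          # monotone precision envelope
    if (interpolation == "101pt") {
      rpts <- seq(0, 1, by = 0.01)
      idx <- findInterval(rpts, rec, left.open = TRUE) + 1L
      mean(ifelse(idx <= length(env), env[idx], 0))
    } else {
      sum(env * c(rec[1], diff(rec)))
    }
  }, numeric(1))
  names(ap) <- sprintf("ap_%g", thresholds)
  list(ap_at = ap, ap_range = mean(ap))
}

#' COCO-style averaged recall at a detection budget
#'
#' Recall averaged over the IoU thresholds 0.5:0.95 when only the
#' `max_det` highest-scored predictions per image are considered (the
#' usual meaning of the Recall@10 / Recall@100 table columns).
#'
#' @inheritParams average_precision
#' @param max_det per-image detection budget.
#' @export
recall_at_maxdet <- function(pred, gt, max_det = 100,
                             thresholds = seq(0.5, 0.95, by = 0.05)) {
  if (nrow(gt) == 0) return(NaN)
  ord <- order(-pred$score, pred$id)
  pred <- pred[ord, , drop = FALSE]
  mean(vapply(thresholds, function(thr) {
    fl <- tp_flags(pred, gt, thr, max_det)
    sum(fl$flags) / fl$n_gt
  }, numeric(1)))
}

#' Size-stratified average precision
#'
#' Boxes are assigned to strata by their own diagonal length: small
#' `< 32` px, medium `[32, 96)` px, large `>= 96` px; AP 0.5:0.95 is
#' computed on each (prediction, ground-truth) stratum pair alone. An
#' empty ground-truth stratum yields `NaN`.
#'
#' @inheritParams average_precision
#' @return named numeric vector `c(ap_small =, ap_medium =, ap_large =)`.
#' @export
size_stratified_ap <- function(pred, gt, thresholds = seq(0.5, 0.95, by = 0.05)) {
  stratum <- function(b) {
    d <- box_diagonal(b)
    dplyr::case_when(d < 32 ~ "small", d < 96 ~ "medium", TRUE ~ "large")
  }
  sp <- stratum(pred); sg <- stratum(gt)
  out <- vapply(c("small", "medium", "large"), function(s) {
    g <- gt[sg == s, , drop = FALSE]
    if (nrow(g) == 0) return(NaN)
    p <- pred[sp == s, , drop = FALSE]
    suppressWarnings(average_precision(p, g, thresholds)$ap_range)
  }, numeric(1))
  names(out) <- c("ap_small", "ap_medium", "ap_large")
  out
}

#' Detection evaluation report
#'
#' One-row tibble with the standard detection columns: AP at 0.5 / 0.75 /
#' 0.9, AP 0.5:0.95, Recall@10 and Recall@100, size-stratified AP, and
#' plain precision/recall of the full detection set at IoU 0.5.
#'
#' @inheritParams average_precision
#' @export
evaluate_detections <- function(pred, gt) {
  ap <- suppressWarnings(average_precision(pred, gt))
  strata <- size_stratified_ap(pred, gt)
  pr <- precision_recall(match_detections(pred, gt, 0.5))
  tibble::tibble(
    ap_50 = unname(ap$ap_at["ap_0.5"]), ap_75 = unname(ap$ap_at["ap_0.75"]),
    ap_90 = unname(ap$ap_at["ap_0.9"]), ap_50_95 = ap$ap_range,
    recall_10 = recall_at_maxdet(pred, gt, 10),
    recall_100 = recall_at_maxdet(pred, gt, 100),
    ap_small = strata[["ap_small"]], ap_medium = strata[["ap_medium"]],
    ap_large = strata[["ap_large"]],
    precision = pr[["precision"]], recall = pr[["recall"]])
}

#' Mask overlap measures: Dice and IoU
#'
#' `dice(a, b) = 2|A ∩ B| / (|A| + |B|)`; both-empty masks score 1 by
#' convention (perfect agreement on absence). The algebraic identity
#' `dice = 2 iou / (1 + iou)` holds for every mask pair.
#'
#' @param a,b logical matrices of identical shape.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  den <- sum(a) + sum(b)
  if (den == 0) return(1)
  2 * sum(a & b) / den
}

#' @rdname dice
#' @export
mask_iou <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Expected calibration error of a probability map
#'
#' Pixels are treated as binary classifiers: predicted class
#' `p >= 0.5`, confidence `max(p, 1 - p)`. Confidences are pooled into
#' `n_bins` equal-width bins over `[0.5, 1]` and
#' `ECE = sum |B_m|/n * |acc(B_m) - conf(B_m)|`.
#'
#' @param prob_map numeric matrix in `[0, 1]`.
#' @param gt_mask logical matrix of the same shape.
#' @param n_bins number of confidence bins.
#' @export
ece <- function(prob_map, gt_mask, n_bins = 10) {
  stopifnot(all(dim(prob_map) == dim(gt_mask)))
  p <- as.numeric(prob_map)
  conf <- pmax(p, 1 - p)
  correct <- (p >= 0.5) == as.logical(gt_mask)
  breaks <- seq(0.5, 1, length.out = n_bins + 1)
  bin <- findInterval(conf, breaks, left.open = TRUE, rightmost.closed = TRUE)
  bin[bin == 0] <- 1L                      # conf == 0.5 goes to the first bin
  n <- length(p)
  out <- 0
  for (m in seq_len(n_bins)) {
    in_bin <- bin == m
    if (any(in_bin)) {
      out <- out + sum(in_bin) / n * abs(mean(correct[in_bin]) - mean(conf[in_bin]))
    }
  }
  out
}

# sample sd with the convention sd(length-1 vector) = 0
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Structure measure (S-measure) of a segmentation map
#'
#' Structure-aware quality score mixing an object-aware term (separate
#' foreground/background dispersion-penalized similarity) and a
#' region-aware term (SSIM over the four blocks induced by the
#' ground-truth centroid, weighted by block area):
#' `Sm = alpha * S_object + (1 - alpha) * S_region`. Degenerate ground
#' truth follows the original definition: all-background GT scores
#' `1 - mean(pred)`, all-foreground GT scores `mean(pred)`.
#'
#' @param pred_map numeric matrix in `[0, 1]`.
#' @param gt_mask logical matrix of the same shape.
#' @param alpha object/region balance; 0.5 weighs them equally.
#' @export
s_measure <- function(pred_map, gt_mask, alpha = 0.5) {
  stopifnot(all(dim(pred_map) == dim(gt_mask)))
  gt <- as.logical(gt_mask); dim(gt) <- dim(gt_mask)
  y <- mean(gt)
  if (y == 0) return(1 - mean(pred_map))
  if (y == 1) return(mean(pred_map))
  max(0, alpha * s_object(pred_map, gt) + (1 - alpha) * s_region(pred_map, gt))
}

s_object <- function(pred, gt) {
  eps <- .Machine$double.eps
  o_score <- function(x) 2 * mean(x) / (mean(x)^2 + 1 + sd0(x) + eps)
  mu <- mean(gt)
  mu * o_score(pred[gt]) + (1 - mu) * o_score((1 - pred)[!gt])
}

s_region <- function(pred, gt) {
  h <- nrow(gt); w <- ncol(gt)
  idx <- which(gt, arr.ind = TRUE)
  rnd <- function(v) floor(v + 0.5)        # round half up, deterministic
  cy <- rnd(mean(idx[, 1])); cx <- rnd(mean(idx[, 2]))
  blocks <- list(list(1:cy, 1:cx), list(1:cy, seq_len(w)[-(1:cx)]),
                 list(seq_len(h)[-(1:cy)], 1:cx),
                 list(seq_len(h)[-(1:cy)], seq_len(w)[-(1:cx)]))
  total <- h * w
  out <- 0
  for (bl in blocks) {
    rr <- bl[[1]]; cc <- bl[[2]]
    if (!length(rr) || !length(cc)) next
    out <- out + length(rr) * length(cc) / total *
      block_ssim(pred[rr, cc, drop = FALSE], gt[rr, cc, drop = FALSE])
  }
  out
}

block_ssim <- function(x, y) {
  eps <- .Machine$double.eps
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  if (n < 2) { vx <- 0; vy <- 0; vxy <- 0 } else {
    vx <- sum((x - mx)^2) / (n - 1); vy <- sum((y - my)^2) / (n - 1)
    vxy <- sum((x - mx) * (y - my)) / (n - 1)
  }
  a <- 4 * mx * my * vxy
  b <- (mx^2 + my^2) * (vx + vy)
  if (a != 0) a / (b + eps) else if (b == 0) 1 else 0
}

# exact nearest-foreground-pixel distance and index for every pixel,
# computed by chunked brute force (exact, deterministic; fine at the
# region sizes this package works with)
nearest_foreground <- function(gt) {
  h <- nrow(gt); w <- ncol(gt)
  fg <- which(gt)
  if (!length(fg)) stop("mask has no foreground", call. = FALSE)
  fr <- (fg - 1L) %% h; fc <- (fg - 1L) %/% h
  dist <- matrix(0, h, w)
  idx <- matrix(rep.int(0L, h * w), h, w)
  idx[fg] <- fg
  bg <- which(!gt)
  if (length(bg)) {
    br <- (bg - 1L) %% h; bc <- (bg - 1L) %/% h
    chunk <- max(1L, floor(4e6 / length(fg)))
    for (start in seq(1L, length(bg), by = chunk)) {
      sel <- start:min(start + chunk - 1L, length(bg))
      d2 <- outer(br[sel], fr, `-`)^2 + outer(bc[sel], fc, `-`)^2
      j <- max.col(-d2, ties.method = "first")
      dist[bg[sel]] <- sqrt(d2[cbind(seq_along(sel), j)])
      idx[bg[sel]] <- fg[j]
    }
  }
  list(dist = dist, idx = idx)
}

# separable Gaussian filter with zero padding (7x7, sigma 5 by default),
# matching the kernel used by the original weighted-F-measure definition
gaussian_filter <- function(x, size = 7, sigma = 5) {
  half <- (size - 1) / 2
  k1 <- exp(-((-half):half)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)  # the 2-D kernel is the normalized outer product
  h <- nrow(x); w <- ncol(x)
  pad <- matrix(0, h + 2 * half, w + 2 * half)
  pad[half + (1:h), half + (1:w)] <- x
  # filter rows then columns
  out <- matrix(0, h + 2 * half, w)
  for (o in (-half):half) {
    out <- out + k1[o + half + 1] * pad[, half + (1:w) + o]
  }
  res <- matrix(0, h, w)
  for (o in (-half):half) {
    res <- res + k1[o + half + 1] * out[half + (1:h) + o, ]
  }
  res
}

#' Weighted F-measure of a segmentation map
#'
#' Spatially weighted precision/recall for foreground maps: errors at
#' background pixels are replaced by the error at their nearest
#' ground-truth pixel, locally averaged with a Gaussian window
#' (7x7, sigma 5), and down-weighted with distance from the object
#' (`B = 2 - exp(log(0.5)/5 * dist)`); the weighted F-score combines the
#' resulting weighted precision and recall with weight `beta2`.
#' Undefined (with a warning) for an empty ground truth.
#'
#' @param pred_map numeric matrix in `[0, 1]`.
#' @param gt_mask logical matrix of the same shape.
#' @param beta2 recall/precision trade-off (`beta^2`); 1 balances them.
#' @export
weighted_fmeasure <- function(pred_map, gt_mask, beta2 = 1) {
  stopifnot(all(dim(pred_map) == dim(gt_mask)))
  gt <- as.logical(gt_mask); dim(gt) <- dim(gt_mask)
  if (!any(gt)) {
    warning("empty ground truth: weighted F-measure undefined (NaN)")
    return(NaN)
  }
  eps <- .Machine$double.eps
  e <- abs(pred_map - gt)
  nf <- nearest_foreground(gt)
  et <- e
  et[!gt] <- et[nf$idx[!gt]]
  ea <- gaussian_filter(et)
  min_e_ea <- e
  repl <- gt & (ea < e)
  min_e_ea[repl] <- ea[repl]
  b <- matrix(1, nrow(gt), ncol(gt))
  b[!gt] <- 2 - exp(log(0.5) / 5 * nf$dist[!gt])
  ew <- min_e_ea * b
  tpw <- sum(gt) - sum(ew[gt])
  fpw <- sum(ew[!gt])
  r <- 1 - mean(ew[gt])
  p <- tpw / (eps + tpw + fpw)
  (1 + beta2) * r * p / (eps + r + beta2 * p)
}

#' Segmentation evaluation report for one probability map
#'
#' One-row tibble with IoU, Dice (both at a 0.5 binarization), ECE,
#' S-measure and weighted F-measure of a predicted foreground map
#' against a ground-truth mask.
#'
#' @inheritParams weighted_fmeasure
#' @export
evaluate_masks <- function(pred_map, gt_mask) {
  bin <- pred_map >= 0.5
  tibble::tibble(
    iou = mask_iou(bin, gt_mask),
    dice = dice(bin, gt_mask),
    ece = ece(pred_map, gt_mask),
    sm = s_measure(pred_map, gt_mask),
    wfm = weighted_fmeasure(pred_map, gt_mask))
}
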