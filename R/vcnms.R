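#' Configuration for Vegetation-Cover-Aware NMS
#'
#' Defaults reflect the settings used for fully automated batch
#' processing of hydroponic plant imagery: `beta = 0.7` balances the
#' vegetation-cover index against detector confidence, the RIoU gate
#' `overlap_threshold = 0.7` restricts the stage-1 overlap penalty to
#' highly overlapping boxes, and `box_threshold = 0.1` is the detector
#' confidence pre-filter. `sigma = 0.5` (Gaussian decay scale) and
#' `final_score_threshold = 0.1` (stage-2 retention cutoff) are this
#' package's documented defaults.
#'
#' @param beta weight of NCGI in the composite score, in `[0, 1]`.
#' @param overlap_threshold RIoU gate `N_t` for the stage-1 penalty.
#' @param sigma Gaussian decay scale for stage 2 (`> 0`).
#' @param final_score_threshold stage-2 retention cutoff.
#' @param box_threshold detector-confidence pre-filter.
#' @param attenuation `"once"` (default): the overlap penalty multiplies a
#'   box's score at most once, when any later-ordered box meets the gate;
#'   `"per_pair"`: multiplied once per qualifying pair (sensitivity
#'   variant); `"none"`: stage-1 penalty disabled.
#' @param decay_overlap overlap measure used by the stage-2 decay,
#'   `"riou"` (default) or `"iou"`.
#' @param oven_gate overlap-count comparison in the stage-1 gate:
#'   `"strict"` (default) penalizes a box only when it has strictly more
#'   overlaps than the qualifying later box (the multi-plant union case
#'   the penalty targets); `"gte"` also fires on equal counts, which
#'   additionally penalizes every member of a uniform redundancy cluster.
#' @param exg_variant Excess-Green variant, see [excess_green()].
#' @return a list of class `"vcnms_config"`.
#' @export
vcnms_config <- function(beta = 0.7, overlap_threshold = 0.7, sigma = 0.5,
                         final_score_threshold = 0.1, box_threshold = 0.1,
                         attenuation = c("once", "per_pair", "none"),
                         decay_overlap = c("riou", "iou"),
                         oven_gate = c("strict", "gte"),
                         exg_variant = c("raw", "chromaticity")) {
  stopifnot(beta >= 0, beta <= 1, overlap_threshold >= 0, overlap_threshold <= 1,
            sigma > 0, final_score_threshold >= 0, final_score_threshold <= 1,
            box_threshold >= 0, box_threshold <= 1)
  structure(list(beta = beta, overlap_threshold = overlap_threshold,
                 sigma = sigma, final_score_threshold = final_score_threshold,
                 box_threshold = box_threshold,
                 attenuation = match.arg(attenuation),
                 decay_overlap = match.arg(decay_overlap),
                 oven_gate = match.arg(oven_gate),
                 exg_variant = match.arg(exg_variant)),
            class = "vcnms_config")
}

#' Composite NCGI score
#'
#' Fuses the Normalized Cover Green Index with the detector confidence:
#' `beta * ncgi + (1 - beta) * score`. Vectorized.
#'
#' @param ncgi NCGI values in `[0, 1]`.
#' @param score confidence scores in `[0, 1]`.
#' @param beta NCGI weight in `[0, 1]`.
#' @export
composite_score <- function(ncgi, score, beta = 0.7) {
  beta * ncgi + (1 - beta) * score
}

#' Gaussian score decay on overlap
#'
#' `exp(-overlap^2 / sigma)`: no penalty at zero overlap, near-total
#' suppression at high overlap. Used with RIoU in stage 2 of VC-NMS so
#' that nested duplicates (RIoU ~ 1) are strongly decayed while adjacent
#' plants (low RIoU) are barely touched.
#'
#' @param overlap overlap values in `[0, 1]` (RIoU or IoU).
#' @param sigma decay scale, `> 0`.
#' @export
gaussian_decay <- function(overlap, sigma = 0.5) exp(-overlap^2 / sigma)

# deterministic processing order: score desc, then larger area, then lower id
nms_order <- function(b) order(-b$score, -box_area(b), b$id)

#' Stage 1 of VC-NMS: composite scoring and overlap-count attenuation
#'
#' Replaces every score by the composite NCGI score (computed in place
#' from the original confidences), sorts boxes in non-ascending composite
#' order, and applies the linear overlap-count penalty: a box `i` whose
#' RIoU with some later-ordered box `j` reaches `overlap_threshold` while
#' having more overlaps than `j` (strictly more under the default
#' `oven_gate = "strict"`) has its score multiplied by
#' `(1 - oven_i / max_oven)`. Under the default `attenuation = "once"`
#' the multiplication happens at most once per box; with `"per_pair"` it
#' repeats for every qualifying pair. When `max_oven = 0` (no overlaps at
#' all) no attenuation occurs.
#'
#' @param b a box tibble carrying an `ncgi` column (see [add_ncgi()]).
#' @param graph the [overlap_graph()] of `b`.
#' @param config a [vcnms_config()].
#' @return `b` with updated `score` and a logical `attenuated` column.
#' @export
stage1_update <- function(b, graph, config = vcnms_config()) {
  stopifnot("ncgi" %in% names(b))
  b$score_input <- b$score
  b$score <- composite_score(b$ncgi, b$score, config$beta)
  b$attenuated <- FALSE
  n <- nrow(b)
  if (n < 2 || config$attenuation == "none" || graph$max_oven == 0) return(b)
  ord <- nms_order(b)
  riou_mat <- box_riou(b, b)
  oven <- graph$oven
  factor_i <- 1 - oven / graph$max_oven
  gate <- if ((config$oven_gate %||% "strict") == "strict") `>` else `>=`
  for (pos in seq_len(n - 1)) {
    i <- ord[pos]
    later <- ord[(pos + 1):n]
    qualifies <- riou_mat[i, later] >= config$overlap_threshold &
      gate(oven[i], oven[later])
    k <- sum(qualifies)
    if (k > 0) {
      b$score[i] <- b$score[i] *
        if (config$attenuation == "once") factor_i[i] else factor_i[i]^k
      b$attenuated[i] <- TRUE
    }
  }
  b
}

# shared greedy pick-and-decay loop used by stage 2 and Soft-NMS
soft_select <- function(b, decay_fn, overlap_fn, score_threshold,
                        stage_label = "stage2") {
  kept <- b[0, ]
  trace <- list()
  work <- b
  while (nrow(work) > 0) {
    work <- work[nms_order(work), ]
    if (work$score[1] < score_threshold) break
    m <- work[1, ]
    kept <- dplyr::bind_rows(kept, m)
    trace[[length(trace) + 1L]] <-
      tibble::tibble(stage = stage_label, event = "pick", id = m$id,
                     score = m$score)
    work <- work[-1, , drop = FALSE]
    if (nrow(work) > 0) {
      ov <- as.numeric(overlap_fn(m, work))
      work$score <- work$score * decay_fn(ov)
    }
  }
  suppressed <- if (nrow(work)) dplyr::mutate(work, reason = "decayed") else
    dplyr::mutate(work[0, ], reason = character())
  list(kept = kept, suppressed = suppressed,
       trace = dplyr::bind_rows(trace))
}

#' Stage 2 of VC-NMS: RIoU-Gaussian greedy selection
#'
#' Iteratively moves the highest-scored box into the final detections and
#' multiplies every remaining score by the Gaussian decay of its RIoU
#' with the picked box; stops when no remaining score reaches
#' `final_score_threshold`. Ties are broken toward larger area, then
#' lower id, making the result invariant to input ordering.
#'
#' @param b a box tibble with stage-1 scores (see [stage1_update()]).
#' @param config a [vcnms_config()].
#' @return an object of class `"nms_result"`; see [vc_nms()].
#' @export
stage2_select <- function(b, config = vcnms_config()) {
  overlap_fn <- if (config$decay_overlap == "riou") box_riou else box_iou
  sel <- soft_select(b, function(ov) gaussian_decay(ov, config$sigma),
                     overlap_fn, config$final_score_threshold)
  new_nms_result(sel$kept, sel$suppressed, sel$trace, "vc", config, nrow(b))
}

new_nms_result <- function(kept, suppressed, trace, method, config, n_input) {
  structure(list(kept = tibble::as_tibble(kept),
                 suppressed = tibble::as_tibble(suppressed),
                 trace = tibble::as_tibble(trace),
                 method = method, config = config, n_input = n_input),
            class = "nms_result")
}

#' Vegetation-Cover-Aware Non-Maximum Suppression
#'
#' The full two-stage algorithm. Boxes below `box_threshold` are removed
#' first; a vegetation mask (ExG + Otsu) is computed on the image; NCGI
#' and the overlap graph are derived; stage 1 replaces confidences by
#' composite NCGI scores and attenuates boxes with many highly
#' overlapping neighbours (typically large multi-plant union boxes);
#' stage 2 greedily selects maxima under an RIoU Gaussian decay. The
#' result keeps suppressed boxes (with reasons) and a stage trace for
#' qualitative inspection.
#'
#' @param image an [rgb_image()].
#' @param raw_boxes detector candidates, a box tibble (see [boxes()]).
#' @param config a [vcnms_config()].
#' @return an object of class `"nms_result"` with elements `kept`
#'   (tibble: box columns, final `score`, original `score_input`, `ncgi`),
#'   `suppressed` (same columns plus `reason`), `trace`, `method`,
#'   `config`, `n_input`. [tidy()] and [glance()] methods are provided.
#' @examples
#' scene <- generate_scene(scene_config(n_plants = 3, seed = 7))
#' props <- generate_proposals(scene, proposal_config(seed = 7))
#' res <- vc_nms(scene$image, props)
#' glance(res)
#' @export
vc_nms <- function(image, raw_boxes, config = vcnms_config()) {
  raw_boxes <- validate_boxes(raw_boxes)
  keep <- raw_boxes$score >= config$box_threshold
  prefiltered <- dplyr::mutate(raw_boxes[!keep, , drop = FALSE],
                               reason = "box_threshold")
  b <- raw_boxes[keep, , drop = FALSE]
  if (nrow(b) == 0) {
    return(new_nms_result(b, prefiltered, tibble::tibble(), "vc", config,
                          nrow(raw_boxes)))
  }
  vm <- vegetation_mask(image, config$exg_variant)
  graph <- overlap_graph(b)
  b <- add_ncgi(b, vm, graph)
  b <- stage1_update(b, graph, config)
  res <- stage2_select(b, config)
  res$suppressed <- dplyr::bind_rows(res$suppressed, prefiltered)
  res$n_input <- nrow(raw_boxes)
  res
}

#' Greedy (hard) NMS baseline
#'
#' Textbook NMS: confidence-ranked greedy selection, removing any
#' remaining box whose overlap with the pick exceeds `iou_threshold`.
#'
#' @param b a box tibble.
#' @param iou_threshold suppression threshold.
#' @param measure overlap measure, `"iou"` (standard) or `"riou"`.
#' @return an `"nms_result"`.
#' @export
greedy_nms <- function(b, iou_threshold = 0.5, measure = c("iou", "riou")) {
  measure <- match.arg(measure)
  b <- validate_boxes(b)
  overlap_fn <- if (measure == "iou") box_iou else box_riou
  kept <- b[0, ]
  suppressed <- dplyr::mutate(b[0, ], reason = character())
  work <- b
  trace <- list()
  while (nrow(work) > 0) {
    work <- work[nms_order(work), ]
    m <- work[1, ]
    kept <- dplyr::bind_rows(kept, m)
    trace[[length(trace) + 1L]] <-
      tibble::tibble(stage = "greedy", event = "pick", id = m$id, score = m$score)
    work <- work[-1, , drop = FALSE]
    if (nrow(work) > 0) {
      ov <- as.numeric(overlap_fn(m, work))
      gone <- ov > iou_threshold
      if (any(gone)) {
        suppressed <- dplyr::bind_rows(
          suppressed, dplyr::mutate(work[gone, ], reason = "overlap"))
        work <- work[!gone, , drop = FALSE]
      }
    }
  }
  new_nms_result(kept, suppressed, dplyr::bind_rows(trace), "greedy",
                 list(iou_threshold = iou_threshold, measure = measure), nrow(b))
}

#' Soft-NMS baselines (linear and Gaussian penalty)
#'
#' Confidence-ranked greedy selection where overlapping boxes have their
#' scores decayed instead of being removed: `mode = "linear"` multiplies
#' by `(1 - overlap)` once overlap reaches `iou_threshold`; `"gaussian"`
#' multiplies by `exp(-overlap^2 / sigma)`. Boxes whose decayed score
#' falls below `score_threshold` are dropped.
#'
#' @param b a box tibble.
#' @param mode `"gaussian"` or `"linear"`.
#' @param sigma Gaussian decay scale.
#' @param iou_threshold linear-mode gate.
#' @param score_threshold retention cutoff.
#' @param measure overlap measure, `"iou"` (standard) or `"riou"`.
#' @return an `"nms_result"`.
#' @export
soft_nms <- function(b, mode = c("gaussian", "linear"), sigma = 0.5,
                     iou_threshold = 0.3, score_threshold = 0.1,
                     measure = c("iou", "riou")) {
  mode <- match.arg(mode); measure <- match.arg(measure)
  b <- validate_boxes(b)
  overlap_fn <- if (measure == "iou") box_iou else box_riou
  decay_fn <- if (mode == "gaussian") {
    function(ov) gaussian_decay(ov, sigma)
  } else {
    function(ov) ifelse(ov >= iou_threshold, 1 - ov, 1)
  }
  sel <- soft_select(b, decay_fn, overlap_fn, score_threshold,
                     stage_label = paste0("soft_", mode))
  new_nms_result(sel$kept, sel$suppressed, sel$trace,
                 paste0("soft_", mode),
                 list(sigma = sigma, iou_threshold = iou_threshold,
                      score_threshold = score_threshold, measure = measure),
                 nrow(b))
}

#' @export
print.nms_result <- function(x, ...) {
  cat("<nms_result: ", x$method, ">  ", nrow(x$kept), " kept / ",
      nrow(x$suppressed), " suppressed (", x$n_input, " input)\n", sep = "")
  print(x$kept)
  invisible(x)
}

#' Tidy an NMS result into one row per box
#'
#' @param x an `"nms_result"`.
#' @param ... unused.
#' @return a tibble with the box columns, final `score`, and `status`
#'   (`"kept"`/`"suppressed"`) plus `reason` for suppressed boxes.
#' @method tidy nms_result
#' @export
tidy.nms_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$kept, status = "kept", reason = NA_character_),
    dplyr::mutate(x$suppressed, status = "suppressed")
  )
}

#' One-row summary of an NMS result
#'
#' @inheritParams tidy.nms_result
#' @method glance nms_result
#' @export
glance.nms_result <- function(x, ...) {
  tibble::tibble(method = x$method, n_input = x$n_input,
                 n_kept = nrow(x$kept), n_suppressed = nrow(x$suppressed),
                 mean_kept_score = mean(x$kept$score))
}
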