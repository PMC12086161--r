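#' Run configuration for the end-to-end segmentation pipeline
#'
#' Bundles the VC-NMS settings with the prompt configuration and the
#' detector text prompt. Defaults are the batch-processing settings for
#' hydroponic imagery: text prompt `"single vegetable"`, two positive
#' and two negative point prompts per box.
#'
#' @param vcnms a [vcnms_config()].
#' @param n_pos,n_neg point-prompt counts per box.
#' @param text_prompt open-set detector text prompt.
#' @param prompt_mode `"both"` (box + points, default), `"box"` (box
#'   prompt only) or `"points"` (point prompts only; the segmenter then
#'   receives the whole image as its search region).
#' @param embed_stride embedding grid stride for the mock embedder.
#' @param seed integer seed for any stochastic backend.
#' @return a list of class `"run_config"`, YAML-serializable via
#'   [write_run_config()].
#' @export
run_config <- function(vcnms = vcnms_config(), n_pos = 2, n_neg = 2,
                       text_prompt = "single vegetable",
                       prompt_mode = c("both", "box", "points"),
                       embed_stride = 8, seed = 1) {
  structure(list(vcnms = vcnms, n_pos = n_pos, n_neg = n_neg,
                 text_prompt = text_prompt,
                 prompt_mode = match.arg(prompt_mode),
                 embed_stride = embed_stride, seed = as.integer(seed)),
            class = "run_config")
}

#' Read and write run configurations as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$vcnms <- unclass(lst$vcnms)
  yaml::write_yaml(c(list(schema = "greenprompt/run-config/1"), lst), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  run_config(vcnms = do.call(vcnms_config, lst$vcnms),
             n_pos = lst$n_pos, n_neg = lst$n_neg,
             text_prompt = lst$text_prompt, prompt_mode = lst$prompt_mode,
             embed_stride = lst$embed_stride, seed = lst$seed)
}

#' Mock backend bundle for a synthetic scene
#'
#' @param scene a [generate_scene()] result.
#' @param proposals a box tibble the mock detector replays (defaults to a
#'   seeded [generate_proposals()] draw for the scene).
#' @param stride embedding grid stride.
#' @return list with `detector`, `embedder`, `segmenter` functions
#'   satisfying the backend interfaces.
#' @export
scene_backends <- function(scene, proposals = NULL, stride = 8) {
  proposals <- proposals %||%
    generate_proposals(scene, proposal_config(seed = scene$config$seed + 1000L))
  list(
    detector = function(image, text_prompt = "single vegetable",
                        box_threshold = 0.1) {
      proposals[proposals$score >= box_threshold, , drop = FALSE]
    },
    embedder = mock_embedder(stride),
    segmenter = mock_segmenter())
}

#' Segment one image end to end: detect, VC-NMS, prompts, segment
#'
#' Runs the full prompt-generation pipeline behind pluggable backends:
#' detector candidates are refined by [vc_nms()], each kept box gets a
#' [build_prompt_set()], and the segmenter produces exactly one mask per
#' box. Deterministic with the mock backends.
#'
#' @param image an [rgb_image()].
#' @param backends a backend bundle (see [scene_backends()]).
#' @param config a [run_config()].
#' @return a tibble with one row per instance: the kept-box columns,
#'   `prompts` (list of `"prompt_set"`), `mask` (list of logical
#'   matrices) and `confidence`; the NMS result is attached as attribute
#'   `"nms"`.
#' @export
segment_image <- function(image, backends, config = run_config()) {
  raw <- tryCatch(
    backends$detector(image, config$text_prompt, config$vcnms$box_threshold),
    error = function(e) stop("detector backend failed: ", conditionMessage(e),
                             call. = FALSE))
  res <- vc_nms(image, raw, config$vcnms)
  kept <- res$kept
  if (nrow(kept) == 0) {
    out <- dplyr::mutate(kept, prompts = list(), mask = list(),
                         confidence = numeric())
    attr(out, "nms") <- res
    return(out)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  prompt_sets <- if (config$prompt_mode == "box") {
    lapply(seq_len(nrow(kept)), function(i) {
      structure(list(box = clip_boxes(kept[i, ], h, w),
                     points = tibble::tibble(x = numeric(), y = numeric(),
                                             label = character(),
                                             kind = character()),
                     y_n = kept$score[i]), class = "prompt_set")
    })
  } else {
    ps <- build_prompt_sets(image, kept, backends$embedder,
                            n_pos = config$n_pos, n_neg = config$n_neg)
    if (config$prompt_mode == "points") {
      lapply(ps, function(p) {
        p$box <- boxes(0, 0, w, h, score = p$y_n, id = p$box$id)
        p
      })
    } else ps
  }
  segs <- lapply(prompt_sets, function(p) {
    tryCatch(backends$segmenter(image, p),
             error = function(e) stop("segmenter backend failed: ",
                                      conditionMessage(e), call. = FALSE))
  })
  out <- dplyr::mutate(kept,
                       prompts = prompt_sets,
                       mask = lapply(segs, `[[`, "mask"),
                       confidence = vapply(segs, `[[`, numeric(1), "confidence"))
  attr(out, "nms") <- res
  out
}

#' Pooled foreground probability map of a set of instances
#'
#' Each pixel gets the maximum confidence among the instance masks that
#' cover it (0 elsewhere); the scene-level comparison surface for the
#' mask metrics.
#'
#' @param instances a [segment_image()] result.
#' @param height,width map size.
#' @export
instance_prob_map <- function(instances, height, width) {
  prob <- matrix(0, height, width)
  for (i in seq_len(nrow(instances))) {
    m <- instances$mask[[i]]
    prob[m] <- pmax(prob[m], instances$confidence[i])
  }
  prob
}

#' Evaluate a segmented scene against its ground truth
#'
#' Pools the instance masks into a probability map ([instance_prob_map()])
#' and compares it with the union of the ground-truth plant masks:
#' returns IoU, Dice, ECE, S-measure and weighted F-measure.
#'
#' @param instances a [segment_image()] result.
#' @param scene the [generate_scene()] scene it was computed on.
#' @export
evaluate_scene_segmentation <- function(instances, scene) {
  h <- scene$config$height; w <- scene$config$width
  gt <- scene$ownership > 0
  evaluate_masks(instance_prob_map(instances, h, w), gt)
}

nms_method_fn <- function(method, config) {
  switch(method,
    vc = function(scene, proposals) vc_nms(scene$image, proposals, config$vcnms),
    greedy = function(scene, proposals) {
      pre <- proposals[proposals$score >= config$vcnms$box_threshold, ]
      greedy_nms(pre, iou_threshold = 0.5)
    },
    soft_linear = function(scene, proposals) {
      pre <- proposals[proposals$score >= config$vcnms$box_threshold, ]
      soft_nms(pre, mode = "linear",
               score_threshold = config$vcnms$final_score_threshold)
    },
    soft_gaussian = function(scene, proposals) {
      pre <- proposals[proposals$score >= config$vcnms$box_threshold, ]
      soft_nms(pre, mode = "gaussian", sigma = config$vcnms$sigma,
               score_threshold = config$vcnms$final_score_threshold)
    },
    stop("unknown NMS method: ", method, call. = FALSE))
}

# stack per-scene boxes into a dataset tibble with image_id
stack_with_image_id <- function(box_list) {
  purrr::imap_dfr(box_list, function(b, i)
    dplyr::mutate(b, image_id = as.integer(i),
                  id = seq_len(nrow(b)) + 100000L * as.integer(i)))
}

#' Compare NMS variants on a battery of scenes
#'
#' Applies each method to identical proposal sets and reports the
#' detection metric table (AP at 0.5/0.75/0.9, AP 0.5:0.95, Recall@10 and
#' Recall@100, size-stratified AP) per method.
#'
#' @param scenes list of [generate_scene()] scenes.
#' @param proposals list of proposal tibbles, parallel to `scenes`
#'   (defaults to seeded [generate_proposals()] draws).
#' @param methods subset of `"vc"`, `"greedy"`, `"soft_linear"`,
#'   `"soft_gaussian"`.
#' @param config a [run_config()].
#' @return a tibble, one row per method.
#' @export
run_nms_comparison <- function(scenes, proposals = NULL,
                               methods = c("vc", "greedy", "soft_linear",
                                           "soft_gaussian"),
                               config = run_config()) {
  if (length(scenes) == 0) return(tibble::tibble(method = character()))
  proposals <- proposals %||% lapply(scenes, function(s)
    generate_proposals(s, proposal_config(seed = s$config$seed + 1000L)))
  gt <- stack_with_image_id(lapply(scenes, `[[`, "gt_boxes"))
  purrr::map_dfr(methods, function(m) {
    fn <- nms_method_fn(m, config)
    kept <- stack_with_image_id(purrr::map2(scenes, proposals, function(s, p) {
      fn(s, p)$kept[, c("x_min", "y_min", "x_max", "y_max", "score", "id")]
    }))
    dplyr::bind_cols(tibble::tibble(method = m),
                     evaluate_detections(kept, gt))
  })
}

run_segmentation_battery <- function(scenes, proposals, config) {
  purrr::map2_dfr(scenes, proposals, function(s, p) {
    inst <- segment_image(s$image, scene_backends(s, p, config$embed_stride),
                          config)
    evaluate_scene_segmentation(inst, s)
  })
}

#' Sweep the number of point prompts over a grid
#'
#' Re-runs the pipeline for every (positive, negative) point-count pair
#' over shared scenes and proposals and reports the mean scene Dice.
#'
#' @inheritParams run_nms_comparison
#' @param n_pos,n_neg integer vectors of counts to sweep.
#' @return a tibble with columns `n_pos`, `n_neg`, `dice`.
#' @export
run_point_sweep <- function(scenes, proposals = NULL, n_pos = 1:5, n_neg = 1:5,
                            config = run_config()) {
  proposals <- proposals %||% lapply(scenes, function(s)
    generate_proposals(s, proposal_config(seed = s$config$seed + 1000L)))
  grid <- tidyr::expand_grid(n_pos = n_pos, n_neg = n_neg)
  purrr::pmap_dfr(grid, function(n_pos, n_neg) {
    cfg <- config; cfg$n_pos <- n_pos; cfg$n_neg <- n_neg
    per_scene <- suppressWarnings(
      run_segmentation_battery(scenes, proposals, cfg))
    tibble::tibble(n_pos = n_pos, n_neg = n_neg,
                   dice = mean(per_scene$dice))
  })
}

#' Sensitivity sweep over the composite-score weight beta
#'
#' Re-runs the full pipeline with each beta on shared scenes and
#' proposals; reports the mean scene-level mask metrics per beta.
#'
#' @inheritParams run_nms_comparison
#' @param betas numeric vector of NCGI weights to test.
#' @return a tibble with columns `beta`, `iou`, `dice`, `ece`, `sm`,
#'   `wfm`.
#' @export
run_beta_sweep <- function(scenes, proposals = NULL,
                           betas = seq(0.1, 0.9, by = 0.1),
                           config = run_config()) {
  proposals <- proposals %||% lapply(scenes, function(s)
    generate_proposals(s, proposal_config(seed = s$config$seed + 1000L)))
  purrr::map_dfr(betas, function(beta) {
    cfg <- config; cfg$vcnms$beta <- beta
    per_scene <- suppressWarnings(
      run_segmentation_battery(scenes, proposals, cfg))
    dplyr::bind_cols(tibble::tibble(beta = beta),
                     dplyr::summarise(per_scene,
                                      dplyr::across(dplyr::everything(), mean)))
  })
}
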