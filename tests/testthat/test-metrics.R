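gt_grid <- function(n, size = 10, gap = 20) {
  x0 <- (seq_len(n) - 1) * gap
  boxes(x0, rep(0, n), x0 + size, rep(size, n), score = 1, id = seq_len(n))
}

test_that("matching is greedy, score-ranked and one-to-one", {
  gt <- gt_grid(1)
  exact <- dplyr::mutate(gt, score = 0.9)
  mt <- match_detections(exact, gt, iou_threshold = 0.9)
  expect_equal(c(mt$tp, mt$fp, mt$fn), c(1, 0, 0))

  off <- boxes(0, 0, 10, 4, score = 0.9)  # IoU 0.4 vs the 10x10 GT
  expect_equal(box_iou(off, gt)[1, 1], 0.4)
  mt2 <- match_detections(off, gt, iou_threshold = 0.5)
  expect_equal(c(mt2$tp, mt2$fp, mt2$fn), c(0, 1, 1))

  # 3 predictions / 2 GT: the top-scored prediction claims the best GT
  gt2 <- gt_grid(2)
  pred <- boxes(c(0, 1, 20), c(0, 0, 0), c(10, 11, 30), c(10, 10, 10),
                score = c(0.5, 0.9, 0.7), id = 1:3)
  mt3 <- match_detections(pred, gt2, iou_threshold = 0.5)
  m <- mt3$matches
  expect_equal(m$pred_id, c(2L, 3L, 1L))           # score order
  expect_equal(m$gt_id, c(1L, 2L, NA_integer_))     # box 1 finds GT1 taken
  expect_equal(c(mt3$tp, mt3$fp, mt3$fn), c(2, 1, 0))
  expect_equal(mt3$tp + mt3$fn, nrow(gt2))
})

test_that("precision and recall follow their definitions with 0/0 = 0", {
  gt <- gt_grid(5)
  pred <- dplyr::bind_rows(
    dplyr::mutate(gt[1:3, ], score = 0.9),
    boxes(200, 200, 210, 210, score = 0.8, id = 99L))
  pr <- precision_recall(match_detections(pred, gt))
  expect_equal(unname(pr), c(0.75, 0.6))
  none <- precision_recall(match_detections(pred[0, ], gt))
  expect_equal(unname(none), c(0, 0))
  perfect <- precision_recall(match_detections(dplyr::mutate(gt, score = 1), gt))
  expect_equal(unname(perfect), c(1, 1))
})

test_that("average precision matches hand-derived two-point curves", {
  gt <- gt_grid(1)
  one <- dplyr::mutate(gt, score = 0.8)
  expect_equal(average_precision(one, gt, 0.5)$ap_at[["ap_0.5"]], 1)
  # a false positive ranked above the true positive halves precision at
  # full recall: the interpolated integral is 0.5 everywhere
  fp_first <- dplyr::bind_rows(
    boxes(100, 100, 110, 110, score = 0.9, id = 2L),
    dplyr::mutate(gt, score = 0.8))
  expect_equal(average_precision(fp_first, gt, 0.5)$ap_at[["ap_0.5"]], 0.5)
  expect_equal(oracle_ap(fp_first, gt, 0.5), 0.5)
  # perfect predictions reach AP 1 at every threshold
  gt5 <- gt_grid(5)
  perfect <- dplyr::mutate(gt5, score = runif(5))
  ap <- average_precision(perfect, gt5)
  expect_equal(unname(ap$ap_at), rep(1, 10))
  expect_equal(ap$ap_range, 1)
})

test_that("average precision equals the naive P-R integration oracle", {
  withr::with_seed(41, {
    for (rep in 1:12) {
      n_gt <- sample(1:4, 1)
      gt <- random_boxes(n_gt)
      pred <- dplyr::bind_rows(
        dplyr::mutate(gt, x_min = x_min + runif(n_gt, 0, 3),
                      score = runif(n_gt)),
        random_boxes(sample(1:6, 1)))
      pred$id <- seq_len(nrow(pred))
      for (thr in c(0.5, 0.75)) {
        expect_equal(average_precision(pred, gt, thr)$ap_at[[1]],
                     oracle_ap(pred, gt, thr), tolerance = 1e-12)
      }
    }
  })
})

test_that("AP is invariant to monotone transforms of the scores", {
  withr::with_seed(43, {
    gt <- random_boxes(5)
    pred <- dplyr::bind_rows(dplyr::mutate(gt, score = runif(5)),
                             random_boxes(5))
    pred$id <- seq_len(nrow(pred))
    a1 <- average_precision(pred, gt)$ap_range
    a2 <- average_precision(dplyr::mutate(pred, score = score^3), gt)$ap_range
    expect_equal(a1, a2)
  })
})

test_that("recall is monotone in the detection budget", {
  withr::with_seed(47, {
    for (rep in 1:5) {
      gt <- random_boxes(8)
      pred <- dplyr::bind_rows(
        dplyr::mutate(gt, score = runif(8)), random_boxes(10))
      pred$id <- seq_len(nrow(pred))
      expect_gte(recall_at_maxdet(pred, gt, 100),
                 recall_at_maxdet(pred, gt, 10))
    }
  })
})

test_that("size strata follow the diagonal conventions", {
  small_gt <- boxes(c(0, 40), c(0, 0), c(12, 56), c(16, 12), 1, 1:2)
  expect_equal(box_diagonal(small_gt), c(20, 20))
  strata <- size_stratified_ap(dplyr::mutate(small_gt, score = 0.9), small_gt)
  expect_equal(unname(strata[["ap_small"]]), 1)
  expect_true(is.nan(strata[["ap_medium"]]) && is.nan(strata[["ap_large"]]))
  # diagonal exactly 32 px sits in the medium stratum
  b32 <- boxes(0, 0, 19.2, 25.6)
  expect_equal(box_diagonal(b32), 32)
  s32 <- size_stratified_ap(dplyr::mutate(b32, score = 1), b32)
  expect_true(is.nan(s32[["ap_small"]]))
  expect_equal(unname(s32[["ap_medium"]]), 1)
})

test_that("per-stratum AP equals recomputation on the stratum subset", {
  withr::with_seed(53, {
    gt <- dplyr::bind_rows(
      boxes(c(0, 30), c(0, 0), c(15, 45), c(15, 15), 1, 1:2),        # small
      boxes(c(60, 120), c(0, 0), c(100, 160), c(40, 40), 1, 3:4))    # medium
    pred <- dplyr::mutate(gt, x_min = x_min + c(1, 2, 3, 50),
                          score = c(0.9, 0.8, 0.7, 0.6))
    full <- size_stratified_ap(pred, gt)
    d <- box_diagonal(gt); dp <- box_diagonal(pred)
    for (s in c("small", "medium")) {
      lo <- if (s == "small") 0 else 32
      hi <- if (s == "small") 32 else 96
      sub <- suppressWarnings(
        average_precision(pred[dp >= lo & dp < hi, ],
                          gt[d >= lo & d < hi, ])$ap_range)
      expect_equal(unname(full[[paste0("ap_", s)]]), sub)
    }
  })
})

test_that("dice matches its examples and the 2iou/(1+iou) identity", {
  m1 <- matrix(runif(100) < 0.5, 10, 10)
  expect_equal(dice(m1, m1), 1)
  m2 <- matrix(FALSE, 10, 10); m2[1:3, 1:3] <- TRUE
  m3 <- matrix(FALSE, 10, 10); m3[7:9, 7:9] <- TRUE
  expect_equal(dice(m2, m3), 0)
  withr::with_seed(59, {
    for (rep in 1:50) {
      a <- matrix(runif(64) < runif(1), 8, 8)
      b <- matrix(runif(64) < runif(1), 8, 8)
      i <- mask_iou(a, b)
      expect_equal(dice(a, b), 2 * i / (1 + i), tolerance = 1e-12)
      expect_gte(dice(a, b), i)
    }
  })
  expect_equal(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 1)
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shapes")
})

test_that("ECE is zero for confident-correct and one for confident-wrong", {
  gt <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  perfect <- matrix(as.numeric(gt), 2, 2)
  expect_equal(ece(perfect, gt), 0)
  wrong <- 1 - perfect
  expect_equal(ece(wrong, gt), 1)
})

test_that("ECE matches a hand-computed two-bin case", {
  # 4 pixels at p = 0.6 (3 correct), 4 at p = 0.95 (2 correct)
  prob <- matrix(c(rep(0.6, 4), rep(0.95, 4)), 2, 4)
  gt <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE), 2, 4)
  # bins (0.55,0.6] and (0.9,0.95]: 0.5*|0.75-0.6| + 0.5*|0.5-0.95|
  expect_equal(ece(prob, gt), 0.5 * 0.15 + 0.5 * 0.45)
})

test_that("structure measure: fixed points and degenerate ground truths", {
  gt <- matrix(FALSE, 12, 12); gt[4:9, 4:9] <- TRUE
  expect_equal(s_measure(matrix(as.numeric(gt), 12, 12), gt), 1)
  expect_equal(s_measure(matrix(0.3, 6, 6), matrix(FALSE, 6, 6)), 0.7)
  expect_equal(s_measure(matrix(0.3, 6, 6), matrix(TRUE, 6, 6)), 0.3)
})

test_that("weighted F-measure: fixed points and empty-GT fallback", {
  gt <- matrix(FALSE, 14, 14); gt[5:10, 5:10] <- TRUE
  expect_equal(weighted_fmeasure(matrix(as.numeric(gt), 14, 14), gt), 1,
               tolerance = 1e-9)
  # inverted prediction with GT clear of the border scores exactly 0
  expect_equal(weighted_fmeasure(1 - matrix(as.numeric(gt), 14, 14), gt), 0,
               tolerance = 1e-9)
  expect_warning(v <- weighted_fmeasure(matrix(0.4, 5, 5), matrix(FALSE, 5, 5)),
                 "empty")
  expect_true(is.nan(v))
})

test_that("Sm and wFm agree with naive reference implementations", {
  gt_half <- matrix(FALSE, 12, 12); gt_half[, 1:6] <- TRUE
  checker <- matrix(as.numeric((row(gt_half) + col(gt_half)) %% 2 == 0), 12, 12)
  expect_equal(s_measure(checker, gt_half), oracle_s_measure(checker, gt_half),
               tolerance = 1e-12)
  expect_equal(weighted_fmeasure(checker, gt_half),
               oracle_weighted_fmeasure(checker, gt_half), tolerance = 1e-9)
  withr::with_seed(61, {
    for (rep in 1:4) {
      gt <- matrix(FALSE, 10, 10)
      gt[sample.int(100, sample(20:60, 1))] <- TRUE
      pred <- matrix(runif(100), 10, 10)
      expect_equal(s_measure(pred, gt), oracle_s_measure(pred, gt),
                   tolerance = 1e-12)
      expect_equal(weighted_fmeasure(pred, gt),
                   oracle_weighted_fmeasure(pred, gt), tolerance = 1e-9)
    }
  })
})

test_that("all metrics stay within [0, 1] on random inputs", {
  withr::with_seed(67, {
    for (rep in 1:5) {
      gt <- matrix(FALSE, 9, 9); gt[sample.int(81, 30)] <- TRUE
      pred <- matrix(runif(81), 9, 9)
      ev <- evaluate_masks(pred, gt)
      expect_true(all(ev >= 0 & ev <= 1))
    }
  })
})

test_that("evaluate_detections warns (NaN AP) when there is no ground truth", {
  pred <- dplyr::mutate(gt_grid(2), score = 0.5)
  expect_warning(ap <- average_precision(pred, gt_grid(0)), "no ground-truth")
  expect_true(is.nan(ap$ap_range))
})
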