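test_that("composite_score blends NCGI and confidence per the weight", {
  expect_equal(composite_score(1.0, 0.4, beta = 0.7), 0.82)
  expect_equal(composite_score(0.3, 0.9, beta = 0), 0.9)
  expect_equal(composite_score(0.3, 0.9, beta = 1), 0.3)
})

test_that("gaussian_decay has the stated limits and monotonicity", {
  expect_equal(gaussian_decay(0, 0.5), 1)
  expect_equal(gaussian_decay(1, 0.5), exp(-2))
  r <- seq(0, 1, by = 0.05)
  expect_true(all(diff(gaussian_decay(r, 0.5)) < 0))
  expect_true(all(gaussian_decay(r, 0.25) > 0))
})

stage1_fixture <- function() {
  b <- boxes(
    x_min = c(0, 0, 9, 30, 30, 30, 30, 30),
    y_min = c(0, 0, 0, 30, 30, 30, 30, 30),
    x_max = c(10, 5, 19, 38, 38, 38, 38, 38),
    y_max = c(10, 10, 10, 38, 38, 38, 38, 38),
    score = c(0.4, 0.2, 0.3, rep(0.5, 5)),
    id = 1:8)
  b$ncgi <- c(1, 0.3, 0.4, rep(0.5, 5))
  b
}

test_that("stage 1 applies the overlap-count penalty exactly once", {
  b <- stage1_fixture()
  g <- overlap_graph(b)
  expect_equal(g$oven[1:3], c(2L, 1L, 1L))
  expect_equal(g$max_oven, 4L)  # the five coincident boxes
  out <- stage1_update(b, g, vcnms_config())
  # box 1: composite 0.7*1 + 0.3*0.4 = 0.82; nested box 2 is later-ordered
  # with RIoU 1 and strictly fewer overlaps -> multiplied by (1 - 2/4)
  expect_equal(out$score[1], 0.41)
  expect_true(out$attenuated[1])
  # coincident boxes tie on overlap count: strict gate leaves them alone
  expect_equal(out$score[4:8], rep(composite_score(0.5, 0.5), 5))
  # boxes 2 and 3 have no later-ordered high-RIoU partner
  expect_equal(out$score[2], composite_score(0.3, 0.2))
  expect_equal(out$score[3], composite_score(0.4, 0.3))
})

test_that("stage 1 under the equation-variant gate also penalizes ties", {
  b <- stage1_fixture()
  g <- overlap_graph(b)
  out <- stage1_update(b, g, vcnms_config(oven_gate = "gte"))
  # the first four coincident boxes now qualify against a later twin
  expect_equal(out$score[4:7], rep(0, 4))
  expect_equal(out$score[8], composite_score(0.5, 0.5))  # last has no later j
})

test_that("a union box with the maximal overlap count is fully attenuated", {
  b <- boxes(
    x_min = c(0, 0, 11, 21, 31), y_min = rep(0, 5),
    x_max = c(41, 9, 19, 29, 39), y_max = rep(10, 5),
    score = c(0.9, rep(0.3, 4)), id = 1:5)
  b$ncgi <- c(1, rep(0.4, 4))
  g <- overlap_graph(b)
  expect_equal(g$oven, c(4L, 1L, 1L, 1L, 1L))
  out <- stage1_update(b, g, vcnms_config())
  expect_equal(out$score[1], 0)  # (1 - 4/4) * composite
  expect_equal(out$score[-1], rep(composite_score(0.4, 0.3), 4))
})

test_that("stage 1 reduces to composite scoring when no pair meets the gate", {
  withr::with_seed(2, {
    b <- boxes(c(0, 30, 60), c(0, 0, 0), c(20, 50, 80), c(20, 20, 20),
               score = runif(3), id = 1:3)
    b$ncgi <- runif(3)
    out <- stage1_update(b, overlap_graph(b), vcnms_config())
    expect_equal(out$score, composite_score(b$ncgi, b$score, 0.7))
    expect_false(any(out$attenuated))
  })
})

test_that("per-pair attenuation compounds over qualifying pairs", {
  b <- boxes(c(0, 1, 2), c(0, 1, 2), c(20, 19, 18), c(20, 19, 18),
             score = c(0.9, 0.5, 0.3), id = 1:3)
  b$ncgi <- c(1, 0.6, 0.4)
  # an extra sliver raises box 1's overlap count above its nested boxes,
  # and a coincident 5-clique elsewhere sets max_oven = 4
  extra <- dplyr::mutate(
    boxes(c(19.5, rep(50, 5)), c(0, rep(50, 5)), c(30, rep(58, 5)),
          c(5, rep(58, 5)), score = 0.2, id = 4:9), ncgi = 0.2)
  b2 <- dplyr::bind_rows(b, extra)
  g2 <- overlap_graph(b2)
  expect_equal(g2$oven[1], 3L)
  expect_equal(g2$max_oven, 4L)
  once <- stage1_update(b2, g2, vcnms_config(attenuation = "once"))
  per <- stage1_update(b2, g2, vcnms_config(attenuation = "per_pair"))
  f <- 1 - 3 / 4
  comp1 <- composite_score(1, 0.9)
  expect_equal(once$score[1], comp1 * f)
  expect_equal(per$score[1], comp1 * f^2)  # boxes 2 and 3 both qualify
})

test_that("stage 2 keeps disjoint boxes untouched", {
  b <- boxes(c(0, 30), c(0, 0), c(10, 40), c(10, 10), c(0.8, 0.6), 1:2)
  b$ncgi <- c(1, 1)
  res <- stage2_select(b, vcnms_config())
  expect_equal(nrow(res$kept), 2)
  expect_equal(sort(res$kept$score), sort(c(0.8, 0.6)))
})

test_that("at most two of N coincident boxes survive stage 2", {
  b <- boxes(rep(0, 5), rep(0, 5), rep(10, 5), rep(10, 5),
             score = c(1, 0.99, 0.98, 0.97, 0.96), id = 1:5)
  res <- stage2_select(b, vcnms_config())
  # second survivor carries exp(-2) ~ 0.135; third exp(-4) < threshold
  expect_equal(nrow(res$kept), 2)
  expect_equal(res$kept$score, c(1, 0.99 * exp(-2)))
  expect_equal(nrow(res$suppressed), 3)
  expect_true(all(res$suppressed$reason == "decayed"))
})

test_that("the three-box union scene resolves to the two tight boxes", {
  # two 10x10 rectangular plants; a multi-plant union box outscores two
  # tight single-plant boxes on confidence but is crushed by VC-NMS
  img <- two_plant_rect_scene()
  b <- boxes(x_min = c(4, 5, 30), y_min = c(9, 10, 10),
             x_max = c(41, 15, 40), y_max = c(21, 20, 20),
             score = c(0.9, 0.5, 0.45), id = 1:3)
  res <- vc_nms(img, b, vcnms_config())
  expect_equal(sort(res$kept$id), c(2L, 3L))
  # manual trace: NCGI = (1, 0.5, 0.5); composites (0.97, 0.5, 0.485);
  # union attenuated by (1 - 2/2) = 0; stage 2 picks the tight boxes with
  # zero mutual RIoU, so their composite scores survive unchanged
  expect_equal(res$kept$score[res$kept$id == 2], 0.5)
  expect_equal(res$kept$score[res$kept$id == 3], 0.485)
  expect_equal(res$suppressed$id, 1L)
})

test_that("vc_nms handles the no-competition and all-filtered edges", {
  img <- flat_green_image()
  single <- boxes(4, 4, 14, 14, score = 0.6)
  res <- vc_nms(img, single, vcnms_config())
  expect_equal(nrow(res$kept), 1)
  expect_equal(res$kept$score, composite_score(1, 0.6))  # isolated: NCGI 1
  low <- boxes(c(2, 8), c(2, 8), c(12, 18), c(12, 18), score = c(0.05, 0.09))
  res2 <- vc_nms(img, low, vcnms_config())
  expect_equal(nrow(res2$kept), 0)
  expect_true(all(res2$suppressed$reason == "box_threshold"))
})

test_that("kept plus suppressed partition the input after pre-filtering", {
  withr::with_seed(15, {
    img <- generate_scene(scene_config(n_plants = 5, seed = 15))$image
    b <- random_boxes(18, extent = 150, min_score = 0.05)
    res <- vc_nms(img, b, vcnms_config())
    expect_setequal(c(res$kept$id, res$suppressed$id), b$id)
    expect_true(all(res$kept$score >= 0.1))
    d <- tidy(res)
    expect_equal(nrow(d), nrow(b))
    g <- glance(res)
    expect_equal(g$n_kept + g$n_suppressed, g$n_input)
  })
})

test_that("vc_nms output is invariant to input row order", {
  withr::with_seed(23, {
    sc <- generate_scene(scene_config(n_plants = 6, seed = 23))
    b <- generate_proposals(sc, proposal_config(seed = 42))
    res1 <- vc_nms(sc$image, b, vcnms_config())
    res2 <- vc_nms(sc$image, b[sample.int(nrow(b)), ], vcnms_config())
    expect_equal(res1$kept, res2$kept)
    expect_setequal(res1$suppressed$id, res2$suppressed$id)
  })
})

test_that("raising the retention threshold never keeps more boxes", {
  withr::with_seed(29, {
    sc <- generate_scene(scene_config(n_plants = 6, seed = 29))
    b <- generate_proposals(sc, proposal_config(seed = 77))
    kept_n <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.6), function(thr) {
      nrow(vc_nms(sc$image, b,
                  vcnms_config(final_score_threshold = thr))$kept)
    }, numeric(1))
    expect_true(all(diff(kept_n) <= 0))
  })
})

test_that("no two kept boxes are geometrically identical", {
  withr::with_seed(37, {
    img <- flat_green_image(70, 70)
    b <- random_boxes(12, extent = 60)
    b <- dplyr::bind_rows(b, dplyr::mutate(b[1:4, ], id = 13:16))  # clones
    res <- vc_nms(img, b, vcnms_config())
    k <- res$kept
    geom <- paste(k$x_min, k$y_min, k$x_max, k$y_max)
    expect_false(anyDuplicated(geom) > 0)
  })
})

test_that("greedy NMS removes the lower-scored box of a high-IoU pair", {
  b <- boxes(c(0, 0), c(0, 0.5), c(10, 10), c(10, 10.5), c(0.9, 0.7), 1:2)
  expect_gt(box_iou(b[1, ], b[2, ])[1, 1], 0.5)
  res <- greedy_nms(b, iou_threshold = 0.5)
  expect_equal(res$kept$id, 1L)
  expect_equal(res$suppressed$id, 2L)
})

test_that("soft NMS decays scores per its linear and Gaussian rules", {
  disj <- boxes(c(0, 30), c(0, 0), c(10, 40), c(10, 10), c(0.9, 0.8), 1:2)
  resg <- soft_nms(disj, mode = "gaussian")
  expect_equal(sort(resg$kept$score), c(0.8, 0.9))
  pair <- boxes(c(0, 0), c(0, 2.5), c(10, 10), c(10, 12.5), c(0.9, 0.8), 1:2)
  expect_equal(box_iou(pair[1, ], pair[2, ])[1, 1], 0.6)
  resl <- soft_nms(pair, mode = "linear")
  expect_equal(resl$kept$score[resl$kept$id == 2], 0.8 * (1 - 0.6))
})

test_that("config defaults reject out-of-range parameters", {
  expect_error(vcnms_config(beta = 1.2))
  expect_error(vcnms_config(sigma = 0))
  expect_error(vcnms_config(box_threshold = -0.1))
})
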