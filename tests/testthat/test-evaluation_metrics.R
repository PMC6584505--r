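test_that("matching follows the IOU cutoff with exact areas", {
  truth <- boxes_df(100, 100, 40, 40)
  # shifted by (4,4): intersection 36^2 = 1296, union 2*1600-1296 = 1904
  near <- boxes_df(104, 104, 40, 40, confidence = 0.9)
  expect_equal(iou(near, truth), 1296 / 1904, tolerance = 1e-12)
  mr <- match_picks(near, truth, 0.6)
  expect_equal(mr$tp, 1)
  expect_equal(mean_iou(mr), 1296 / 1904, tolerance = 1e-12)
  # shifted by (20,20): intersection 400, union 2800 -> FP and FN
  far <- boxes_df(120, 120, 40, 40, confidence = 0.9)
  expect_equal(iou(far, truth), 400 / 2800, tolerance = 1e-12)
  mr2 <- match_picks(far, truth, 0.6)
  expect_equal(c(mr2$tp, mr2$fp, mr2$fn), c(0, 1, 1))
  # no picks at all
  mr3 <- match_picks(boxes_df(), boxes_df(cx = 1:5 * 50, cy = 100,
                                          w = 30, h = 30), 0.6)
  expect_equal(c(mr3$tp, mr3$fp, mr3$fn), c(0, 0, 5))
  # the cutoff is strict: IOU exactly 0.6 is a false positive
  a <- boxes_df(0, 0, 10, 15, confidence = 1)   # iou with 10x10 at 0,0:
  t6 <- boxes_df(0, 0, 10, 10)                  # 100/150 = 2/3 > 0.6
  expect_gt(iou(a, t6), 0.6)
  shifted <- boxes_df(0, 2.5, 10, 10, confidence = 1)  # 75/125 = 0.6
  expect_equal(iou(shifted, t6), 0.6, tolerance = 1e-12)
  expect_equal(match_picks(shifted, t6, 0.6)$tp, 0)
})

test_that("each truth is matched at most once, TP + FN = |truth|", {
  set.seed(71)
  for (i in 1:25) {
    truth <- random_boxes(sample(1:8, 1), lim = 100, wmin = 10, wmax = 30)
    picks <- random_boxes(sample(0:10, 1), lim = 100, wmin = 10, wmax = 30)
    mr <- match_picks(picks, truth, 0.4)
    expect_equal(mr$tp + mr$fn, nrow(truth))
    expect_equal(mr$tp + mr$fp, nrow(picks))
    expect_equal(anyDuplicated(mr$pairs$truth), 0)
    expect_equal(anyDuplicated(mr$pairs$pick), 0)
  }
})

test_that("precision and recall definitions including degenerate cases", {
  mr <- list(tp = 8, fp = 2, fn = 2)
  class(mr) <- "match_result"
  pr <- precision_recall(mr)
  expect_equal(pr[["precision"]], 0.8)
  expect_equal(pr[["recall"]], 0.8)
  mr0 <- match_picks(boxes_df(), boxes_df(10, 10, 5, 5), 0.6)
  pr0 <- precision_recall(mr0)
  expect_equal(pr0[["precision"]], 1.0)
  expect_equal(pr0[["recall"]], 0.0)
  perfect <- boxes_df(10, 10, 5, 5, confidence = 1)
  prp <- precision_recall(match_picks(perfect, boxes_df(10, 10, 5, 5),
                                      0.6))
  expect_equal(unname(prp), c(1, 1))
  expect_true(is.na(mean_iou(mr0)))
})

test_that("the worked precision-recall example integrates to AUC 1", {
  truth <- boxes_df(cx = c(50, 150), cy = 50, w = 20, h = 20)
  picks <- boxes_df(cx = c(50, 150, 300), cy = 50, w = 20, h = 20,
                    confidence = c(0.9, 0.8, 0.7))
  prc <- pr_curve(picks, truth, 0.6)
  expect_equal(prc$recall, c(0.5, 1.0, 1.0))
  expect_equal(prc$precision, c(1.0, 1.0, 2 / 3))
  expect_equal(prc$auc, 1.0)
  # perfect picker
  prp <- pr_curve(boxes_df(cx = c(50, 150), cy = 50, w = 20, h = 20,
                           confidence = 1),
                  truth, 0.6)
  expect_equal(prp$auc, 1.0)
  # picker emitting only false positives
  prf <- pr_curve(boxes_df(cx = 400, cy = 400, w = 20, h = 20,
                           confidence = 0.9), truth, 0.6)
  expect_equal(prf$auc, 0.0)
})

test_that("pr_curve equals the per-threshold re-matching oracle", {
  set.seed(72)
  for (i in 1:200) {
    n_t <- sample(0:6, 1)
    n_p <- sample(0:8, 1)
    truth <- random_boxes(n_t, lim = 60, wmin = 8, wmax = 20)
    picks <- random_boxes(n_p, lim = 60, wmin = 8, wmax = 20)
    # duplicate confidences are possible in practice
    if (n_p > 2) picks$confidence[2] <- picks$confidence[1]
    prc <- pr_curve(picks, truth, 0.4)
    orc <- oracle_pr(picks, truth, 0.4)
    expect_equal(prc$thresholds, orc$thresholds)
    expect_equal(prc$precision, orc$precision)
    expect_equal(prc$recall, orc$recall)
  }
})

test_that("appending a lowest-confidence FP keeps earlier points intact", {
  set.seed(73)
  truth <- random_boxes(5, lim = 80, wmin = 10, wmax = 20)
  picks <- truth
  picks$confidence <- runif(5, 0.5, 1)
  class(picks) <- c("boxes", "data.frame")
  base <- pr_curve(picks, truth, 0.6)
  withfp <- rbind(picks, boxes_df(500, 500, 10, 10, confidence = 0.1))
  class(withfp) <- c("boxes", "data.frame")
  ext <- pr_curve(withfp, truth, 0.6)
  k <- length(base$thresholds)
  expect_equal(ext$precision[1:k], base$precision)
  expect_equal(ext$recall[1:k], base$recall)
})

test_that("duplicating picks then suppressing leaves metrics unchanged", {
  set.seed(74)
  truth <- random_boxes(6, lim = 100, wmin = 12, wmax = 24)
  picks <- truth
  picks$cx <- picks$cx + runif(6, -1, 1)
  picks$confidence <- runif(6, 0.4, 1)
  class(picks) <- c("boxes", "data.frame")
  doubled <- rbind(picks, transform(picks, confidence = confidence * 0.9))
  class(doubled) <- c("boxes", "data.frame")
  deduped <- nms(doubled, 0.6)
  mr1 <- match_picks(picks, truth, 0.5)
  mr2 <- match_picks(deduped, truth, 0.5)
  expect_equal(c(mr2$tp, mr2$fp, mr2$fn), c(mr1$tp, mr1$fp, mr1$fn))
  expect_equal(pr_curve(deduped, truth, 0.5)$auc,
               pr_curve(picks, truth, 0.5)$auc)
})

test_that("pooled curves aggregate micrographs into one ranking", {
  set.seed(75)
  truths <- list(random_boxes(4, lim = 80, wmin = 15, wmax = 25),
                 random_boxes(3, lim = 80, wmin = 15, wmax = 25))
  picks <- lapply(truths, function(tr) {
    p <- tr; p$confidence <- runif(nrow(tr), 0.5, 1)
    class(p) <- c("boxes", "data.frame"); p
  })
  prc <- pooled_pr_curve(picks, truths, 0.6)
  expect_equal(prc$auc, 1.0)
  expect_equal(max(prc$recall), 1.0)
  # one set of pure false positives halves the attainable precision tail
  picks2 <- picks
  picks2[[2]] <- boxes_df(cx = c(700, 750), cy = 700, w = 20, h = 20,
                          confidence = c(0.2, 0.1))
  prc2 <- pooled_pr_curve(picks2, truths, 0.6)
  expect_lt(prc2$auc, 1.0)
  expect_equal(max(prc2$recall), 4 / 7)
})

test_that("evaluate_picks reports aggregate and per-micrograph scores", {
  td <- file.path(tempdir(), "eval_truth")
  pd <- file.path(tempdir(), "eval_picks")
  dir.create(td, showWarnings = FALSE)
  dir.create(pd, showWarnings = FALSE)
  set.seed(76)
  for (i in 1:2) {
    tr <- random_boxes(5, lim = 200, wmin = 30, wmax = 31)
    p <- tr
    p$confidence <- runif(5, 0.5, 1)
    class(p) <- c("boxes", "data.frame")
    write_boxes(tr, file.path(td, sprintf("m%d.box", i)))
    write_boxes(p, file.path(pd, sprintf("m%d.star", i)), format = "star")
  }
  res <- evaluate_picks(pd, td, 0.6, box_size = 30)
  expect_equal(res$summary$recall, 1.0)
  expect_equal(res$summary$precision, 1.0)
  expect_equal(nrow(res$per_micrograph), 2)
  unlink(c(td, pd), recursive = TRUE)
})
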