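make_dets <- function(boxes, classes_vec, conf, C = 3) {
  n <- length(conf)
  probs <- matrix(0.0001, n, C)
  if (n > 0) probs[cbind(seq_len(n), classes_vec + 1)] <- 1
  probs <- probs / rowSums(probs)
  structure(list(boxes = matrix(boxes, ncol = 4), class_probs = probs,
                 confidence = conf), class = "pw_detections")
}

test_that("perfect predictions score AP 1 for every class at every threshold", {
  sc <- tiny_scenes(6, seed = 3)
  truths <- lapply(sc, function(s) s$boxes)
  preds <- lapply(sc, function(s)
    make_dets(as.matrix(s$boxes[, c("x1", "y1", "x2", "y2")]),
              s$boxes$class_id, rep(0.95, nrow(s$boxes))))
  ap <- average_precision(preds, truths, 0.5, classes = 3)
  expect_equal(unname(ap), rep(1, 3), tolerance = 1e-12)
  rep <- evaluate_detections(preds, truths, classes = 3)
  expect_equal(rep$map50, 1, tolerance = 1e-12)
  expect_equal(rep$map50_95, 1, tolerance = 1e-12)
  expect_identical(rep$fp, 0L)
  expect_identical(rep$fn, 0L)
})

test_that("the hand-walked (TP, FP, TP) case gives all-point AP 0.8333", {
  truths <- list(data.frame(class_id = c(0L, 0L),
                            x1 = c(10, 60), y1 = c(10, 60),
                            x2 = c(30, 80), y2 = c(30, 80)))
  preds <- list(make_dets(rbind(c(10, 10, 30, 30),    # TP, conf .9
                                c(40, 40, 55, 55),    # FP, conf .8
                                c(60, 60, 80, 80)),   # TP, conf .7
                          c(0L, 0L, 0L), c(0.9, 0.8, 0.7)))
  ap <- average_precision(preds, truths, 0.5, classes = 1)
  expect_equal(unname(ap[1]), 0.5 * 1.0 + 0.5 * (2 / 3), tolerance = 1e-12)
  expect_equal(unname(ap[1]), 0.8333, tolerance = 1e-4)
})

test_that("appending a lowest-confidence false positive never increases AP", {
  set.seed(5)
  for (case in 1:10) {
    sc <- tiny_scenes(3, seed = case)
    truths <- lapply(sc, function(s) s$boxes)
    preds <- lapply(sc, function(s) {
      keep <- runif(nrow(s$boxes)) < 0.7
      jit <- as.matrix(s$boxes[keep, c("x1", "y1", "x2", "y2")]) +
        rnorm(sum(keep) * 4, 0, 2)
      make_dets(jit, s$boxes$class_id[keep], runif(sum(keep), 0.3, 1))
    })
    ap0 <- suppressWarnings(mean(average_precision(preds, truths, 0.5, 3),
                                 na.rm = TRUE))
    preds_fp <- preds
    fp_box <- matrix(c(1, 1, 9, 9), 1, 4)
    preds_fp[[1]] <- make_dets(rbind(preds[[1]]$boxes, fp_box),
                               c(max.col(preds[[1]]$class_probs) - 1L, 0L),
                               c(preds[[1]]$confidence, 0.01))
    ap1 <- suppressWarnings(mean(average_precision(preds_fp, truths, 0.5, 3),
                                 na.rm = TRUE))
    expect_lte(ap1, ap0 + 1e-12)
  }
})

test_that("AP agrees with an independent staircase reference on random cases", {
  set.seed(9)
  for (case in 1:20) {
    n_gt <- sample(1:6, 1)
    gt <- data.frame(class_id = 0L,
                     x1 = runif(n_gt, 0, 60), y1 = runif(n_gt, 0, 60))
    gt$x2 <- gt$x1 + runif(n_gt, 8, 20)
    gt$y2 <- gt$y1 + runif(n_gt, 8, 20)
    n_p <- sample(1:10, 1)
    src <- sample(n_gt, n_p, replace = TRUE)
    jitter <- matrix(rnorm(n_p * 4, 0, 4), n_p, 4)
    pb <- as.matrix(gt[src, c("x1", "y1", "x2", "y2")]) + jitter
    pb[, 3] <- pmax(pb[, 3], pb[, 1] + 1)
    pb[, 4] <- pmax(pb[, 4], pb[, 2] + 1)
    conf <- runif(n_p)
    preds <- list(make_dets(pb, rep(0L, n_p), conf, C = 1))
    truths <- list(gt)
    ap <- unname(average_precision(preds, truths, 0.5, classes = 1)[1])

    # independent reference: same matching definition, separate code
    ord <- order(conf, decreasing = TRUE)
    used <- rep(FALSE, n_gt)
    is_tp <- logical(n_p)
    for (r in ord) {
      iou <- box_iou(pb[r, , drop = FALSE],
                     as.matrix(gt[, c("x1", "y1", "x2", "y2")]))[1, ]
      j_ord <- order(iou, decreasing = TRUE)
      for (j in j_ord) {
        if (iou[j] >= 0.5 && !used[j]) { is_tp[r] <- TRUE; used[j] <- TRUE; break }
        if (iou[j] < 0.5) break
      }
    }
    expect_equal(ap, ref_ap_one_class(conf, is_tp, n_gt), tolerance = 1e-10)
  }
})

test_that("image order does not change the report; empty predictions score zero", {
  sc <- tiny_scenes(5, seed = 13)
  truths <- lapply(sc, function(s) s$boxes)
  preds <- lapply(sc, function(s)
    make_dets(as.matrix(s$boxes[, c("x1", "y1", "x2", "y2")]) + rnorm(4, 0, 3),
              s$boxes$class_id, runif(nrow(s$boxes))))
  r1 <- evaluate_detections(preds, truths, classes = 3)
  perm <- c(4, 2, 5, 1, 3)
  r2 <- evaluate_detections(preds[perm], truths[perm], classes = 3)
  expect_equal(r1$map50, r2$map50, tolerance = 1e-12)
  expect_equal(r1$precision, r2$precision, tolerance = 1e-12)
  expect_identical(r1$tp, r2$tp)

  none <- lapply(sc, function(s) make_dets(numeric(), integer(), numeric()))
  r0 <- evaluate_detections(none, truths, classes = 3)
  expect_identical(r0$precision, 0)
  expect_identical(r0$recall, 0)
  expect_equal(r0$map50, 0, tolerance = 1e-12)
})

test_that("mAP50-95 uses exactly ten thresholds and is bounded by mAP50", {
  sc <- tiny_scenes(4, seed = 17)
  truths <- lapply(sc, function(s) s$boxes)
  preds <- lapply(sc, function(s)
    make_dets(as.matrix(s$boxes[, c("x1", "y1", "x2", "y2")]) +
                rnorm(nrow(s$boxes) * 4, 0, 1.5),
              s$boxes$class_id, runif(nrow(s$boxes), 0.5, 1)))
  rep <- evaluate_detections(preds, truths, classes = 3)
  expect_identical(names(rep$ap_by_iou),
                   sprintf("iou_%.2f", seq(0.5, 0.95, 0.05)))
  expect_gte(rep$map50 + 1e-12, rep$map50_95)
})

test_that("classes without ground truth are excluded from the mean with a warning", {
  truths <- list(data.frame(class_id = 0L, x1 = 10, y1 = 10, x2 = 30, y2 = 30))
  preds <- list(make_dets(matrix(c(10, 10, 30, 30), 1, 4), 0L, 0.9, C = 3))
  expect_warning(ap <- average_precision(preds, truths, 0.5, classes = 3),
                 "without ground truth")
  expect_true(is.na(ap[2]) && is.na(ap[3]))
  expect_equal(unname(ap[1]), 1, tolerance = 1e-12)
})
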