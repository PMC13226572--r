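# VOC-style detection scoring: per-class all-point-interpolated average
# precision with greedy one-to-one matching (confidence-descending, each
# ground truth consumable once), precision/recall at a fixed confidence,
# mAP50 and mAP50-95 (IoU 0.50:0.05:0.95).

# flatten detections into one table: image, class, score, box
detections_table <- function(preds) {
  rows <- list()
  for (im in seq_along(preds)) {
    d <- preds[[im]]
    if (nrow(d$boxes) == 0) next
    cls <- max.col(d$class_probs) - 1L
    score <- d$confidence * d$class_probs[cbind(seq_len(nrow(d$boxes)), cls + 1L)]
    rows[[length(rows) + 1]] <- data.frame(
      image = im, class_id = cls, score = score,
      x1 = d$boxes[, 1], y1 = d$boxes[, 2], x2 = d$boxes[, 3], y2 = d$boxes[, 4])
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(image = integer(), class_id = integer(), score = numeric(),
               x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric())
}

# Greedy matching for one class across a whole vector of IoU thresholds.
# Per-image IoU matrices are computed once and reused for every threshold;
# matching runs in global confidence order, each ground truth consumable once.
# Returns the TP flag matrix (predictions x thresholds) in confidence order.
match_class <- function(det, truths, cls, iou_thrs) {
  gt_by_img <- lapply(truths, function(b)
    as.matrix(b[b$class_id == cls, c("x1", "y1", "x2", "y2"), drop = FALSE]))
  n_gt <- sum(vapply(gt_by_img, nrow, integer(1)))
  dd <- det[det$class_id == cls, , drop = FALSE]
  dd <- dd[order(dd$score, decreasing = TRUE), , drop = FALSE]
  np <- nrow(dd)
  tp <- matrix(FALSE, np, length(iou_thrs))
  if (np > 0 && n_gt > 0) {
    iou_rows <- vector("list", np)
    for (im in unique(dd$image)) {
      rows <- which(dd$image == im)
      if (nrow(gt_by_img[[im]]) == 0) next
      iou_img <- box_iou(as.matrix(dd[rows, c("x1", "y1", "x2", "y2")]),
                         gt_by_img[[im]])
      for (k in seq_along(rows)) iou_rows[[rows[k]]] <- iou_img[k, ]
    }
    for (t in seq_along(iou_thrs)) {
      used <- lapply(gt_by_img, function(g) rep(FALSE, nrow(g)))
      for (r in seq_len(np)) {
        iou <- iou_rows[[r]]
        if (is.null(iou)) next
        im <- dd$image[r]
        avail <- which(iou >= iou_thrs[t] & !used[[im]])
        if (length(avail)) {
          j <- avail[which.max(iou[avail])]
          used[[im]][j] <- TRUE
          tp[r, t] <- TRUE
        }
      }
    }
  }
  list(tp = tp, scores = dd$score, n_gt = n_gt)
}

ap_from_matches <- function(tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # all-point interpolation: precision envelope from the right, integrate over
  # recall increments
  prec_env <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * prec_env)
}

#' Per-class average precision at one IoU threshold
#'
#' All-point interpolated AP with greedy one-to-one matching in global
#' confidence order. Classes with no ground truth get `NA` and are excluded
#' from means (with a warning).
#'
#' @param preds list of `pw_detections`, one per image.
#' @param truths list of ground-truth data frames (columns `class_id`, `x1`,
#'   `y1`, `x2`, `y2`), same order.
#' @param iou_thr matching IoU threshold.
#' @param classes number of classes (defaults to those present).
#' @return named numeric vector of AP values, one per class.
#' @export
average_precision <- function(preds, truths, iou_thr = 0.5, classes = NULL) {
  det <- detections_table(preds)
  if (is.null(classes))
    classes <- max(c(det$class_id, unlist(lapply(truths, function(b) b$class_id)),
                     -1L)) + 1L
  ap <- setNames(numeric(classes), paste0("class_", seq_len(classes) - 1L))
  for (cls in seq_len(classes) - 1L) {
    m <- match_class(det, truths, cls, iou_thr)
    ap[cls + 1L] <- ap_from_matches(m$tp[, 1], m$n_gt)
  }
  if (anyNA(ap))
    warning("classes without ground truth excluded from mean AP: ",
            paste(names(ap)[is.na(ap)], collapse = ", "))
  ap
}

#' Score a set of detections against ground truth
#'
#' @param preds list of `pw_detections` per image (decoded at a LOW confidence
#'   floor so the AP curve is complete).
#' @param truths list of ground-truth box data frames.
#' @param conf confidence threshold at which the precision/recall/TP/FP/FN
#'   point counts are reported.
#' @param classes number of classes.
#' @return a `pw_eval_report`: precision, recall, per-class AP50, `map50`,
#'   `map50_95`, TP/FP/FN counts and a predicted-vs-true class count matrix.
#' @export
evaluate_detections <- function(preds, truths, conf = 0.25, classes = NULL) {
  det <- detections_table(preds)
  if (is.null(classes))
    classes <- max(c(det$class_id, unlist(lapply(truths, function(b) b$class_id)),
                     -1L)) + 1L
  thresholds <- seq(0.5, 0.95, by = 0.05)
  ap_mat <- matrix(NA_real_, classes, length(thresholds))
  for (cls in seq_len(classes) - 1L) {
    m <- match_class(det, truths, cls, thresholds)
    if (m$n_gt > 0)
      ap_mat[cls + 1L, ] <- vapply(seq_along(thresholds), function(t)
        ap_from_matches(m$tp[, t], m$n_gt), numeric(1))
  }
  ap_by_thr <- colMeans(ap_mat, na.rm = TRUE)
  ap_by_thr[is.nan(ap_by_thr)] <- 0
  ap50 <- setNames(ap_mat[, 1], paste0("class_", seq_len(classes) - 1L))
  if (anyNA(ap50))
    warning("classes without ground truth excluded from mean AP: ",
            paste(names(ap50)[is.na(ap50)], collapse = ", "))

  # point precision/recall and class-confusion counts at `conf`, IoU 0.5
  tp <- 0L; fp <- 0L
  n_gt <- sum(vapply(truths, nrow, integer(1)))
  cmat <- matrix(0L, classes, classes,
                 dimnames = list(true = paste0("class_", seq_len(classes) - 1L),
                                 pred = paste0("class_", seq_len(classes) - 1L)))
  dc <- det[det$score >= conf, , drop = FALSE]
  dc <- dc[order(dc$score, decreasing = TRUE), , drop = FALSE]
  used <- lapply(truths, function(b) rep(FALSE, nrow(b)))
  for (r in seq_len(nrow(dc))) {
    g <- truths[[dc$image[r]]]
    matched <- FALSE
    if (nrow(g) > 0) {
      iou <- box_iou(as.matrix(dc[r, c("x1", "y1", "x2", "y2")]),
                     as.matrix(g[, c("x1", "y1", "x2", "y2")]))[1, ]
      avail <- which(iou >= 0.5 & !used[[dc$image[r]]] & g$class_id == dc$class_id[r])
      if (length(avail)) {
        j <- avail[which.max(iou[avail])]
        used[[dc$image[r]]][j] <- TRUE
        tp <- tp + 1L
        matched <- TRUE
        cmat[g$class_id[j] + 1L, dc$class_id[r] + 1L] <-
          cmat[g$class_id[j] + 1L, dc$class_id[r] + 1L] + 1L
      } else {
        # class-agnostic localization match feeds the confusion counts
        loc <- which(iou >= 0.5 & !used[[dc$image[r]]])
        if (length(loc)) {
          j <- loc[which.max(iou[loc])]
          cmat[g$class_id[j] + 1L, dc$class_id[r] + 1L] <-
            cmat[g$class_id[j] + 1L, dc$class_id[r] + 1L] + 1L
        }
      }
    }
    if (!matched) fp <- fp + 1L
  }
  fn <- n_gt - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (n_gt > 0) tp / n_gt else 0
  structure(list(precision = precision, recall = recall,
                 ap50 = ap50,
                 map50 = suppressWarnings(mean(ap50, na.rm = TRUE)),
                 map50_95 = mean(ap_by_thr),
                 ap_by_iou = setNames(ap_by_thr, sprintf("iou_%.2f", thresholds)),
                 tp = tp, fp = fp, fn = fn, n_gt = n_gt,
                 class_matrix = cmat, conf = conf),
            class = "pw_eval_report")
}

#' Evaluate a detector on labeled scenes
#'
#' Decodes at a low confidence floor (`ap_conf`) so average precision sees the
#' full ranking, and reports the precision/recall point at `conf`.
#'
#' @param det a `pw_detector`.
#' @param scenes nonempty list of labeled scenes.
#' @param conf reporting confidence (default 0.25).
#' @param nms_iou NMS threshold (default 0.5).
#' @param ap_conf decoding confidence floor for the AP curve.
#' @return a `pw_eval_report`.
#' @export
evaluate <- function(det, scenes, conf = 0.25, nms_iou = 0.5, ap_conf = 0.05) {
  if (length(scenes) == 0) stop("empty scene set")
  preds <- detector_predict(det, scenes, conf_threshold = ap_conf,
                            nms_iou = nms_iou)
  truths <- lapply(scenes, function(s) s$boxes)
  evaluate_detections(preds, truths, conf = conf, classes = det$classes)
}

#' @export
print.pw_eval_report <- function(x, ...) {
  cat(sprintf("<pw_eval_report> P %.3f R %.3f (conf %.2f) | mAP50 %.3f | mAP50-95 %.3f\n",
              x$precision, x$recall, x$conf, x$map50, x$map50_95))
  cat(sprintf("  TP %d FP %d FN %d of %d ground truths\n", x$tp, x$fp, x$fn, x$n_gt))
  invisible(x)
}
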