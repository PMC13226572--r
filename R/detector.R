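# A compact anchor-free detector. Four backbone stages (stride-2 conv followed
# by a residual 3x3 conv block, GELU activations), a 1x1 neck and a dense
# per-cell head on the stage-4 grid. The stage outputs are the exchange points
# used by the dual-branch training framework; all gradients are hand-derived.

#' Build a compact four-stage detector
#'
#' The backbone has four stages; stage `s` halves the spatial resolution and
#' outputs `channels_per_stage[s]` feature channels. The head predicts, for
#' every cell of the stage-4 grid, an objectness logit, four box activations
#' (sigmoid-squashed center offsets within the cell and image-relative
#' width/height) and one logit per class. Initialization is deterministic
#' under `seed`.
#'
#' @param channels_per_stage integer vector of length 4.
#' @param classes number of object classes (>= 1).
#' @param seed integer seed for weight initialization.
#' @return an object of class `pw_detector`.
#' @export
build_detector <- function(channels_per_stage = c(8L, 16L, 32L, 64L),
                           classes = 3L, seed = 1L) {
  if (length(channels_per_stage) != 4L)
    stop("configuration error: `channels_per_stage` must list exactly 4 stages")
  if (classes < 1L) stop("configuration error: `classes` must be >= 1")
  ch <- as.integer(channels_per_stage)
  set.seed(as.integer(seed))
  cin <- c(3L, ch[1:3])
  params <- list()
  for (s in 1:4) {
    params[[paste0("s", s)]] <- list(
      down = conv_layer(3, 3, cin[s], ch[s]),
      res  = conv_layer(3, 3, ch[s], ch[s])
    )
  }
  params$neck <- conv_layer(1, 1, ch[4], ch[4])
  params$head <- conv_layer(1, 1, ch[4], 5L + classes)
  # standard head priors: rare-object objectness (~0.1) and a small box-size
  # prior (~1/6 of the image side) so IoU regression starts near the target
  # scale rather than at half-image boxes
  params$head$b[1] <- stats::qlogis(0.1)
  params$head$b[4:5] <- stats::qlogis(1 / 6)
  structure(list(channels = ch, classes = as.integer(classes),
                 total_stride = 16L, params = params, seed = as.integer(seed)),
            class = "pw_detector")
}

#' @export
print.pw_detector <- function(x, ...) {
  cat(sprintf("<pw_detector> stages %s, %d classes, %d parameters\n",
              paste(x$channels, collapse = "-"), x$classes, n_params(x$params)))
  invisible(x)
}

#' @export
get_params <- function(det) det$params

#' @export
set_params <- function(det, params) { det$params <- params; det }

# ---- stage / neck / head primitives -----------------------------------------

stage_fwd <- function(p, x) {
  c1 <- conv_fwd(x, p$down, stride = 2L, pad = 1L)
  g1 <- gelu_fwd2(c1)
  c2 <- conv_fwd(g1$y, p$res, stride = 1L, pad = 1L)
  g2 <- gelu_fwd2(c2)
  list(out = g1$y + g2$y,
       cache = list(x = x, d1 = g1$d, h = g1$y, d2 = g2$d))
}

stage_bwd <- function(p, cache, dout, need_dx = TRUE) {
  dc2 <- dout * cache$d2
  br  <- conv_bwd(cache$h, p$res, dc2, stride = 1L, pad = 1L)
  dc1 <- (dout + br$dx) * cache$d1
  bd  <- conv_bwd(cache$x, p$down, dc1, stride = 2L, pad = 1L,
                  need_dx = need_dx)
  list(dx = if (need_dx) bd$dx else NULL,
       grads = list(down = list(w = bd$dw, b = bd$db),
                    res  = list(w = br$dw, b = br$db)))
}

neck_head_fwd <- function(params, f4) {
  n1 <- conv_fwd(f4, params$neck)
  g <- gelu_fwd2(n1)
  raw <- conv_fwd(g$y, params$head)
  list(raw = raw, cache = list(f4 = f4, dn = g$d, nh = g$y))
}

neck_head_bwd <- function(params, cache, draw) {
  bh <- conv_bwd(cache$nh, params$head, draw)
  dn1 <- bh$dx * cache$dn
  bn <- conv_bwd(cache$f4, params$neck, dn1)
  list(dx = bn$dx,
       grads = list(neck = list(w = bn$dw, b = bn$db),
                    head = list(w = bh$dw, b = bh$db)))
}

#' Forward pass of the detector
#'
#' @param det a `pw_detector`.
#' @param x input array with dim (H, W, 3, B), values in [0, 1]; H and W must
#'   be divisible by 16.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return list with `stages` (the four stage outputs, the exchange points),
#'   `raw` (head output, dim (G, G, 5 + classes, B)) and, if requested,
#'   `cache`.
#' @export
detector_forward <- function(det, x, keep_cache = FALSE) {
  if (length(dim(x)) != 4L) stop("input must have dim (H, W, 3, B)")
  p <- det$params
  stages <- vector("list", 4)
  caches <- if (keep_cache) vector("list", 5) else NULL
  cur <- x
  for (s in 1:4) {
    st <- stage_fwd(p[[paste0("s", s)]], cur)
    stages[[s]] <- cur <- st$out
    if (keep_cache) caches[[s]] <- st$cache
  }
  nh <- neck_head_fwd(p, cur)
  if (keep_cache) caches[[5]] <- nh$cache
  list(stages = stages, raw = nh$raw,
       cache = if (keep_cache) caches else NULL)
}

# Backward from d(raw); returns parameter gradients shaped like det$params.
detector_backward <- function(det, cache, draw) {
  p <- det$params
  grads <- list()
  bnh <- neck_head_bwd(p, cache[[5]], draw)
  grads$neck <- bnh$grads$neck
  grads$head <- bnh$grads$head
  dcur <- bnh$dx
  for (s in 4:1) {
    bs <- stage_bwd(p[[paste0("s", s)]], cache[[s]], dcur, need_dx = s > 1)
    grads[[paste0("s", s)]] <- bs$grads
    dcur <- bs$dx
  }
  grads[c(paste0("s", 1:4), "neck", "head")]
}

# ---- boxes, decoding, NMS ----------------------------------------------------

#' Pairwise intersection-over-union of two corner-format box sets
#' @param a,b matrices with columns x1, y1, x2, y2.
#' @return `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4); b <- matrix(b, ncol = 4)
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  if (n == 0 || m == 0) return(out)
  area_a <- pmax(0, a[, 3] - a[, 1]) * pmax(0, a[, 4] - a[, 2])
  area_b <- pmax(0, b[, 3] - b[, 1]) * pmax(0, b[, 4] - b[, 2])
  for (j in seq_len(m)) {
    iw <- pmax(0, pmin(a[, 3], b[j, 3]) - pmax(a[, 1], b[j, 1]))
    ih <- pmax(0, pmin(a[, 4], b[j, 4]) - pmax(a[, 2], b[j, 2]))
    ai <- iw * ih
    out[, j] <- ai / pmax(area_a + area_b[j] - ai, 1e-12)
  }
  out
}

#' Greedy non-maximum suppression
#' @param boxes N x 4 corner matrix; `scores` length-N confidences.
#' @param iou_thr suppression threshold.
#' @return indices of retained boxes, highest score first.
#' @export
nms <- function(boxes, scores, iou_thr = 0.5) {
  n <- length(scores)
  if (n == 0) return(integer())
  ord <- order(scores, decreasing = TRUE)
  keep <- integer()
  alive <- rep(TRUE, n)
  iou <- box_iou(boxes, boxes)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[iou[i, ] >= iou_thr] <- FALSE
  }
  keep
}

empty_detections <- function(classes) {
  structure(list(boxes = matrix(numeric(), 0, 4,
                                dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
                 class_probs = matrix(numeric(), 0, classes),
                 confidence = numeric()),
            class = "pw_detections")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Decode raw head output into detections
#'
#' Cells with objectness above `conf_threshold` are converted to corner-format
#' boxes and pruned by greedy class-agnostic NMS.
#'
#' @param raw head output for one image or a batch (dim (G, G, 5+C) or
#'   (G, G, 5+C, B)).
#' @param conf_threshold,nms_iou thresholds in [0, 1].
#' @param img_size image side length in pixels.
#' @return a `pw_detections` (or a list of them for a batch): `boxes` (N x 4),
#'   `class_probs` (N x C rows summing to 1), `confidence` (N).
#' @export
decode <- function(raw, conf_threshold = 0.25, nms_iou = 0.5, img_size) {
  if (conf_threshold < 0 || conf_threshold > 1 || nms_iou < 0 || nms_iou > 1)
    stop("thresholds must lie in [0, 1]")
  if (length(dim(raw)) == 4L) {
    return(lapply(seq_len(dim(raw)[4]),
                  function(b) decode(raw[, , , b], conf_threshold, nms_iou, img_size)))
  }
  G <- dim(raw)[1]
  C <- dim(raw)[3] - 5L
  stride <- img_size / G
  conf <- sigmoid(raw[, , 1])
  sel <- which(conf >= conf_threshold, arr.ind = TRUE)
  if (nrow(sel) == 0) return(empty_detections(C))
  i <- sel[, 1]; j <- sel[, 2]
  pick <- function(k) raw[cbind(i, j, rep(k, length(i)))]
  cx <- (j - 1 + sigmoid(pick(2))) * stride
  cy <- (i - 1 + sigmoid(pick(3))) * stride
  w <- img_size * sigmoid(pick(4))
  h <- img_size * sigmoid(pick(5))
  boxes <- cbind(x1 = pmax(0, cx - w / 2), y1 = pmax(0, cy - h / 2),
                 x2 = pmin(img_size, cx + w / 2), y2 = pmin(img_size, cy + h / 2))
  logits <- vapply(seq_len(C), function(k) pick(5 + k), numeric(length(i)))
  logits <- matrix(logits, ncol = C)
  probs <- softmax_rows(logits)
  scores <- conf[cbind(i, j)]
  keep <- nms(boxes, scores, nms_iou)
  structure(list(boxes = boxes[keep, , drop = FALSE],
                 class_probs = probs[keep, , drop = FALSE],
                 confidence = scores[keep]),
            class = "pw_detections")
}

#' Run the detector on scenes and decode detections
#' @param det a `pw_detector`; `scenes` a list of scenes (see
#'   [generate_scenes()]) or an input array.
#' @inheritParams decode
#' @return list of `pw_detections`, one per scene.
#' @export
detector_predict <- function(det, scenes, conf_threshold = 0.25, nms_iou = 0.5) {
  x <- if (is.array(scenes)) scenes else scenes_to_input(scenes)
  img <- dim(x)[1]
  fw <- detector_forward(det, x)
  decode(fw$raw, conf_threshold, nms_iou, img_size = img)
}

# ---- targets and loss --------------------------------------------------------

# Assign each ground-truth box to the head cell containing its center; the
# first box claiming a cell wins. Returns a list of matched-cell records.
assign_targets <- function(boxes_df, G, stride, classes) {
  taken <- matrix(FALSE, G, G)
  recs <- list()
  if (!is.null(boxes_df) && nrow(boxes_df) > 0) {
    for (r in seq_len(nrow(boxes_df))) {
      cx <- (boxes_df$x1[r] + boxes_df$x2[r]) / 2
      cy <- (boxes_df$y1[r] + boxes_df$y2[r]) / 2
      j <- min(G, max(1, floor(cx / stride) + 1))
      i <- min(G, max(1, floor(cy / stride) + 1))
      if (taken[i, j]) next
      taken[i, j] <- TRUE
      recs[[length(recs) + 1]] <- list(
        i = i, j = j, cls = boxes_df$class_id[r] + 1L,
        box = c(boxes_df$x1[r], boxes_df$y1[r], boxes_df$x2[r], boxes_df$y2[r]))
    }
  }
  recs
}

# IoU of one pred box against one gt box together with d(IoU)/d(pred corners).
iou_with_grad <- function(p, g) {
  ix1 <- max(p[1], g[1]); iy1 <- max(p[2], g[2])
  ix2 <- min(p[3], g[3]); iy2 <- min(p[4], g[4])
  iw <- max(0, ix2 - ix1); ih <- max(0, iy2 - iy1)
  ai <- iw * ih
  ap <- max(0, p[3] - p[1]) * max(0, p[4] - p[2])
  ag <- max(0, g[3] - g[1]) * max(0, g[4] - g[2])
  au <- ap + ag - ai
  iou <- if (au > 0) ai / au else 0
  dai <- numeric(4); dap <- numeric(4)
  if (iw > 0 && ih > 0) {
    if (p[1] > g[1]) dai[1] <- -ih
    if (p[3] < g[3]) dai[3] <- ih
    if (p[2] > g[2]) dai[2] <- -iw
    if (p[4] < g[4]) dai[4] <- iw
  }
  dap[1] <- -(p[4] - p[2]); dap[3] <- p[4] - p[2]
  dap[2] <- -(p[3] - p[1]); dap[4] <- p[3] - p[1]
  diou <- if (au > 0) (dai * au - ai * (dap - dai)) / au^2 else numeric(4)
  list(iou = iou, grad = diou)
}

#' Detection loss (classification + box + objectness)
#'
#' `L = lambda_cls * L_cls + lambda_bb * L_bb + lambda_conf * L_conf` with
#' cross-entropy on matched cells, `1 - IoU` box regression on matched cells
#' and binary cross-entropy objectness over every cell. Targets may be ground
#' truth or pseudo-labels. With an empty target set the loss reduces to the
#' background objectness term.
#'
#' @param raw head output, dim (G, G, 5+C, B).
#' @param targets list (length B) of data frames with columns `class_id`
#'   (0-based), `x1`, `y1`, `x2`, `y2` in pixels.
#' @param img_size image side length in pixels.
#' @param lambda_cls,lambda_bb,lambda_conf loss weights.
#' @param grad if TRUE also return `draw`, the gradient w.r.t. `raw`.
#' @return list with `loss`, `cls`, `bb`, `conf` and optionally `draw`.
#' @export
detection_loss <- function(raw, targets, img_size,
                           lambda_cls = 1.0, lambda_bb = 5.0, lambda_conf = 1.0,
                           grad = FALSE) {
  dm <- dim(raw)
  G <- dm[1]; C <- dm[3] - 5L; B <- dm[4]
  stride <- img_size / G
  obj <- array(0, c(G, G, B))
  draw <- if (grad) array(0, dm) else NULL

  matched <- list()
  for (b in seq_len(B)) {
    tb <- if (b <= length(targets)) targets[[b]] else NULL
    recs <- assign_targets(tb, G, stride, C)
    for (rec in recs) {
      obj[rec$i, rec$j, b] <- 1
      matched[[length(matched) + 1]] <- c(rec, list(b = b))
    }
  }
  M <- length(matched)

  # objectness BCE over all cells (numerically stable form)
  s <- raw[, , 1, , drop = FALSE]
  dim(s) <- c(G, G, B)
  nc <- G * G * B
  lconf <- sum(ifelse(obj > 0.5, log1p(exp(-s)), s + log1p(exp(-s)))) / nc
  if (grad) {
    p <- 1 / (1 + exp(-s))
    dconf <- (p - obj) / nc
    draw[, , 1, ] <- dconf
  }

  lcls <- 0; lbb <- 0
  if (M > 0) {
    for (m in matched) {
      i <- m$i; j <- m$j; b <- m$b
      # classification
      z <- raw[i, j, 6:(5 + C), b]
      z <- z - max(z)
      pz <- exp(z) / sum(exp(z))
      lcls <- lcls + (-log(max(pz[m$cls], 1e-12)))
      # box
      t <- raw[i, j, 2:5, b]
      st <- 1 / (1 + exp(-t))
      cx <- (j - 1 + st[1]) * stride
      cy <- (i - 1 + st[2]) * stride
      w <- img_size * st[3]
      h <- img_size * st[4]
      pb <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
      ig <- iou_with_grad(pb, m$box)
      lbb <- lbb + (1 - ig$iou)
      if (grad) {
        dz <- pz
        dz[m$cls] <- dz[m$cls] - 1
        draw[i, j, 6:(5 + C), b] <- draw[i, j, 6:(5 + C), b] + lambda_cls * dz / M
        dpb <- -ig$grad / M               # d(1 - IoU)/d corners, mean reduction
        dcx <- dpb[1] + dpb[3]
        dcy <- dpb[2] + dpb[4]
        dw <- (dpb[3] - dpb[1]) / 2
        dh <- (dpb[4] - dpb[2]) / 2
        sg <- st * (1 - st)
        dt <- c(dcx * stride * sg[1], dcy * stride * sg[2],
                dw * img_size * sg[3], dh * img_size * sg[4])
        draw[i, j, 2:5, b] <- draw[i, j, 2:5, b] + lambda_bb * dt
      }
    }
    lcls <- lcls / M
    lbb <- lbb / M
  }
  if (grad) draw[, , 1, ] <- lambda_conf * draw[, , 1, , drop = FALSE]

  loss <- lambda_cls * lcls + lambda_bb * lbb + lambda_conf * lconf
  out <- list(loss = loss, cls = lcls, bb = lbb, conf = lconf)
  if (grad) out$draw <- draw
  out
}

# ---- plain training ----------------------------------------------------------

cosine_lr <- function(epoch, epochs, lr0, lrf, warmup = 0L) {
  frac <- if (epochs > 1) (epoch - 1) / (epochs - 1) else 0
  lr <- lr0 * (lrf + (1 - lrf) * 0.5 * (1 + cos(pi * frac)))
  if (warmup > 0 && epoch <= warmup) lr <- lr * epoch / warmup
  lr
}

clip_grads <- function(grads, max_norm = 10) {
  nrm <- sqrt(param_sq_norms(grads))
  if (is.finite(nrm) && nrm > max_norm) grads <- axpy_params(zero_like(grads), grads, max_norm / nrm)
  grads
}

#' Train a plain single-branch detector
#'
#' SGD with momentum under a cosine-decayed learning rate (`lr0` down to
#' `lr0 * lrf`) with a short linear warmup - the same optimizer and schedule
#' as [train_maf()], so the two are directly comparable.
#'
#' @param det a `pw_detector`.
#' @param scenes list of labeled scenes.
#' @param epochs,batch_size,lr0,lrf,momentum,warmup_epochs training schedule.
#' @param seed integer seed controlling batch order.
#' @return list with the trained `detector` and a `log` tibble (class
#'   `pw_training_log`).
#' @export
train_detector <- function(det, scenes, epochs = 50L, batch_size = 16L,
                           lr0 = 0.015, lrf = 0.01, momentum = 0.937,
                           warmup_epochs = 3L, seed = 1L) {
  if (length(scenes) == 0) stop("empty dataset")
  x_all <- scenes_to_input(scenes)
  img <- dim(x_all)[1]
  n <- length(scenes)
  log <- vector("list", epochs)
  vel <- zero_like(det$params)
  set.seed(child_seed(seed, "train"))
  for (e in seq_len(epochs)) {
    lr <- cosine_lr(e, epochs, lr0, lrf, warmup_epochs)
    ord <- sample.int(n)
    tot <- 0; nb <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      x <- x_all[, , , idx, drop = FALSE]
      tg <- lapply(scenes[idx], function(s) s$boxes)
      fw <- detector_forward(det, x, keep_cache = TRUE)
      ls <- detection_loss(fw$raw, tg, img_size = img, grad = TRUE)
      if (!is.finite(ls$loss)) stop("non-finite training loss")
      grads <- clip_grads(detector_backward(det, fw$cache, ls$draw))
      vel <- axpy_params(axpy_params(zero_like(grads), vel, momentum), grads, 1)
      det$params <- axpy_params(det$params, vel, -lr)
      tot <- tot + ls$loss; nb <- nb + 1
    }
    log[[e]] <- data.frame(epoch = e, loss = tot / nb, lr = lr)
  }
  log <- do.call(rbind, log)
  class(log) <- c("pw_training_log", class(log))
  list(detector = det, log = log)
}
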