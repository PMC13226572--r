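# Augmented-view certainty quantification. The teacher predicts on the
# original image (proxy labels) and on X augmented views (intermediate
# labels); per-detection certainty scores are exp(-dispersion) over the views,
# for the four box corners and the C class probabilities. 1 means perfect
# cross-view agreement.
#
# Geometric transforms act on box coordinates as a similarity map of the box
# CENTER (flip, rotate about the image center, scale, translate) with
# width/height multiplied by the scale factor only, so that every transform
# has an exact inverse for boxes; pixels are warped with the full affine map.

neutral_transform <- function() {
  list(flip = FALSE, angle = 0, scale = 1, tx = 0, ty = 0,
       brightness = 1, contrast = 1, blur_sigma = 0)
}

#' Build a set of augmented views of an image
#'
#' Each view combines a seeded draw of horizontal flip, rotation (<= 10
#' degrees), scale (0.9-1.1), translation (<= 5%), brightness (+-20%),
#' contrast (0.8-1.2) and Gaussian blur (sigma <= 1). Transform parameters are
#' stored so box coordinates can be mapped exactly both ways.
#'
#' @param image (H, W, 3) 8-bit array (or a scene).
#' @param X number of views (>= 2; cross-view variance is undefined below 2).
#' @param seed integer seed.
#' @param identity_only if TRUE every view is an untouched copy of the input.
#' @return a `pw_viewset`: list with `views` (images), `transforms`, `X`.
#' @export
make_views <- function(image, X = 8L, seed = 1L, identity_only = FALSE) {
  if (inherits(image, "pw_scene")) image <- image$image
  if (X < 2) stop("X must be >= 2 (cross-view variance undefined)")
  set.seed(child_seed(seed, "views"))
  transforms <- lapply(seq_len(X), function(k) {
    if (identity_only) return(neutral_transform())
    size <- dim(image)[1]
    list(flip = stats::runif(1) < 0.5,
         angle = stats::runif(1, -10, 10) * pi / 180,
         scale = stats::runif(1, 0.9, 1.1),
         tx = stats::runif(1, -0.05, 0.05) * size,
         ty = stats::runif(1, -0.05, 0.05) * size,
         brightness = stats::runif(1, 0.8, 1.2),
         contrast = stats::runif(1, 0.8, 1.2),
         blur_sigma = stats::runif(1, 0, 1))
  })
  views <- lapply(transforms, function(tf) apply_view(image, tf))
  structure(list(views = views, transforms = transforms, X = as.integer(X),
                 seed = as.integer(seed)), class = "pw_viewset")
}

# forward point map of the geometric part: flip, then rotate+scale about the
# image center, then translate
transform_points <- function(pts, tf, size) {
  x <- pts[, 1]; y <- pts[, 2]
  if (tf$flip) x <- size - x
  c0 <- size / 2
  xr <- c0 + tf$scale * (cos(tf$angle) * (x - c0) - sin(tf$angle) * (y - c0))
  yr <- c0 + tf$scale * (sin(tf$angle) * (x - c0) + cos(tf$angle) * (y - c0))
  cbind(xr + tf$tx, yr + tf$ty)
}

inverse_points <- function(pts, tf, size) {
  x <- pts[, 1] - tf$tx; y <- pts[, 2] - tf$ty
  c0 <- size / 2
  xr <- c0 + (cos(tf$angle) * (x - c0) + sin(tf$angle) * (y - c0)) / tf$scale
  yr <- c0 + (-sin(tf$angle) * (x - c0) + cos(tf$angle) * (y - c0)) / tf$scale
  if (tf$flip) xr <- size - xr
  cbind(xr, yr)
}

#' Map corner-format boxes into view coordinates
#'
#' The box center follows the view's similarity transform; width and height
#' are multiplied by the scale factor. [map_boxes_inverse()] is the exact
#' inverse.
#'
#' @param boxes N x 4 matrix (x1, y1, x2, y2); `tf` a transform record from
#'   [make_views()]; `size` image side length.
#' @export
map_boxes_forward <- function(boxes, tf, size) {
  boxes <- matrix(boxes, ncol = 4)
  if (nrow(boxes) == 0) return(boxes)
  ctr <- cbind((boxes[, 1] + boxes[, 3]) / 2, (boxes[, 2] + boxes[, 4]) / 2)
  wh <- cbind(boxes[, 3] - boxes[, 1], boxes[, 4] - boxes[, 2]) * tf$scale
  ctr <- transform_points(ctr, tf, size)
  cbind(ctr[, 1] - wh[, 1] / 2, ctr[, 2] - wh[, 2] / 2,
        ctr[, 1] + wh[, 1] / 2, ctr[, 2] + wh[, 2] / 2)
}

#' @rdname map_boxes_forward
#' @export
map_boxes_inverse <- function(boxes, tf, size) {
  boxes <- matrix(boxes, ncol = 4)
  if (nrow(boxes) == 0) return(boxes)
  ctr <- cbind((boxes[, 1] + boxes[, 3]) / 2, (boxes[, 2] + boxes[, 4]) / 2)
  wh <- cbind(boxes[, 3] - boxes[, 1], boxes[, 4] - boxes[, 2]) / tf$scale
  ctr <- inverse_points(ctr, tf, size)
  cbind(ctr[, 1] - wh[, 1] / 2, ctr[, 2] - wh[, 2] / 2,
        ctr[, 1] + wh[, 1] / 2, ctr[, 2] + wh[, 2] / 2)
}

# inverse-mapped bilinear warp with edge clamping
warp_image <- function(image, tf, size) {
  grid <- expand.grid(x = seq_len(size) - 0.5, y = seq_len(size) - 0.5)
  src <- inverse_points(as.matrix(grid), tf, size)
  sx <- pmin(pmax(src[, 1] - 0.5, 0), size - 1)
  sy <- pmin(pmax(src[, 2] - 0.5, 0), size - 1)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  x1 <- pmin(x0 + 1, size - 1); y1 <- pmin(y0 + 1, size - 1)
  out <- array(0, dim(image))
  for (ch in 1:3) {
    plane <- image[, , ch]
    v <- (1 - fx) * (1 - fy) * plane[cbind(y0 + 1, x0 + 1)] +
         fx * (1 - fy) * plane[cbind(y0 + 1, x1 + 1)] +
         (1 - fx) * fy * plane[cbind(y1 + 1, x0 + 1)] +
         fx * fy * plane[cbind(y1 + 1, x1 + 1)]
    out[, , ch] <- matrix(v, size, size, byrow = TRUE)
  }
  out
}

gauss_blur <- function(image, sigma) {
  if (sigma <= 0.05) return(image)
  r <- max(1L, ceiling(2 * sigma))
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  ker <- outer(k1, k1)
  ker <- ker / sum(ker)
  H <- dim(image)[1]; W <- dim(image)[2]
  xin <- array(image, c(H, W, 1, 3))
  w <- array(ker, c(2 * r + 1, 2 * r + 1, 1, 1))
  array(conv2d_fwd(xin, w, 0, 1L, r), c(H, W, 3))
}

#' Apply one view transform to an image
#' @param image (H, W, 3) 8-bit array; `tf` a transform record.
#' @export
apply_view <- function(image, tf) {
  size <- dim(image)[1]
  geo_neutral <- !tf$flip && tf$angle == 0 && tf$scale == 1 &&
    tf$tx == 0 && tf$ty == 0
  out <- if (geo_neutral) image else warp_image(image, tf, size)
  out <- (out - 128) * tf$contrast + 128
  out <- out * tf$brightness
  out <- gauss_blur(out, tf$blur_sigma)
  clamp8(out)
}

#' Match proxy detections against view predictions
#'
#' For each proxy box and each view, the view box with the highest IoU is
#' selected if that IoU exceeds `iou_min` (0.1); otherwise the proxy box's own
#' coordinates and class vector are substituted (zero deviation for that
#' view). View predictions must already be inverse-mapped into original image
#' coordinates.
#'
#' @param proxy a `pw_detections` on the original image.
#' @param view_preds list of `pw_detections`, one per view.
#' @param iou_min matching threshold.
#' @param unmatched `"proxy"` (literal substitution rule) or `"penalty"`
#'   (unmatched views contribute a fixed corner displacement of 10% of
#'   `img_size` and a uniform class vector, so missing detections lower the
#'   certainty instead of raising it).
#' @param img_size image side, required for `unmatched = "penalty"`.
#' @return list with arrays `p_tilde` (N x X x 4) and `c_tilde` (N x X x C).
#' @export
match_views <- function(proxy, view_preds, iou_min = 0.1,
                        unmatched = c("proxy", "penalty"), img_size = NULL) {
  unmatched <- match.arg(unmatched)
  n <- nrow(proxy$boxes)
  X <- length(view_preds)
  C <- ncol(proxy$class_probs)
  p_tilde <- array(0, c(n, X, 4))
  c_tilde <- array(0, c(n, X, C))
  if (n == 0) return(list(p_tilde = p_tilde, c_tilde = c_tilde))
  for (x in seq_len(X)) {
    vp <- view_preds[[x]]
    iou <- box_iou(proxy$boxes, vp$boxes)
    for (i in seq_len(n)) {
      j <- if (ncol(iou) > 0) which.max(iou[i, ]) else integer()
      if (length(j) == 1 && iou[i, j] > iou_min) {
        p_tilde[i, x, ] <- vp$boxes[j, ]
        c_tilde[i, x, ] <- vp$class_probs[j, ]
      } else if (unmatched == "proxy") {
        p_tilde[i, x, ] <- proxy$boxes[i, ]
        c_tilde[i, x, ] <- proxy$class_probs[i, ]
      } else {
        if (is.null(img_size)) stop("img_size required for penalty mode")
        p_tilde[i, x, ] <- proxy$boxes[i, ] + 0.1 * img_size
        c_tilde[i, x, ] <- rep(1 / C, C)
      }
    }
  }
  list(p_tilde = p_tilde, c_tilde = c_tilde)
}

#' Corner-certainty matrix
#'
#' `Mu[i, j] = exp(-(1/(X-1)) * sum_x (p_tilde[i,x,j] - p_bar[i,j])^2)` with
#' corner coordinates normalized by the image size first, so the exponent is
#' scale-free.
#'
#' @param p_tilde N x X x 4 matched view corners (pixels).
#' @param p_bar N x 4 proxy corners (pixels).
#' @param img_size image side length used for normalization.
#' @return N x 4 matrix with entries in (0, 1].
#' @export
corner_certainty <- function(p_tilde, p_bar, img_size) {
  n <- dim(p_tilde)[1]; X <- dim(p_tilde)[2]
  if (X < 2) stop("X must be >= 2")
  p_bar <- matrix(p_bar, ncol = 4)
  mu <- matrix(0, n, 4, dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
  for (j in 1:4) {
    dev <- (p_tilde[, , j, drop = FALSE][, , 1] -
              matrix(p_bar[, j], n, X)) / img_size
    dev <- matrix(dev, n, X)
    mu[, j] <- exp(-rowSums(dev^2) / (X - 1))
  }
  mu
}

#' Class-certainty matrix
#'
#' `Mc[i, n] = exp(-(1/X) * sum_x (-c_bar[i,n] * log c_tilde[i,x,n]))`; view
#' probabilities are clipped to `[eps, 1]` before the log.
#'
#' @param c_tilde N x X x C matched view class probabilities.
#' @param c_bar N x C proxy class probabilities.
#' @param eps clipping floor (1e-7).
#' @return N x C matrix with entries in (0, 1].
#' @export
class_certainty <- function(c_tilde, c_bar, eps = 1e-7) {
  n <- dim(c_tilde)[1]; X <- dim(c_tilde)[2]; C <- dim(c_tilde)[3]
  c_bar <- matrix(c_bar, ncol = C)
  mc <- matrix(0, n, C)
  for (k in seq_len(C)) {
    ct <- matrix(pmin(pmax(c_tilde[, , k, drop = FALSE][, , 1], eps), 1), n, X)
    cross <- -matrix(c_bar[, k], n, X) * log(ct)
    mc[, k] <- exp(-rowSums(cross) / X)
  }
  mc
}

#' Concatenate corner and class certainty into the unified matrix
#' @param Mu N x 4 corner certainty; `Mc` N x C class certainty.
#' @return N x (4 + C) matrix `[Mu | Mc]`.
#' @export
assemble_certainty <- function(Mu, Mc) {
  if (nrow(Mu) != nrow(Mc)) stop("row mismatch between Mu and Mc")
  cbind(Mu, Mc)
}

#' Full certainty pipeline for one image under a teacher detector
#'
#' Runs the teacher on the original image (proxy) and on X augmented views,
#' inverse-maps the view boxes, matches them, and assembles the unified
#' certainty matrix.
#'
#' @param teacher a `pw_detector`.
#' @param scene a scene (or raw image array).
#' @param X number of views; `seed` drives the augmentation draw.
#' @param conf_threshold,nms_iou decoding thresholds.
#' @param iou_min view-matching threshold.
#' @return list with `proxy` detections, `M` (N x (4+C)), `mean_certainty`
#'   (row means of M) and the `viewset`.
#' @export
view_certainty <- function(teacher, scene, X = 8L, seed = 1L,
                           conf_threshold = 0.25, nms_iou = 0.5,
                           iou_min = 0.1) {
  img <- if (inherits(scene, "pw_scene")) scene$image else scene
  size <- dim(img)[1]
  x_in <- array(img / 255, c(dim(img), 1))
  proxy <- decode(detector_forward(teacher, x_in)$raw[, , , 1],
                  conf_threshold, nms_iou, img_size = size)
  vs <- make_views(img, X = X, seed = seed)
  view_preds <- lapply(seq_len(vs$X), function(k) {
    xv <- array(vs$views[[k]] / 255, c(dim(img), 1))
    d <- decode(detector_forward(teacher, xv)$raw[, , , 1],
                conf_threshold, nms_iou, img_size = size)
    d$boxes <- map_boxes_inverse(d$boxes, vs$transforms[[k]], size)
    d
  })
  mt <- match_views(proxy, view_preds, iou_min = iou_min)
  if (nrow(proxy$boxes) == 0) {
    return(list(proxy = proxy, M = matrix(numeric(), 0, 4 + ncol(proxy$class_probs)),
                mean_certainty = numeric(), viewset = vs))
  }
  Mu <- corner_certainty(mt$p_tilde, proxy$boxes, size)
  Mc <- class_certainty(mt$c_tilde, proxy$class_probs)
  M <- assemble_certainty(Mu, Mc)
  list(proxy = proxy, M = M, mean_certainty = rowMeans(M), viewset = vs)
}
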