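# Diagonal Fisher-information importance of detector parameters, and the
# binary partition into domain-sensitive (1) and domain-invariant (0)
# coordinates. The likelihood gradient is instantiated as the gradient of the
# detection loss against certainty-filtered teacher pseudo-labels; squared
# per-parameter gradients are averaged over the streamed images and min-max
# normalized before thresholding.

# teacher pseudo-labels for one scene: certainty-filtered proxy detections
teacher_pseudo_labels <- function(teacher, scene, X = 8L, seed = 1L,
                                  cert_min = 0.5, conf_floor = 0.25,
                                  nms_iou = 0.5) {
  vc <- view_certainty(teacher, scene, X = X, seed = seed,
                       conf_threshold = conf_floor, nms_iou = nms_iou)
  keep <- which(vc$mean_certainty >= cert_min)
  boxes <- vc$proxy$boxes[keep, , drop = FALSE]
  probs <- vc$proxy$class_probs[keep, , drop = FALSE]
  df <- if (length(keep)) data.frame(
    class_id = max.col(probs) - 1L,
    x1 = boxes[, 1], y1 = boxes[, 2], x2 = boxes[, 3], y2 = boxes[, 4])
  else data.frame(class_id = integer(), x1 = numeric(), y1 = numeric(),
                  x2 = numeric(), y2 = numeric())
  list(labels = df, certainty = vc$mean_certainty, n_proxy = nrow(vc$proxy$boxes))
}

# squared per-parameter gradient of the detection loss on one image
squared_grad_flat <- function(det, scene, labels, img_size) {
  x <- array(scene$image / 255, c(dim(scene$image), 1))
  fw <- detector_forward(det, x, keep_cache = TRUE)
  ls <- detection_loss(fw$raw, list(labels), img_size = img_size, grad = TRUE)
  g <- flatten_params(detector_backward(det, fw$cache, ls$draw))
  g * g
}

#' Accumulate diagonal Fisher importance over an image stream
#'
#' For every image the teacher's certainty-filtered pseudo-labels are scored
#' with the detection loss, the per-parameter gradient is squared, and the
#' squares are averaged over the stream into the importance vector `K`;
#' `K_hat` is its normalization onto [0, 1] (quantile rank by default, plain
#' min-max as an option).
#'
#' @param teacher a `pw_detector` (evaluation weights; gradients are computed
#'   but never applied).
#' @param image_stream list of scenes.
#' @param n_images images to use (defaults to the whole stream).
#' @param X,seed,cert_min,conf_floor pseudo-label controls (certainty filter
#'   keeps detections whose mean certainty-matrix row is >= `cert_min`).
#' @param normalization `"rank"` (default) or `"minmax"`.
#' @return a `pw_importance`: list with `K`, `K_hat`, `n_images`.
#' @export
accumulate_fim <- function(teacher, image_stream, n_images = length(image_stream),
                           X = 8L, seed = 1L, cert_min = 0.5,
                           conf_floor = 0.25,
                           normalization = c("rank", "minmax")) {
  normalization <- match.arg(normalization)
  if (n_images < 1) stop("n_images must be >= 1")
  stream <- image_stream[seq_len(min(n_images, length(image_stream)))]
  img_size <- dim(stream[[1]]$image)[1]
  K <- NULL; used <- 0L
  for (k in seq_along(stream)) {
    pl <- teacher_pseudo_labels(teacher, stream[[k]], X = X,
                                seed = child_seed(seed, "fim", stream[[k]]$seed),
                                cert_min = cert_min, conf_floor = conf_floor)
    if (nrow(pl$labels) == 0) next
    g2 <- squared_grad_flat(teacher, stream[[k]], pl$labels, img_size)
    K <- if (is.null(K)) g2 else K + g2
    used <- used + 1L
  }
  if (used == 0L)
    stop("no pseudo-labels survived the certainty filter on any image; ",
         "lower cert_min")
  K <- K / used
  fim_importance(K, used, normalization)
}

# Wrap a squared-gradient average as an importance vector. Squared detection
# gradients span many orders of magnitude, so a plain min-max of the raw
# values collapses nearly everything to ~0 and a fixed threshold selects a
# vacuous handful of coordinates; the default quantile-rank normalization
# spreads the importances evenly over [0, 1] (min 0, max 1), giving the
# threshold tau a stable meaning. For a two-parameter model both
# normalizations agree.
fim_importance <- function(K, n_images, normalization = c("rank", "minmax")) {
  normalization <- match.arg(normalization)
  rng <- range(K)
  K_hat <- if (rng[2] <= rng[1]) rep(0, length(K))
  else if (normalization == "rank") {
    r <- rank(K, ties.method = "average")
    (r - min(r)) / (max(r) - min(r)) # ties at the extremes still map to 0 / 1
  } else (K - rng[1]) / (rng[2] - rng[1])
  structure(list(K = K, K_hat = K_hat, n_images = as.integer(n_images),
                 normalization = normalization),
            class = "pw_importance")
}

#' Partition parameters by thresholding normalized Fisher importance
#'
#' `b_i = 1` exactly when `K_hat_i > tau` (strict); 1 marks domain-sensitive
#' parameters, 0 domain-invariant ones.
#'
#' @param importance a `pw_importance` from [accumulate_fim()] (or a bare
#'   numeric vector of normalized importances).
#' @param tau threshold in [0, 1] (default 0.3).
#' @return a `pw_param_mask`: numeric 0/1 vector with attributes `tau`,
#'   `n_images`, `density`.
#' @export
make_mask <- function(importance, tau = 0.3) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  k_hat <- if (inherits(importance, "pw_importance")) importance$K_hat
           else as.numeric(importance)
  b <- as.numeric(k_hat > tau)
  structure(b, tau = tau,
            n_images = if (inherits(importance, "pw_importance"))
              importance$n_images else NA_integer_,
            density = mean(b), class = "pw_param_mask")
}
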