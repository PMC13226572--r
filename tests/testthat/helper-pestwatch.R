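# Shared fixtures and independent oracles for the test suite. Fixtures are
# generated in code; oracles are written independently of the implementation
# paths they check.

tiny_scenes <- function(n = 8, size = 64, classes = 3, objects = c(1, 3),
                        seed = 42) {
  generate_scenes(n, size, classes, objects, seed = seed)
}

tiny_detector <- function(seed = 1, classes = 3, channels = c(4L, 8L, 16L, 32L)) {
  build_detector(channels, classes, seed = seed)
}

# exact scalar GELU (Gaussian CDF form), independent of the C++ path
gelu_exact <- function(x) x * pnorm(x)

# O(N^2) reference NMS: keep boxes in score order, drop any box whose IoU with
# an already-kept box reaches the threshold
brute_nms <- function(boxes, scores, iou_thr) {
  ord <- order(scores, decreasing = TRUE)
  kept <- integer()
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      a <- boxes[i, ]; b <- boxes[j, ]
      iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
      ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
      inter <- iw * ih
      uni <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
      if (inter / max(uni, 1e-12) >= iou_thr) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

# independent reference AP: greedy confidence-descending one-to-one matching,
# then all-point interpolation done directly from the PR staircase
ref_ap_one_class <- function(scores, is_tp, n_gt) {
  if (n_gt == 0) return(NA_real_)
  if (length(scores) == 0) return(0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(is_tp[ord]); fp <- cumsum(!is_tp[ord])
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  ap <- 0
  prev_r <- 0
  for (k in seq_along(rec)) {
    pmax_right <- max(prec[k:length(prec)])
    ap <- ap + (rec[k] - prev_r) * pmax_right
    prev_r <- rec[k]
  }
  ap
}

# memoized heavy experiments shared between acceptance blocks
.exp_cache <- new.env(parent = emptyenv())
get_maf_experiment <- function(seed) {
  key <- paste0("maf_", seed)
  if (is.null(.exp_cache[[key]]))
    .exp_cache[[key]] <- experiment_maf_gain(seed = seed)
  .exp_cache[[key]]
}
get_saodl_experiment <- function(seed) {
  key <- paste0("saodl_", seed)
  if (is.null(.exp_cache[[key]])) {
    src <- get_maf_experiment(seed)$baseline_detector
    .exp_cache[[key]] <- experiment_saodl(src, seed = seed)
  }
  .exp_cache[[key]]
}
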