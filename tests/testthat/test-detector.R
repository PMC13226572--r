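test_that("stages halve resolution and initialization is seed-deterministic", {
  det <- build_detector(c(8, 16, 32, 64), classes = 3, seed = 11)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  fw <- detector_forward(det, x)
  expect_identical(sapply(fw$stages, function(f) dim(f)[1]), c(32L, 16L, 8L, 4L))
  expect_identical(sapply(fw$stages, function(f) dim(f)[3]), c(8L, 16L, 32L, 64L))
  expect_identical(dim(fw$raw), c(4L, 4L, 8L, 2L))

  det2 <- build_detector(c(8, 16, 32, 64), classes = 3, seed = 11)
  expect_identical(flatten_params(det$params), flatten_params(det2$params))
  expect_error(build_detector(c(8, 16, 32), 3, 1), "4 stages")
})

test_that("flatten/unflatten is a bit-identical round trip", {
  det <- tiny_detector(seed = 4)
  v <- flatten_params(det$params)
  back <- unflatten_params(v, det$params)
  expect_identical(back, det$params)
  # and on an arbitrary random vector
  rv <- rnorm(length(v))
  expect_identical(flatten_params(unflatten_params(rv, det$params)), rv,
                   ignore_attr = TRUE)
})

test_that("feature shapes at every stage agree between detectors of one spec", {
  a <- build_detector(c(4, 8, 16, 32), 3, seed = 1)
  b <- build_detector(c(4, 8, 16, 32), 3, seed = 99)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  fa <- detector_forward(a, x)$stages
  fb <- detector_forward(b, x)$stages
  for (s in 1:4) expect_identical(dim(fa[[s]]), dim(fb[[s]]))
})

test_that("decode respects the confidence threshold and NMS keeps the top box", {
  raw <- array(-10, c(4, 4, 8, 1)) # conf logits very negative
  expect_identical(nrow(decode(raw[, , , 1], 0.25, 0.5, 64)$boxes), 0L)

  # two cells decoding to (nearly) identical boxes -> one survivor, higher conf
  raw[2, 2, 1, 1] <- 2.0
  raw[2, 3, 1, 1] <- 1.0
  raw[2, 2, 2:5, 1] <- c(0.0, 0.0, 0.0, 0.0)   # centered, half-image box
  raw[2, 3, 2:5, 1] <- c(-12, 0.0, 0.0, 0.0)   # same box from the next cell
  d <- decode(raw[, , , 1], 0.25, 0.5, 64)
  expect_identical(length(d$confidence), 1L)
  expect_equal(d$confidence, plogis(2.0), tolerance = 1e-12)
  expect_true(all(abs(rowSums(d$class_probs) - 1) < 1e-5))
})

test_that("greedy NMS matches the exhaustive reference on random box sets", {
  set.seed(101)
  for (case in 1:25) {
    n <- sample(3:20, 1)
    ctr <- matrix(runif(2 * n, 10, 50), n, 2)
    wh <- matrix(runif(2 * n, 5, 25), n, 2)
    boxes <- cbind(ctr - wh / 2, ctr + wh / 2)
    scores <- runif(n)
    thr <- sample(c(0.3, 0.5, 0.7), 1)
    expect_identical(sort(nms(boxes, scores, thr)),
                     sort(brute_nms(boxes, scores, thr)))
  }
})

test_that("detection loss obeys weight zeroing, linearity, and empty targets", {
  det <- tiny_detector(seed = 3)
  sc <- tiny_scenes(2, seed = 5)
  x <- pestwatch:::scenes_to_input(sc)
  raw <- detector_forward(det, x)$raw
  tg <- lapply(sc, function(s) s$boxes)

  full <- detection_loss(raw, tg, 64)
  conf_only <- detection_loss(raw, tg, 64, lambda_cls = 0, lambda_bb = 0)
  expect_equal(conf_only$loss, full$conf, tolerance = 1e-12)
  doubled <- detection_loss(raw, tg, 64, lambda_cls = 2, lambda_bb = 10,
                            lambda_conf = 2)
  expect_equal(doubled$loss, 2 * full$loss, tolerance = 1e-12)

  empty <- detection_loss(raw, list(tg[[1]][integer(), ], tg[[2]][integer(), ]), 64)
  expect_identical(empty$cls, 0)
  expect_identical(empty$bb, 0)
  expect_equal(empty$loss, empty$conf, tolerance = 1e-12)
})

test_that("loss attains its minimum on a head output encoding the targets", {
  sc <- tiny_scenes(1, size = 64, objects = c(2, 2), seed = 8)[[1]]
  G <- 4L; stride <- 16; C <- 3L
  raw <- array(0, c(G, G, 5 + C, 1))
  raw[, , 1, ] <- -30
  for (r in seq_len(nrow(sc$boxes))) {
    b <- sc$boxes[r, ]
    cx <- (b$x1 + b$x2) / 2; cy <- (b$y1 + b$y2) / 2
    j <- floor(cx / stride) + 1; i <- floor(cy / stride) + 1
    raw[i, j, 1, 1] <- 30
    raw[i, j, 2, 1] <- qlogis(cx / stride - (j - 1))
    raw[i, j, 3, 1] <- qlogis(cy / stride - (i - 1))
    raw[i, j, 4, 1] <- qlogis((b$x2 - b$x1) / 64)
    raw[i, j, 5, 1] <- qlogis((b$y2 - b$y1) / 64)
    raw[i, j, 6:8, 1] <- -20
    raw[i, j, 6 + b$class_id, 1] <- 20
  }
  ls <- detection_loss(raw, list(sc$boxes), 64)
  expect_lt(ls$cls, 1e-8)
  expect_lt(ls$bb, 1e-6)
  expect_lt(ls$conf, 1e-8)
})

test_that("analytic loss gradients match finite differences and reach every group", {
  det <- tiny_detector(seed = 6)
  sc <- tiny_scenes(2, seed = 9)
  x <- pestwatch:::scenes_to_input(sc)
  tg <- lapply(sc, function(s) s$boxes)
  fw <- detector_forward(det, x, keep_cache = TRUE)
  ls <- detection_loss(fw$raw, tg, 64, grad = TRUE)
  grads <- pestwatch:::detector_backward(det, fw$cache, ls$draw)

  gflat <- flatten_params(grads)
  expect_true(all(is.finite(gflat)))
  for (grp in names(grads)) # every parameter group receives gradient
    expect_gt(sqrt(pestwatch:::param_sq_norms(grads[[grp]])), 0)

  loss_at <- function(v) {
    d2 <- set_params(det, unflatten_params(v, det$params))
    detection_loss(detector_forward(d2, x)$raw, tg, 64)$loss
  }
  v0 <- flatten_params(det$params)
  set.seed(10)
  idx <- sample(length(v0), 10)
  eps <- 1e-5
  for (i in idx) {
    vp <- v0; vp[i] <- vp[i] + eps
    vm <- v0; vm[i] <- vm[i] - eps
    num <- (loss_at(vp) - loss_at(vm)) / (2 * eps)
    if (abs(num) > 1e-8)
      expect_lt(abs(num - gflat[i]) / max(abs(num), 1e-8), 1e-3)
  }
})
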