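test_that("view sets are seeded, identity mode copies, and variance needs X >= 2", {
  img <- generate_scenes(1, 64, 3, c(1, 1), seed = 3)[[1]]$image
  vs <- make_views(img, X = 4, seed = 5)
  vs2 <- make_views(img, X = 4, seed = 5)
  expect_identical(vs$views, vs2$views)
  expect_identical(vs$transforms, vs2$transforms)

  id <- make_views(img, X = 3, seed = 5, identity_only = TRUE)
  for (v in id$views) expect_identical(v, img)
  expect_error(make_views(img, X = 1, seed = 5), "X must be >= 2")
})

test_that("box coordinates map through each view transform with an exact inverse", {
  img <- generate_scenes(1, 96, 3, c(1, 1), seed = 3)[[1]]$image
  vs <- make_views(img, X = 8, seed = 11)
  boxes <- matrix(c(10, 20, 40, 55,
                    3, 3, 90, 90,
                    50.5, 60.25, 58.75, 70.5), 3, 4, byrow = TRUE)
  for (tf in vs$transforms) {
    fwd <- map_boxes_forward(boxes, tf, 96)
    back <- map_boxes_inverse(fwd, tf, 96)
    expect_lt(max(abs(back - boxes)), 1e-6)
  }
})

test_that("view matching picks the highest-IoU box and falls back to the proxy", {
  proxy <- structure(list(
    boxes = matrix(c(10, 10, 30, 30, 50, 50, 70, 70), 2, 4, byrow = TRUE),
    class_probs = matrix(c(0.7, 0.2, 0.1, 0.1, 0.8, 0.1), 2, 3, byrow = TRUE),
    confidence = c(0.9, 0.8)), class = "pw_detections")

  # view 1 predicts proxy exactly; view 2 has no detections;
  # view 3 offers IoU ~0.68 and ~0.33 candidates for proxy box 1
  v_exact <- proxy
  v_empty <- structure(list(boxes = matrix(numeric(), 0, 4),
                            class_probs = matrix(numeric(), 0, 3),
                            confidence = numeric()), class = "pw_detections")
  cand <- matrix(c(10, 10, 30, 26,   # IoU 0.8 with box 1
                   10, 18, 30, 42,   # IoU 0.5 with box 1
                   50, 50, 70, 70), 3, 4, byrow = TRUE)
  v_two <- structure(list(boxes = cand,
                          class_probs = matrix(1 / 3, 3, 3),
                          confidence = c(0.5, 0.6, 0.7)), class = "pw_detections")

  mt <- match_views(proxy, list(v_exact, v_empty, v_two))
  expect_identical(dim(mt$p_tilde), c(2L, 3L, 4L))
  expect_identical(mt$p_tilde[1, 1, ], proxy$boxes[1, ])       # exact match
  expect_identical(mt$c_tilde[1, 1, ], proxy$class_probs[1, ])
  expect_identical(mt$p_tilde[1, 2, ], proxy$boxes[1, ])       # empty-view fallback
  expect_identical(mt$c_tilde[2, 2, ], proxy$class_probs[2, ])
  expect_identical(mt$p_tilde[1, 3, ], cand[1, ])              # argmax IoU
  # brute-force argmax confirmation
  iou <- box_iou(proxy$boxes, cand)
  expect_identical(which.max(iou[1, ]), 1L)
  expect_gt(iou[1, 1], 0.6); expect_lt(iou[1, 2], 0.55)
})

test_that("corner certainty hits exp(0) and the X = 2 hand case, and is monotone", {
  # perfect agreement
  p_bar <- matrix(c(10, 10, 30, 30), 1, 4)
  p_tilde <- array(rep(p_bar, each = 2), c(1, 2, 4))
  expect_identical(corner_certainty(p_tilde, p_bar, 100)[1, ],
                   c(x1 = 1, y1 = 1, x2 = 1, y2 = 1))

  # X = 2 with normalized deviations +1 and -1 -> exp(-2)
  p_bar1 <- matrix(0, 1, 4)
  p_t <- array(0, c(1, 2, 4))
  p_t[1, 1, 1] <- 1; p_t[1, 2, 1] <- -1 # img_size 1 keeps units normalized
  mu <- corner_certainty(p_t, p_bar1, img_size = 1)
  expect_equal(unname(mu[1, 1]), exp(-2), tolerance = 1e-9)
  expect_equal(unname(mu[1, 1]), 0.13534, tolerance = 1e-4)

  # larger spread gives strictly smaller certainty
  p_t2 <- p_t; p_t2[1, 1, 1] <- 2
  expect_lt(corner_certainty(p_t2, p_bar1, 1)[1, 1], mu[1, 1])
})

test_that("class certainty hits exp(0), exp(-1), and ignores zero-weight classes", {
  c_bar <- matrix(c(1, 0, 0), 1, 3)
  agree <- array(0, c(1, 4, 3)); agree[, , 1] <- 1
  mc <- class_certainty(agree, c_bar)
  expect_equal(mc[1, 1], 1, tolerance = 1e-9)
  expect_equal(mc[1, 2], 1, tolerance = 1e-12) # c_bar = 0 -> certainty 1

  views_e <- array(0, c(1, 4, 3)); views_e[, , 1] <- exp(-1)
  mc2 <- class_certainty(views_e, c_bar)
  expect_equal(mc2[1, 1], exp(-1), tolerance = 1e-9)
  expect_equal(mc2[1, 1], 0.36788, tolerance = 1e-5)
})

test_that("the unified matrix concatenates unchanged blocks and is permutation-equivariant", {
  set.seed(4)
  n <- 3; X <- 5; C <- 5
  p_bar <- matrix(runif(n * 4, 0, 90), n, 4)
  p_tilde <- array(rep(p_bar, times = X), c(n, 4, X))
  p_tilde <- aperm(p_tilde, c(1, 3, 2)) + array(rnorm(n * X * 4, 0, 2), c(n, X, 4))
  c_bar <- matrix(runif(n * C), n, C); c_bar <- c_bar / rowSums(c_bar)
  c_tilde <- array(runif(n * X * C, 0.05, 1), c(n, X, C))

  Mu <- corner_certainty(p_tilde, p_bar, 96)
  Mc <- class_certainty(c_tilde, c_bar)
  M <- assemble_certainty(Mu, Mc)
  expect_identical(dim(M), c(3L, 9L))
  expect_equal(M[, 1:4], Mu, ignore_attr = TRUE)
  expect_equal(M[, 5:9], Mc, ignore_attr = TRUE)
  expect_true(all(M > 0 & M <= 1))
  expect_error(assemble_certainty(Mu[1:2, , drop = FALSE], Mc), "row mismatch")

  perm <- c(3, 1, 2)
  Mu_p <- corner_certainty(p_tilde[perm, , , drop = FALSE],
                           p_bar[perm, , drop = FALSE], 96)
  expect_equal(Mu_p, Mu[perm, ], tolerance = 1e-14, ignore_attr = TRUE)

  # triple-loop reference for both matrices
  mu_ref <- matrix(NA_real_, n, 4)
  mc_ref <- matrix(NA_real_, n, C)
  for (i in 1:n) {
    for (j in 1:4) {
      acc <- 0
      for (x in 1:X) acc <- acc + ((p_tilde[i, x, j] - p_bar[i, j]) / 96)^2
      mu_ref[i, j] <- exp(-acc / (X - 1))
    }
    for (k in 1:C) {
      acc <- 0
      for (x in 1:X) acc <- acc + (-c_bar[i, k] * log(max(c_tilde[i, x, k], 1e-7)))
      mc_ref[i, k] <- exp(-acc / X)
    }
  }
  expect_lt(max(abs(Mu - mu_ref)), 1e-10)
  expect_lt(max(abs(Mc - mc_ref)), 1e-10)
})

test_that("perfect cross-view agreement with one-hot classes gives certainty one", {
  # strict agreement: every view reproduces the proxy boxes and the class
  # vectors are one-hot (the class cross-entropy term vanishes only then)
  probs <- diag(3)[c(1, 3, 2), ]
  proxy <- structure(list(
    boxes = matrix(c(5, 5, 20, 20, 30, 10, 50, 28, 8, 40, 25, 60),
                   3, 4, byrow = TRUE),
    class_probs = probs, confidence = c(0.9, 0.8, 0.7)),
    class = "pw_detections")
  vp <- lapply(1:4, function(k) proxy)
  mt <- match_views(proxy, vp)
  M <- assemble_certainty(corner_certainty(mt$p_tilde, proxy$boxes, 64),
                          class_certainty(mt$c_tilde, proxy$class_probs))
  expect_true(all(abs(M - 1) < 1e-9))
  expect_equal(unname(rowMeans(M)), rep(1, nrow(M)), tolerance = 1e-9)
})
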