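# materialize the teacher or student detector from a state
detector_with_params <- function(state, which = c("t", "s")) {
  which <- match.arg(which)
  pestwatch:::detector_with(state$model,
                            if (which == "t") state$theta_t else state$theta_s)
}

frozen_mask_state <- function(det, config, density = 0.3, seed = 1) {
  state <- make_adapt_state(det, config)
  set.seed(seed)
  b <- as.numeric(runif(length(state$theta_s)) < density)
  state$b <- structure(b, tau = config$tau, density = mean(b),
                       class = "pw_param_mask")
  state
}

test_that("a zero mask leaves the student bit-identical; a sparse mask touches only its support", {
  det <- tiny_detector(seed = 2)
  sc <- tiny_scenes(1, seed = 3)[[1]]
  pseudo <- data.frame(class_id = 0L, x1 = 10, y1 = 10, x2 = 30, y2 = 30)

  cfg <- adapt_config(seed = 1)
  st0 <- make_adapt_state(det, cfg) # b all zeros
  out0 <- student_step(st0, sc, pseudo)
  expect_identical(out0$state$theta_s, st0$theta_s)

  # exactly one unmasked coordinate changes, by exactly eta * clipped gradient
  st1 <- make_adapt_state(det, cfg)
  b <- rep(0, length(st1$theta_s)); b[123] <- 1
  st1$b <- structure(b, class = "pw_param_mask", density = mean(b))
  out1 <- student_step(st1, sc, pseudo)
  diff_idx <- which(out1$state$theta_s != st1$theta_s)
  expect_identical(diff_idx, 123L)
  g <- flatten_params(pestwatch:::detector_backward(
    det,
    detector_forward(det, array(sc$image / 255, c(dim(sc$image), 1)),
                     keep_cache = TRUE)$cache,
    detection_loss(detector_forward(det, array(sc$image / 255, c(dim(sc$image), 1)))$raw,
                   list(pseudo), 64, grad = TRUE)$draw))
  nrm <- sqrt(sum(g^2))
  if (nrm > 10) g <- g * 10 / nrm
  expect_equal(out1$state$theta_s[123], st1$theta_s[123] - 0.001 * g[123],
               tolerance = 1e-12)
})

test_that("the isolated EMA freezes masked coordinates and hits the hand value", {
  cfg <- adapt_config(mu = 0.85, seed = 1)
  det <- tiny_detector(seed = 4)
  st <- make_adapt_state(det, cfg)
  A <- length(st$theta_t)
  st$theta_t <- rep(2.0, A)
  st$theta_s <- rep(1.0, A)

  # b all ones -> teacher untouched
  st$b <- structure(rep(1, A), class = "pw_param_mask", density = 1)
  expect_identical(teacher_ema(st)$theta_t, rep(2.0, A))

  # b all zeros -> classical EMA, 0.85 * 2 + 0.15 * 1 = 1.85
  st$b <- structure(rep(0, A), class = "pw_param_mask", density = 0)
  expect_equal(teacher_ema(st)$theta_t, rep(1.85, A), tolerance = 1e-12)

  # EMA fixed point when student equals teacher
  st$theta_s <- st$theta_t
  set.seed(5)
  st$b <- structure(as.numeric(runif(A) < 0.5), class = "pw_param_mask")
  expect_identical(teacher_ema(st)$theta_t, rep(2.0, A))
})

test_that("isolation holds bitwise over 100 adaptation steps with a fixed mask", {
  det <- tiny_detector(seed = 6)
  sc <- tiny_scenes(10, size = 64, seed = 7)
  cfg <- adapt_config(cert_min = 0, conf_floor = 0.05, X = 2, seed = 2)
  st <- frozen_mask_state(det, cfg, density = 0.3, seed = 8)
  b <- as.numeric(st$b)
  s0 <- st$theta_s
  t0 <- st$theta_t
  for (step in 1:100) {
    scene <- sc[[(step - 1) %% 10 + 1]]
    pl <- pestwatch:::teacher_pseudo_labels(
      detector_with_params(st, "t"), scene, X = 2,
      seed = step, cert_min = 0, conf_floor = 0.05)
    out <- student_step(st, scene, pl$labels)
    st <- teacher_ema(out$state)
  }
  expect_identical(st$theta_s[b == 0], s0[b == 0]) # student isolation
  expect_identical(st$theta_t[b == 1], t0[b == 1]) # teacher isolation
  expect_gt(max(abs(st$theta_s - s0)), 0)          # but adaptation happened
  expect_identical(st$source_checkpoint, s0)       # checkpoint untouched
})

test_that("no-op settings reproduce the frozen source outputs exactly", {
  det <- tiny_detector(seed = 9)
  sc <- tiny_scenes(6, seed = 10)
  stream <- lapply(sc, corrupt, kind = "gaussian_noise", severity = 2)
  cfg <- adapt_config(eta = 0, mu = 1, X = 2, cert_min = 0, conf_floor = 0.05,
                      refresh_every = 2, seed = 3)
  res <- adapt_stream(det, stream, cfg)
  frozen <- detector_predict(det, stream, conf_threshold = 0.05)
  for (k in seq_along(stream)) {
    expect_identical(res$detections[[k]]$boxes, frozen[[k]]$boxes)
    expect_identical(res$detections[[k]]$confidence, frozen[[k]]$confidence)
  }
  expect_identical(res$state$source_checkpoint, flatten_params(det$params))
})

test_that("adaptation runs are deterministic and log the stream", {
  det <- tiny_detector(seed = 11)
  sc <- tiny_scenes(5, seed = 12)
  stream <- lapply(sc, corrupt, kind = "dark", severity = 3)
  cfg <- adapt_config(X = 2, cert_min = 0, conf_floor = 0.05,
                      refresh_every = 3, seed = 4)
  r1 <- adapt_stream(det, stream, cfg)
  r2 <- adapt_stream(det, stream, cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$state$theta_s, r2$state$theta_s)
  expect_identical(r1$state$theta_t, r2$state$theta_t)
  expect_identical(nrow(r1$log), 5L)
  expect_identical(r1$log$domain_tag, rep("dark", 5))
})

test_that("an empty pseudo-label set skips the update and returns teacher output", {
  det <- tiny_detector(seed = 13) # untrained: objectness prior keeps conf ~0.1
  sc <- tiny_scenes(1, seed = 14)[[1]]
  cfg <- adapt_config(seed = 5)
  st <- frozen_mask_state(det, cfg, density = 0.5, seed = 6)
  out <- student_step(st, sc, pseudo = NULL)
  expect_identical(out$state$theta_s, st$theta_s)
  expect_true(is.na(out$loss))
  expect_s3_class(out$detections, "pw_detections")
})
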