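tiny_maf_state <- function(seed = 1, epochs = 2, gamma = 0.5, ...) {
  cfg <- maf_config(epochs = epochs, batch_size = 4, gamma = gamma,
                    occlusion = occlusion_spec(seed = seed), seed = seed, ...)
  make_maf_state(cfg, channels_per_stage = c(4L, 8L, 16L, 32L), classes = 3L)
}

test_that("unidirectional exchange is gated fusion into the main branch only", {
  set.seed(1)
  g <- make_gate(4)
  main <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  aux <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  aux_before <- aux + 0
  out <- exchange_uni(main, aux, g)
  expect_equal(out, fuse(aux, main, g), tolerance = 1e-14, ignore_attr = TRUE)
  expect_identical(aux, aux_before) # no back-flow
  gc <- g; gc$M$b[] <- -800
  expect_lt(max(abs(exchange_uni(main, aux, gc) - main)), 1e-12)
})

test_that("bidirectional exchange uses pre-exchange features simultaneously", {
  set.seed(2)
  g1 <- make_gate(4); g2 <- make_gate(4)
  main <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  aux <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  bi <- exchange_bi(main, aux, g1, g2)
  expect_equal(bi$main, fuse(aux, main, g1), tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(bi$aux, fuse(main, aux, g2), tolerance = 1e-14, ignore_attr = TRUE)

  # sequential update (aux sees the ALREADY-fused main) differs generically
  seq_aux <- fuse(bi$main, aux, g2)
  expect_gt(max(abs(seq_aux - bi$aux)), 1e-6)

  # closed gates -> identity on both branches
  g1$M$b[] <- -800; g2$M$b[] <- -800
  bi0 <- exchange_bi(main, aux, g1, g2)
  expect_lt(max(abs(bi0$main - main)), 1e-12)
  expect_lt(max(abs(bi0$aux - aux)), 1e-12)

  # tied gates + symmetric inputs -> symmetric outputs
  bis <- exchange_bi(main, main, g1, g1)
  expect_identical(bis$main, bis$aux)
})

test_that("gamma = 0 zeroes the auxiliary-head gradient; gamma > 0 reaches all groups", {
  sc <- tiny_scenes(4, seed = 21)
  st0 <- tiny_maf_state(seed = 3, gamma = 0)
  stp0 <- maf_step(st0, sc, update = FALSE)
  expect_identical(max(abs(stp0$grads$aux$head$w)), 0)
  expect_identical(max(abs(stp0$grads$aux$head$b)), 0)

  st <- tiny_maf_state(seed = 3, gamma = 0.5)
  stp <- maf_step(st, sc, update = FALSE)
  expect_true(all(stp$grad_norms > 0))
  expect_equal(stp$l_t, stp$l_main + 0.5 * stp$l_aux, tolerance = 1e-12)
  st1 <- tiny_maf_state(seed = 3, gamma = 1)
  stp1 <- maf_step(st1, sc, update = FALSE)
  expect_equal(stp1$l_t, stp1$l_main + stp1$l_aux, tolerance = 1e-12)
})

test_that("dual-branch gradients match finite differences across all four groups", {
  sc <- tiny_scenes(2, seed = 31)
  state <- tiny_maf_state(seed = 5)
  x_m <- pestwatch:::scenes_to_input(sc)
  x_a <- pestwatch:::scenes_to_input(
    lapply(sc, occlude, spec = occlusion_spec(seed = 6)))
  tg <- lapply(sc, function(s) s$boxes)
  res <- pestwatch:::maf_grads(state, x_m, x_a, tg, 64)

  cases <- list(
    list(path = '$main$params$s2$down$w[5]', grad = res$grads$main$s2$down$w[5]),
    list(path = '$main$params$head$w[3]',    grad = res$grads$main$head$w[3]),
    list(path = '$aux$params$s1$res$w[7]',   grad = res$grads$aux$s1$res$w[7]),
    list(path = '$aux$params$s3$down$w[2]',  grad = res$grads$aux$s3$down$w[2]),
    list(path = '$caes$cae1$enc1$w[4]',      grad = res$grads$cae$cae1$enc1$w[4]),
    list(path = '$caes$cae2$dec2$w[6]',      grad = res$grads$cae$cae2$dec2$w[6]),
    list(path = '$gates$u1$M$w[2]',          grad = res$grads$agiin$u1$M$w[2]),
    list(path = '$gates$b4_ma$N$w[9]',       grad = res$grads$agiin$b4_ma$N$w[9]),
    list(path = '$gates$b2_am$M$b[1]',       grad = res$grads$agiin$b2_am$M$b[1]),
    list(path = '$gates$u3$N$b[2]',          grad = res$grads$agiin$u3$N$b[2]))
  eps <- 1e-5
  for (cs in cases) {
    sp <- state; eval(parse(text = sprintf("sp%s <- sp%s + eps", cs$path, cs$path)))
    sm <- state; eval(parse(text = sprintf("sm%s <- sm%s - eps", cs$path, cs$path)))
    lp <- pestwatch:::maf_grads(sp, x_m, x_a, tg, 64)$l_t
    lm <- pestwatch:::maf_grads(sm, x_m, x_a, tg, 64)$l_t
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - cs$grad) / max(abs(num), 1e-6), 1e-3, label = cs$path)
  }
})

test_that("a short dual-branch run reduces the total loss in best-so-far trend", {
  sc <- tiny_scenes(16, size = 64, objects = c(1, 3), seed = 41)
  cfg <- maf_config(epochs = 5, batch_size = 8,
                    occlusion = occlusion_spec(seed = 2), seed = 7)
  tr <- train_maf(sc, cfg, channels_per_stage = c(4, 8, 16, 32), classes = 3)
  expect_lt(min(tr$log$l_t), tr$log$l_t[1])
  expect_true(all(is.finite(tr$log$l_t)))
})

test_that("the retained main model is structurally a plain detector", {
  sc <- tiny_scenes(8, size = 64, seed = 51)
  cfg <- maf_config(epochs = 1, batch_size = 8,
                    occlusion = occlusion_spec(seed = 2), seed = 7)
  tr <- train_maf(sc, cfg, channels_per_stage = c(4, 8, 16, 32), classes = 3)
  det <- tr$detector
  expect_s3_class(det, "pw_detector")
  fresh <- build_detector(c(4, 8, 16, 32), 3, seed = 1)
  expect_identical(names(det$params), names(fresh$params))
  expect_identical(rapply(det$params, dim, how = "list"),
                   rapply(fresh$params, dim, how = "list"))
  # forward pass equals a plain detector carrying the same weights
  fresh$params <- det$params
  x <- pestwatch:::scenes_to_input(sc[1:2])
  expect_identical(detector_forward(det, x)$raw, detector_forward(fresh, x)$raw)
})

test_that("with every component off, training reproduces the plain baseline exactly", {
  sc <- tiny_scenes(8, size = 64, seed = 61)
  cfg <- maf_config(epochs = 2, batch_size = 8, use_cae = FALSE,
                    use_agiin = FALSE, use_aux = FALSE, seed = 9)
  via_maf <- train_maf(sc, cfg, channels_per_stage = c(4, 8, 16, 32), classes = 3)
  det0 <- build_detector(c(4, 8, 16, 32), 3,
                         seed = pestwatch:::child_seed(9, "main"))
  plain <- train_detector(det0, sc, epochs = 2, batch_size = 8, seed = 9)
  expect_identical(flatten_params(via_maf$detector$params),
                   flatten_params(plain$detector$params))
  expect_equal(via_maf$log$l_t, plain$log$loss, tolerance = 1e-12)
})

test_that("the optional reconstruction term is logged and differentiates correctly", {
  sc <- tiny_scenes(2, seed = 71)
  cfg <- maf_config(epochs = 1, batch_size = 2, recon_weight = 0.5,
                    occlusion = occlusion_spec(seed = 72), seed = 72)
  state <- make_maf_state(cfg, c(4, 8, 16, 32), 3)
  x_m <- pestwatch:::scenes_to_input(sc)
  x_a <- pestwatch:::scenes_to_input(
    lapply(sc, occlude, spec = occlusion_spec(seed = 73)))
  tg <- lapply(sc, function(s) s$boxes)
  res <- pestwatch:::maf_grads(state, x_m, x_a, tg, 64)
  expect_true(all(is.finite(res$cae_mse)))
  expect_gt(res$l_t, res$l_main + cfg$gamma * res$l_aux) # recon term included

  # finite differences through the reconstruction path (CAE and its input)
  eps <- 1e-5
  for (path in c('$caes$cae1$dec2$w[3]', '$aux$params$s1$down$w[2]')) {
    sp <- state; eval(parse(text = sprintf("sp%s <- sp%s + eps", path, path)))
    sm <- state; eval(parse(text = sprintf("sm%s <- sm%s - eps", path, path)))
    num <- (pestwatch:::maf_grads(sp, x_m, x_a, tg, 64)$l_t -
            pestwatch:::maf_grads(sm, x_m, x_a, tg, 64)$l_t) / (2 * eps)
    ana <- if (grepl("cae1", path)) res$grads$cae$cae1$dec2$w[3]
           else res$grads$aux$s1$down$w[2]
    expect_lt(abs(num - ana) / max(abs(num), 1e-6), 1e-3, label = path)
  }

  # default training logs the diagnostic without optimizing it
  tr <- train_maf(tiny_scenes(4, seed = 74),
                  maf_config(epochs = 1, batch_size = 4,
                             occlusion = occlusion_spec(seed = 75), seed = 75),
                  channels_per_stage = c(4, 8, 16, 32), classes = 3)
  expect_true(all(is.finite(tr$log$cae_mse)))
})
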