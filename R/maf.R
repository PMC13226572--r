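# Dual-branch main/auxiliary training. The main detector sees clean images,
# the auxiliary detector sees occluded copies of the same images; features are
# exchanged four times per forward pass (unidirectional aux -> main after
# stages 1 and 3, bidirectional after stages 2 and 4), the auxiliary branch
# inpaints its features with two autoencoders after the unidirectional
# exchanges, and one SGD step updates the main, auxiliary, autoencoder and
# gate parameter groups simultaneously from L_t = L_main + gamma * L_aux.
# After training only the main detector is retained.

#' Configuration for dual-branch training
#'
#' Defaults follow the training protocol: initial learning rate 0.015 decayed
#' by a cosine schedule to 0.015 * 0.01, 50 epochs, batch size 16. `gamma`
#' weighs the auxiliary loss (0.5 keeps the main task dominant). The three
#' `use_*` switches form the ablation grid: with all three off training
#' degenerates to plain single-branch training.
#'
#' @param gamma auxiliary-loss weight (>= 0).
#' @param lr0,lrf,epochs,batch_size,momentum,warmup_epochs SGD schedule
#'   (momentum 0.937 with a 3-epoch linear warmup, detector-training
#'   practice for this lr range).
#' @param occlusion an [occlusion_spec()]; fresh masks are drawn every epoch.
#' @param use_cae,use_agiin,use_aux component switches (see Details).
#' @param recon_weight weight of an explicit autoencoder reconstruction term
#'   added to the total loss. 0 by default: the autoencoders train through
#'   the detection loss alone and their reconstruction error is only logged
#'   as a diagnostic.
#' @param seed integer seed.
#' @details Without AGIIN (`use_agiin = FALSE`) the exchange becomes a plain
#'   1x1 convolution of `0.5 * sender + receiver`. Without the auxiliary model
#'   (`use_aux = FALSE`) the occluded branch runs through the main detector's
#'   own weights (tied), so occluded images act as extra training signal only.
#' @export
maf_config <- function(gamma = 0.5, lr0 = 0.015, lrf = 0.01, epochs = 50L,
                       batch_size = 16L, momentum = 0.937, warmup_epochs = 3L,
                       occlusion = occlusion_spec(),
                       use_cae = TRUE, use_agiin = TRUE, use_aux = TRUE,
                       recon_weight = 0,
                       seed = 1L) {
  if (gamma < 0) stop("configuration error: gamma must be >= 0")
  if (epochs < 1) stop("configuration error: epochs must be >= 1")
  structure(list(gamma = gamma, lr0 = lr0, lrf = lrf,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 momentum = momentum, warmup_epochs = as.integer(warmup_epochs),
                 occlusion = occlusion, use_cae = isTRUE(use_cae),
                 use_agiin = isTRUE(use_agiin), use_aux = isTRUE(use_aux),
                 recon_weight = recon_weight,
                 seed = as.integer(seed)),
            class = "pw_maf_config")
}

# near-identity 1x1 conv used when AGIIN is ablated away
plain_fusion_layer <- function(channels) {
  l <- conv_layer(1, 1, channels, channels, gain = 0.05)
  for (c in seq_len(channels)) l$w[1, 1, c, c] <- l$w[1, 1, c, c] + 1
  l
}

#' Assemble the dual-branch training state
#'
#' @param config a [maf_config()].
#' @param channels_per_stage,classes detector architecture.
#' @return list with `main` and `aux` detectors, two `pw_cae` blocks (after
#'   stages 1 and 3), six gates (one per exchange point and direction) and the
#'   config.
#' @export
make_maf_state <- function(config, channels_per_stage = c(8L, 16L, 32L, 64L),
                           classes = 3L) {
  ch <- as.integer(channels_per_stage)
  main <- build_detector(ch, classes, seed = child_seed(config$seed, "main"))
  aux <- if (config$use_aux)
    build_detector(ch, classes, seed = child_seed(config$seed, "aux")) else NULL
  set.seed(child_seed(config$seed, "fusion"))
  caes <- if (config$use_cae) list(cae1 = make_cae(ch[1]), cae2 = make_cae(ch[3]))
          else NULL
  gates <- if (config$use_agiin) {
    list(u1 = make_gate(ch[1]), b2_am = make_gate(ch[2]), b2_ma = make_gate(ch[2]),
         u3 = make_gate(ch[3]), b4_am = make_gate(ch[4]), b4_ma = make_gate(ch[4]))
  } else {
    list(u1 = plain_fusion_layer(ch[1]),
         b2_am = plain_fusion_layer(ch[2]), b2_ma = plain_fusion_layer(ch[2]),
         u3 = plain_fusion_layer(ch[3]),
         b4_am = plain_fusion_layer(ch[4]), b4_ma = plain_fusion_layer(ch[4]))
  }
  structure(list(main = main, aux = aux, caes = caes, gates = gates,
                 config = config, channels = ch, classes = as.integer(classes)),
            class = "pw_maf_state")
}

#' Unidirectional feature exchange (auxiliary -> main)
#'
#' The main branch's next-layer input is the gated fusion of the auxiliary
#' features into the main features; the auxiliary branch continues unchanged
#' (no back-flow).
#'
#' @param main_feat,aux_feat stage outputs with matching shapes.
#' @param gate a `pw_gate`.
#' @return the new main-branch feature map.
#' @export
exchange_uni <- function(main_feat, aux_feat, gate) {
  fuse(sender = aux_feat, receiver_prev = main_feat, gate = gate)
}

#' Bidirectional feature exchange with simultaneous semantics
#'
#' Both directions are computed from the PRE-exchange features: the new main
#' input fuses the old auxiliary features, and the new auxiliary input fuses
#' the old main features.
#'
#' @param main_feat,aux_feat stage outputs with matching shapes.
#' @param gate_am gate for the aux -> main direction; `gate_ma` for
#'   main -> aux.
#' @return list `(main, aux)` of new branch inputs.
#' @export
exchange_bi <- function(main_feat, aux_feat, gate_am, gate_ma) {
  list(main = fuse(sender = aux_feat, receiver_prev = main_feat, gate = gate_am),
       aux = fuse(sender = main_feat, receiver_prev = aux_feat, gate = gate_ma))
}

# -- internal fused exchange with cache, honoring the use_agiin switch --------
fusion_fwd <- function(state, name, sender, receiver) {
  if (state$config$use_agiin) {
    out <- fuse(sender, receiver, state$gates[[name]], keep_cache = TRUE)
    list(out = out, cache = attr(out, "cache"))
  } else {
    pre <- 0.5 * sender + receiver
    out <- conv_fwd(pre, state$gates[[name]])
    list(out = out, cache = list(pre = pre))
  }
}

fusion_bwd <- function(state, name, cache, dout) {
  if (state$config$use_agiin) {
    b <- fuse_bwd(state$gates[[name]], cache, dout)
    list(dsender = b$dsender, dreceiver = b$dreceiver, grads = b$grads)
  } else {
    b <- conv_bwd(cache$pre, state$gates[[name]], dout)
    list(dsender = 0.5 * b$dx, dreceiver = b$dx,
         grads = list(w = b$dw, b = b$db))
  }
}

# One full dual-branch forward + backward. Returns losses, per-group gradient
# lists and gradient norms.
maf_grads <- function(state, x_main, x_aux, targets, img_size) {
  cfg <- state$config
  main_p <- state$main$params
  aux_p <- if (cfg$use_aux) state$aux$params else main_p

  # ---------- forward ----------
  m <- list(); a <- list(); cm <- list(); ca <- list(); fc <- list()
  st <- stage_fwd(main_p$s1, x_main); m$f1 <- st$out; cm$s1 <- st$cache
  st <- stage_fwd(aux_p$s1, x_aux);   a$f1 <- st$out; ca$s1 <- st$cache
  fx <- fusion_fwd(state, "u1", a$f1, m$f1); m$f1x <- fx$out; fc$u1 <- fx$cache
  if (cfg$use_cae) {
    a$f1c <- cae_forward(a$f1, state$caes$cae1, keep_cache = TRUE)
    ca$cae1 <- attr(a$f1c, "cache")
    rec1 <- a$f1c - a$f1
  } else a$f1c <- a$f1
  st <- stage_fwd(main_p$s2, m$f1x); m$f2 <- st$out; cm$s2 <- st$cache
  st <- stage_fwd(aux_p$s2, a$f1c);  a$f2 <- st$out; ca$s2 <- st$cache
  fx <- fusion_fwd(state, "b2_am", a$f2, m$f2); m$f2x <- fx$out; fc$b2_am <- fx$cache
  fx <- fusion_fwd(state, "b2_ma", m$f2, a$f2); a$f2x <- fx$out; fc$b2_ma <- fx$cache
  st <- stage_fwd(main_p$s3, m$f2x); m$f3 <- st$out; cm$s3 <- st$cache
  st <- stage_fwd(aux_p$s3, a$f2x);  a$f3 <- st$out; ca$s3 <- st$cache
  fx <- fusion_fwd(state, "u3", a$f3, m$f3); m$f3x <- fx$out; fc$u3 <- fx$cache
  if (cfg$use_cae) {
    a$f3c <- cae_forward(a$f3, state$caes$cae2, keep_cache = TRUE)
    ca$cae2 <- attr(a$f3c, "cache")
    rec2 <- a$f3c - a$f3
  } else a$f3c <- a$f3
  st <- stage_fwd(main_p$s4, m$f3x); m$f4 <- st$out; cm$s4 <- st$cache
  st <- stage_fwd(aux_p$s4, a$f3c);  a$f4 <- st$out; ca$s4 <- st$cache
  fx <- fusion_fwd(state, "b4_am", a$f4, m$f4); m$f4x <- fx$out; fc$b4_am <- fx$cache
  fx <- fusion_fwd(state, "b4_ma", m$f4, a$f4); a$f4x <- fx$out; fc$b4_ma <- fx$cache
  nhm <- neck_head_fwd(main_p, m$f4x)
  nha <- neck_head_fwd(aux_p, a$f4x)

  lm <- detection_loss(nhm$raw, targets, img_size, grad = TRUE)
  la <- detection_loss(nha$raw, targets, img_size, grad = TRUE)
  if (!is.finite(lm$loss) || !is.finite(la$loss))
    stop("non-finite loss in dual-branch step (L_main = ", lm$loss,
         ", L_aux = ", la$loss, ")")
  # diagnostic autoencoder reconstruction error (optimized only when
  # recon_weight > 0)
  rw <- cfg$recon_weight %||% 0
  cae_mse <- if (cfg$use_cae)
    c(cae1 = mean(rec1^2), cae2 = mean(rec2^2)) else c(cae1 = NA, cae2 = NA)
  l_recon <- if (cfg$use_cae) sum(cae_mse) else 0

  # ---------- backward ----------
  gm <- list(); ga <- list(); gcae <- list(); ggate <- list()
  bm <- neck_head_bwd(main_p, nhm$cache, lm$draw)
  ba <- neck_head_bwd(aux_p, nha$cache, cfg$gamma * la$draw)
  gm$neck <- bm$grads$neck; gm$head <- bm$grads$head
  ga$neck <- ba$grads$neck; ga$head <- ba$grads$head

  fb <- fusion_bwd(state, "b4_am", fc$b4_am, bm$dx)
  da4 <- fb$dsender; dm4 <- fb$dreceiver; ggate$b4_am <- fb$grads
  fb <- fusion_bwd(state, "b4_ma", fc$b4_ma, ba$dx)
  dm4 <- dm4 + fb$dsender; da4 <- da4 + fb$dreceiver; ggate$b4_ma <- fb$grads

  bs <- stage_bwd(main_p$s4, cm$s4, dm4); gm$s4 <- bs$grads; dm3x <- bs$dx
  bs <- stage_bwd(aux_p$s4, ca$s4, da4);  ga$s4 <- bs$grads; da3c <- bs$dx
  if (cfg$use_cae) {
    if (rw > 0) da3c <- da3c + rw * (2 / length(rec2)) * rec2
    cb <- cae_bwd(state$caes$cae2, ca$cae2, da3c)
    gcae$cae2 <- cb$grads; da3 <- cb$dx
    if (rw > 0) da3 <- da3 - rw * (2 / length(rec2)) * rec2
  } else da3 <- da3c
  fb <- fusion_bwd(state, "u3", fc$u3, dm3x)
  da3 <- da3 + fb$dsender; dm3 <- fb$dreceiver; ggate$u3 <- fb$grads

  bs <- stage_bwd(main_p$s3, cm$s3, dm3); gm$s3 <- bs$grads; dm2x <- bs$dx
  bs <- stage_bwd(aux_p$s3, ca$s3, da3);  ga$s3 <- bs$grads; da2x <- bs$dx
  fb <- fusion_bwd(state, "b2_am", fc$b2_am, dm2x)
  da2 <- fb$dsender; dm2 <- fb$dreceiver; ggate$b2_am <- fb$grads
  fb <- fusion_bwd(state, "b2_ma", fc$b2_ma, da2x)
  dm2 <- dm2 + fb$dsender; da2 <- da2 + fb$dreceiver; ggate$b2_ma <- fb$grads

  bs <- stage_bwd(main_p$s2, cm$s2, dm2); gm$s2 <- bs$grads; dm1x <- bs$dx
  bs <- stage_bwd(aux_p$s2, ca$s2, da2);  ga$s2 <- bs$grads; da1c <- bs$dx
  if (cfg$use_cae) {
    if (rw > 0) da1c <- da1c + rw * (2 / length(rec1)) * rec1
    cb <- cae_bwd(state$caes$cae1, ca$cae1, da1c)
    gcae$cae1 <- cb$grads; da1 <- cb$dx
    if (rw > 0) da1 <- da1 - rw * (2 / length(rec1)) * rec1
  } else da1 <- da1c
  fb <- fusion_bwd(state, "u1", fc$u1, dm1x)
  da1 <- da1 + fb$dsender; dm1 <- fb$dreceiver; ggate$u1 <- fb$grads

  bs <- stage_bwd(main_p$s1, cm$s1, dm1); gm$s1 <- bs$grads
  bs <- stage_bwd(aux_p$s1, ca$s1, da1);  ga$s1 <- bs$grads

  if (!cfg$use_aux) { # tied branches: occluded-branch gradients flow to main
    gm <- axpy_params(gm, ga[names(gm)])
    ga <- NULL
  }
  list(l_t = lm$loss + cfg$gamma * la$loss + rw * l_recon,
       l_main = lm$loss, l_aux = la$loss, cae_mse = cae_mse,
       grads = list(main = gm, aux = ga, cae = if (cfg$use_cae) gcae else NULL,
                    agiin = ggate))
}

# one momentum-SGD step over all four parameter groups (one optimizer, one
# learning rate)
maf_apply_update <- function(state, g, lr) {
  mom <- state$config$momentum %||% 0
  step_group <- function(params, grads, vel) {
    grads <- clip_grads(grads)
    vel <- if (is.null(vel)) grads
           else axpy_params(axpy_params(zero_like(grads), vel, mom), grads, 1)
    list(params = apply_grads(params, vel, lr), vel = vel)
  }
  if (is.null(state$vel)) state$vel <- list()
  up <- step_group(state$main$params, g$main, state$vel$main)
  state$main$params <- up$params; state$vel$main <- up$vel
  if (!is.null(g$aux)) {
    up <- step_group(state$aux$params, g$aux, state$vel$aux)
    state$aux$params <- up$params; state$vel$aux <- up$vel
  }
  if (!is.null(g$cae)) {
    up <- step_group(state$caes, g$cae, state$vel$cae)
    state$caes <- up$params; state$vel$cae <- up$vel
  }
  up <- step_group(state$gates, g$agiin, state$vel$agiin)
  state$gates <- up$params; state$vel$agiin <- up$vel
  state
}

#' One dual-branch training step
#'
#' Forwards the batch through both branches with the four exchange events,
#' computes `L_t = L_main + gamma * L_aux` on the shared ground truth, and (if
#' `update`) applies one SGD step to all four parameter groups simultaneously.
#'
#' @param state a `pw_maf_state`.
#' @param batch list of clean scenes; the auxiliary branch sees occluded
#'   copies of the SAME scenes drawn under `occ_spec`.
#' @param lr learning rate for this step.
#' @param occ_spec occlusion specification for this step.
#' @param update apply the parameter update (FALSE = losses/gradients only).
#' @return list with `state`, `l_t`, `l_main`, `l_aux` and `grad_norms` (one
#'   Euclidean norm per parameter group).
#' @export
maf_step <- function(state, batch, lr = state$config$lr0,
                     occ_spec = state$config$occlusion, update = TRUE) {
  if (length(batch) == 0) stop("empty batch")
  x_main <- scenes_to_input(batch)
  occ <- lapply(batch, occlude, spec = occ_spec)
  x_aux <- scenes_to_input(occ)
  targets <- lapply(batch, function(s) s$boxes)
  img <- dim(x_main)[1]
  res <- maf_grads(state, x_main, x_aux, targets, img)

  norms <- vapply(res$grads, function(g)
    if (is.null(g)) NA_real_ else sqrt(param_sq_norms(g)), numeric(1))

  if (update) state <- maf_apply_update(state, res$grads, lr)
  list(state = state, l_t = res$l_t, l_main = res$l_main, l_aux = res$l_aux,
       cae_mse = res$cae_mse,
       grad_norms = norms, grads = if (update) NULL else res$grads)
}

#' Train with the dual-branch framework and retain only the main detector
#'
#' Fresh occlusion masks are drawn for the auxiliary branch every epoch. With
#' all three component switches off this reduces to [train_detector()].
#'
#' @param scenes nonempty list of labeled scenes.
#' @param config a [maf_config()].
#' @param channels_per_stage,classes detector architecture.
#' @return list with `detector` (the retained main `pw_detector`; auxiliary
#'   branch, autoencoders and gates are discarded) and `log` (per-epoch
#'   `l_t`, `l_main`, `l_aux`).
#' @export
train_maf <- function(scenes, config = maf_config(),
                      channels_per_stage = c(8L, 16L, 32L, 64L), classes = 3L) {
  if (length(scenes) == 0) stop("empty dataset")
  if (!config$use_cae && !config$use_agiin && !config$use_aux) {
    det <- build_detector(channels_per_stage, classes,
                          seed = child_seed(config$seed, "main"))
    tr <- train_detector(det, scenes, epochs = config$epochs,
                         batch_size = config$batch_size, lr0 = config$lr0,
                         lrf = config$lrf, momentum = config$momentum,
                         warmup_epochs = config$warmup_epochs,
                         seed = config$seed)
    log <- data.frame(epoch = tr$log$epoch, l_t = tr$log$loss,
                      l_main = tr$log$loss, l_aux = NA_real_,
                      cae_mse = NA_real_)
    class(log) <- c("pw_training_log", class(log))
    return(list(detector = tr$detector, log = log))
  }
  state <- make_maf_state(config, channels_per_stage, classes)
  n <- length(scenes)
  x_clean <- scenes_to_input(scenes)
  img <- dim(x_clean)[1]
  targets_all <- lapply(scenes, function(s) s$boxes)
  log <- vector("list", config$epochs)
  set.seed(child_seed(config$seed, "mafloop"))
  for (e in seq_len(config$epochs)) {
    lr <- cosine_lr(e, config$epochs, config$lr0, config$lrf,
                    config$warmup_epochs)
    occ <- state$config$occlusion
    occ$seed <- child_seed(config$seed, "epoch-occ", e)
    x_occ <- scenes_to_input(lapply(scenes, occlude, spec = occ))
    ord <- sample.int(n)
    tots <- c(0, 0, 0, 0); nb <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      res <- maf_grads(state, x_clean[, , , idx, drop = FALSE],
                       x_occ[, , , idx, drop = FALSE], targets_all[idx], img)
      state <- maf_apply_update(state, res$grads, lr)
      tots <- tots + c(res$l_t, res$l_main, res$l_aux, sum(res$cae_mse))
      nb <- nb + 1
    }
    log[[e]] <- data.frame(epoch = e, l_t = tots[1] / nb,
                           l_main = tots[2] / nb, l_aux = tots[3] / nb,
                           cae_mse = tots[4] / nb)
  }
  log <- do.call(rbind, log)
  class(log) <- c("pw_training_log", class(log))
  list(detector = state$main, log = log)
}
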