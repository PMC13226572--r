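# Streaming test-time adaptation. Teacher and student start as copies of the
# trained source detector. Per image: the teacher produces certainty-filtered
# pseudo-labels from augmented views; the student takes one gradient step on
# the detection loss masked to the domain-sensitive coordinates
# (Theta_S <- Theta_S - eta * grad (*) b); the teacher then receives the
# isolated EMA update Theta_T <- Theta_T (*) b + (1 - b) (*) (mu Theta_T +
# (1 - mu) Theta_S). The mask b is refreshed every `refresh_every` images from
# Fisher importance accumulated over the window; before the first refresh b
# is all zeros, so adaptation warms up on a frozen model. Final detections
# always come from the post-update student forward pass. The architecture
# carries no batch-normalization state, so the masked gradient and EMA updates
# are the only state that changes; the source checkpoint is never modified.

#' Configuration for streaming adaptation
#'
#' Defaults: student learning rate `eta = 0.001`, teacher EMA momentum
#' `mu = 0.85`, `X = 8` augmented views, Fisher threshold `tau = 0.3`, mask
#' refresh window of 64 images, pseudo-label certainty gate 0.5 and confidence
#' floor 0.25. `detect_conf` is the decode threshold for the detections the
#' stream EMITS (defaults to `conf_floor`; set it low when the output feeds an
#' average-precision computation) - it never affects the pseudo-labels.
#' `alpha` (a Bernoulli rate for a stochastic mask) is accepted but only used
#' when `stochastic_mask = TRUE`.
#'
#' @param eta,mu,X,tau,refresh_every,cert_min,conf_floor,nms_iou see above.
#' @param detect_conf decode threshold for emitted detections.
#' @param normalization Fisher normalization, `"rank"` or `"minmax"`.
#' @param alpha,stochastic_mask optional stochastic-mask mode.
#' @param seed integer seed.
#' @export
adapt_config <- function(eta = 0.001, mu = 0.85, X = 8L, tau = 0.3,
                         refresh_every = 64L, cert_min = 0.5,
                         conf_floor = 0.25, nms_iou = 0.5,
                         detect_conf = conf_floor,
                         normalization = c("rank", "minmax"),
                         alpha = 0.5, stochastic_mask = FALSE, seed = 1L) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  structure(list(eta = eta, mu = mu, X = as.integer(X), tau = tau,
                 refresh_every = as.integer(refresh_every),
                 cert_min = cert_min, conf_floor = conf_floor,
                 nms_iou = nms_iou, detect_conf = detect_conf,
                 normalization = match.arg(normalization),
                 alpha = alpha,
                 stochastic_mask = isTRUE(stochastic_mask),
                 seed = as.integer(seed)),
            class = "pw_adapt_config")
}

#' Initialize the adaptation state from a trained source detector
#'
#' @param source_model a trained `pw_detector`; copied into both the student
#'   and the teacher. The flat source checkpoint is stored immutably.
#' @param config an [adapt_config()].
#' @return a `pw_adapt_state` with flat parameter vectors `theta_s`,
#'   `theta_t`, mask `b` (all zeros until the first refresh), step counter `t`
#'   and `source_checkpoint`.
#' @export
make_adapt_state <- function(source_model, config = adapt_config()) {
  theta <- flatten_params(source_model$params)
  structure(list(
    model = source_model,
    theta_s = theta, theta_t = theta,
    b = structure(rep(0, length(theta)), tau = config$tau, density = 0,
                  class = "pw_param_mask"),
    t = 0L, config = config,
    source_checkpoint = theta,
    fim_sum = NULL, fim_count = 0L), class = "pw_adapt_state")
}

# materialize a detector with the given flat parameters
detector_with <- function(model, theta) {
  model$params <- unflatten_params(theta, model$params)
  model
}

#' Isolated student gradient step
#'
#' Computes the gradient of the detection loss between student predictions
#' and the teacher pseudo-labels over ALL parameters, multiplies it
#' elementwise by the mask `b`, and applies one step of size `eta`:
#' coordinates with `b = 0` are bit-identical before and after. Detections
#' are produced by the UPDATED student.
#'
#' @param state a `pw_adapt_state`.
#' @param scene the current stream image.
#' @param pseudo data frame of certainty-filtered teacher pseudo-labels
#'   (columns `class_id`, `x1`, `y1`, `x2`, `y2`). With zero rows the update
#'   is skipped and the teacher detections are returned.
#' @return list with the updated `state`, `detections` and the student `loss`
#'   (NA when skipped).
#' @export
student_step <- function(state, scene, pseudo) {
  cfg <- state$config
  img <- scene$image
  size <- dim(img)[1]
  x <- array(img / 255, c(dim(img), 1))
  if (is.null(pseudo) || nrow(pseudo) == 0) {
    teacher <- detector_with(state$model, state$theta_t)
    det <- decode(detector_forward(teacher, x)$raw[, , , 1],
                  cfg$detect_conf %||% cfg$conf_floor, cfg$nms_iou,
                  img_size = size)
    return(list(state = state, detections = det, loss = NA_real_))
  }
  student <- detector_with(state$model, state$theta_s)
  fw <- detector_forward(student, x, keep_cache = TRUE)
  ls <- detection_loss(fw$raw, list(pseudo), img_size = size, grad = TRUE)
  g <- flatten_params(detector_backward(student, fw$cache, ls$draw))
  # same global-norm clip as the training loops: single-image detection
  # gradients are much larger than batch-averaged ones, and eta is calibrated
  # for the clipped scale
  nrm <- sqrt(sum(g^2))
  if (is.finite(nrm) && nrm > 10) g <- g * (10 / nrm)
  state$theta_s <- state$theta_s - cfg$eta * (g * as.numeric(state$b))
  student <- detector_with(state$model, state$theta_s)
  det <- decode(detector_forward(student, x)$raw[, , , 1],
                cfg$detect_conf %||% cfg$conf_floor, cfg$nms_iou,
                img_size = size)
  list(state = state, detections = det, loss = ls$loss)
}

#' Isolated exponential-moving-average update of the teacher
#'
#' Coordinates with `b = 1` keep the previous teacher value exactly; the
#' complement takes the classical EMA `mu * Theta_T + (1 - mu) * Theta_S`.
#' With `b` identically zero this reduces to the classical EMA.
#'
#' @param state a `pw_adapt_state` whose student was already updated.
#' @return the state with `theta_t` updated.
#' @export
teacher_ema <- function(state) {
  b <- as.numeric(state$b)
  mu <- state$config$mu
  state$theta_t <- state$theta_t * b +
    (1 - b) * (mu * state$theta_t + (1 - mu) * state$theta_s)
  state
}

# refresh the mask from the Fisher importance accumulated over the window
refresh_mask <- function(state) {
  cfg <- state$config
  if (is.null(state$fim_sum) || state$fim_count == 0L) return(state)
  imp <- fim_importance(state$fim_sum / state$fim_count, state$fim_count,
                        state$config$normalization %||% "rank")
  if (cfg$stochastic_mask) {
    set.seed(child_seed(cfg$seed, "bernoulli", state$t))
    b <- structure(as.numeric(stats::runif(length(imp$K_hat)) < cfg$alpha),
                   tau = cfg$tau, density = cfg$alpha, class = "pw_param_mask")
  } else {
    b <- make_mask(imp, cfg$tau)
  }
  state$b <- b
  state$fim_sum <- NULL
  state$fim_count <- 0L
  state
}

#' Adapt a trained detector over a streaming sequence of images
#'
#' For each image: augmented-view certainty with the teacher, pseudo-label
#' filtering, one isolated student step, one isolated teacher EMA update.
#' Fisher importance is accumulated with the teacher on every image with
#' surviving pseudo-labels and the mask is refreshed every
#' `config$refresh_every` images. Deterministic given the source model,
#' stream and seed; the stored source checkpoint never changes.
#'
#' @param source_model a trained `pw_detector`.
#' @param image_stream ordered list of scenes (environments may change
#'   mid-stream).
#' @param config an [adapt_config()].
#' @return list with `detections` (one `pw_detections` per image), `log`
#'   (per-image tibble: domain tag, detection count, mean certainty, mask
#'   density, student loss) and the final `state`.
#' @export
adapt_stream <- function(source_model, image_stream, config = adapt_config()) {
  state <- make_adapt_state(source_model, config)
  n <- length(image_stream)
  detections <- vector("list", n)
  log <- vector("list", n)
  for (t in seq_len(n)) {
    scene <- image_stream[[t]]
    size <- dim(scene$image)[1]
    teacher <- detector_with(state$model, state$theta_t)
    pl <- teacher_pseudo_labels(teacher, scene, X = config$X,
                                seed = child_seed(config$seed, "stream", t),
                                cert_min = config$cert_min,
                                conf_floor = config$conf_floor,
                                nms_iou = config$nms_iou)
    if (nrow(pl$labels) > 0) {
      g2 <- squared_grad_flat(teacher, scene, pl$labels, size)
      state$fim_sum <- if (is.null(state$fim_sum)) g2 else state$fim_sum + g2
      state$fim_count <- state$fim_count + 1L
    }
    st <- student_step(state, scene, pl$labels)
    state <- st$state
    state <- teacher_ema(state)
    state$t <- t
    if (t %% config$refresh_every == 0L) state <- refresh_mask(state)
    detections[[t]] <- st$detections
    log[[t]] <- data.frame(
      step = t,
      domain_tag = scene$domain_tag,
      n_proxy = pl$n_proxy,
      n_pseudo = nrow(pl$labels),
      mean_certainty = if (length(pl$certainty)) mean(pl$certainty) else NA_real_,
      mask_density = attr(state$b, "density"),
      loss = st$loss)
  }
  log <- do.call(rbind, log)
  class(log) <- c("pw_adapt_log", class(log))
  list(detections = detections, log = log, state = state)
}
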