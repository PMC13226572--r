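# Scaled-down versions of the two headline experiments, used by the test
# suite, the acceptance script and the README example. Problem sizes (400
# training scenes at 96 px, 30 epochs, 100 occluded test scenes; nine
# corruption regimes of 50 images) are the package's standard desk-scale
# study conditions.

#' Occlusion-robustness experiment: dual-branch training vs plain baseline
#'
#' Trains a plain detector and a dual-branch-trained detector on the same
#' synthetic scenes and scores both on occluded test scenes.
#'
#' @param seed integer seed (drives data, training and test occlusion).
#' @param n_train,n_test,image_size,classes,epochs study conditions.
#' @param channels detector architecture.
#' @return list with `baseline` and `maf` eval reports, `gain_map50`
#'   (percentage points), and the two training logs.
#' @export
experiment_maf_gain <- function(seed, n_train = 400L, n_test = 100L,
                                image_size = 96L, classes = 3L, epochs = 30L,
                                channels = c(8L, 16L, 32L, 64L)) {
  train_sc <- generate_scenes(n_train, image_size, classes,
                              seed = child_seed(seed, "train-data"))
  test_sc <- generate_scenes(n_test, image_size, classes,
                             seed = child_seed(seed, "test-data"))
  test_occ <- lapply(test_sc, occlude,
                     spec = occlusion_spec(seed = child_seed(seed, "test-occ")))

  base_cfg <- maf_config(epochs = epochs, use_cae = FALSE, use_agiin = FALSE,
                         use_aux = FALSE, seed = seed)
  base <- train_maf(train_sc, base_cfg, channels_per_stage = channels,
                    classes = classes)
  maf_cfg <- maf_config(epochs = epochs,
                        occlusion = occlusion_spec(seed = child_seed(seed, "occ")),
                        seed = seed)
  maf <- train_maf(train_sc, maf_cfg, channels_per_stage = channels,
                   classes = classes)

  rep_base <- evaluate(base$detector, test_occ)
  rep_maf <- evaluate(maf$detector, test_occ)
  list(baseline = rep_base, maf = rep_maf,
       baseline_detector = base$detector, maf_detector = maf$detector,
       gain_map50 = 100 * (rep_maf$map50 - rep_base$map50),
       baseline_log = base$log, maf_log = maf$log,
       test_occluded = test_occ)
}

#' Streaming-adaptation experiment over the nine corruption regimes
#'
#' Streams `n_per_regime` corrupted images per regime (in the fixed order of
#' [corruption_kinds()]) through [adapt_stream()] and through the frozen
#' source model, and scores mAP50 per regime.
#'
#' @param source_model a trained `pw_detector` (e.g. the baseline from
#'   [experiment_maf_gain()]).
#' @param seed integer seed.
#' @param n_per_regime images per corruption regime.
#' @param severity corruption severity (1-5).
#' @param image_size,classes scene parameters (must match the source model).
#' @return list with `per_regime` (regime, frozen, adapted, delta in mAP50),
#'   `mean_frozen`, `mean_adapted`, and the adaptation `log`.
#' @export
experiment_saodl <- function(source_model, seed, n_per_regime = 50L,
                             severity = 3L, image_size = 96L, classes = 3L) {
  kinds <- corruption_kinds()
  clean <- lapply(seq_along(kinds), function(k)
    generate_scenes(n_per_regime, image_size, classes,
                    seed = child_seed(seed, "regime", k)))
  stream <- list()
  for (k in seq_along(kinds))
    stream <- c(stream, lapply(clean[[k]], corrupt, kind = kinds[k],
                               severity = severity))
  truths <- lapply(stream, function(s) s$boxes)
  regime <- rep(kinds, each = n_per_regime)

  frozen_preds <- detector_predict(source_model, stream, conf_threshold = 0.05)
  ac <- adapt_config(detect_conf = 0.05, seed = child_seed(seed, "adapt"))
  res <- adapt_stream(source_model, stream, ac)

  per <- do.call(rbind, lapply(kinds, function(kd) {
    sel <- which(regime == kd)
    f <- evaluate_detections(frozen_preds[sel], truths[sel], classes = classes)
    a <- evaluate_detections(res$detections[sel], truths[sel], classes = classes)
    data.frame(regime = kd, frozen = f$map50, adapted = a$map50,
               delta = a$map50 - f$map50)
  }))
  list(per_regime = per, mean_frozen = mean(per$frozen),
       mean_adapted = mean(per$adapted), log = res$log)
}
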