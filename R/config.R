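# Structured run configuration: nested sections with defaults equal to the
# training/adaptation protocol values (lr0 0.015, lrf 0.01, epochs 50, batch
# 16, X 8, eta 0.001, mu 0.85, tau 0.3). Unknown keys are rejected; every
# command requires an explicit seed.

#' Default run configuration
#'
#' @param ... named overrides of nested sections, e.g.
#'   `run_config(maf = list(gamma = 1), seed = 3)`.
#' @return a `pw_run_config` (nested named list).
#' @export
run_config <- function(...) {
  defaults <- list(
    data = list(n_train = 400L, n_test = 100L, image_size = 96L, classes = 3L,
                objects = c(2L, 5L)),
    detector = list(channels = c(8L, 16L, 32L, 64L)),
    maf = list(gamma = 0.5, lr0 = 0.015, lrf = 0.01, epochs = 50L,
               batch_size = 16L, momentum = 0.937, warmup_epochs = 3L,
               recon_weight = 0, use_cae = TRUE, use_agiin = TRUE,
               use_aux = TRUE,
               occlusion = list(n_rects = c(1L, 3L), area_frac = c(0.10, 0.30),
                                fill = "gray")),
    tta = list(X = 8L, tau = 0.3, eta = 0.001, mu = 0.85, refresh_every = 64L,
               cert_min = 0.5, conf_floor = 0.25, normalization = "rank",
               alpha = 0.5, stochastic_mask = FALSE, severity = 3L),
    eval = list(conf = 0.25, nms_iou = 0.5, ap_conf = 0.05),
    seed = NULL,
    out_dir = "pestwatch_runs")
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  structure(cfg, class = "pw_run_config")
}

merge_config <- function(base, override, path) {
  for (nm in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        stop("configuration section ", full, " must be a named list")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], full)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read / write a configuration as YAML
#'
#' `load_config(save_config(cfg))` reproduces the configuration exactly;
#' unknown keys in the file are rejected.
#'
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw)
  cfg
}

#' @rdname load_config
#' @param cfg a `pw_run_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

require_seed <- function(cfg) {
  if (is.null(cfg$seed))
    stop("a seed is mandatory: set `seed` in the config or pass --seed")
  as.integer(cfg$seed)
}

occlusion_from_config <- function(cfg, seed) {
  occlusion_spec(n_rects = cfg$maf$occlusion$n_rects,
                 area_frac = cfg$maf$occlusion$area_frac,
                 fill = cfg$maf$occlusion$fill, seed = seed)
}

maf_config_from <- function(cfg, seed, ...) {
  maf_config(gamma = cfg$maf$gamma, lr0 = cfg$maf$lr0, lrf = cfg$maf$lrf,
             epochs = cfg$maf$epochs, batch_size = cfg$maf$batch_size,
             momentum = cfg$maf$momentum, warmup_epochs = cfg$maf$warmup_epochs,
             recon_weight = cfg$maf$recon_weight,
             occlusion = occlusion_from_config(cfg, seed),
             use_cae = cfg$maf$use_cae, use_agiin = cfg$maf$use_agiin,
             use_aux = cfg$maf$use_aux, seed = seed, ...)
}

adapt_config_from <- function(cfg, seed) {
  adapt_config(eta = cfg$tta$eta, mu = cfg$tta$mu, X = cfg$tta$X,
               tau = cfg$tta$tau, refresh_every = cfg$tta$refresh_every,
               cert_min = cfg$tta$cert_min, conf_floor = cfg$tta$conf_floor,
               nms_iou = cfg$eval$nms_iou,
               normalization = cfg$tta$normalization, alpha = cfg$tta$alpha,
               stochastic_mask = cfg$tta$stochastic_mask, seed = seed)
}

write_provenance <- function(cfg, seed, dir, extra = list()) {
  rec <- c(list(config_hash = config_hash(cfg), seed = seed,
                package_version = as.character(utils::packageVersion("pestwatch")),
                timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(rec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
}
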