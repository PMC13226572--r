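# Synthetic pest scenes: textured crop-like backgrounds with small elliptical
# pest sprites carrying per-class color/texture signatures, plus the
# training-time random occlusion and the nine test-time corruptions. Images
# are 8-bit rasters stored as numeric (H, W, 3) arrays with integral values in
# [0, 255]; boxes are 0-based half-open pixel corners.

# fixed per-class sprite palette (RGB 0-255); classes beyond 6 cycle hues
class_palette <- function(classes) {
  base <- rbind(c(72, 48, 28),    # dark brown beetle
                c(168, 52, 40),   # reddish bug
                c(96, 98, 104),   # gray weevil
                c(140, 120, 40),  # ochre moth
                c(40, 70, 120),   # blue-black fly
                c(120, 60, 110))  # purplish mite
  base[((seq_len(classes) - 1) %% nrow(base)) + 1, , drop = FALSE]
}

# bilinear upsample of a small matrix to (H, W) via interpolation matrices
upsample_bilinear <- function(m, H, W) {
  interp_mat <- function(n_out, n_in) {
    pos <- (seq_len(n_out) - 0.5) / n_out * n_in - 0.5
    pos <- pmin(pmax(pos, 0), n_in - 1)
    lo <- floor(pos); hi <- pmin(lo + 1, n_in - 1); fr <- pos - lo
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), lo + 1)] <- 1 - fr
    A[cbind(seq_len(n_out), hi + 1)] <- A[cbind(seq_len(n_out), hi + 1)] + fr
    A
  }
  interp_mat(H, nrow(m)) %*% m %*% t(interp_mat(W, ncol(m)))
}

clamp8 <- function(img) {
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  img
}

make_background <- function(size) {
  g <- 7L
  img <- array(0, c(size, size, 3))
  base <- c(70, 110, 55) # crop-green ground tone
  for (ch in 1:3) {
    coarse <- matrix(base[ch] + stats::rnorm(g * g, 0, 22), g, g)
    img[, , ch] <- upsample_bilinear(coarse, size, size)
  }
  img + array(stats::rnorm(size * size * 3, 0, 5), c(size, size, 3))
}

# Draw one elliptical sprite; returns modified image and the tight box.
draw_sprite <- function(img, cx, cy, a, b, theta, color, size) {
  r <- ceiling(max(a, b)) + 1L
  xs <- max(0L, floor(cx - r)):min(size - 1L, ceiling(cx + r))
  ys <- max(0L, floor(cy - r)):min(size - 1L, ceiling(cy + r))
  px <- outer(rep(1, length(ys)), xs + 0.5)
  py <- outer(ys + 0.5, rep(1, length(xs)))
  dx <- px - cx; dy <- py - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  mask <- (u^2 + v^2) <= 1
  if (!any(mask)) return(NULL)
  shade <- 1 - 0.35 * (u^2 + v^2)              # center highlight
  spots <- stats::rnorm(length(mask), 0, 14)   # body texture
  idx <- which(mask, arr.ind = TRUE)
  for (ch in 1:3) {
    plane <- img[, , ch]
    vals <- color[ch] * shade[mask] + spots[which(mask)]
    plane[cbind(ys[idx[, 1]] + 1L, xs[idx[, 2]] + 1L)] <- vals
    img[, , ch] <- plane
  }
  cols_any <- apply(mask, 2, any); rows_any <- apply(mask, 1, any)
  box <- c(x1 = xs[which(cols_any)[1]],
           y1 = ys[which(rows_any)[1]],
           x2 = xs[max(which(cols_any))] + 1L,
           y2 = ys[max(which(rows_any))] + 1L)
  list(img = img, box = box)
}

#' Generate synthetic labeled pest scenes
#'
#' Each scene is a textured crop-like background with `objects_per_scene`
#' elliptical pest sprites; classes carry distinct color signatures. Boxes are
#' tight around the drawn sprite mask, 0-based half-open pixel corners.
#' Generation is fully deterministic under `seed`.
#'
#' @param n number of scenes (>= 1).
#' @param image_size side length in pixels (>= 32).
#' @param classes number of classes (>= 1).
#' @param objects_per_scene integer range `c(min, max)`.
#' @param seed integer seed.
#' @return list of scenes, each a list with `image` ((H, W, 3) 8-bit array),
#'   `boxes` (data frame `class_id`, `x1`, `y1`, `x2`, `y2`), `domain_tag`,
#'   `seed`.
#' @export
generate_scenes <- function(n, image_size = 96L, classes = 3L,
                            objects_per_scene = c(2L, 5L), seed = 1L) {
  if (n < 1) stop("configuration error: n must be >= 1")
  if (image_size < 32) stop("configuration error: image_size must be >= 32")
  if (classes < 1) stop("configuration error: classes must be >= 1")
  if (length(objects_per_scene) == 1) objects_per_scene <- rep(objects_per_scene, 2)
  pal <- class_palette(classes)
  lapply(seq_len(n), function(k) {
    sseed <- child_seed(seed, "scene", k)
    set.seed(sseed)
    img <- make_background(image_size)
    n_obj <- sample(objects_per_scene[1]:objects_per_scene[2], 1)
    centers <- matrix(numeric(), 0, 2)
    boxes <- list()
    min_dist <- min(18, image_size / 4)
    margin <- 12
    for (o in seq_len(n_obj)) {
      ok <- FALSE
      for (try in 1:300) {
        cx <- stats::runif(1, margin, image_size - margin)
        cy <- stats::runif(1, margin, image_size - margin)
        if (nrow(centers) == 0 ||
            min(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)) >= min_dist) {
          ok <- TRUE; break
        }
      }
      if (!ok) break
      centers <- rbind(centers, c(cx, cy))
      cls <- sample.int(classes, 1) - 1L
      a <- stats::runif(1, 6, 11)
      b <- stats::runif(1, 3.5, a)
      theta <- stats::runif(1, 0, pi)
      col <- pal[cls + 1, ] * stats::runif(1, 0.85, 1.15)
      d <- draw_sprite(img, cx, cy, a, b, theta, col, image_size)
      if (is.null(d)) next
      img <- d$img
      boxes[[length(boxes) + 1]] <- data.frame(class_id = cls,
                                               x1 = d$box[1], y1 = d$box[2],
                                               x2 = d$box[3], y2 = d$box[4])
    }
    boxes <- if (length(boxes)) do.call(rbind, boxes) else
      data.frame(class_id = integer(), x1 = numeric(), y1 = numeric(),
                 x2 = numeric(), y2 = numeric())
    rownames(boxes) <- NULL
    structure(list(image = clamp8(img), boxes = boxes,
                   domain_tag = "clean", seed = sseed),
              class = "pw_scene")
  })
}

# batch scenes into a (H, W, 3, B) float array in [0, 1]
scenes_to_input <- function(scenes) {
  H <- dim(scenes[[1]]$image)[1]; W <- dim(scenes[[1]]$image)[2]
  x <- array(0, c(H, W, 3, length(scenes)))
  for (b in seq_along(scenes)) x[, , , b] <- scenes[[b]]$image / 255
  x
}

# ---- occlusion ---------------------------------------------------------------

#' Specify the random-occlusion generator
#'
#' @param n_rects integer range `c(min, max)` of rectangles per image (1-3 by
#'   default).
#' @param area_frac range of per-rectangle area fractions (default 0.10-0.30).
#' @param fill `"gray"` (uniform 128) or `"noise"` (uniform random pixels).
#' @param seed integer seed.
#' @export
occlusion_spec <- function(n_rects = c(1L, 3L), area_frac = c(0.10, 0.30),
                           fill = c("gray", "noise"), seed = 1L) {
  fill <- match.arg(fill)
  if (length(n_rects) == 1) n_rects <- rep(n_rects, 2)
  if (length(area_frac) == 1) area_frac <- rep(area_frac, 2)
  if (any(area_frac <= 0) || any(area_frac > 0.9) || area_frac[1] > area_frac[2])
    stop("configuration error: area_frac must lie in (0, 0.9] with lower <= upper")
  if (n_rects[1] < 1 || n_rects[1] > n_rects[2])
    stop("configuration error: invalid n_rects range")
  structure(list(n_rects = as.integer(n_rects), area_frac = area_frac,
                 fill = fill, seed = as.integer(seed)),
            class = "pw_occlusion_spec")
}

#' Paint random occluding rectangles over a scene
#'
#' Ground-truth boxes are NOT modified: labels keep describing the full,
#' un-occluded object, so detectors are scored on recovering occluded objects.
#' Deterministic under `spec$seed`.
#'
#' @param scene a scene from [generate_scenes()].
#' @param spec an [occlusion_spec()].
#' @return the occluded copy of `scene`.
#' @export
occlude <- function(scene, spec = occlusion_spec()) {
  stopifnot(inherits(spec, "pw_occlusion_spec"))
  set.seed(child_seed(spec$seed, "occlude", scene$seed))
  img <- scene$image
  H <- dim(img)[1]; W <- dim(img)[2]
  k <- if (spec$n_rects[1] == spec$n_rects[2]) spec$n_rects[1] else
    sample(spec$n_rects[1]:spec$n_rects[2], 1)
  for (r in seq_len(k)) {
    frac <- stats::runif(1, spec$area_frac[1], spec$area_frac[2])
    area <- frac * H * W
    aspect <- stats::runif(1, 0.5, 2)
    rw <- max(1, min(W, round(sqrt(area * aspect))))
    rh <- max(1, min(H, round(area / rw)))
    x0 <- sample.int(W - rw + 1, 1)
    y0 <- sample.int(H - rh + 1, 1)
    if (spec$fill == "gray") {
      img[y0:(y0 + rh - 1), x0:(x0 + rw - 1), ] <- 128
    } else {
      img[y0:(y0 + rh - 1), x0:(x0 + rw - 1), ] <-
        array(round(stats::runif(rh * rw * 3, 0, 255)), c(rh, rw, 3))
    }
  }
  out <- scene
  out$image <- img
  out$occluded <- TRUE
  out
}

# ---- corruptions -------------------------------------------------------------

#' The nine supported corruption kinds
#' @export
corruption_kinds <- function() {
  c("fog", "rain", "snow", "bright", "dark",
    "gaussian_noise", "salt_pepper", "motion_blur", "jpeg")
}

#' Severity-to-parameter ladder for each corruption kind
#'
#' Five severity levels per kind; the returned list can be edited and passed
#' back to [corrupt()] to override individual parameters.
#'
#' @param kind one of [corruption_kinds()].
#' @param severity integer 1-5.
#' @export
corruption_params <- function(kind, severity = 3L) {
  kind <- match.arg(kind, corruption_kinds())
  if (severity < 1 || severity > 5) stop("severity must be 1-5")
  s <- as.integer(severity)
  switch(kind,
    fog = list(transmission = 1 - 0.05 * s),
    rain = list(n_streaks = 30L * s, length = 8L + 2L * s, alpha = 0.55),
    snow = list(n_flakes = 25L * s, radius = 1.2 + 0.2 * s, alpha = 0.8),
    bright = list(gain = 1 + 0.15 * s),
    dark = list(gain = 1 / (1 + 0.15 * s)),
    gaussian_noise = list(sd = 10 * s),
    salt_pepper = list(density = 0.03 * s),
    motion_blur = list(len = 2L * s + 1L),
    jpeg = list(quality = c(80L, 60L, 40L, 25L, 15L)[s]))
}

blend_line <- function(img, x0, y0, dx, dy, len, color, alpha) {
  H <- dim(img)[1]; W <- dim(img)[2]
  t <- seq(0, len, by = 0.7)
  xs <- round(x0 + t * dx); ys <- round(y0 + t * dy)
  keep <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
  if (!any(keep)) return(img)
  pix <- unique(cbind(ys[keep], xs[keep]))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[pix] <- (1 - alpha) * plane[pix] + alpha * color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Apply one of nine environmental corruptions to a scene
#'
#' Fog is a convex blend toward white; rain/snow stamp seeded streaks/flakes;
#' bright/dark apply a multiplicative gain; Gaussian noise is additive
#' zero-mean; salt-and-pepper flips whole pixels to 0/255 at the severity
#' density; motion blur convolves with a normalized linear kernel; jpeg does a
#' real encode/decode round trip at the severity quality. Shape, dtype and
#' boxes are preserved; deterministic under the scene seed and the kind.
#'
#' @param scene a scene.
#' @param kind one of [corruption_kinds()].
#' @param severity integer 1-5.
#' @param params optional overrides of [corruption_params()].
#' @return corrupted copy of `scene`, `domain_tag` set to `kind`.
#' @export
corrupt <- function(scene, kind, severity = 3L, params = NULL) {
  kind <- match.arg(kind, corruption_kinds())
  p <- utils::modifyList(corruption_params(kind, severity), as.list(params))
  set.seed(child_seed(scene$seed, "corrupt", kind, severity))
  img <- scene$image
  H <- dim(img)[1]; W <- dim(img)[2]
  img <- switch(kind,
    fog = p$transmission * img + (1 - p$transmission) * 255,
    bright = img * p$gain,
    dark = img * p$gain,
    gaussian_noise = img + array(stats::rnorm(length(img), 0, p$sd), dim(img)),
    salt_pepper = {
      n_pix <- H * W
      n_hit <- round(p$density * n_pix)
      hit <- sample.int(n_pix, n_hit)
      val <- ifelse(stats::runif(n_hit) < 0.5, 0, 255)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[hit] <- val
        img[, , ch] <- plane
      }
      img
    },
    rain = {
      ang <- stats::runif(1, 60, 80) * pi / 180
      dx <- cos(ang); dy <- sin(ang)
      for (i in seq_len(p$n_streaks))
        img <- blend_line(img, stats::runif(1, 1, W), stats::runif(1, 1, H),
                          dx, dy, p$length, c(205, 210, 220), p$alpha)
      img
    },
    snow = {
      for (i in seq_len(p$n_flakes)) {
        cx <- stats::runif(1, 1, W); cy <- stats::runif(1, 1, H)
        rr <- p$radius * stats::runif(1, 0.6, 1.4)
        xs <- max(1, floor(cx - rr)):min(W, ceiling(cx + rr))
        ys <- max(1, floor(cy - rr)):min(H, ceiling(cy + rr))
        d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
        m <- which(d2 <= rr^2, arr.ind = TRUE)
        if (nrow(m) == 0) next
        pix <- cbind(ys[m[, 1]], xs[m[, 2]])
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[pix] <- (1 - p$alpha) * plane[pix] + p$alpha * 245
          img[, , ch] <- plane
        }
      }
      img
    },
    motion_blur = {
      L <- p$len
      ker <- matrix(0, L, L)
      ori <- sample(0:3, 1)
      if (ori == 0) ker[(L + 1) / 2, ] <- 1
      else if (ori == 1) ker[, (L + 1) / 2] <- 1
      else if (ori == 2) diag(ker) <- 1
      else ker[cbind(L:1, 1:L)] <- 1
      ker <- ker / sum(ker)
      xin <- array(img, c(H, W, 1, 3))
      w <- array(ker, c(L, L, 1, 1))
      out <- conv2d_fwd(xin, w, 0, 1L, as.integer((L - 1) / 2))
      array(out, c(H, W, 3))
    },
    jpeg = {
      tmp <- tempfile(fileext = ".jpg")
      on.exit(unlink(tmp), add = TRUE)
      eb <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
      EBImage::writeImage(eb, tmp, quality = p$quality)
      back <- EBImage::readImage(tmp)
      aperm(back@.Data, c(2, 1, 3)) * 255
    })
  out <- scene
  out$image <- clamp8(img)
  out$domain_tag <- kind
  out
}

# ---- annotation I/O ----------------------------------------------------------

scene_stem <- function(k) sprintf("scene_%05d", k)

#' Write scenes as YOLO-txt labels (and PNG images)
#'
#' One label file per image, lines `class cx cy w h` with coordinates
#' normalized to [0, 1] at 6-decimal fixed precision.
#'
#' @param scenes list of scenes.
#' @param dir output directory (created if needed).
#' @param images also write `scene_*.png` images (default TRUE).
#' @return invisible character vector of label paths.
#' @export
write_labels <- function(scenes, dir, images = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(scenes))
  for (k in seq_along(scenes)) {
    sc <- scenes[[k]]
    H <- dim(sc$image)[1]; W <- dim(sc$image)[2]
    b <- sc$boxes
    lines <- if (nrow(b) > 0) sprintf("%d %.6f %.6f %.6f %.6f",
                                      b$class_id,
                                      (b$x1 + b$x2) / 2 / W, (b$y1 + b$y2) / 2 / H,
                                      (b$x2 - b$x1) / W, (b$y2 - b$y1) / H)
             else character()
    paths[k] <- file.path(dir, paste0(scene_stem(k), ".txt"))
    writeLines(lines, paths[k])
    if (images) write_scene_png(sc, file.path(dir, paste0(scene_stem(k), ".png")))
  }
  invisible(paths)
}

#' Read YOLO-txt labels (+ PNG images) back into scenes
#'
#' @param dir directory written by [write_labels()].
#' @return list of scenes; malformed label lines raise an error naming the
#'   file and line number.
#' @export
read_labels <- function(dir) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(txts, function(f) {
    png_path <- sub("\\.txt$", ".png", f)
    if (!file.exists(png_path))
      stop("no image found for label file ", f)
    img <- read_scene_png(png_path)
    H <- dim(img)[1]; W <- dim(img)[2]
    lines <- readLines(f)
    boxes <- list()
    for (li in seq_along(lines)) {
      if (!nzchar(trimws(lines[li]))) next
      parts <- strsplit(trimws(lines[li]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(parts) != 5 || anyNA(vals))
        stop(sprintf("parse error in %s at line %d: '%s'", f, li, lines[li]))
      cx <- vals[2] * W; cy <- vals[3] * H
      w <- vals[4] * W; h <- vals[5] * H
      boxes[[length(boxes) + 1]] <- data.frame(
        class_id = as.integer(vals[1]),
        x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2)
    }
    boxes <- if (length(boxes)) do.call(rbind, boxes) else
      data.frame(class_id = integer(), x1 = numeric(), y1 = numeric(),
                 x2 = numeric(), y2 = numeric())
    structure(list(image = img, boxes = boxes, domain_tag = "clean", seed = 0L),
              class = "pw_scene")
  })
}

#' @rdname write_labels
#' @param scene a single scene; `path` output file.
#' @export
write_scene_png <- function(scene, path) {
  png::writePNG(scene$image / 255, path)
  invisible(path)
}

#' @rdname read_labels
#' @param path a PNG written by [write_scene_png()].
#' @export
read_scene_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(img, c(dim(img), 3))
  clamp8(img[, , 1:3] * 255)
}

#' Export scenes to COCO-JSON
#'
#' Boxes use COCO `[x, y, w, h]` pixel format (0-based).
#' @param scenes list of scenes; `path` output .json file.
#' @export
write_coco <- function(scenes, path) {
  images <- list(); anns <- list(); aid <- 0L
  classes <- 0L
  for (k in seq_along(scenes)) {
    sc <- scenes[[k]]
    H <- dim(sc$image)[1]; W <- dim(sc$image)[2]
    images[[k]] <- list(id = k, file_name = paste0(scene_stem(k), ".png"),
                        width = W, height = H)
    b <- sc$boxes
    classes <- max(classes, if (nrow(b)) max(b$class_id) + 1L else 0L)
    for (r in seq_len(nrow(b))) {
      aid <- aid + 1L
      anns[[aid]] <- list(id = aid, image_id = k,
                          category_id = b$class_id[r],
                          bbox = c(b$x1[r], b$y1[r], b$x2[r] - b$x1[r], b$y2[r] - b$y1[r]),
                          area = (b$x2[r] - b$x1[r]) * (b$y2[r] - b$y1[r]),
                          iscrowd = 0L)
    }
  }
  cats <- lapply(seq_len(max(classes, 1L)) - 1L,
                 function(c) list(id = c, name = paste0("pest_", c)))
  jsonlite::write_json(list(images = images, annotations = anns, categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-JSON annotation file
#' @param path .json file written by [write_coco()].
#' @return list with one element per image: `file_name`, `width`, `height`,
#'   `boxes` in corner format.
#' @export
read_coco <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  imgs <- d$images
  anns <- d$annotations
  lapply(seq_len(nrow(imgs)), function(k) {
    rows <- anns[anns$image_id == imgs$id[k], , drop = FALSE]
    boxes <- if (nrow(rows)) {
      bb <- do.call(rbind, rows$bbox)
      data.frame(class_id = as.integer(rows$category_id),
                 x1 = bb[, 1], y1 = bb[, 2],
                 x2 = bb[, 1] + bb[, 3], y2 = bb[, 2] + bb[, 4])
    } else data.frame(class_id = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric())
    list(file_name = imgs$file_name[k], width = imgs$width[k],
         height = imgs$height[k], boxes = boxes)
  })
}
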