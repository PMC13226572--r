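# Convolutional autoencoder over intermediate feature maps. Two stride-2
# 2x2 convolutions halve the channel count at each step (D -> D/2 -> D/4),
# producing a code z with strictly smaller spatial extent and channel count;
# two mirrored 2x2 transposed convolutions map z back to the input shape.
# GELU activations throughout, linear output layer. During dual-branch
# training the block learns to reconstruct occlusion-damaged features purely
# through the detection loss; an explicit reconstruction objective is only
# used by the diagnostic trainer [train_cae()].

#' Create a feature-inpainting autoencoder block
#'
#' @param channels input channel count `D`; must be divisible by 4 (code has
#'   `D/4` channels).
#' @return a `pw_cae`.
#' @export
make_cae <- function(channels) {
  if (channels %% 4 != 0)
    stop("configuration error: CAE channels must be divisible by 4")
  d <- as.integer(channels)
  structure(list(
    enc1 = conv_layer(2, 2, d, d %/% 2),
    enc2 = conv_layer(2, 2, d %/% 2, d %/% 4),
    dec1 = conv_layer(2, 2, d %/% 4, d %/% 2),
    dec2 = conv_layer(2, 2, d %/% 2, d)),
    channels = d, class = "pw_cae")
}

#' Autoencoder forward pass
#'
#' @param x feature map, dim (H, W, D, B) with H and W divisible by 4.
#' @param block a `pw_cae` built for `D` channels.
#' @param keep_cache keep intermediates (and the code `z`) for the backward
#'   pass.
#' @return reconstruction `xhat` with exactly the shape of `x`; when
#'   `keep_cache = TRUE` the attribute `"cache"` holds the intermediates and
#'   `"z"` the bottleneck code (dim (H/4, W/4, D/4, B)).
#' @export
cae_forward <- function(x, block, keep_cache = FALSE) {
  dm <- dim(x)
  if (dm[1] %% 4 != 0 || dm[2] %% 4 != 0)
    stop("shape error: H and W must be divisible by 4 (pad the feature map)")
  if (dm[3] != attr(block, "channels"))
    stop("shape error: feature map has ", dm[3], " channels, CAE expects ",
         attr(block, "channels"))
  e1 <- conv_fwd(x, block$enc1, stride = 2L)
  g1 <- gelu_fwd2(e1)
  e2 <- conv_fwd(g1$y, block$enc2, stride = 2L)
  g2 <- gelu_fwd2(e2)
  z <- g2$y
  d1 <- tconv_fwd(z, block$dec1)
  g3 <- gelu_fwd2(d1)
  xhat <- tconv_fwd(g3$y, block$dec2)
  if (keep_cache) {
    attr(xhat, "cache") <- list(x = x, h1 = g1$y, dg1 = g1$d, dg2 = g2$d,
                                z = z, h2 = g3$y, dg3 = g3$d)
    attr(xhat, "z") <- z
  }
  xhat
}

# Backward through the CAE; returns d(input) and parameter gradients.
cae_bwd <- function(block, cache, dxhat) {
  b2 <- tconv_bwd(cache$h2, block$dec2, dxhat)
  dd1 <- b2$dx * cache$dg3
  b1 <- tconv_bwd(cache$z, block$dec1, dd1)
  de2 <- b1$dx * cache$dg2
  be2 <- conv_bwd(cache$h1, block$enc2, de2, stride = 2L)
  de1 <- be2$dx * cache$dg1
  be1 <- conv_bwd(cache$x, block$enc1, de1, stride = 2L)
  list(dx = be1$dx,
       grads = list(enc1 = list(w = be1$dw, b = be1$db),
                    enc2 = list(w = be2$dw, b = be2$db),
                    dec1 = list(w = b1$dw, b = b1$db),
                    dec2 = list(w = b2$dw, b = b2$db)))
}

#' Train a CAE on (damaged, clean) feature pairs
#'
#' Diagnostic reconstruction trainer: plain SGD on the squared error
#' `||xhat - x_clean||^2 / n`. Used to verify that the block can learn feature
#' inpainting in isolation; inside [train_maf()] the CAE is trained through
#' the detection loss instead.
#'
#' @param block a `pw_cae`.
#' @param x_damaged,x_clean congruent feature maps (H, W, D, B).
#' @param steps gradient steps; `lr` learning rate.
#' @return list with the trained `block` and the per-step `mse` vector.
#' @export
train_cae <- function(block, x_damaged, x_clean, steps = 200L, lr = 0.05) {
  mse <- numeric(steps)
  n <- length(x_clean)
  for (t in seq_len(steps)) {
    xhat <- cae_forward(x_damaged, block, keep_cache = TRUE)
    err <- xhat - x_clean
    mse[t] <- sum(err^2) / n
    bw <- cae_bwd(block, attr(xhat, "cache"), 2 * err / n)
    for (nm in c("enc1", "enc2", "dec1", "dec2")) {
      block[[nm]]$w <- block[[nm]]$w - lr * bw$grads[[nm]]$w
      block[[nm]]$b <- block[[nm]]$b - lr * bw$grads[[nm]]$b
    }
  }
  list(block = block, mse = mse)
}
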