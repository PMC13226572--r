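# Adaptive gated cross-branch feature fusion. A gate owns two learnable 1x1
# channel-mixing maps over the sender's channels: (M, a) produce the sigmoid
# flow coefficient alpha, (N, b) produce the transformed message. The fused
# receiver input is alpha (*) GELU(N f_x + b) (+) f_y, elementwise, so the
# receiver falls back to a plain skip connection as the gate saturates closed.

#' Create a fusion gate
#'
#' @param sender_channels,receiver_channels channel counts of the two branches
#'   at the exchange point (equal for twin-architecture branches).
#' @param bias_init initial gate bias `a` (0 starts the gate half-open).
#' @return a `pw_gate` with 1x1 conv layers `M` (gate) and `N` (message).
#' @export
make_gate <- function(sender_channels, receiver_channels = sender_channels,
                      bias_init = 0) {
  g <- list(M = conv_layer(1, 1, sender_channels, receiver_channels),
            N = conv_layer(1, 1, sender_channels, receiver_channels))
  g$M$b[] <- bias_init
  structure(g, class = "pw_gate")
}

#' Information-flow coefficients of a gate
#'
#' `alpha = Sigmoid(M f + a)` over the sender feature map; every entry lies
#' strictly in (0, 1).
#'
#' @param sender feature map, dim (H, W, C_sender, B).
#' @param gate a `pw_gate` whose `M` expects `C_sender` input channels.
#' @return array with the receiver's channel count, same spatial dims.
#' @export
gate_coefficients <- function(sender, gate) {
  if (dim(sender)[3] != dim(gate$M$w)[3])
    stop("shape error: sender has ", dim(sender)[3],
         " channels, gate expects ", dim(gate$M$w)[3])
  sigmoid(conv_fwd(sender, gate$M))
}

#' Gated fusion of a sender message into a receiver branch
#'
#' `f_out = alpha (*) GELU(N f_sender + b) (+) f_receiver` with
#' `alpha = Sigmoid(M f_sender + a)`. Returns the receiver's next-layer input;
#' with `keep_cache = TRUE` the intermediates needed by [fuse_bwd()] are
#' attached.
#'
#' @param sender,receiver_prev feature maps with identical spatial dims and
#'   batch; the gate output channels must equal the receiver channels.
#' @param gate a `pw_gate`.
#' @param keep_cache keep intermediates for the backward pass.
#' @return fused feature map (attribute `"cache"` when requested).
#' @export
fuse <- function(sender, receiver_prev, gate, keep_cache = FALSE) {
  if (!all(dim(sender)[c(1, 2, 4)] == dim(receiver_prev)[c(1, 2, 4)]))
    stop("shape error: sender and receiver spatial/batch dims differ")
  if (dim(sender)[3] != dim(gate$M$w)[3])
    stop("shape error: sender channels do not match gate input")
  u <- conv_fwd(sender, gate$M)
  alpha <- sigmoid(u)
  if (dim(alpha)[3] != dim(receiver_prev)[3])
    stop("shape error: gate output channels do not match receiver")
  v <- conv_fwd(sender, gate$N)
  gg <- gelu_fwd2(v)
  out <- fuse_fwd_elem(alpha, gg$y, receiver_prev)
  if (keep_cache)
    attr(out, "cache") <- list(sender = sender, alpha = alpha,
                               g = gg$y, gd = gg$d)
  out
}

# Backward through fuse: returns gradients w.r.t. sender, receiver and the
# gate parameters.
fuse_bwd <- function(gate, cache, dout) {
  dreceiver <- dout
  el <- fuse_bwd_elem(dout, cache$alpha, cache$g, cache$gd)
  bM <- conv_bwd(cache$sender, gate$M, el$du)
  bN <- conv_bwd(cache$sender, gate$N, el$dv)
  list(dsender = bM$dx + bN$dx, dreceiver = dreceiver,
       grads = list(M = list(w = bM$dw, b = bM$db),
                    N = list(w = bN$dw, b = bN$db)))
}
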