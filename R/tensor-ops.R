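# Low-level tensor helpers shared by the detector, the autoencoder blocks and
# the gates. Feature maps are numeric arrays with dim (H, W, C, B); parameters
# live in nested named lists of conv layers, each `list(w = array(kh, kw, Cin,
# Cout), b = numeric(Cout))`.

sigmoid <- function(x) sigmoid_fwd(x)

#' @noRd
gelu <- function(x) gelu_fwd(x)

#' Make a convolution layer with seeded He-style initialization
#' @noRd
conv_layer <- function(kh, kw, cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (kh * kw * cin))
  list(w = array(stats::rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout)),
       b = numeric(cout))
}

conv_fwd <- function(x, layer, stride = 1L, pad = 0L) {
  conv2d_fwd(x, layer$w, layer$b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, layer, dy, stride = 1L, pad = 0L, need_dx = TRUE) {
  conv2d_bwd(x, layer$w, dy, as.integer(stride), as.integer(pad), need_dx)
}

tconv_fwd <- function(x, layer) tconv2d_fwd(x, layer$w, layer$b)
tconv_bwd <- function(x, layer, dy) tconv2d_bwd(x, layer$w, dy)

# ---- parameter-vector (flat) utilities -------------------------------------

#' Flatten a nested parameter list into a single numeric vector
#'
#' The layout (ordered names, shapes and offsets) is attached as an attribute
#' so that [unflatten_params()] is an exact inverse: `unflatten(flatten(p))`
#' reproduces every entry bit for bit.
#'
#' @param params nested named list whose leaves are numeric vectors/arrays.
#' @return numeric vector with attribute `"layout"`.
#' @export
flatten_params <- function(params) {
  leaves <- list()
  layout <- list()
  walk <- function(node, path) {
    if (is.list(node)) {
      for (nm in names(node)) walk(node[[nm]], c(path, nm))
    } else {
      key <- paste(path, collapse = ".")
      leaves[[key]] <<- as.numeric(node)
      layout[[key]] <<- if (is.null(dim(node))) length(node) else dim(node)
    }
  }
  walk(params, character())
  v <- unlist(leaves, use.names = FALSE)
  attr(v, "layout") <- layout
  v
}

#' Restore a nested parameter list from a flat vector
#'
#' @param v numeric vector of length [n_params()].
#' @param template nested list with the target structure (values ignored).
#' @return nested list shaped like `template`.
#' @export
unflatten_params <- function(v, template) {
  offset <- 0L
  walk <- function(node) {
    if (is.list(node)) {
      for (nm in names(node)) node[[nm]] <- walk(node[[nm]])
      node
    } else {
      n <- length(node)
      out <- v[(offset + 1L):(offset + n)]
      offset <<- offset + n
      if (!is.null(dim(node))) dim(out) <- dim(node)
      out
    }
  }
  walk(template)
}

#' Total number of scalar parameters in a nested parameter list
#' @param params nested parameter list (or an object with a `$params` field).
#' @export
n_params <- function(params) {
  if (!is.null(params$params)) params <- params$params
  length(flatten_params(params))
}

# elementwise: template-shaped list of zeros
zero_like <- function(params) {
  walk <- function(node) {
    if (is.list(node)) lapply(node, walk) else {
      z <- numeric(length(node)); dim(z) <- dim(node); z
    }
  }
  walk(params)
}

# a + s * b over two congruent nested lists
axpy_params <- function(a, b, s = 1) {
  walk <- function(x, y) {
    if (is.list(x)) {
      for (nm in names(x)) x[[nm]] <- walk(x[[nm]], y[[nm]])
      x
    } else x + s * y
  }
  walk(a, b)
}

# obj <- obj - lr * grads, walking the gradient structure so that any extra
# attributes (classes) on obj survive
apply_grads <- function(obj, grads, lr) {
  for (nm in names(grads)) {
    if (is.list(grads[[nm]])) obj[[nm]] <- apply_grads(obj[[nm]], grads[[nm]], lr)
    else obj[[nm]] <- obj[[nm]] - lr * grads[[nm]]
  }
  obj
}

param_sq_norms <- function(grads) {
  walk <- function(node) {
    if (is.list(node) && !is.null(names(node)) && all(c("w", "b") %in% names(node)))
      sum(node$w^2) + sum(node$b^2)
    else if (is.list(node)) sum(vapply(node, walk, numeric(1)))
    else sum(node^2)
  }
  walk(grads)
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, ...) {
  mix <- as.numeric(seed)
  for (k in list(...)) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    mix <- (mix * 69069 + kk * 2654435761) %% 2147483647
  }
  as.integer(mix %% 2147483647L)
}
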