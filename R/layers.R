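## Primitive trainable layers. Each layer is an environment carrying `params`
## (named list of arrays), `grads` (same shapes, accumulated by ly_backward),
## and whatever forward cache its backward pass needs. Composite blocks
## (mixer block, Swin cycle, ...) hold child layers under `children`.

new_layer <- function(cls, params = list(), fields = list()) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$grads <- lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
  e$children <- list()
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(cls, "scmix_layer")
  e
}

ly_forward <- function(layer, x, training = FALSE) UseMethod("ly_forward")
ly_backward <- function(layer, gout) UseMethod("ly_backward")

## recursively collect every primitive layer that owns parameters
collect_layers <- function(layer) {
  out <- list()
  if (length(layer$params)) out <- list(layer)
  for (ch in layer$children) out <- c(out, collect_layers(ch))
  out
}

zero_grads <- function(layers) {
  for (ly in layers) {
    for (nm in names(ly$grads)) ly$grads[[nm]][] <- 0
  }
  invisible(NULL)
}

n_params <- function(layer) {
  sum(vapply(collect_layers(layer),
             function(ly) sum(vapply(ly$params, length, 1L)), 1))
}

## dense ---------------------------------------------------------------------

new_dense <- function(d_in, d_out, init_std = 0.02, zero_init = FALSE) {
  W <- if (zero_init) matrix(0, d_in, d_out) else
    matrix(init_trunc_normal(d_in * d_out, init_std), d_in, d_out)
  new_layer("ly_dense", params = list(W = W, b = numeric(d_out)))
}

#' @export
ly_forward.ly_dense <- function(layer, x, training = FALSE) {
  if (training) layer$x <- x
  add_rowvec(x %*% layer$params$W, layer$params$b)
}

#' @export
ly_backward.ly_dense <- function(layer, gout) {
  layer$grads$W <- layer$grads$W + crossprod(layer$x, gout)
  layer$grads$b <- layer$grads$b + colSums(gout)
  gout %*% t(layer$params$W)
}

## layer normalization over the last (embedding) axis; input is a matrix
## (rows = tokens, cols = embedding). eps fixed at 1e-5.

new_layernorm <- function(d, eps = 1e-5) {
  new_layer("ly_layernorm",
            params = list(gamma = rep(1, d), beta = numeric(d)),
            fields = list(eps = eps))
}

#' @export
ly_forward.ly_layernorm <- function(layer, x, training = FALSE) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- xc * inv
  if (training) {
    layer$xhat <- xhat
    layer$inv <- inv
  }
  add_rowvec(xhat * rep(layer$params$gamma, each = nrow(x)),
             layer$params$beta)
}

#' @export
ly_backward.ly_layernorm <- function(layer, gout) {
  n <- nrow(gout)
  xhat <- layer$xhat
  layer$grads$gamma <- layer$grads$gamma + colSums(gout * xhat)
  layer$grads$beta <- layer$grads$beta + colSums(gout)
  dxhat <- gout * rep(layer$params$gamma, each = n)
  layer$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
}

## batch normalization, per channel (columns of a (pixels x channels) matrix).
## Training mode normalizes by batch statistics; running moments are seeded
## from the first training batch and then decayed with momentum 0.9;
## inference mode uses the running moments.

new_batchnorm <- function(c, momentum = 0.9, eps = 1e-5) {
  new_layer("ly_batchnorm",
            params = list(gamma = rep(1, c), beta = numeric(c)),
            fields = list(momentum = momentum, eps = eps, seen = FALSE,
                          run_mean = numeric(c), run_var = rep(1, c)))
}

#' @export
ly_forward.ly_batchnorm <- function(layer, x, training = FALSE) {
  m <- nrow(x)
  if (training) {
    res <- bn_fwd_cpp(x, layer$params$gamma, layer$params$beta, layer$eps)
    if (layer$seen) {
      layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * res$mu
      layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * res$var
    } else {
      layer$run_mean <- res$mu
      layer$run_var <- res$var
      layer$seen <- TRUE
    }
    layer$xhat <- res$xhat
    layer$inv <- res$inv
    res$y
  } else {
    inv <- 1 / sqrt(layer$run_var + layer$eps)
    ## fused affine: y = x * (gamma*inv) + (beta - mean*gamma*inv)
    a <- layer$params$gamma * inv
    add_rowvec(x * rep(a, each = m), layer$params$beta - layer$run_mean * a)
  }
}

#' @export
ly_backward.ly_batchnorm <- function(layer, gout) {
  res <- bn_bwd_cpp(gout, layer$xhat, layer$inv, layer$params$gamma)
  layer$grads$gamma <- layer$grads$gamma + res$dgamma
  layer$grads$beta <- layer$grads$beta + res$dbeta
  res$dx
}

## inverted dropout ----------------------------------------------------------

new_dropout <- function(rate) {
  new_layer("ly_dropout", fields = list(rate = rate))
}

#' @export
ly_forward.ly_dropout <- function(layer, x, training = FALSE) {
  if (!training || layer$rate <= 0) {
    layer$mask <- NULL
    return(x)
  }
  keep <- 1 - layer$rate
  mask <- (stats::runif(length(x)) < keep) / keep
  dim(mask) <- dim(x)
  layer$mask <- mask
  x * mask
}

#' @export
ly_backward.ly_dropout <- function(layer, gout) {
  if (is.null(layer$mask)) gout else gout * layer$mask
}

## patch-embedding convolution: kernel = stride = p, h filters. Input
## (N, H, W, C) -> (N, H/p, W/p, h). Columns of W enumerate the patch in
## (row-within-patch fastest, then column, then channel) order.

new_patchconv <- function(p, c_in, h) {
  new_layer("ly_patchconv",
            params = list(W = matrix(init_trunc_normal(p * p * c_in * h), p * p * c_in, h),
                          b = numeric(h)),
            fields = list(p = p, c_in = c_in, h = h))
}

patchify <- function(x, p) {
  d <- dim(x)                                  # (N, H, W, C)
  oh <- d[2] / p; ow <- d[3] / p
  dim(x) <- c(d[1], p, oh, p, ow, d[4])
  pm <- aperm(x, c(1, 3, 5, 2, 4, 6))          # (N, oh, ow, pr, pc, C)
  dim(pm) <- c(d[1] * oh * ow, p * p * d[4])
  list(pm = pm, n = d[1], oh = oh, ow = ow, c = d[4])
}

unpatchify <- function(pm, p, n, oh, ow, c) {
  dim(pm) <- c(n, oh, ow, p, p, c)
  x <- aperm(pm, c(1, 4, 2, 5, 3, 6))          # (N, pr, oh, pc, ow, C)
  dim(x) <- c(n, oh * p, ow * p, c)
  x
}

#' @export
ly_forward.ly_patchconv <- function(layer, x, training = FALSE) {
  d <- dim(x)
  p <- layer$p
  if (d[2] %% p != 0 || d[3] %% p != 0)
    stop(sprintf("patch size %d does not divide input size %dx%d", p, d[2], d[3]),
         call. = FALSE)
  pk <- patchify(x, p)
  if (training) layer$pk <- pk
  y <- add_rowvec(pk$pm %*% layer$params$W, layer$params$b)
  dim(y) <- c(pk$n, pk$oh, pk$ow, layer$h)
  y
}

#' @export
ly_backward.ly_patchconv <- function(layer, gout) {
  pk <- layer$pk
  gm <- gout
  dim(gm) <- c(pk$n * pk$oh * pk$ow, layer$h)
  layer$grads$W <- layer$grads$W + crossprod(pk$pm, gm)
  layer$grads$b <- layer$grads$b + colSums(gm)
  gpm <- gm %*% t(layer$params$W)
  unpatchify(gpm, layer$p, pk$n, pk$oh, pk$ow, pk$c)
}

## depthwise convolution, k x k, "same" zero padding, one spatial filter per
## channel. W is (k*k, C) with taps enumerated row-major over (dy, dx).

new_dwconv <- function(k, c) {
  new_layer("ly_dwconv",
            params = list(W = matrix(init_trunc_normal(k * k * c), k * k, c),
                          b = numeric(c)),
            fields = list(k = k, c = c))
}

## pad a (N, H, W, C) array by `pad` zeros on each spatial side
pad_spatial <- function(x, pad) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

#' @export
ly_forward.ly_dwconv <- function(layer, x, training = FALSE) {
  d <- dim(x)
  k <- layer$k
  pad <- (k - 1) %/% 2
  xp <- pad_spatial(x, pad)
  if (training) {
    layer$xp <- xp
    layer$d <- d
  }
  dw_taps_cpp(xp, dim(xp), k, d[2], d[3], layer$params$W, layer$params$b, TRUE)
}

#' @export
ly_backward.ly_dwconv <- function(layer, gout) {
  d <- layer$d
  k <- layer$k
  pad <- (k - 1) %/% 2
  gm <- gout
  dim(gm) <- c(d[1] * d[2] * d[3], d[4])
  layer$grads$b <- layer$grads$b + colSums(gm)
  layer$grads$W <- layer$grads$W +
    dw_gradw_cpp(layer$xp, dim(layer$xp), k, gout, d[2], d[3])
  ## input gradient = same-padded correlation of gout with the flipped kernel
  gp <- pad_spatial(gout, pad)
  dw_taps_cpp(gp, dim(gp), k, d[2], d[3],
              layer$params$W[rev(seq_len(k * k)), , drop = FALSE],
              numeric(d[4]), FALSE)
}

## pointwise (1x1) convolution: per-pixel matrix multiply across channels

new_pwconv <- function(c_in, c_out) {
  new_layer("ly_pwconv",
            params = list(W = matrix(init_trunc_normal(c_in * c_out), c_in, c_out),
                          b = numeric(c_out)),
            fields = list(c_in = c_in, c_out = c_out))
}

#' @export
ly_forward.ly_pwconv <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (d[4] != layer$c_in)
    stop(sprintf("pointwise conv expects %d channels, got %d", layer$c_in, d[4]),
         call. = FALSE)
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  if (training) {
    layer$xm <- xm
    layer$d <- d
  }
  y <- add_rowvec(xm %*% layer$params$W, layer$params$b)
  dim(y) <- c(d[1], d[2], d[3], layer$c_out)
  y
}

#' @export
ly_backward.ly_pwconv <- function(layer, gout) {
  d <- layer$d
  gm <- gout
  dim(gm) <- c(d[1] * d[2] * d[3], layer$c_out)
  layer$grads$W <- layer$grads$W + crossprod(layer$xm, gm)
  layer$grads$b <- layer$grads$b + colSums(gm)
  gx <- gm %*% t(layer$params$W)
  dim(gx) <- d
  gx
}
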