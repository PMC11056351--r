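## ConvMixer branch: patch embedding (kernel = stride = p, GELU, BN) followed
## by `depth` depthwise-separable mixer blocks
##   z' = BN(GELU(DepthwiseConv(x))) + x
##   z  = BN(GELU(PointwiseConv(z')))
## with the residual connection around the depthwise stage only.

#' Configuration of one ConvMixer branch
#'
#' @param patch_size patch side `p` in pixels; kernel and stride of the
#'   embedding convolution.
#' @param filters number of filters `h` (128 at full scale).
#' @param depth number of mixer blocks (4 at full scale).
#' @param dw_kernel depthwise kernel side (3).
#' @return a list of class `scmix_convmixer_config`.
#' @export
convmixer_config <- function(patch_size = 2L, filters = 128L, depth = 4L,
                             dw_kernel = 3L) {
  stopifnot(patch_size >= 1, filters >= 1, depth >= 0, dw_kernel >= 1)
  structure(list(patch_size = as.integer(patch_size),
                 filters = as.integer(filters),
                 depth = as.integer(depth),
                 dw_kernel = as.integer(dw_kernel)),
            class = "scmix_convmixer_config")
}

## patch embedding: conv(kernel = stride = p) -> GELU -> BN
new_patch_embed <- function(cfg, c_in) {
  ly <- new_layer("ly_patch_embed", fields = list(h = cfg$filters))
  ly$children <- list(conv = new_patchconv(cfg$patch_size, c_in, cfg$filters),
                      bn = new_batchnorm(cfg$filters))
  ly
}

#' @export
ly_forward.ly_patch_embed <- function(layer, x, training = FALSE) {
  a <- ly_forward(layer$children$conv, x, training)
  gf <- gelu_fwd_cpp(a)
  if (training) {
    layer$a <- a
    layer$ph <- gf$ph
  }
  d <- dim(a)
  g <- gf$y
  dim(g) <- c(d[1] * d[2] * d[3], d[4])
  y <- ly_forward(layer$children$bn, g, training)
  dim(y) <- d
  y
}

#' @export
ly_backward.ly_patch_embed <- function(layer, gout) {
  d <- dim(gout)
  gm <- gout
  dim(gm) <- c(d[1] * d[2] * d[3], d[4])
  g <- ly_backward(layer$children$bn, gm)
  dim(g) <- d
  ly_backward(layer$children$conv, g * gelu_grad_cpp(layer$a, layer$ph))
}

## one depthwise-separable mixer block
new_mixer_block <- function(cfg) {
  h <- cfg$filters
  ly <- new_layer("ly_mixer_block", fields = list(h = h))
  ly$children <- list(dw = new_dwconv(cfg$dw_kernel, h),
                      bn_dw = new_batchnorm(h),
                      pw = new_pwconv(h, h),
                      bn_pw = new_batchnorm(h))
  ly
}

#' @export
ly_forward.ly_mixer_block <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (d[4] != layer$h)
    stop(sprintf("mixer block expects %d channels, got %d", layer$h, d[4]),
         call. = FALSE)
  ch <- layer$children
  a <- ly_forward(ch$dw, x, training)
  gf <- gelu_fwd_cpp(a)
  if (training) {
    layer$a <- a
    layer$ph_a <- gf$ph
  }
  ga <- gf$y
  dim(ga) <- c(d[1] * d[2] * d[3], d[4])
  b1 <- ly_forward(ch$bn_dw, ga, training)
  dim(b1) <- d
  zp <- b1 + x
  cpw <- ly_forward(ch$pw, zp, training)
  gf2 <- gelu_fwd_cpp(cpw)
  if (training) {
    layer$cpw <- cpw
    layer$ph_c <- gf2$ph
  }
  g2 <- gf2$y
  dim(g2) <- c(d[1] * d[2] * d[3], d[4])
  y <- ly_forward(ch$bn_pw, g2, training)
  dim(y) <- d
  y
}

#' @export
ly_backward.ly_mixer_block <- function(layer, gout) {
  d <- dim(gout)
  ch <- layer$children
  gm <- gout
  dim(gm) <- c(d[1] * d[2] * d[3], d[4])
  g <- ly_backward(ch$bn_pw, gm)
  dim(g) <- d
  gzp <- ly_backward(ch$pw, g * gelu_grad_cpp(layer$cpw, layer$ph_c))
  gb1 <- gzp
  dim(gb1) <- c(d[1] * d[2] * d[3], d[4])
  gga <- ly_backward(ch$bn_dw, gb1)
  dim(gga) <- d
  gx_dw <- ly_backward(ch$dw, gga * gelu_grad_cpp(layer$a, layer$ph_a))
  gx_dw + gzp          # residual path around the depthwise stage
}

## full branch: embedding + depth mixer blocks
new_convmixer_branch <- function(cfg, c_in) {
  ly <- new_layer("ly_convmixer_branch", fields = list(cfg = cfg))
  blocks <- lapply(seq_len(cfg$depth), function(i) new_mixer_block(cfg))
  ly$children <- c(list(embed = new_patch_embed(cfg, c_in)), blocks)
  ly
}

#' @export
ly_forward.ly_convmixer_branch <- function(layer, x, training = FALSE) {
  y <- ly_forward(layer$children$embed, x, training)
  for (i in seq_along(layer$children)[-1]) {
    y <- ly_forward(layer$children[[i]], y, training)
  }
  y
}

#' @export
ly_backward.ly_convmixer_branch <- function(layer, gout) {
  g <- gout
  for (i in rev(seq_along(layer$children)[-1])) {
    g <- ly_backward(layer$children[[i]], g)
  }
  ly_backward(layer$children$embed, g)
}

#' Apply a ConvMixer patch embedding
#'
#' Convolution with kernel and stride equal to the patch size, `filters`
#' output channels, followed by GELU and batch normalization. An input of
#' `(W, H)` pixels becomes a `(W/p, H/p, filters)` map.
#'
#' @param image array `(batch, H, W, C)` scaled to `[0, 1]`.
#' @param layer a patch-embedding layer
#'   (`scmix:::new_patch_embed(convmixer_config(...), c_in)`).
#' @param training training mode (batch statistics in BN).
#' @return feature map `(batch, H/p, W/p, filters)`.
#' @export
patch_embed <- function(image, layer, training = FALSE) {
  ly_forward(layer, image, training)
}

#' Apply one depthwise-separable mixer block
#'
#' @param x feature map `(batch, H, W, filters)`.
#' @param layer a mixer-block layer
#'   (`scmix:::new_mixer_block(convmixer_config(...))`).
#' @param training training mode.
#' @return feature map of identical shape.
#' @export
mixer_block <- function(x, layer, training = FALSE) {
  ly_forward(layer, x, training)
}

#' Run a full ConvMixer branch
#'
#' Patch embedding followed by `depth` mixer blocks.
#'
#' @param image array `(batch, H, W, C)`.
#' @param layer a branch built by `scmix:::new_convmixer_branch(cfg, c_in)`.
#' @param training training mode.
#' @return feature map `(batch, H/p, W/p, filters)`.
#' @export
convmixer_branch <- function(image, layer, training = FALSE) {
  ly_forward(layer, image, training)
}
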