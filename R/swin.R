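## Windowed and shifted-window multi-head self-attention on token grids.
##
## A token grid is a (batch, grid_h, grid_w, dim) array. One Swin cycle is
##   z_hat   = W-MSA(LN(z))  + z
##   z'      = MLP(LN(z_hat)) + z_hat
##   z_hat2  = SW-MSA(LN(z')) + z'
##   z''     = MLP(LN(z_hat2)) + z_hat2
## with the shifted step realized as a cyclic roll plus an additive mask that
## blocks attention between tokens that were not spatially contiguous before
## the roll.

MASK_NEG <- -1e9

#' Configuration of one Swin attention cycle
#'
#' @param window window side length in tokens; must divide both grid sides.
#' @param shift cyclic shift offset for the shifted-window step
#'   (default `floor(window / 2)`); must satisfy `0 <= shift < window`.
#' @param heads number of attention heads; must divide the embedding width.
#' @param mlp_dim hidden width of the two-layer MLP (256 at full scale).
#' @param dropout_rate dropout probability in the MLP, in `[0, 1]`.
#' @param use_relative_bias add a learned relative position bias per head.
#' @param cycles_per_branch number of full cycles each multipath branch runs.
#' @return a list of class `scmix_swin_config`.
#' @export
swin_config <- function(window = 7L, shift = NULL, heads = 4L, mlp_dim = 256L,
                        dropout_rate = 0.1, use_relative_bias = TRUE,
                        cycles_per_branch = 2L) {
  shift <- as.integer(shift %||% (window %/% 2))
  window <- as.integer(window)
  if (shift < 0 || shift >= window)
    stop("shift must satisfy 0 <= shift < window", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]", call. = FALSE)
  structure(list(window = window, shift = shift, heads = as.integer(heads),
                 mlp_dim = as.integer(mlp_dim), dropout_rate = dropout_rate,
                 use_relative_bias = isTRUE(use_relative_bias),
                 cycles_per_branch = as.integer(cycles_per_branch)),
            class = "scmix_swin_config")
}

#' Partition a token grid into non-overlapping windows
#'
#' Blocks are ordered batch-slowest, windows row-major within the grid, and
#' tokens row-major within each window.
#'
#' @param g token grid, array `(batch, grid_h, grid_w, dim)`.
#' @param window window side length; must divide both grid sides.
#' @return array `(batch * n_windows, window^2, dim)`.
#' @export
window_partition <- function(g, window) {
  d <- dim(g)
  if (d[2] %% window != 0 || d[3] %% window != 0)
    stop(sprintf("window %d does not divide grid %dx%d", window, d[2], d[3]),
         call. = FALSE)
  nh <- d[2] %/% window
  nw <- d[3] %/% window
  dim(g) <- c(d[1], window, nh, window, nw, d[4])
  ## fastest-to-slowest target order: window-col index, window-row index,
  ## batch, token-col, token-row, dim
  pm <- aperm(g, c(5, 3, 1, 4, 2, 6))
  dim(pm) <- c(d[1] * nh * nw, window * window, d[4])
  pm
}

#' Reassemble windows into a token grid (inverse of [window_partition()])
#'
#' @param blocks array `(batch * n_windows, window^2, dim)`.
#' @param grid_h,grid_w target grid sides.
#' @param window window side length.
#' @return array `(batch, grid_h, grid_w, dim)`.
#' @export
window_reverse <- function(blocks, grid_h, grid_w, window) {
  d <- dim(blocks)
  nh <- grid_h %/% window
  nw <- grid_w %/% window
  nbatch <- d[1] / (nh * nw)
  if (grid_h %% window != 0 || grid_w %% window != 0 ||
      nbatch != round(nbatch) || d[2] != window * window)
    stop("block stack is inconsistent with the target grid", call. = FALSE)
  dim(blocks) <- c(nw, nh, nbatch, window, window, d[3])
  g <- aperm(blocks, c(3, 5, 2, 4, 1, 6))
  dim(g) <- c(nbatch, grid_h, grid_w, d[3])
  g
}

#' Cyclically roll a token grid along both spatial axes
#'
#' `forward` rolls contents up-left by `shift` (position i takes the token
#' from position i + shift); `reverse` undoes it.
#'
#' @param g token grid `(batch, grid_h, grid_w, dim)`.
#' @param shift nonnegative offset smaller than both grid sides.
#' @param direction `"forward"` or `"reverse"`.
#' @return rolled grid of identical shape.
#' @export
cyclic_shift <- function(g, shift, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  d <- dim(g)
  if (shift < 0 || shift >= min(d[2], d[3]))
    stop("shift must satisfy 0 <= shift < min(grid sides)", call. = FALSE)
  if (shift == 0) return(g)
  s <- if (direction == "forward") shift else -shift
  ri <- ((seq_len(d[2]) - 1 + s) %% d[2]) + 1
  ci <- ((seq_len(d[3]) - 1 + s) %% d[3]) + 1
  g[, ri, ci, , drop = FALSE]
}

#' Additive attention mask for shifted-window attention
#'
#' After a forward cyclic shift, windows along the wrap-around edges contain
#' tokens that were not adjacent in the unshifted grid. Pairs of tokens whose
#' pre-shift coordinates fall in different wrap segments receive a large
#' negative additive bias; with `shift = 0` the mask is all zero.
#'
#' @param grid_h,grid_w grid sides. @param window window side. @param shift
#'   cyclic shift offset.
#' @return array `(n_windows, window^2, window^2)` ordered as the blocks of
#'   [window_partition()].
#' @export
attention_mask <- function(grid_h, grid_w, window, shift) {
  nh <- grid_h %/% window
  nw <- grid_w %/% window
  t_len <- window * window
  if (shift == 0) return(array(0, c(nh * nw, t_len, t_len)))
  ## label every token of the unshifted grid by its wrap segment per axis
  seg <- function(n) as.integer(seq_len(n) <= shift)   # original coords < shift wrap
  lab <- outer(seg(grid_h) * 2L, seg(grid_w), `+`)     # (grid_h, grid_w)
  lab <- array(lab, c(1, grid_h, grid_w, 1))
  lab <- cyclic_shift(lab, shift, "forward")
  blocks <- window_partition(lab, window)              # (n_windows, window^2, 1)
  m <- array(0, c(nh * nw, t_len, t_len))
  for (w in seq_len(nh * nw)) {
    lw <- blocks[w, , 1]
    m[w, , ] <- ifelse(outer(lw, lw, `!=`), MASK_NEG, 0)
  }
  m
}

## relative-position-bias index for a (window x window) block: entry (i, j)
## indexes a ((2w-1)^2) table by the coordinate offset between tokens i and j
## (tokens row-major within the window).
rel_pos_index <- function(window) {
  coords <- expand.grid(col = seq_len(window), row = seq_len(window))[, c("row", "col")]
  di <- outer(coords$row, coords$row, `-`) + window - 1L
  dj <- outer(coords$col, coords$col, `-`) + window - 1L
  di * (2L * window - 1L) + dj + 1L
}

#' Multi-head self-attention over stacked window blocks
#'
#' Functional form: computes `softmax(QK' / sqrt(d_head) + bias + mask) V` per
#' head and block, then the output projection. `weights` is a list with
#' matrices `Wq`, `Wk`, `Wv`, `Wo` (dim x dim), vectors `bq`, `bk`, `bv`,
#' `bo`, and optionally `rel_bias` (`(2*window-1)^2` x heads) with `window`.
#'
#' @param blocks array `(n_blocks, tokens, dim)`.
#' @param weights named list of projection weights (see details).
#' @param heads head count; must divide `dim`.
#' @param mask optional additive mask: `(n_windows, tokens, tokens)` recycled
#'   over the batch, or a single `(tokens, tokens)` matrix.
#' @return array of the same shape as `blocks`.
#' @export
multi_head_self_attention <- function(blocks, weights, heads, mask = NULL) {
  stopifnot_finite(blocks, "attention input")
  msa_forward(blocks, weights, heads, mask, cache = NULL)
}

## shared forward used by both the functional op and the layer. When `cache`
## is an environment, intermediates are stored there for the backward pass.
msa_forward <- function(blocks, weights, heads, mask = NULL, cache = NULL) {
  d <- dim(blocks)
  nb <- d[1]; tt <- d[2]; dm <- d[3]
  if (dm %% heads != 0) stop("embedding dim must be divisible by heads", call. = FALSE)
  dh <- dm %/% heads
  scale <- 1 / sqrt(dh)
  xm <- blocks
  dim(xm) <- c(nb * tt, dm)
  Q <- add_rowvec(xm %*% weights$Wq, weights$bq)
  K <- add_rowvec(xm %*% weights$Wk, weights$bk)
  V <- add_rowvec(xm %*% weights$Wv, weights$bv)
  nW <- if (is.null(mask)) 1L else if (length(dim(mask)) == 3L) dim(mask)[1] else 1L
  rb <- weights$rel_bias
  rb_idx <- if (!is.null(rb)) rel_pos_index(as.integer(sqrt(tt))) else NULL
  ctx <- matrix(0, nb * tt, dm)
  attn <- if (!is.null(cache)) vector("list", nb * heads) else NULL
  for (b in seq_len(nb)) {
    rows <- b + nb * (seq_len(tt) - 1L)
    mb <- if (is.null(mask)) NULL else if (length(dim(mask)) == 3L)
      mask[((b - 1L) %% nW) + 1L, , ] else mask
    for (h in seq_len(heads)) {
      sl <- ((h - 1L) * dh + 1L):(h * dh)
      q <- Q[rows, sl, drop = FALSE]
      k <- K[rows, sl, drop = FALSE]
      s <- tcrossprod(q, k) * scale
      if (!is.null(rb)) s <- s + matrix(rb[rb_idx, h], tt, tt)
      if (!is.null(mb)) s <- s + mb
      a <- softmax_rows(s)
      ctx[rows, sl] <- a %*% V[rows, sl, drop = FALSE]
      if (!is.null(cache)) attn[[(b - 1L) * heads + h]] <- a
    }
  }
  out <- add_rowvec(ctx %*% weights$Wo, weights$bo)
  if (!is.null(cache)) {
    cache$xm <- xm; cache$Q <- Q; cache$K <- K; cache$V <- V
    cache$ctx <- ctx; cache$attn <- attn; cache$d <- d
    cache$rb_idx <- rb_idx
  }
  dim(out) <- d
  out
}

## MSA as a trainable layer --------------------------------------------------

new_msa <- function(dim, heads, window, use_relative_bias = TRUE) {
  params <- list(
    Wq = matrix(init_trunc_normal(dim * dim), dim, dim),
    Wk = matrix(init_trunc_normal(dim * dim), dim, dim),
    Wv = matrix(init_trunc_normal(dim * dim), dim, dim),
    Wo = matrix(init_trunc_normal(dim * dim), dim, dim),
    bq = numeric(dim), bk = numeric(dim), bv = numeric(dim), bo = numeric(dim))
  if (use_relative_bias)
    params$rel_bias <- matrix(init_trunc_normal((2 * window - 1)^2 * heads),
                              (2 * window - 1)^2, heads)
  new_layer("ly_msa", params = params,
            fields = list(heads = as.integer(heads), window = as.integer(window)))
}

#' @export
ly_forward.ly_msa <- function(layer, x, training = FALSE) {
  ## layer$mask is set by the enclosing cycle before the call
  msa_forward(x, layer$params, layer$heads, layer$mask,
              cache = if (training) layer else NULL)
}

#' @export
ly_backward.ly_msa <- function(layer, gout) {
  d <- layer$d
  nb <- d[1]; tt <- d[2]; dm <- d[3]
  heads <- layer$heads
  dh <- dm %/% heads
  scale <- 1 / sqrt(dh)
  gm <- gout
  dim(gm) <- c(nb * tt, dm)
  layer$grads$Wo <- layer$grads$Wo + crossprod(layer$ctx, gm)
  layer$grads$bo <- layer$grads$bo + colSums(gm)
  gctx <- gm %*% t(layer$params$Wo)
  gQ <- matrix(0, nb * tt, dm)
  gK <- matrix(0, nb * tt, dm)
  gV <- matrix(0, nb * tt, dm)
  grb_sum <- if (!is.null(layer$params$rel_bias))
    matrix(0, tt * tt, heads) else NULL
  for (b in seq_len(nb)) {
    rows <- b + nb * (seq_len(tt) - 1L)
    for (h in seq_len(heads)) {
      sl <- ((h - 1L) * dh + 1L):(h * dh)
      a <- layer$attn[[(b - 1L) * heads + h]]
      dctx <- gctx[rows, sl, drop = FALSE]
      v <- layer$V[rows, sl, drop = FALSE]
      dA <- tcrossprod(dctx, v)
      gV[rows, sl] <- crossprod(a, dctx)
      ds <- a * (dA - rowSums(dA * a))
      if (!is.null(grb_sum)) grb_sum[, h] <- grb_sum[, h] + as.vector(ds)
      gQ[rows, sl] <- ds %*% layer$K[rows, sl, drop = FALSE] * scale
      gK[rows, sl] <- crossprod(ds, layer$Q[rows, sl, drop = FALSE]) * scale
    }
  }
  if (!is.null(grb_sum)) {
    acc <- rowsum(grb_sum, group = as.vector(layer$rb_idx))
    layer$grads$rel_bias[as.integer(rownames(acc)), ] <-
      layer$grads$rel_bias[as.integer(rownames(acc)), ] + acc
  }
  xm <- layer$xm
  layer$grads$Wq <- layer$grads$Wq + crossprod(xm, gQ)
  layer$grads$bq <- layer$grads$bq + colSums(gQ)
  layer$grads$Wk <- layer$grads$Wk + crossprod(xm, gK)
  layer$grads$bk <- layer$grads$bk + colSums(gK)
  layer$grads$Wv <- layer$grads$Wv + crossprod(xm, gV)
  layer$grads$bv <- layer$grads$bv + colSums(gV)
  gx <- gQ %*% t(layer$params$Wq) + gK %*% t(layer$params$Wk) +
    gV %*% t(layer$params$Wv)
  dim(gx) <- d
  gx
}

## transformer MLP: FC(mlp_dim) -> GELU -> dropout -> FC(dim) -> dropout

new_mlp <- function(dim, mlp_dim, dropout_rate) {
  ly <- new_layer("ly_mlp")
  ly$children <- list(fc1 = new_dense(dim, mlp_dim),
                      drop1 = new_dropout(dropout_rate),
                      fc2 = new_dense(mlp_dim, dim),
                      drop2 = new_dropout(dropout_rate))
  ly
}

#' @export
ly_forward.ly_mlp <- function(layer, x, training = FALSE) {
  ch <- layer$children
  a <- ly_forward(ch$fc1, x, training)
  gf <- gelu_fwd_cpp(a)
  if (training) {
    layer$a <- a
    layer$ph <- gf$ph
  }
  h <- ly_forward(ch$drop1, gf$y, training)
  ly_forward(ch$drop2, ly_forward(ch$fc2, h, training), training)
}

#' @export
ly_backward.ly_mlp <- function(layer, gout) {
  ch <- layer$children
  g <- ly_backward(ch$drop2, gout)
  g <- ly_backward(ch$fc2, g)
  g <- ly_backward(ch$drop1, g)
  ly_backward(ch$fc1, g * gelu_grad_cpp(layer$a, layer$ph))
}

## one full Swin cycle on a token grid ---------------------------------------

new_swin_cycle <- function(dim, cfg) {
  ly <- new_layer("ly_swin_cycle",
                  fields = list(window = cfg$window, shift = cfg$shift,
                                dim = dim))
  ly$children <- list(
    ln1 = new_layernorm(dim),
    wmsa = new_msa(dim, cfg$heads, cfg$window, cfg$use_relative_bias),
    ln2 = new_layernorm(dim),
    mlp1 = new_mlp(dim, cfg$mlp_dim, cfg$dropout_rate),
    ln3 = new_layernorm(dim),
    swmsa = new_msa(dim, cfg$heads, cfg$window, cfg$use_relative_bias),
    ln4 = new_layernorm(dim),
    mlp2 = new_mlp(dim, cfg$mlp_dim, cfg$dropout_rate))
  ly
}

## attention sub-step: LN -> (shift) -> partition -> MSA -> reverse -> (unshift)
swin_attend <- function(layer, msa, ln, xm, d, shifted, training) {
  w <- layer$window
  t1 <- ly_forward(ln, xm, training)
  g <- t1
  dim(g) <- d
  if (shifted && layer$shift > 0) g <- cyclic_shift(g, layer$shift, "forward")
  blocks <- window_partition(g, w)
  if (shifted && layer$shift > 0) {
    if (is.null(layer$mask_cache) || !identical(layer$mask_dim, d[2:3])) {
      layer$mask_cache <- attention_mask(d[2], d[3], w, layer$shift)
      layer$mask_dim <- d[2:3]
    }
    msa$mask <- layer$mask_cache
  } else {
    msa$mask <- NULL
  }
  att <- ly_forward(msa, blocks, training)
  g <- window_reverse(att, d[2], d[3], w)
  if (shifted && layer$shift > 0) g <- cyclic_shift(g, layer$shift, "reverse")
  dim(g) <- dim(xm)
  g
}

swin_attend_bwd <- function(layer, msa, ln, gm, d, shifted) {
  w <- layer$window
  g <- gm
  dim(g) <- d
  if (shifted && layer$shift > 0) g <- cyclic_shift(g, layer$shift, "forward")
  blocks <- window_partition(g, w)
  gatt <- ly_backward(msa, blocks)
  g <- window_reverse(gatt, d[2], d[3], w)
  if (shifted && layer$shift > 0) g <- cyclic_shift(g, layer$shift, "reverse")
  dim(g) <- dim(gm)
  ly_backward(ln, g)
}

#' @export
ly_forward.ly_swin_cycle <- function(layer, x, training = FALSE) {
  d <- dim(x)
  layer$d <- d
  ch <- layer$children
  xm <- x
  dim(xm) <- c(d[1] * d[2] * d[3], d[4])
  zhat <- swin_attend(layer, ch$wmsa, ch$ln1, xm, d, FALSE, training) + xm
  z <- ly_forward(ch$mlp1, ly_forward(ch$ln2, zhat, training), training) + zhat
  zhat2 <- swin_attend(layer, ch$swmsa, ch$ln3, z, d, TRUE, training) + z
  out <- ly_forward(ch$mlp2, ly_forward(ch$ln4, zhat2, training), training) + zhat2
  dim(out) <- d
  out
}

#' @export
ly_backward.ly_swin_cycle <- function(layer, gout) {
  d <- layer$d
  ch <- layer$children
  gm <- gout
  dim(gm) <- c(d[1] * d[2] * d[3], d[4])
  g_zhat2 <- gm + ly_backward(ch$ln4, ly_backward(ch$mlp2, gm))
  g_z <- g_zhat2 + swin_attend_bwd(layer, ch$swmsa, ch$ln3, g_zhat2, d, TRUE)
  g_zhat <- g_z + ly_backward(ch$ln2, ly_backward(ch$mlp1, g_z))
  g_x <- g_zhat + swin_attend_bwd(layer, ch$wmsa, ch$ln1, g_zhat, d, FALSE)
  dim(g_x) <- d
  g_x
}

#' Apply one full Swin attention cycle to a token grid
#'
#' Convenience functional wrapper around a built cycle layer: W-MSA, MLP,
#' SW-MSA, MLP, each behind layer normalization with a residual connection.
#'
#' @param g token grid `(batch, grid_h, grid_w, dim)`.
#' @param cycle a cycle layer built by [build_model()] internals or
#'   `scmix:::new_swin_cycle(dim, swin_config(...))`.
#' @param training use training-mode dropout and cache gradients.
#' @return token grid of identical shape.
#' @export
swin_cycle <- function(g, cycle, training = FALSE) {
  d <- dim(g)
  if (d[2] %% cycle$window != 0 || d[3] %% cycle$window != 0)
    stop(sprintf("window %d does not divide grid %dx%d", cycle$window, d[2], d[3]),
         call. = FALSE)
  ly_forward(cycle, g, training)
}

#' Zero the residual-branch output projections of a Swin cycle
#'
#' Diagnostic helper: with the attention output projections and the MLP
#' output layers zeroed, every residual branch contributes nothing and the
#' cycle is the identity map.
#'
#' @param cycle a Swin cycle layer.
#' @return the cycle, modified in place.
#' @export
zero_branch_outputs <- function(cycle) {
  ch <- cycle$children
  for (msa in list(ch$wmsa, ch$swmsa)) {
    msa$params$Wo[] <- 0
    msa$params$bo[] <- 0
  }
  for (mlp in list(ch$mlp1, ch$mlp2)) {
    mlp$children$fc2$params$W[] <- 0
    mlp$children$fc2$params$b[] <- 0
  }
  invisible(cycle)
}
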