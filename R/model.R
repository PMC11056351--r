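## Assembly of the full hybrid classifier and its ablation variants:
## Stage 1 (MPCM)  F_out = F_C1 + Up^2(F_C2) + Up^4(F_C3)
## Stage 2 (MPST)  two patch-extraction + Swin-cycle branches, token matrices
##                 concatenated along the token axis (784 + 196 = 980 rows at
##                 full-scale defaults)
## Stage 3         global average pooling over tokens, FC(c), softmax.

MODEL_VARIANTS <- c("convmixer_only", "swtrans_only", "mpcm_only",
                    "mpcm_swtrans", "mpst_only", "convmixer_mpst", "full")

#' Architecture configuration for the hybrid classifier
#'
#' Defaults reproduce the full-scale architecture: 224x224x3 input, three
#' ConvMixer branches at patch sizes 2/4/8 with 128 filters and depth 4,
#' nearest-neighbor upsampling fusion, two Swin branches on 28x28 and 14x14
#' token grids of 256-wide tokens, and a softmax head.
#'
#' @param num_classes number of target classes (>= 2).
#' @param input_size input image side in pixels.
#' @param mpcm_patches patch sizes of the parallel ConvMixer branches; the
#'   first branch sets the fused map resolution (`input_size / patches[1]`).
#' @param filters,depth,dw_kernel ConvMixer hyperparameters (see
#'   [convmixer_config()]).
#' @param mpst_grids token-grid sides of the two Swin branches; each must
#'   divide the fused map side, and `token_dim / (side/grid)^2` must be a
#'   positive integer (the filter count of the patch-extraction convolution).
#' @param token_dim token embedding width (256 at full scale).
#' @param swin a [swin_config()].
#' @param variant one of `"convmixer_only"`, `"swtrans_only"`, `"mpcm_only"`,
#'   `"mpcm_swtrans"`, `"mpst_only"`, `"convmixer_mpst"`, `"full"`.
#' @return a list of class `scmix_model_config`.
#' @export
model_config <- function(num_classes, input_size = 224L,
                         mpcm_patches = c(2L, 4L, 8L), filters = 128L,
                         depth = 4L, dw_kernel = 3L,
                         mpst_grids = c(28L, 14L), token_dim = 256L,
                         swin = swin_config(), variant = "full") {
  if (missing(num_classes) || num_classes < 2)
    stop("num_classes must be at least 2", call. = FALSE)
  if (!variant %in% MODEL_VARIANTS)
    stop(sprintf("unknown variant '%s'; valid variants: %s", variant,
                 paste(MODEL_VARIANTS, collapse = ", ")), call. = FALSE)
  mpcm_patches <- as.integer(mpcm_patches)
  if (any(input_size %% mpcm_patches != 0))
    stop(sprintf("input_size %d is not divisible by all mpcm_patches (%s)",
                 input_size, paste(mpcm_patches, collapse = ", ")), call. = FALSE)
  cfg <- structure(list(
    num_classes = as.integer(num_classes), input_size = as.integer(input_size),
    mpcm_patches = mpcm_patches, filters = as.integer(filters),
    depth = as.integer(depth), dw_kernel = as.integer(dw_kernel),
    mpst_grids = as.integer(mpst_grids), token_dim = as.integer(token_dim),
    swin = swin, variant = variant), class = "scmix_model_config")
  validate_variant_shapes(cfg)
  cfg
}

## checks the grid arithmetic of the branches the chosen variant actually uses
validate_variant_shapes <- function(cfg) {
  side <- switch(cfg$variant,
                 swtrans_only = cfg$input_size,
                 mpst_only = cfg$input_size,
                 cfg$input_size %/% cfg$mpcm_patches[1])
  grids <- switch(cfg$variant,
                  convmixer_only = integer(0),
                  mpcm_only = integer(0),
                  swtrans_only = cfg$mpst_grids[1],
                  mpcm_swtrans = cfg$mpst_grids[1],
                  cfg$mpst_grids)
  for (grid in grids) {
    if (side %% grid != 0)
      stop(sprintf("token grid %d does not divide the feature-map side %d",
                   grid, side), call. = FALSE)
    p_eff <- side %/% grid
    k <- cfg$token_dim / p_eff^2
    if (k != round(k) || k < 1)
      stop(sprintf(
        "token_dim %d / (effective patch %d)^2 = %.3f is not a positive integer",
        cfg$token_dim, p_eff, k), call. = FALSE)
    if (grid %% cfg$swin$window != 0)
      stop(sprintf("window %d does not divide token grid %d",
                   cfg$swin$window, grid), call. = FALSE)
  }
  invisible(cfg)
}

## nearest-neighbor upsampling (parameter-free) ------------------------------

new_upsample <- function(s) new_layer("ly_upsample", fields = list(s = as.integer(s)))

#' @export
ly_forward.ly_upsample <- function(layer, x, training = FALSE) {
  s <- layer$s
  if (s == 1) return(x)
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = s), rep(seq_len(d[3]), each = s), , drop = FALSE]
}

#' @export
ly_backward.ly_upsample <- function(layer, gout) {
  s <- layer$s
  if (s == 1) return(gout)
  d <- dim(gout)
  h <- d[2] %/% s; w <- d[3] %/% s
  dim(gout) <- c(d[1], s, h, s, w, d[4])
  g <- aperm(gout, c(2, 4, 1, 3, 5, 6))
  dim(g) <- c(s * s, d[1] * h * w * d[4])
  g <- colSums(g)
  dim(g) <- c(d[1], h, w, d[4])
  g
}

## Stage 1: multipath ConvMixer ----------------------------------------------

new_mpcm <- function(cfg, c_in = 3L) {
  ly <- new_layer("ly_mpcm", fields = list(patches = cfg$mpcm_patches))
  branches <- lapply(cfg$mpcm_patches, function(p)
    new_convmixer_branch(convmixer_config(p, cfg$filters, cfg$depth, cfg$dw_kernel), c_in))
  ups <- lapply(cfg$mpcm_patches / cfg$mpcm_patches[1], new_upsample)
  ly$children <- c(stats::setNames(branches, paste0("cm", seq_along(branches))),
                   stats::setNames(ups, paste0("up", seq_along(ups))))
  ly$n_branches <- length(branches)
  ly
}

#' @export
ly_forward.ly_mpcm <- function(layer, x, training = FALSE) {
  nb <- layer$n_branches
  out <- NULL
  for (i in seq_len(nb)) {
    fi <- ly_forward(layer$children[[i]], x, training)
    fi <- ly_forward(layer$children[[nb + i]], fi, training)
    out <- if (is.null(out)) fi else out + fi
  }
  out
}

#' @export
ly_backward.ly_mpcm <- function(layer, gout) {
  nb <- layer$n_branches
  gx <- NULL
  for (i in seq_len(nb)) {
    g <- ly_backward(layer$children[[nb + i]], gout)
    g <- ly_backward(layer$children[[i]], g)
    gx <- if (is.null(gx)) g else gx + g
  }
  gx
}

#' Run the multipath ConvMixer stage
#'
#' Element-wise sum of the parallel ConvMixer branch outputs after
#' nearest-neighbor upsampling to the resolution of the finest branch.
#'
#' @param image array `(batch, H, W, C)`.
#' @param layer an MPCM module (`scmix:::new_mpcm(cfg)` or
#'   `model$modules$mpcm` of a built model).
#' @param training training mode.
#' @return fused feature map `(batch, H/p1, W/p1, filters)`.
#' @export
mpcm_forward <- function(image, layer, training = FALSE) {
  ly_forward(layer, image, training)
}

## Stage 2: patch extraction + Swin branches ---------------------------------

## 1x1 conv to k = token_dim / p_eff^2 channels, then non-overlapping
## p_eff x p_eff patching; each patch flattens to one token of width token_dim.
new_patch_extract <- function(c_in, p_eff, token_dim) {
  k <- token_dim / p_eff^2
  if (k != round(k) || k < 1)
    stop(sprintf("token_dim %d / %d^2 is not a positive integer", token_dim, p_eff),
         call. = FALSE)
  ly <- new_layer("ly_patch_extract",
                  fields = list(p_eff = as.integer(p_eff), k = as.integer(k),
                                token_dim = as.integer(token_dim)))
  ly$children <- list(conv = new_pwconv(c_in, as.integer(k)))
  ly
}

## space-to-depth: (N, S, S, k) -> grid (N, S/p, S/p, p^2 k)
space_to_depth <- function(x, p) {
  d <- dim(x)
  gh <- d[2] %/% p; gw <- d[3] %/% p
  dim(x) <- c(d[1], p, gh, p, gw, d[4])
  g <- aperm(x, c(1, 3, 5, 2, 4, 6))
  dim(g) <- c(d[1], gh, gw, p * p * d[4])
  g
}

depth_to_space <- function(g, p, k) {
  d <- dim(g)
  dim(g) <- c(d[1], d[2], d[3], p, p, k)
  x <- aperm(g, c(1, 4, 2, 5, 3, 6))
  dim(x) <- c(d[1], d[2] * p, d[3] * p, k)
  x
}

#' @export
ly_forward.ly_patch_extract <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (d[2] %% layer$p_eff != 0 || d[3] %% layer$p_eff != 0)
    stop(sprintf("effective patch %d does not divide map side %dx%d",
                 layer$p_eff, d[2], d[3]), call. = FALSE)
  l <- ly_forward(layer$children$conv, x, training)
  space_to_depth(l, layer$p_eff)
}

#' @export
ly_backward.ly_patch_extract <- function(layer, gout) {
  gl <- depth_to_space(gout, layer$p_eff, layer$k)
  ly_backward(layer$children$conv, gl)
}

#' Extract patch tokens from a feature map
#'
#' 1x1 convolution to `k = token_dim / p_eff^2` channels followed by
#' non-overlapping `p_eff` x `p_eff` patching and flattening, so every token
#' has width `token_dim`.
#'
#' @param f feature map `(batch, S, S, C)`.
#' @param layer a patch-extraction layer
#'   (`scmix:::new_patch_extract(c_in, p_eff, token_dim)`).
#' @param training training mode.
#' @param as_tokens return `(batch, (S/p_eff)^2, token_dim)` tokens instead of
#'   the `(batch, S/p_eff, S/p_eff, token_dim)` grid.
#' @return token grid or token matrix.
#' @export
patch_extract <- function(f, layer, training = FALSE, as_tokens = FALSE) {
  g <- ly_forward(layer, f, training)
  if (as_tokens) {
    d <- dim(g)
    dim(g) <- c(d[1], d[2] * d[3], d[4])
  }
  g
}

## one Swin branch: patch extraction, then n full cycles, then flatten
new_swin_branch <- function(c_in, side, grid, cfg) {
  p_eff <- side %/% grid
  ly <- new_layer("ly_swin_branch",
                  fields = list(grid = as.integer(grid), p_eff = p_eff,
                                token_dim = cfg$token_dim))
  cycles <- lapply(seq_len(cfg$swin$cycles_per_branch), function(i)
    new_swin_cycle(cfg$token_dim, cfg$swin))
  ly$children <- c(list(extract = new_patch_extract(c_in, p_eff, cfg$token_dim)),
                   cycles)
  ly
}

#' @export
ly_forward.ly_swin_branch <- function(layer, x, training = FALSE) {
  g <- ly_forward(layer$children$extract, x, training)
  for (i in seq_along(layer$children)[-1]) {
    g <- ly_forward(layer$children[[i]], g, training)
  }
  d <- dim(g)
  ## flatten the grid to tokens (column-major; any fixed bijection suffices
  ## for the downstream pooling and concatenation)
  dim(g) <- c(d[1], d[2] * d[3], d[4])
  layer$grid_dim <- d
  g
}

#' @export
ly_backward.ly_swin_branch <- function(layer, gout) {
  g <- gout
  dim(g) <- layer$grid_dim
  for (i in rev(seq_along(layer$children)[-1])) {
    g <- ly_backward(layer$children[[i]], g)
  }
  ly_backward(layer$children$extract, g)
}

## Stage 2 container: two (or more) parallel Swin branches, token-concatenated
new_mpst <- function(c_in, side, cfg, grids = cfg$mpst_grids) {
  ly <- new_layer("ly_mpst")
  ly$children <- lapply(grids, function(g) new_swin_branch(c_in, side, g, cfg))
  names(ly$children) <- paste0("branch", seq_along(grids))
  ly
}

#' @export
ly_forward.ly_mpst <- function(layer, x, training = FALSE) {
  outs <- lapply(layer$children, function(br) ly_forward(br, x, training))
  layer$t_counts <- vapply(outs, function(o) dim(o)[2], 1)
  d1 <- dim(outs[[1]])
  tok <- array(0, c(d1[1], sum(layer$t_counts), d1[3]))
  at <- 0L
  for (o in outs) {
    tok[, at + seq_len(dim(o)[2]), ] <- o
    at <- at + dim(o)[2]
  }
  tok
}

#' @export
ly_backward.ly_mpst <- function(layer, gout) {
  gx <- NULL
  at <- 0L
  for (i in seq_along(layer$children)) {
    ti <- layer$t_counts[i]
    g <- ly_backward(layer$children[[i]], gout[, at + seq_len(ti), , drop = FALSE])
    at <- at + ti
    gx <- if (is.null(gx)) g else gx + g
  }
  gx
}

#' Run the multipath Swin stage
#'
#' Each branch extracts tokens at its own effective patch size and applies its
#' Swin cycles; branch token matrices are concatenated along the token axis
#' (784 + 196 = 980 rows at full-scale defaults).
#'
#' @param f fused feature map `(batch, S, S, C)`.
#' @param layer an MPST module (`model$modules$mpst` of a built model).
#' @param training training mode.
#' @return token matrix `(batch, T_total, token_dim)`.
#' @export
mpst_forward <- function(f, layer, training = FALSE) {
  ly_forward(layer, f, training)
}

## Stage 3: GAP + FC + softmax -----------------------------------------------

new_head <- function(d_in, num_classes) {
  if (num_classes < 2) stop("num_classes must be at least 2", call. = FALSE)
  ly <- new_layer("ly_head", fields = list(d_in = d_in, c = as.integer(num_classes)))
  ly$children <- list(fc = new_dense(d_in, num_classes))
  ly
}

#' @export
ly_forward.ly_head <- function(layer, x, training = FALSE) {
  layer$in_dim <- dim(x)
  d <- dim(x)
  if (length(d) == 4L) dim(x) <- d <- c(d[1], d[2] * d[3], d[4])  # map -> tokens
  n <- d[1]; tt <- d[2]
  layer$token_count <- tt
  xm <- x
  dim(xm) <- c(n * tt, d[3])
  pooled <- rowsum(xm, group = rep_len(seq_len(n), n * tt)) / tt
  if (training) layer$n_tt <- c(n, tt)
  logits <- ly_forward(layer$children$fc, pooled, training)
  softmax_rows(logits)
}

## the head's backward expects d(loss)/d(logits) (softmax + cross-entropy
## gradients are combined in the training loop)
#' @export
ly_backward.ly_head <- function(layer, gout) {
  gpooled <- ly_backward(layer$children$fc, gout)
  n <- layer$n_tt[1]; tt <- layer$n_tt[2]
  gx <- gpooled[rep_len(seq_len(n), n * tt), , drop = FALSE] / tt
  dim(gx) <- layer$in_dim
  gx
}

#' Classification head: pooled tokens to class probabilities
#'
#' Global average over the token axis, a fully connected layer with one
#' output per class, and a numerically stabilized softmax.
#'
#' @param tokens token matrix `(batch, T, D)` or feature map `(batch, H, W, C)`.
#' @param layer a head module (`model$modules$head`).
#' @param training training mode.
#' @return probability matrix `(batch, num_classes)`; rows sum to 1.
#' @export
classification_head <- function(tokens, layer, training = FALSE) {
  ly_forward(layer, tokens, training)
}

#' Categorical cross-entropy
#'
#' `L = -sum_k Y_k log(P_k)` averaged over the batch. Probabilities are
#' clamped to `[1e-7, 1]` so the loss is always finite.
#'
#' @param y one-hot target matrix `(batch, classes)`.
#' @param p probability matrix `(batch, classes)`; rows must sum to 1.
#' @return scalar nonnegative loss.
#' @export
cross_entropy <- function(y, p) {
  stopifnot(identical(dim(y), dim(p)))
  if (any(abs(rowSums(p) - 1) > 1e-5))
    stop("probability rows must sum to 1", call. = FALSE)
  p <- pmin(pmax(p, 1e-7), 1)
  -sum(y * log(p)) / nrow(p)
}

## channel-lifting 1x1 convolution used by the mpst_only variant
new_lift <- function(c_in, c_out) {
  ly <- new_layer("ly_lift")
  ly$children <- list(conv = new_pwconv(c_in, c_out))
  ly
}

#' @export
ly_forward.ly_lift <- function(layer, x, training = FALSE)
  ly_forward(layer$children$conv, x, training)

#' @export
ly_backward.ly_lift <- function(layer, gout)
  ly_backward(layer$children$conv, gout)

## model assembly ------------------------------------------------------------

#' Build the hybrid classifier or one of its ablation variants
#'
#' Variants: `convmixer_only` (single ConvMixer branch + head),
#' `swtrans_only` (patch extraction on the raw image + Swin cycles + head),
#' `mpcm_only` (multipath ConvMixer + head), `mpcm_swtrans` (MPCM + single
#' Swin branch + head), `mpst_only` (1x1-conv-lifted image + MPST + head),
#' `convmixer_mpst` (single ConvMixer branch + MPST + head), and `full`
#' (MPCM + MPST + head).
#'
#' @param cfg a [model_config()].
#' @param seed optional integer; seeds the weight initialization.
#' @return an object of class `scmix_model`.
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scmix_model_config"))
  validate_variant_shapes(cfg)
  if (!is.null(seed)) set.seed(seed)
  side1 <- cfg$input_size %/% cfg$mpcm_patches[1]
  cm1 <- function() convmixer_config(cfg$mpcm_patches[1], cfg$filters,
                                     cfg$depth, cfg$dw_kernel)
  modules <- switch(
    cfg$variant,
    convmixer_only = list(cm = new_convmixer_branch(cm1(), 3L),
                          head = new_head(cfg$filters, cfg$num_classes)),
    mpcm_only = list(mpcm = new_mpcm(cfg),
                     head = new_head(cfg$filters, cfg$num_classes)),
    swtrans_only = list(
      swin = new_swin_branch(3L, cfg$input_size, cfg$mpst_grids[1], cfg),
      head = new_head(cfg$token_dim, cfg$num_classes)),
    mpcm_swtrans = list(
      mpcm = new_mpcm(cfg),
      swin = new_swin_branch(cfg$filters, side1, cfg$mpst_grids[1], cfg),
      head = new_head(cfg$token_dim, cfg$num_classes)),
    mpst_only = list(
      lift = new_lift(3L, cfg$filters),
      mpst = new_mpst(cfg$filters, cfg$input_size, cfg),
      head = new_head(cfg$token_dim, cfg$num_classes)),
    convmixer_mpst = list(
      cm = new_convmixer_branch(cm1(), 3L),
      mpst = new_mpst(cfg$filters, side1, cfg),
      head = new_head(cfg$token_dim, cfg$num_classes)),
    full = list(
      mpcm = new_mpcm(cfg),
      mpst = new_mpst(cfg$filters, side1, cfg),
      head = new_head(cfg$token_dim, cfg$num_classes)))
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$modules <- modules
  model$layers <- do.call(c, lapply(modules, collect_layers))
  class(model) <- "scmix_model"
  model
}

#' @export
print.scmix_model <- function(x, ...) {
  cat(sprintf("<scmix_model> variant = %s, input %dx%dx3, %d classes, %s parameters\n",
              x$cfg$variant, x$cfg$input_size, x$cfg$input_size,
              x$cfg$num_classes, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters of a built model
#'
#' @param model a `scmix_model`.
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$layers,
             function(ly) sum(vapply(ly$params, length, 1L)), 1))
}

#' Forward pass of a built model
#'
#' @param model a `scmix_model`.
#' @param x image batch `(batch, H, W, 3)` in `[0, 1]`.
#' @param training training mode (batch statistics, dropout, gradient cache).
#' @return probability matrix `(batch, num_classes)`. The token count entering
#'   the pooling step is retained as `model$last_token_count`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  stopifnot_finite(x, "image batch")
  y <- x
  for (m in model$modules) y <- ly_forward(m, y, training)
  model$last_token_count <- model$modules$head$token_count
  y
}

## backward from d(loss)/d(logits)
model_backward <- function(model, dlogits) {
  g <- dlogits
  for (m in rev(model$modules)) g <- ly_backward(m, g)
  invisible(g)
}

#' Token matrix entering the classification head
#'
#' Runs the model up to (but not including) global average pooling and
#' returns the concatenated token matrix — at full-scale defaults a
#' `(batch, 980, 256)` array.
#'
#' @param model a `scmix_model` whose variant has a token stage.
#' @param x image batch `(batch, H, W, 3)`.
#' @return token array `(batch, T, D)` (maps are returned as `(batch, H*W, C)`).
#' @export
forward_tokens <- function(model, x) {
  y <- x
  for (m in model$modules) {
    if (inherits(m, "ly_head")) break
    y <- ly_forward(m, y, FALSE)
  }
  d <- dim(y)
  if (length(d) == 4L) dim(y) <- c(d[1], d[2] * d[3], d[4])
  y
}

#' @param object a `scmix_model`.
#' @param newdata image batch `(batch, H, W, 3)` array or a dataset from
#'   [make_dataset()]/[read_image_folder()].
#' @param batch_size forward-pass batch size (result is batch-size invariant).
#' @param ... unused.
#' @rdname model_forward
#' @export
predict.scmix_model <- function(object, newdata, batch_size = 16L, ...) {
  x <- if (inherits(newdata, "scmix_dataset")) dataset_tensor(newdata) else newdata
  n <- dim(x)[1]
  out <- matrix(0, n, object$cfg$num_classes)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    out[idx, ] <- model_forward(object, x[idx, , , , drop = FALSE], training = FALSE)
  }
  out
}
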