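# Shared fixtures and independent oracles, written from first principles so
# they never share code paths with the implementation.

# token grid numbered row-major (token id = (row-1)*gw + (col-1)), batch 1
numbered_grid <- function(gh, gw) {
  g <- array(0, c(1, gh, gw, 1))
  for (i in seq_len(gh)) for (j in seq_len(gw)) g[1, i, j, 1] <- (i - 1) * gw + (j - 1)
  g
}

# dense single-block attention oracle: softmax(QK'/sqrt(dh) + mask) V + output
# projection, computed head by head with explicit loops
attention_oracle <- function(X, w, heads, mask = NULL) {
  tt <- nrow(X); dm <- ncol(X); dh <- dm / heads
  Q <- X %*% w$Wq + matrix(w$bq, tt, dm, byrow = TRUE)
  K <- X %*% w$Wk + matrix(w$bk, tt, dm, byrow = TRUE)
  V <- X %*% w$Wv + matrix(w$bv, tt, dm, byrow = TRUE)
  ctx <- matrix(0, tt, dm)
  for (h in seq_len(heads)) {
    sl <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, sl, drop = FALSE] %*% t(K[, sl, drop = FALSE]) / sqrt(dh)
    if (!is.null(mask)) S <- S + mask
    A <- matrix(0, tt, tt)
    for (i in seq_len(tt)) {
      e <- exp(S[i, ] - max(S[i, ]))
      A[i, ] <- e / sum(e)
    }
    ctx[, sl] <- A %*% V[, sl, drop = FALSE]
  }
  ctx %*% w$Wo + matrix(w$bo, tt, dm, byrow = TRUE)
}

random_msa_weights <- function(dm, seed = 1) {
  set.seed(seed)
  list(Wq = matrix(rnorm(dm * dm), dm, dm), Wk = matrix(rnorm(dm * dm), dm, dm),
       Wv = matrix(rnorm(dm * dm), dm, dm), Wo = matrix(rnorm(dm * dm), dm, dm),
       bq = rnorm(dm), bk = rnorm(dm), bv = rnorm(dm), bo = rnorm(dm))
}

# brute-force per-channel same-padding 2-D correlation (depthwise oracle);
# x: (H, W, C); W_taps: (k*k, C) taps row-major over (dy, dx)
dw_oracle <- function(x, W_taps, b, k) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  pad <- (k - 1) %/% 2
  y <- array(0, dim(x))
  for (c in seq_len(C)) for (i in seq_len(H)) for (j in seq_len(Wd)) {
    acc <- b[c]
    for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
      ii <- i + dy - pad; jj <- j + dx - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd)
        acc <- acc + x[ii, jj, c] * W_taps[dy * k + dx + 1, c]
    }
    y[i, j, c] <- acc
  }
  y
}

# brute-force strided patch convolution (patch-embedding oracle); weight
# columns enumerate (row-within-patch fastest, then column, then channel)
patchconv_oracle <- function(x, W, b, p) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]; h <- ncol(W)
  oh <- H / p; ow <- Wd / p
  y <- array(0, c(oh, ow, h))
  for (oi in seq_len(oh)) for (oj in seq_len(ow)) {
    patch <- numeric(p * p * C)
    idx <- 0
    for (c in seq_len(C)) for (pc in seq_len(p)) for (pr in seq_len(p)) {
      idx <- idx + 1
      patch[idx] <- x[(oi - 1) * p + pr, (oj - 1) * p + pc, c]
    }
    y[oi, oj, ] <- as.vector(patch %*% W) + b
  }
  y
}

# tiny-but-complete model configuration used across structural tests
tiny_model_config <- function(variant = "full", mpst_grids = c(4L, 2L)) {
  model_config(num_classes = 3, input_size = 16, mpcm_patches = c(2, 4),
               filters = 6, depth = 1, mpst_grids = mpst_grids, token_dim = 16,
               swin = swin_config(window = 2, shift = 1, heads = 2,
                                  mlp_dim = 12, dropout_rate = 0,
                                  cycles_per_branch = 1),
               variant = variant)
}

tiny_image_batch <- function(n = 2, size = 16, seed = 1) {
  set.seed(seed)
  array(runif(n * size * size * 3), c(n, size, size, 3))
}
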