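test_that("window partition matches the row-major enumeration and inverts", {
  g <- numbered_grid(4, 4)
  b <- window_partition(g, 2)
  expect_equal(dim(b), c(4, 4, 1))
  expect_equal(sort(b[1, , 1]), c(0, 1, 4, 5))
  expect_equal(sort(b[2, , 1]), c(2, 3, 6, 7))
  expect_equal(sort(b[3, , 1]), c(8, 9, 12, 13))
  expect_equal(sort(b[4, , 1]), c(10, 11, 14, 15))
  expect_identical(window_reverse(b, 4, 4, 2), g)

  # a 28x28 grid under window 7 yields (28/7)^2 blocks of 49 tokens each
  g28 <- array(stats::rnorm(2 * 28 * 28 * 4), c(2, 28, 28, 4))
  b28 <- window_partition(g28, 7)
  expect_equal(dim(b28), c(2 * 16, 49, 4))
  # every token appears exactly once
  expect_equal(sort(as.vector(b28)), sort(as.vector(g28)))

  # window equal to the whole grid: one block per batch item
  b1 <- window_partition(numbered_grid(2, 2), 2)
  expect_equal(dim(b1), c(1, 4, 1))
  expect_equal(b1[1, , 1], c(0, 1, 2, 3))   # row-major within the window

  expect_error(window_partition(numbered_grid(5, 4), 2), "divide")
  expect_error(window_reverse(b, 6, 6, 2), "inconsistent")
})

test_that("partition and reverse are mutual inverses over random shapes", {
  set.seed(42)
  cases <- list(c(2, 4, 4, 2, 3), c(1, 6, 9, 3, 5), c(3, 8, 4, 4, 1),
                c(2, 14, 14, 7, 2))
  for (cs in cases) {
    g <- array(stats::rnorm(prod(cs[1:3]) * cs[5]), c(cs[1], cs[2], cs[3], cs[5]))
    expect_identical(window_reverse(window_partition(g, cs[4]), cs[2], cs[3], cs[4]), g)
  }
})

test_that("cyclic shift rolls both axes and reverses exactly", {
  g <- numbered_grid(3, 3)
  expect_identical(cyclic_shift(g, 0, "forward"), g)
  f <- cyclic_shift(g, 1, "forward")
  # brute-force index map: out[i, j] = in[(i + 1) mod 3, (j + 1) mod 3]
  expected <- array(0, c(1, 3, 3, 1))
  for (i in 1:3) for (j in 1:3)
    expected[1, i, j, 1] <- g[1, (i %% 3) + 1, (j %% 3) + 1, 1]
  expect_identical(f, expected)
  set.seed(7)
  for (s in 1:3) {
    r <- array(stats::rnorm(2 * 5 * 5 * 2), c(2, 5, 5, 2))
    expect_identical(cyclic_shift(cyclic_shift(r, s, "forward"), s, "reverse"), r)
  }
  expect_error(cyclic_shift(g, 5, "forward"), "shift")
})

test_that("shifted-window mask separates pre-shift regions", {
  expect_true(all(attention_mask(4, 4, 2, 0) == 0))
  m <- attention_mask(4, 4, 2, 1)
  # independent oracle: for each window and token pair, recover the original
  # (pre-shift) coordinates and compare wrap segments per axis
  orig_coord <- function(p, s, n) ((p - 1 + s) %% n) + 1
  seg <- function(r, s) r <= s
  # blocks ordered window-column fastest; tokens row-major within a window
  blocks_rc <- list()
  for (wr in 0:1) for (wc in 0:1) {
    rows <- wr * 2 + 1:2; cols <- wc * 2 + 1:2
    blocks_rc[[length(blocks_rc) + 1]] <- expand.grid(c = cols, r = rows)
  }
  for (w in 1:4) {
    cells <- blocks_rc[[w]]
    for (i in 1:4) for (j in 1:4) {
      oi <- c(orig_coord(cells$r[i], 1, 4), orig_coord(cells$c[i], 1, 4))
      oj <- c(orig_coord(cells$r[j], 1, 4), orig_coord(cells$c[j], 1, 4))
      same <- identical(c(seg(oi[1], 1), seg(oi[2], 1)),
                        c(seg(oj[1], 1), seg(oj[2], 1)))
      if (same) expect_equal(m[w, i, j], 0)
      else expect_lt(m[w, i, j], -1e6)
    }
  }
  # a row masked everywhere but self puts softmax weight 1 on self
  row <- c(0, rep(scmix:::MASK_NEG, 3))
  sm <- softmax_rows(matrix(row, 1))
  expect_equal(as.vector(sm), c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("multi-head self-attention agrees with the dense softmax oracle", {
  dm <- 8
  w <- random_msa_weights(dm, seed = 3)
  # single token: softmax over one key is 1, output = projection of its value
  x1 <- array(stats::rnorm(dm), c(1, 1, dm))
  out1 <- multi_head_self_attention(x1, w, heads = 2)
  v <- matrix(x1[1, 1, ], 1) %*% w$Wv + matrix(w$bv, 1)
  expect_equal(as.vector(out1), as.vector(v %*% w$Wo + matrix(w$bo, 1)),
               tolerance = 1e-10)
  # 2 tokens, 1 head, hand-set weights vs the closed-form computation
  set.seed(4)
  x2 <- array(stats::rnorm(2 * 2), c(1, 2, 2))
  w2 <- list(Wq = matrix(c(1, 0, 0, 1), 2), Wk = matrix(c(0, 1, 1, 0), 2),
             Wv = matrix(c(2, 0, 1, 1), 2), Wo = diag(2),
             bq = c(0.1, 0), bk = c(0, -0.2), bv = c(0, 0), bo = c(0, 0))
  expect_equal(multi_head_self_attention(x2, w2, heads = 1)[1, , ],
               attention_oracle(x2[1, , ], w2, heads = 1), tolerance = 1e-10)
  # random blocks of <= 9 tokens, several head counts
  for (tt in c(3, 5, 9)) {
    for (heads in c(1, 2, 4)) {
      set.seed(tt * 10 + heads)
      x <- array(stats::rnorm(2 * tt * dm), c(2, tt, dm))
      out <- multi_head_self_attention(x, w, heads)
      for (b in 1:2)
        expect_equal(out[b, , ], attention_oracle(x[b, , ], w, heads),
                     tolerance = 1e-5)
    }
  }
})

test_that("attention weights are nonnegative and rows sum to 1", {
  set.seed(9)
  msa <- scmix:::new_msa(8, heads = 2, window = 2, use_relative_bias = TRUE)
  x <- array(stats::rnorm(3 * 4 * 8), c(3, 4, 8))
  msa$mask <- NULL
  ly_forward <- scmix:::ly_forward
  out <- ly_forward(msa, x, training = TRUE)
  for (a in msa$attn) {
    expect_true(all(a >= 0))
    expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-5)
  }
  # with a mask, masked keys receive zero weight
  mask <- matrix(0, 4, 4)
  mask[, 3:4] <- scmix:::MASK_NEG
  msa$mask <- mask
  out <- ly_forward(msa, x, training = TRUE)
  for (a in msa$attn) {
    expect_true(all(a[, 3:4] < 1e-12))
    expect_equal(rowSums(a), rep(1, nrow(a)), tolerance = 1e-5)
  }
})

test_that("attention is permutation-equivariant without mask or bias", {
  dm <- 8
  w <- random_msa_weights(dm, seed = 11)
  set.seed(12)
  x <- array(stats::rnorm(1 * 5 * dm), c(1, 5, dm))
  perm <- c(3, 1, 5, 2, 4)
  xp <- x[, perm, , drop = FALSE]
  out <- multi_head_self_attention(x, w, heads = 2)
  outp <- multi_head_self_attention(xp, w, heads = 2)
  expect_equal(outp[1, , ], out[1, perm, ], tolerance = 1e-10)
  expect_error(multi_head_self_attention(x * NA, w, heads = 2), "non-finite")
})

test_that("a swin cycle with zeroed branch outputs is the identity", {
  set.seed(20)
  cyc <- scmix:::new_swin_cycle(16, swin_config(window = 2, shift = 1, heads = 2,
                                                mlp_dim = 8, dropout_rate = 0))
  zero_branch_outputs(cyc)
  g <- array(stats::rnorm(2 * 4 * 4 * 16), c(2, 4, 4, 16))
  expect_equal(swin_cycle(g, cyc), g, tolerance = 1e-6)
})

test_that("swin cycles preserve shape on the full-scale token grids", {
  set.seed(21)
  cfg <- swin_config(window = 7, heads = 4, mlp_dim = 32, dropout_rate = 0)
  cyc <- scmix:::new_swin_cycle(32, cfg)
  for (side in c(28, 14)) {
    g <- array(stats::rnorm(side * side * 32), c(1, side, side, 32))
    out <- swin_cycle(g, cyc)
    expect_equal(dim(out), dim(g))
    expect_true(all(is.finite(out)))
    # repeated calls with dropout 0 and fixed weights are bit-identical
    expect_identical(out, swin_cycle(g, cyc))
  }
})
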