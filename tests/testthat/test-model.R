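test_that("nearest-neighbor upsampling replicates values and sums gradients", {
  up <- scmix:::new_upsample(2)
  x <- array(1:4, c(1, 2, 2, 1))
  y <- scmix:::ly_forward(up, x)
  # index oracle: out[i, j] = in[ceil(i/2), ceil(j/2)]
  for (i in 1:4) for (j in 1:4)
    expect_equal(y[1, i, j, 1], x[1, ceiling(i / 2), ceiling(j / 2), 1])
  g <- array(1, c(1, 4, 4, 1))
  expect_equal(scmix:::ly_backward(up, g), array(4, c(1, 2, 2, 1)))
})

test_that("the multipath ConvMixer stage fuses branches by addition", {
  set.seed(30)
  cfg <- tiny_model_config("mpcm_only")
  mpcm <- scmix:::new_mpcm(cfg)
  x <- tiny_image_batch(2)
  out <- mpcm_forward(x, mpcm)
  expect_equal(dim(out), c(2, 8, 8, 6))  # input/p1 with `filters` channels

  # forcing branches 2..n to output zeros leaves exactly branch 1
  zero_out <- function(branch) {
    bn <- branch$children[[length(branch$children)]]$children$bn_pw
    bn$params$gamma[] <- 0
    bn$params$beta[] <- 0
  }
  for (i in 2:mpcm$n_branches) zero_out(mpcm$children[[i]])
  b1 <- convmixer_branch(x, mpcm$children[[1]])
  expect_equal(mpcm_forward(x, mpcm), b1, tolerance = 1e-12)
})

test_that("full-scale MPCM yields the 112x112x128 fused map", {
  set.seed(31)
  cfg <- model_config(num_classes = 4, depth = 1)  # depth reduced for speed
  mpcm <- scmix:::new_mpcm(cfg)
  x <- array(stats::runif(224 * 224 * 3), c(1, 224, 224, 3))
  expect_equal(dim(mpcm_forward(x, mpcm)), c(1, 112, 112, 128))
})

test_that("patch extraction produces 256-wide tokens at the printed counts", {
  set.seed(32)
  f <- array(stats::rnorm(112 * 112 * 8), c(1, 112, 112, 8))
  # grid 28 (effective patch 4): k = 16 channels, 784 tokens
  pe4 <- scmix:::new_patch_extract(8, 4, 256)
  t4 <- patch_extract(f, pe4, as_tokens = TRUE)
  expect_equal(dim(t4), c(1, 784, 256))
  # grid 14 (effective patch 8): k = 4 channels, 196 tokens
  pe8 <- scmix:::new_patch_extract(8, 8, 256)
  t8 <- patch_extract(f, pe8, as_tokens = TRUE)
  expect_equal(dim(t8), c(1, 196, 256))
  # non-integer k is a configuration error
  expect_error(scmix:::new_patch_extract(8, 3, 256), "not a positive integer")

  # p_eff = 1 with an identity 1x1 conv: each token is its pixel's channels
  pe1 <- scmix:::new_patch_extract(4, 1, 4)
  pe1$children$conv$params$W <- diag(4)
  pe1$children$conv$params$b[] <- 0
  fs <- array(stats::rnorm(3 * 3 * 4), c(1, 3, 3, 4))
  g1 <- patch_extract(fs, pe1)
  for (i in 1:3) for (j in 1:3)
    expect_equal(g1[1, i, j, ], fs[1, i, j, ], tolerance = 1e-12)
})

test_that("the multipath Swin stage concatenates branch token matrices", {
  set.seed(33)
  cfg <- tiny_model_config("full")
  mpst <- scmix:::new_mpst(cfg$filters, 8, cfg)
  f <- array(stats::rnorm(2 * 8 * 8 * 6), c(2, 8, 8, 6))
  tok <- mpst_forward(f, mpst)
  # token counts are additive over branches: 4^2 + 2^2
  expect_equal(dim(tok), c(2, 16 + 4, 16))

  # zeroed residual branches: output equals the raw patch-extraction tokens
  for (br in mpst$children)
    for (i in seq_along(br$children)[-1]) zero_branch_outputs(br$children[[i]])
  tok0 <- mpst_forward(f, mpst)
  raw <- lapply(mpst$children, function(br)
    patch_extract(f, br$children$extract, as_tokens = TRUE))
  expect_equal(tok0[, 1:16, ], raw[[1]][, , ], tolerance = 1e-6)
  expect_equal(tok0[, 17:20, ], raw[[2]][, , ], tolerance = 1e-6)
})

test_that("the classification head pools tokens and normalizes probabilities", {
  set.seed(34)
  head <- scmix:::new_head(6, 3)
  # identical tokens: GAP returns that vector; zero FC gives uniform rows
  v <- stats::rnorm(6)
  x <- array(rep(v, each = 2 * 5), c(2, 5, 6))
  head$children$fc$params$W[] <- 0
  head$children$fc$params$b[] <- 0
  p <- classification_head(x, head)
  expect_equal(p, matrix(1 / 3, 2, 3), tolerance = 1e-12)

  # hand-set 2-class FC against the closed-form softmax
  head2 <- scmix:::new_head(3, 2)
  W <- matrix(c(1, 0, -1, 0.5, 2, 0), 3, 2)
  b <- c(0.1, -0.1)
  head2$children$fc$params$W <- W
  head2$children$fc$params$b <- b
  v2 <- c(0.2, -0.4, 1.1)
  x2 <- array(rep(v2, each = 3), c(1, 3, 3))
  z <- as.vector(v2 %*% W) + b
  expect_equal(as.vector(classification_head(x2, head2)),
               exp(z) / sum(exp(z)), tolerance = 1e-10)
  expect_error(scmix:::new_head(6, 1), "at least 2")
})

test_that("cross-entropy matches its closed forms and is clamped", {
  y <- matrix(c(1, 0), 1)
  expect_equal(cross_entropy(y, matrix(c(1, 0), 1)), 0)
  expect_equal(cross_entropy(y, matrix(c(0.5, 0.5), 1)), log(2), tolerance = 1e-12)
  # permutation invariance under a joint class relabeling
  set.seed(35)
  p <- matrix(stats::runif(12), 3); p <- p / rowSums(p)
  yy <- scmix:::one_hot(c(1, 3, 2), 4)
  perm <- c(4, 1, 3, 2)
  expect_equal(cross_entropy(yy[, perm], p[, perm]), cross_entropy(yy, p),
               tolerance = 1e-12)
  # zero probability at the true class stays finite via the clamp
  expect_true(is.finite(cross_entropy(y, matrix(c(0, 1), 1))))
  expect_equal(cross_entropy(y, matrix(c(0, 1), 1)), -log(1e-7), tolerance = 1e-9)
  expect_error(cross_entropy(y, matrix(c(2, 1), 1)), "sum to 1")
})

test_that("cross-entropy gradient w.r.t. logits is (P - Y) / batch", {
  set.seed(36)
  z <- matrix(stats::rnorm(6), 2, 3)
  y <- scmix:::one_hot(c(2, 3), 3)
  p <- softmax_rows(z)
  analytic <- (p - y) / 2
  fd <- matrix(0, 2, 3)
  eps <- 1e-6
  for (i in 1:2) for (j in 1:3) {
    zp <- z; zp[i, j] <- zp[i, j] + eps
    zm <- z; zm[i, j] <- zm[i, j] - eps
    fd[i, j] <- (cross_entropy(y, softmax_rows(zp)) -
                   cross_entropy(y, softmax_rows(zm))) / (2 * eps)
  }
  expect_equal(analytic, fd, tolerance = 1e-5)
})

test_that("every ablation variant builds and produces normalized predictions", {
  x <- tiny_image_batch(1)
  for (v in scmix:::MODEL_VARIANTS) {
    grids <- if (v == "mpst_only") c(8L, 4L) else c(4L, 2L)
    model <- build_model(tiny_model_config(v, mpst_grids = grids), seed = 5)
    p <- model_forward(model, x)
    expect_equal(dim(p), c(1, 3))
    expect_equal(rowSums(p), 1, tolerance = 1e-5)
    expect_true(all(p >= 0))
  }
  expect_error(model_config(3, variant = "bogus"), "convmixer_only")
})

test_that("submodels have strictly fewer parameters than the full model", {
  full <- build_model(tiny_model_config("full"), seed = 1)
  sub <- build_model(tiny_model_config("mpcm_only"), seed = 1)
  expect_lt(count_parameters(sub), count_parameters(full))
})

test_that("forward passes are deterministic given seed and dropout 0", {
  x <- tiny_image_batch(2)
  m1 <- build_model(tiny_model_config("full"), seed = 9)
  m2 <- build_model(tiny_model_config("full"), seed = 9)
  expect_identical(model_forward(m1, x), model_forward(m2, x))
  expect_identical(model_forward(m1, x), model_forward(m1, x))
})

test_that("probability rows sum to 1 across variants and random inputs", {
  set.seed(37)
  for (v in c("full", "mpcm_only", "swtrans_only")) {
    model <- build_model(tiny_model_config(v), seed = 3)
    for (rep in 1:3) {
      x <- array(stats::runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
      expect_equal(rowSums(model_forward(model, x)), c(1, 1), tolerance = 1e-5)
    }
  }
})

test_that("the token-count identity 784 + 196 = 980 holds structurally", {
  cfg <- model_config(num_classes = 2)
  token_counts <- cfg$mpst_grids^2
  expect_equal(token_counts, c(784, 196))
  expect_equal(sum(token_counts), 980)
})
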