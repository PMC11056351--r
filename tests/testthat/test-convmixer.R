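test_that("patch embedding produces the strided-convolution geometry", {
  set.seed(1)
  # full-scale geometry: 224x224x3 with p = 2 and 128 filters -> 112x112x128
  pe <- scmix:::new_patch_embed(convmixer_config(2, 128, 0), 3)
  x <- array(stats::runif(224 * 224 * 3), c(1, 224, 224, 3))
  expect_equal(dim(patch_embed(x, pe)), c(1, 112, 112, 128))

  # p = 1 preserves the spatial size
  pe1 <- scmix:::new_patch_embed(convmixer_config(1, 5, 0), 3)
  xs <- array(stats::runif(2 * 6 * 6 * 3), c(2, 6, 6, 3))
  expect_equal(dim(patch_embed(xs, pe1)), c(2, 6, 6, 5))

  # non-divisible input errors with the offending sizes
  expect_error(patch_embed(array(0, c(1, 7, 7, 3)),
                           scmix:::new_patch_embed(convmixer_config(2, 4, 0), 3)),
               "7x7")
})

test_that("patch-embedding convolution matches a sliding-window oracle", {
  set.seed(2)
  conv <- scmix:::new_patchconv(2, 3, 4)
  x <- array(stats::runif(8 * 8 * 3), c(1, 8, 8, 3))
  got <- scmix:::ly_forward(conv, x)
  want <- patchconv_oracle(x[1, , , ], conv$params$W, conv$params$b, 2)
  expect_equal(got[1, , , ], want, tolerance = 1e-10)

  # spatially constant input: all output positions identical
  xc <- array(0.37, c(1, 8, 8, 3))
  yc <- scmix:::ly_forward(conv, xc)
  expect_equal(max(abs(sweep(yc[1, , , ], 3, yc[1, 1, 1, ]))), 0, tolerance = 1e-12)
})

test_that("depthwise convolution equals the channelwise correlation oracle", {
  set.seed(3)
  for (sz in c(5, 7)) {
    dw <- scmix:::new_dwconv(3, 2)
    x <- array(stats::rnorm(sz * sz * 2), c(1, sz, sz, 2))
    got <- scmix:::ly_forward(dw, x)
    want <- dw_oracle(x[1, , , ], dw$params$W, dw$params$b, 3)
    expect_equal(got[1, , , ], want, tolerance = 1e-5)
  }
  # hand-set kernel: pure shift-down-right tap
  dw <- scmix:::new_dwconv(3, 1)
  dw$params$W[] <- 0
  dw$params$W[1, 1] <- 1          # tap (dy = 0, dx = 0) reads the up-left neighbor
  dw$params$b[] <- 0
  x <- array(0, c(1, 3, 3, 1)); x[1, 1, 1, 1] <- 1
  y <- scmix:::ly_forward(dw, x)
  expect_equal(y[1, 2, 2, 1], 1)  # mass moved down-right
  expect_equal(sum(y), 1)
})

test_that("pointwise convolution equals the per-pixel matrix multiply oracle", {
  set.seed(4)
  pw <- scmix:::new_pwconv(3, 5)
  x <- array(stats::rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  got <- scmix:::ly_forward(pw, x)
  for (n in 1:2) for (i in 1:4) for (j in 1:4)
    expect_equal(got[n, i, j, ],
                 as.vector(x[n, i, j, ] %*% pw$params$W) + pw$params$b,
                 tolerance = 1e-5)
  expect_error(scmix:::ly_forward(pw, array(0, c(1, 4, 4, 2))), "channels")
})

test_that("mixer block follows the two-stage composition with one residual", {
  set.seed(5)
  cfg <- convmixer_config(2, 4, 1)
  blk <- scmix:::new_mixer_block(cfg)
  x <- array(stats::rnorm(1 * 5 * 5 * 4), c(1, 5, 5, 4))

  # shape-preserving for any valid input
  expect_equal(dim(mixer_block(x, blk)), dim(x))

  # zeroed depthwise stage: the residual carries x into the pointwise stage
  blk$params <- NULL # guard: params live in children
  blk2 <- scmix:::new_mixer_block(cfg)
  blk2$children$dw$params$W[] <- 0
  blk2$children$dw$params$b[] <- 0
  # pointwise = identity, so output = BN(GELU(x)) with fresh inference BN
  blk2$children$pw$params$W <- diag(4)
  blk2$children$pw$params$b[] <- 0
  got <- mixer_block(x, blk2, training = FALSE)
  want <- gelu(x) / sqrt(1 + 1e-5)   # fresh BN: running mean 0, var 1
  expect_equal(got, want, tolerance = 1e-6)

  # fully zeroed kernels: output is BN(GELU(0)) = 0
  blk3 <- scmix:::new_mixer_block(cfg)
  for (nm in c("dw", "pw")) {
    blk3$children[[nm]]$params$W[] <- 0
    blk3$children[[nm]]$params$b[] <- 0
  }
  expect_equal(max(abs(mixer_block(x, blk3))), 0, tolerance = 1e-12)
})

test_that("mixer block matches the correlation oracle through its first stage", {
  set.seed(6)
  cfg <- convmixer_config(2, 2, 1)
  blk <- scmix:::new_mixer_block(cfg)
  # isolate the depthwise stage: identity pointwise, neutral BNs (inference)
  blk$children$pw$params$W <- diag(2)
  blk$children$pw$params$b[] <- 0
  x <- array(stats::rnorm(5 * 5 * 2), c(1, 5, 5, 2))
  dwo <- dw_oracle(x[1, , , ], blk$children$dw$params$W, blk$children$dw$params$b, 3)
  zp <- gelu(dwo) / sqrt(1 + 1e-5) + x[1, , , ]
  want <- gelu(zp) / sqrt(1 + 1e-5)
  expect_equal(mixer_block(x, blk)[1, , , ], want, tolerance = 1e-5)
})

test_that("a ConvMixer branch has the documented shapes and parameter count", {
  set.seed(7)
  x <- array(stats::runif(224 * 224 * 3), c(1, 224, 224, 3))
  br4 <- scmix:::new_convmixer_branch(convmixer_config(4, 128, 1), 3)
  expect_equal(dim(convmixer_branch(x, br4)), c(1, 56, 56, 128))
  br8 <- scmix:::new_convmixer_branch(convmixer_config(8, 128, 1), 3)
  expect_equal(dim(convmixer_branch(x, br8)), c(1, 28, 28, 128))

  # depth 0 equals the embedding alone
  br0 <- scmix:::new_convmixer_branch(convmixer_config(4, 8, 0), 3)
  xs <- tiny_image_batch(1)
  expect_identical(convmixer_branch(xs, br0),
                   patch_embed(xs, br0$children$embed))

  # one mixer block: h*(3*3) + h depthwise, h*h + h pointwise, 4h from two BNs
  h <- 16
  blk <- scmix:::new_mixer_block(convmixer_config(2, h, 1))
  expect_equal(scmix:::n_params(blk), h * 9 + h + h * h + h + 4 * h)
})
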