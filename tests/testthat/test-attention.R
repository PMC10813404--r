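test_that("pyramid descriptor length is 2*sum(L^2) regardless of input size", {
  levels <- c(1, 2, 4)
  for (d in list(c(3, 64, 64), c(2, 128, 96), c(1, 300, 250))) {
    M <- array(seq_len(prod(d)) / prod(d), dim = d)
    sp <- spatialPyramidPool(M, levels)
    expect_equal(nrow(sp$descriptor), 2 * (1 + 4 + 16))
    expect_equal(ncol(sp$descriptor), d[1])
  }
})

test_that("pooling a constant map returns the constant in every bin", {
  M <- array(3.0, dim = c(2, 8, 8))
  sp <- spatialPyramidPool(M, c(1, 2, 4))
  expect_true(all(sp$descriptor == 3.0))
})

test_that("pyramid pooling matches the explicit bin-enumeration oracle", {
  set.seed(13)
  M <- array(sample(seq_len(32)) / 32, dim = c(2, 4, 4))
  sp <- spatialPyramidPool(M, c(1, 2))
  oc <- oracleSPP(M, c(1, 2))
  expect_equal(unname(sp$avg), unname(oc$avg))
  expect_equal(unname(sp$max), unname(oc$max))
  ## also on non-divisible sizes
  M2 <- array(rnorm(3 * 7 * 5), dim = c(3, 7, 5))
  sp2 <- spatialPyramidPool(M2, c(1, 2, 3))
  oc2 <- oracleSPP(M2, c(1, 2, 3))
  expect_equal(unname(sp2$avg), unname(oc2$avg))
  expect_equal(unname(sp2$max), unname(oc2$max))
})

test_that("oversized pyramid levels are a bin-degeneracy error", {
  M <- array(0, dim = c(1, 3, 3))
  expect_error(spatialPyramidPool(M, c(1, 4)), "degenerate")
})

test_that("zero-weight channel attention gates at one half", {
  cfg <- attentionConfig(pyramid_levels = c(1, 2))
  M <- array(rnorm(3 * 6 * 6), dim = c(3, 6, 6))
  w <- attentionWeights(3, cfg, seed = 1)
  w$W0[] <- 0; w$W1[] <- 0
  expect_equal(channelAttention(M, w, cfg), rep(0.5, 3))
})

test_that("channel attention lies strictly inside (0,1)", {
  cfg <- attentionConfig(pyramid_levels = c(1, 2))
  set.seed(2)
  for (i in 1:5) {
    M <- array(rnorm(4 * 8 * 8), dim = c(4, 8, 8))
    dc <- channelAttention(M, attentionWeights(4, cfg, seed = i), cfg)
    expect_true(all(dc > 0 & dc < 1))
  }
})

test_that("channel attention matches the scalar loop oracle", {
  cfg <- attentionConfig(pyramid_levels = c(1, 2), reduction_ratio = 2)
  set.seed(5)
  for (i in 1:5) {
    M <- array(rnorm(3 * 5 * 7), dim = c(3, 5, 7))
    w <- attentionWeights(3, cfg, seed = i + 10)
    expect_equal(channelAttention(M, w, cfg),
                 oracleChannelAttention(M, w, c(1, 2)), tolerance = 1e-12)
  }
})

test_that("rbf activation option is honored", {
  cfg <- attentionConfig(pyramid_levels = c(1, 2), activation = "rbf")
  M <- array(rnorm(2 * 4 * 4), dim = c(2, 4, 4))
  w <- attentionWeights(2, cfg, seed = 3)
  expect_equal(channelAttention(M, w, cfg),
               oracleChannelAttention(M, w, c(1, 2), activation = "rbf"),
               tolerance = 1e-12)
})

test_that("zero-kernel spatial attention gates at one half", {
  M <- array(rnorm(3 * 6 * 6), dim = c(3, 6, 6))
  w <- list(conv_kernel = array(0, dim = c(9, 9, 2)))
  expect_equal(spatialAttention(M, w), matrix(0.5, 6, 6))
})

test_that("single-channel maps make mean and max pooling coincide", {
  M <- array(rnorm(1 * 8 * 8), dim = c(1, 8, 8))
  k <- array(0, dim = c(3, 3, 2))
  k[2, 2, 1] <- 1      # identity on the mean map only
  w <- list(conv_kernel = k)
  got <- spatialAttention(M, w)
  expect_equal(got, 1 / (1 + exp(-M[1, , ])))
})

test_that("spatial attention matches the scalar loop oracle", {
  set.seed(8)
  M <- array(rnorm(3 * 6 * 5), dim = c(3, 6, 5))
  w <- attentionWeights(3, attentionConfig(), seed = 4)
  expect_equal(spatialAttention(M, w),
               oracleSpatialAttention(M, w$conv_kernel), tolerance = 1e-12)
})

test_that("zero-weight attention block scales the input by one quarter", {
  cfg <- attentionConfig(pyramid_levels = c(1, 2))
  M <- array(rnorm(3 * 8 * 8), dim = c(3, 8, 8))
  w <- attentionWeights(3, cfg, seed = 1)
  w$W0[] <- 0; w$W1[] <- 0; w$conv_kernel[] <- 0
  expect_equal(scmBlock(M, w, cfg), 0.25 * M, tolerance = 1e-12)
  expect_equal(scmBlock(array(0, dim = dim(M)), w, cfg),
               array(0, dim = dim(M)))
})

test_that("attention block matches the naive loop oracle", {
  cfg <- attentionConfig(pyramid_levels = c(1, 2), reduction_ratio = 2,
                         spatial_kernel = 3)
  set.seed(14)
  for (i in 1:5) {
    C <- sample(2:4, 1); H <- sample(4:10, 1); W <- sample(4:10, 1)
    M <- array(rnorm(C * H * W), dim = c(C, H, W))
    w <- attentionWeights(C, cfg, seed = i + 40)
    expect_equal(scmBlock(M, w, cfg), oracleScmBlock(M, w, c(1, 2)),
                 tolerance = 1e-6)
  }
})

test_that("attention preserves shape and can only attenuate", {
  cfg <- attentionConfig(pyramid_levels = c(1, 2))
  set.seed(19)
  for (d in list(c(2, 6, 6), c(3, 9, 7), c(4, 12, 5))) {
    M <- array(rnorm(prod(d), sd = 2), dim = d)
    w <- attentionWeights(d[1], cfg, seed = d[1])
    out <- scmBlock(M, w, cfg)
    expect_equal(dim(out), d)
    expect_lte(max(abs(out)), max(abs(M)))
    outP <- scmBlock(M, w, attentionConfig(pyramid_levels = c(1, 2),
                                           arrangement = "parallel"))
    expect_equal(dim(outP), d)
    expect_lte(max(abs(outP)), max(abs(M)))
  }
})
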