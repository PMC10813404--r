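## Gradient correctness of the hand-written layers: every backward pass is
## compared against central finite differences on small instances.

numGrad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("convolution forward matches a direct nested-loop evaluation", {
  set.seed(1)
  x <- array(rnorm(2 * 5 * 4), dim = c(2, 5, 4))
  K <- array(rnorm(3 * 2 * 3 * 3), dim = c(3, 2, 3, 3))
  b <- rnorm(3)
  y <- fundusHR:::convForward(x, K, b)$y
  for (o in 1:3) for (r in 1:5) for (cc in 1:4) {
    acc <- b[o]
    for (ci in 1:2) for (i in 1:3) for (j in 1:3) {
      rr <- r + i - 2; cj <- cc + j - 2
      if (rr >= 1 && rr <= 5 && cj >= 1 && cj <= 4)
        acc <- acc + K[o, ci, i, j] * x[ci, rr, cj]
    }
    expect_equal(y[o, r, cc], acc)
  }
})

test_that("convolution gradients match finite differences", {
  set.seed(2)
  x <- array(rnorm(2 * 4 * 4), dim = c(2, 4, 4))
  K <- array(rnorm(2 * 2 * 3 * 3), dim = c(2, 2, 3, 3))
  b <- rnorm(2)
  dy <- array(rnorm(2 * 4 * 4), dim = c(2, 4, 4))
  fw <- fundusHR:::convForward(x, K, b)
  bk <- fundusHR:::convBackward(dy, x, K, fw)
  expect_equal(bk$dx,
               numGrad(function(xx)
                 sum(fundusHR:::convForward(xx, K, b)$y * dy), x),
               tolerance = 1e-6)
  expect_equal(bk$dK,
               numGrad(function(KK)
                 sum(fundusHR:::convForward(x, KK, b)$y * dy), K),
               tolerance = 1e-6)
  expect_equal(bk$db,
               as.vector(numGrad(function(bb)
                 sum(fundusHR:::convForward(x, K, bb)$y * dy), b)),
               tolerance = 1e-6)
})

test_that("max pooling and upsampling invert shapes and route gradients", {
  set.seed(3)
  x <- array(rnorm(2 * 6 * 6), dim = c(2, 6, 6))
  pf <- fundusHR:::poolForward(x)
  expect_equal(dim(pf$y), c(2, 3, 3))
  expect_equal(pf$y[1, 1, 1], max(x[1, 1:2, 1:2]))
  dy <- array(rnorm(2 * 3 * 3), dim = c(2, 3, 3))
  dx <- fundusHR:::poolBackward(dy, pf)
  expect_equal(dx,
               numGrad(function(xx)
                 sum(fundusHR:::poolForward(xx)$y * dy), x),
               tolerance = 1e-6)
  uf <- fundusHR:::upForward(pf$y)
  expect_equal(dim(uf$y), c(2, 6, 6))
  expect_equal(uf$y[1, 1, 1], pf$y[1, 1, 1])
  expect_equal(uf$y[1, 2, 2], pf$y[1, 1, 1])
  du <- fundusHR:::upBackward(x, uf)
  expect_equal(du,
               numGrad(function(zz)
                 sum(fundusHR:::upForward(zz)$y * x), pf$y),
               tolerance = 1e-6)
})

test_that("attention block backward matches finite differences", {
  set.seed(4)
  cfg <- attentionConfig(pyramid_levels = c(1, 2), reduction_ratio = 2,
                         spatial_kernel = 3)
  M <- array(rnorm(3 * 6 * 5), dim = c(3, 6, 5))
  w <- attentionWeights(3, cfg, seed = 2)
  dy <- array(rnorm(3 * 6 * 5), dim = c(3, 6, 5))
  fw <- fundusHR:::scmForwardT(M, w, cfg)
  bk <- fundusHR:::scmBackwardT(dy, w, cfg, fw$cache)
  expect_equal(bk$dx,
               numGrad(function(MM)
                 sum(fundusHR:::scmForwardT(MM, w, cfg)$y * dy), M),
               tolerance = 1e-5)
  expect_equal(bk$dW0,
               numGrad(function(W0) {
                 w2 <- w; w2$W0 <- W0
                 sum(fundusHR:::scmForwardT(M, w2, cfg)$y * dy)
               }, w$W0), tolerance = 1e-5)
  expect_equal(bk$dkern,
               numGrad(function(kk) {
                 w2 <- w; w2$conv_kernel <- kk
                 sum(fundusHR:::scmForwardT(M, w2, cfg)$y * dy)
               }, w$conv_kernel), tolerance = 1e-5)
})

test_that("dice+bce loss gradient matches finite differences", {
  set.seed(5)
  z <- matrix(rnorm(20), 4, 5)
  t <- matrix(rbinom(20, 1, 0.4), 4, 5)
  p <- 1 / (1 + exp(-z))
  ls <- fundusHR:::diceBceLoss(p, t)
  gz <- numGrad(function(zz) {
    pp <- 1 / (1 + exp(-zz))
    fundusHR:::diceBceLoss(pp, t)$loss
  }, z)
  expect_equal(ls$dz, gz, tolerance = 1e-5)
  expect_true(ls$dice >= 0 && ls$dice <= 1)
})

test_that("whole-network gradients match finite differences", {
  set.seed(6)
  cfg <- segNetConfig(depth = 2, base_channels = 4,
                      attention = attentionConfig(pyramid_levels = c(1, 2),
                                                  spatial_kernel = 3),
                      seed = 7)
  net <- buildSegNet(cfg)
  x <- matrix(runif(16 * 12), 16, 12)
  y <- matrix(rbinom(16 * 12, 1, 0.3), 16, 12)
  fw <- fundusHR:::segNetForward(net, x, keepCache = TRUE)
  ls <- fundusHR:::diceBceLoss(fw$prob, y)
  g <- fundusHR:::segNetBackward(net, fw$cache, ls$dz)
  lossAt <- function(wts) {
    net2 <- net; net2@weights <- wts
    fundusHR:::diceBceLoss(fundusHR:::segNetForward(net2, x)$prob, y)$loss
  }
  for (nm in c("enc1_K", "attn2_kern", "bott_K", "dec1_K", "head_K")) {
    p <- net@weights[[nm]]
    ii <- sample(length(p), min(4, length(p)))
    for (i in ii) {
      eps <- 1e-5
      a <- net@weights; a[[nm]][i] <- a[[nm]][i] + eps
      b <- net@weights; b[[nm]][i] <- b[[nm]][i] - eps
      expect_equal(g[[nm]][i], (lossAt(a) - lossAt(b)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("paired augmentation: identity, determinism, and involution", {
  set.seed(7)
  img <- matrix(runif(40 * 40), 40, 40)
  msk <- matrix(FALSE, 40, 40); msk[15:25, 10:30] <- TRUE
  ident <- augmentPair(img, msk, seed = 1, rotation = 0, shear = 0,
                       translate = 0)
  expect_equal(ident$image, img, tolerance = 1e-9)
  expect_equal(ident$mask, msk)
  a1 <- augmentPair(img, msk, seed = 42)
  a2 <- augmentPair(img, msk, seed = 42)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_error(augmentPair(img, msk[1:20, ], seed = 1), "differ")
  ## rotating 180 degrees twice recovers the interior
  pars <- list(angle = 180, shear = 0, dy = 0, dx = 0)
  once <- fundusHR:::applyAffinePair(img, msk, pars)
  twice <- fundusHR:::applyAffinePair(once$image, once$mask, pars)
  core <- 10:30
  expect_equal(twice$image[core, core], img[core, core], tolerance = 1e-6)
  expect_equal(twice$mask[core, core], msk[core, core])
})
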