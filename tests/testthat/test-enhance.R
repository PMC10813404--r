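test_that("gaussian response matches hand arithmetic on a 2x2 channel", {
  ch <- matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)
  st <- gaussianResponse(ch)
  m <- (0.2 + 0.4 + 0.6 + 0.8) / 4
  s <- sqrt(((0.2 - m)^2 + (0.4 - m)^2 + (0.6 - m)^2 + (0.8 - m)^2) / 4)
  expect_equal(st$m, m)
  expect_equal(st$s, s)
  expect_equal(st$n, 4)
  for (i in 1:4)
    expect_equal(st$G[i], exp(-(ch[i] - m)^2 / s) / (2 * pi * s))
})

test_that("gaussian response peaks where intensity equals the mean", {
  ch <- matrix(c(0.1, 0.5, 0.9, 0.5, 0.3, 0.7), 2, 3)
  st <- gaussianResponse(ch)
  expect_equal(max(st$G), 1 / (2 * pi * st$s))
  expect_true(all(which(st$G == max(st$G)) %in% which(ch == st$m)))
})

test_that("constant channels raise the degenerate-channel condition", {
  expect_error(gaussianResponse(matrix(0.4, 3, 3)),
               class = "fundusHR_degenerate_channel")
})

test_that("textbook Gaussian option uses the standard density", {
  ch <- matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)
  st <- gaussianResponse(ch, textbookGaussian = TRUE)
  expect_equal(st$G[1], dnorm(0.2, st$m, st$s))
})

test_that("channel probability equals brute-force histogram counting", {
  expect_equal(channelProbability(matrix(0.3, 4, 4)),
               matrix(1, 4, 4))
  half <- matrix(rep(c(0.2, 0.8), each = 8), 4, 4)
  expect_equal(channelProbability(half), matrix(0.5, 4, 4))
  set.seed(9)
  p <- matrix(sample(c(0.1, 0.25, 0.25, 0.7), 16, replace = TRUE), 4, 4)
  got <- channelProbability(p)
  for (i in seq_along(p)) {
    bin <- min(floor(p[i] * 256), 255)
    cnt <- sum(pmin(floor(p * 256), 255) == bin)
    expect_equal(got[i], cnt / 16)
  }
})

test_that("contrast gain follows the printed algebra", {
  ch <- matrix(c(0.2, 0.6, 0.4, 0.8), 2, 2)
  st <- gaussianResponse(ch)
  ## forced G = 0: g = 1 everywhere, gain = 1 + f
  st0 <- st; st0$G <- matrix(0, 2, 2)
  cg0 <- contrastGain(ch, st0, lam = 0.2)
  expect_equal(cg0$g, matrix(1, 2, 2))
  expect_equal(cg0$gain, matrix(1 + cg0$f, 2, 2))
  ## f = 0 when every pixel is at full intensity: identity gain
  ones <- matrix(1, 2, 2)
  stOnes <- list(G = matrix(0.5, 2, 2))
  cg1 <- contrastGain(ones, stOnes, lam = 0.2)
  expect_equal(cg1$f, 0)
  expect_equal(cg1$gain, matrix(1, 2, 2))
  expect_equal(cg1$enhanced, ones)
  ## worked 2x2 example against scalar arithmetic
  cg <- contrastGain(ch, st, lam = 0.2)
  fExp <- 0
  for (i in 1:4) fExp <- fExp + (1 / 4) * (1 - ch[i])   # each value unique
  fExp <- fExp / 4
  expect_equal(cg$f, fExp)
  for (i in 1:4) {
    gi <- 1 + st$G[i] / 0.2
    expect_equal(cg$g[i], gi)
    expect_equal(cg$gain[i], 1 + fExp / gi)
    expect_equal(cg$enhanced[i], min(ch[i] * (1 + fExp / gi), 1))
  }
  expect_error(contrastGain(ch, st, lam = 0), "positive")
})

test_that("HSV transform handles gray, pure and mixed pixels", {
  gray <- array(0.5, dim = c(1, 1, 3))
  hg <- hsvTransform(gray)
  expect_equal(hg$beta_s[1, 1], 0)
  expect_equal(hg$beta_v[1, 1], 1 / 3)
  expect_equal(hg$beta_h[1, 1], 0)      # sentinel
  expect_false(hg$hueValid[1, 1])

  red <- array(c(1, 0, 0), dim = c(1, 1, 3))
  hr <- hsvTransform(red)
  expect_equal(hr$beta_r[1, 1], 1)
  expect_equal(hr$beta_v[1, 1], 1)
  expect_equal(hr$beta_s[1, 1], 1)

  px <- array(c(0.6, 0.3, 0.1), dim = c(1, 1, 3))
  hp <- hsvTransform(px)
  br <- 0.6 / 1; bg <- 0.3 / 1; bb <- 0.1 / 1
  expect_equal(hp$beta_r[1, 1], br)
  expect_equal(hp$beta_s[1, 1], (br - bb) / br)
  expect_equal(hp$beta_v[1, 1], br)
  hExp <- acos(0.5 * (2 * br - bg - bb) /
               sqrt((br - bg)^2 + (br - bb) * (bg - bb)))
  expect_equal(hp$beta_h[1, 1], hExp)
})

test_that("chromaticities sum to one wherever the pixel is lit", {
  set.seed(4)
  img <- array(runif(30 * 20 * 3), dim = c(30, 20, 3))
  hh <- hsvTransform(img)
  tot <- hh$beta_r + hh$beta_g + hh$beta_b
  expect_true(all(abs(tot - 1) < 1e-9))
  expect_true(all(hh$beta_s >= 0 & hh$beta_s <= 1))
  expect_true(all(hh$beta_v >= 0 & hh$beta_v <= 1))
})

test_that("Doane normalization: symmetric data has zero skewness", {
  sym <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), 4), 4, 4)
  expect_lt(abs(doaneNormalize(sym)$skew), 1e-12)
})

test_that("Doane skewness matches the central-moment oracle", {
  pl <- matrix(rep(c(0.1, 0.2, 0.7), 8), 4, 6)
  dn <- doaneNormalize(pl)
  m <- mean(pl); s <- sqrt(mean((pl - m)^2))
  kExp <- mean((pl - m)^3) / s^3
  expect_equal(dn$skew, kExp)
  expect_true(all(is.finite(dn$psi_h)))
  expect_true(all(dn$psi_h >= 0 & dn$psi_h <= 1))
})

test_that("Doane guards absorb zeros and constants", {
  withZeros <- matrix(c(0, 0.5, 0.25, 1), 2, 2)
  expect_true(all(is.finite(doaneNormalize(withZeros)$psi_h)))
  expect_true(all(is.finite(doaneNormalize(matrix(0.3, 2, 2))$psi_h)))
})

test_that("channel selection cascade: ties fall through to the value plane", {
  pl <- matrix(runif(25), 5, 5)
  sel <- selectChannel(list(beta_h = pl, beta_s = pl, beta_v = pl))
  expect_true(all(sel$choice_map == "v"))
  expect_equal(sel$selected_plane, pl)
})

test_that("channel selection picks hue when its probability is lowest", {
  h <- matrix(seq(0, 1, length.out = 16), 4, 4)  # all unique: prob 1/16
  s <- matrix(0.5, 4, 4)                         # prob 1
  v <- matrix(0.25, 4, 4)
  sel <- selectChannel(list(beta_h = h, beta_s = s, beta_v = v))
  expect_true(all(sel$choice_map == "h"))
})

test_that("channel selection equals the brute-force cascade per pixel", {
  set.seed(11)
  for (rep in 1:5) {
    hsv <- list(beta_h = matrix(sample(seq(0, 1, 0.1), 36, TRUE), 6, 6),
                beta_s = matrix(sample(seq(0, 1, 0.25), 36, TRUE), 6, 6),
                beta_v = matrix(sample(seq(0, 1, 0.5), 36, TRUE), 6, 6))
    sel <- selectChannel(hsv)
    ph <- channelProbability(hsv$beta_h)
    ps <- channelProbability(hsv$beta_s)
    pv <- channelProbability(hsv$beta_v)
    for (i in seq_len(36)) {
      mp <- (ph[i] + ps[i] + pv[i]) / 3
      exp_tag <- if (ph[i] < mp) "h" else if (ps[i] < mp) "s" else "v"
      expect_identical(sel$choice_map[i], exp_tag)
      exp_val <- switch(exp_tag, h = hsv$beta_h[i], s = hsv$beta_s[i],
                        v = hsv$beta_v[i])
      expect_identical(sel$selected_plane[i], exp_val)
    }
  }
})

test_that("preprocessing is deterministic and stays in [0,1]", {
  s <- generateFundus(syntheticSpec(seed = 21, width = 64, height = 64,
                                    grade = "mild"))
  e1 <- preprocessFundus(s@fundus)
  e2 <- preprocessFundus(s@fundus)
  expect_identical(enhancedPlane(e1), enhancedPlane(e2))
  expect_identical(choiceMap(e1), choiceMap(e2))
  expect_true(all(enhancedPlane(e1) >= 0 & enhancedPlane(e1) <= 1))
})

test_that("achromatic input reduces to the Doane-normalized value plane", {
  g <- matrix(seq(0.1, 0.9, length.out = 64), 8, 8)
  img <- array(rep(g, 3), dim = c(8, 8, 3))   # gray: identical HSV planes
  e <- preprocessFundus(img)
  expect_true(all(choiceMap(e) == "v"))
})

test_that("enhancement does not reduce local contrast on clean fixtures", {
  for (seed in c(31, 32)) {
    s <- generateFundus(syntheticSpec(seed = seed, width = 64, height = 64,
                                      grade = "normal", noise_sd = 0))
    e <- preprocessFundus(s@fundus)
    rawGreen <- imageData(s)[, , 2]
    expect_gte(localRMSContrast(enhancedPlane(e)),
               localRMSContrast(rawGreen))
  }
})

test_that("a constant channel degrades to identity gain with a warning", {
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  img[, , 3] <- 0.5
  expect_warning(e <- preprocessFundus(img), "constant")
  expect_true(provenance(e)$channels[[3]]$degenerate)
})
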