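barMask <- function(h = 40, w = 40, rows = 18:22, cols = 5:35) {
  m <- matrix(FALSE, h, w); m[rows, cols] <- TRUE; m
}

test_that("a straight bar yields one segment of its width and no junctions", {
  g <- skeletonizeVessels(barMask())   # 5 px wide horizontal bar
  expect_equal(length(vesselSegments(g)), 1)
  expect_equal(nrow(junctions(g)), 0)
  expect_gte(segmentWidths(g)[1], 4)
  expect_lte(segmentWidths(g)[1], 6)
})

test_that("an empty mask gives an empty graph", {
  g <- skeletonizeVessels(matrix(FALSE, 20, 20))
  expect_equal(length(vesselSegments(g)), 0)
  expect_equal(length(segmentWidths(g)), 0)
})

test_that("a Y-shaped mask has one bifurcation and three segments", {
  m <- matrix(FALSE, 48, 48)
  ## stem plus two diverging branches
  m[24:44, 22:26] <- TRUE
  for (i in 0:18) {
    m[24 - i, (22:26) - i] <- TRUE
    m[24 - i, (22:26) + i] <- TRUE
  }
  g <- skeletonizeVessels(m)
  jn <- junctions(g)
  expect_equal(nrow(jn), 1)
  expect_identical(jn$type, "bifurcation")
  expect_equal(length(vesselSegments(g)), 3)
})

test_that("crossing bars are typed as a crossover that segments pass through", {
  m <- matrix(FALSE, 41, 41)
  m[19:23, 3:39] <- TRUE
  m[3:39, 19:23] <- TRUE
  g <- skeletonizeVessels(m)
  jn <- junctions(g)
  expect_equal(sum(jn$type == "crossover"), 1)
  expect_equal(sum(jn$type == "bifurcation"), 0)
  expect_equal(length(vesselSegments(g)), 4)
  ## the crossover sits near the intersection center
  expect_lt(abs(jn$row[jn$type == "crossover"] - 21), 3)
  expect_lt(abs(jn$col[jn$type == "crossover"] - 21), 3)
})

test_that("crossover erosion removes a disc around crossings only", {
  m <- matrix(FALSE, 41, 41)
  m[19:23, 3:39] <- TRUE
  m[3:39, 19:23] <- TRUE
  g <- skeletonizeVessels(m)
  pruned <- erodeCrossovers(m, g, radius = 3)
  expect_lt(sum(pruned), sum(m))
  expect_false(pruned[21, 21])
  expect_true(pruned[21, 5])
  ## no crossovers: mask unchanged
  gb <- skeletonizeVessels(barMask())
  expect_identical(erodeCrossovers(barMask(), gb), barMask())
})

test_that("bifurcation counts on a clean binary tree match its depth", {
  ## a deterministic non-overlapping binary tree: 1 + 2 + 4 = 7 branch
  ## points over three splitting generations
  mask <- matrix(FALSE, 160, 160)
  drawBranch <- function(mask, p0, ang, len, w) {
    t <- seq(0, 1, length.out = 2 * len)
    for (tt in t)
      mask <- fundusHR:::stampDisc(mask, p0[1] - tt * len * cos(ang),
                                   p0[2] + tt * len * sin(ang), w / 2)
    mask
  }
  tip <- function(p0, ang, len) c(p0[1] - len * cos(ang),
                                  p0[2] + len * sin(ang))
  grow <- function(mask, p0, ang, len, w, depth) {
    mask <- drawBranch(mask, p0, ang, len, w)
    if (depth > 1) {
      p1 <- tip(p0, ang, len)
      for (s in c(-0.55, 0.55))
        mask <- grow(mask, p1, ang + s, len * 0.62, w * 0.7, depth - 1)
    }
    mask
  }
  mask <- grow(mask, c(150, 80), 0, 52, 6, 4)
  g <- skeletonizeVessels(mask)
  jn <- junctions(g)
  nb <- sum(jn$type == "bifurcation")
  expect_gte(nb, 5)       # 7 drawn branch points, merge tolerance +-2
  expect_lte(nb, 9)
  expect_equal(sum(jn$type == "crossover"), 0)
})

test_that("junction detection finds the generator's rendered branch points", {
  s <- generateFundus(syntheticSpec(seed = 5, width = 128, height = 128,
                                    grade = "normal", vessel_tree_depth = 3,
                                    noise_sd = 0))
  ## veins only; the two arcades share a root and their wiggly strokes
  ## self-overlap, so detection sees the rendered branch points plus
  ## overlap-induced junctions -- at least half the bookkeeping count of
  ## all four arcades must surface
  g <- skeletonizeVessels(veinMask(s))
  nb <- sum(junctions(g)$type == "bifurcation")
  expect_gte(nb, s@spec$rendered$n_bifurcations / 4)
})

test_that("artery/vein fallback rule recovers the generator's labels", {
  s <- generateFundus(syntheticSpec(seed = 9, width = 128, height = 128,
                                    grade = "normal", noise_sd = 0))
  g <- skeletonizeVessels(vesselMask(s))
  av <- classifyArteryVein(s@fundus, g)
  expect_equal(nrow(av), length(vesselSegments(g)))
  ## ground truth per segment by centerline-majority against the masks
  truth <- vapply(vesselSegments(g), function(px) {
    a <- sum(arteryMask(s)[px]); v <- sum(veinMask(s)[px])
    if (a >= v) "artery" else "vein"
  }, character(1))
  keep <- vapply(vesselSegments(g), function(px) {
    a <- sum(arteryMask(s)[px]); v <- sum(veinMask(s)[px])
    max(a, v) / max(a + v, 1) > 0.8    # unambiguous segments
  }, logical(1))
  expect_gte(mean(av$label[keep] == truth[keep]), 0.9)
  expect_true(all(av$confidence >= 0 & av$confidence <= 1))
})

test_that("identical segments degenerate to one class with a flag", {
  m <- matrix(FALSE, 40, 60)
  m[10:12, 5:55] <- TRUE
  m[30:32, 5:55] <- TRUE        # two identical bars
  g <- skeletonizeVessels(m)
  img <- array(0.4, dim = c(40, 60, 3))
  expect_warning(av <- classifyArteryVein(img, g), "degenerate")
  expect_equal(length(unique(av$label)), 1)
})

test_that("a model can drive the artery/vein decision", {
  s <- generateFundus(syntheticSpec(seed = 9, width = 128, height = 128,
                                    grade = "normal", noise_sd = 0))
  g <- skeletonizeVessels(vesselMask(s))
  av <- classifyArteryVein(s@fundus, g)
  feats <- as.matrix(av[, c("brightness", "width", "reflex", "hue_var")])
  model <- fitClassifier(knnVariant("fine"), feats, av$label)
  av2 <- classifyArteryVein(s@fundus, g, model = model)
  expect_identical(av2$label, av$label)   # self-neighbor reproduces labels
  expect_error(classifyArteryVein(s@fundus, g, fallback = FALSE),
               "fallback")
})
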