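#' Configuration of the vessel-segmentation network
#'
#' A U-shaped encoder--decoder: each encoder stage is a 3x3 convolution +
#' ReLU followed by a spatial-convolution attention block and 2x2 max
#' pooling; the decoder mirrors with nearest-neighbor upsampling and skip
#' connections; a 1x1 sigmoid head emits per-pixel vessel probabilities.
#' The bottleneck is summarized by a spatial-pyramid-pooled descriptor of
#' fixed length regardless of the input size.
#'
#' @param depth encoder stages (default 3).
#' @param base_channels channels of the first stage, doubled per stage.
#' @param attention an [attentionConfig()]; pyramid levels must fit the
#'   bottleneck (`c(1,2)` by default here, safe down to 64 x 64 inputs).
#' @param threshold probability cut for [segmentVessels()], in (0,1).
#' @param epochs,batch_size,learning_rate,seed training controls.
#' @return named list of class `"segNetConfig"`.
#' @export
segNetConfig <- function(depth = 3L, base_channels = 16L,
                         attention = attentionConfig(pyramid_levels = c(1, 2)),
                         threshold = 0.5, epochs = 30L, batch_size = 1L,
                         learning_rate = 1e-2, seed = 1L) {
  if (depth < 1) stop("depth must be at least 1")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 attention = attention, threshold = threshold,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "segNetConfig")
}

heConv <- function(Cout, Cin, k) {
  lim <- sqrt(6 / (Cin * k * k))
  array(runif(Cout * Cin * k * k, -lim, lim), dim = c(Cout, Cin, k, k))
}

#' Build an untrained segmentation network
#'
#' Initializes all weights (He-uniform) deterministically from the config
#' seed.
#'
#' @param cfg a [segNetConfig()].
#' @return a [SegNet-class].
#' @export
buildSegNet <- function(cfg = segNetConfig()) {
  d <- cfg$depth; base <- cfg$base_channels
  chans <- base * 2^(seq_len(d) - 1L)
  withSeed(cfg$seed, {
    w <- list()
    cin <- 1L
    for (i in seq_len(d)) {
      w[[paste0("enc", i, "_K")]] <- heConv(chans[i], cin, 3L)
      w[[paste0("enc", i, "_b")]] <- numeric(chans[i])
      aw <- attentionWeights(chans[i], cfg$attention,
                             seed = sample.int(1e6, 1))
      w[[paste0("attn", i, "_W0")]] <- aw$W0
      w[[paste0("attn", i, "_W1")]] <- aw$W1
      w[[paste0("attn", i, "_kern")]] <- aw$conv_kernel
      cin <- chans[i]
    }
    w$bott_K <- heConv(chans[d], chans[d], 3L)
    w$bott_b <- numeric(chans[d])
    cprev <- chans[d]
    for (i in rev(seq_len(d))) {
      w[[paste0("dec", i, "_K")]] <- heConv(chans[i], cprev + chans[i], 3L)
      w[[paste0("dec", i, "_b")]] <- numeric(chans[i])
      cprev <- chans[i]
    }
    w$head_K <- heConv(1L, chans[1], 1L)
    ## start the head at the vessel-class prior (~10% of the FOV) instead
    ## of 0.5: with Dice+BCE on sparse masks a neutral start can spend
    ## many epochs un-learning the background
    w$head_b <- -2
    new("SegNet", config = unclass(cfg), weights = w)
  })
}

#' Number of parameters of a segmentation network
#'
#' @param model a [SegNet-class].
#' @return integer parameter count.
#' @export
segNetParameterCount <- function(model) {
  sum(vapply(model@weights, length, integer(1)))
}

## Forward pass. x: H x W matrix (single input plane). Returns the
## probability map, the fixed-length bottleneck descriptor, and (when
## `keepCache`) everything backward needs.
segNetForward <- function(model, x, keepCache = FALSE) {
  cfg <- model@config; w <- model@weights
  d <- cfg$depth
  acfg <- cfg$attention
  t0 <- array(x, dim = c(1L, nrow(x), ncol(x)))
  caches <- list(); skips <- list(); skipDims <- list()
  cur <- t0
  for (i in seq_len(d)) {
    cv <- convForward(cur, w[[paste0("enc", i, "_K")]],
                      w[[paste0("enc", i, "_b")]])
    rl <- reluForward(cv$y)
    sc <- scmForwardT(rl$y, list(W0 = w[[paste0("attn", i, "_W0")]],
                                 W1 = w[[paste0("attn", i, "_W1")]],
                                 conv_kernel = w[[paste0("attn", i, "_kern")]]),
                      acfg)
    pl <- poolForward(sc$y)
    caches[[i]] <- list(conv = cv, relu = rl, scm = sc$cache, pool = pl,
                        convIn = cur)
    skips[[i]] <- sc$y
    skipDims[[i]] <- dim(sc$y)
    cur <- pl$y
  }
  bt <- convForward(cur, w$bott_K, w$bott_b)
  btr <- reluForward(bt$y)
  descriptor <- as.vector(
    spatialPyramidPool(btr$y, acfg$pyramid_levels, pool = "both")$descriptor)
  decCaches <- list()
  cur2 <- btr$y
  for (i in rev(seq_len(d))) {
    up <- upForward(cur2)
    ft <- fitForward(up$y, skipDims[[i]][2], skipDims[[i]][3])
    cat_ <- concatC(ft$y, skips[[i]])
    cv <- convForward(cat_, w[[paste0("dec", i, "_K")]],
                      w[[paste0("dec", i, "_b")]])
    rl <- reluForward(cv$y)
    decCaches[[i]] <- list(up = up, fit = ft, conv = cv, relu = rl,
                           catIn = cat_, upC = dim(ft$y)[1])
    cur2 <- rl$y
  }
  hd <- convForward(cur2, w$head_K, w$head_b)
  prob <- logistic(hd$y[1, , ])
  out <- list(prob = prob, descriptor = descriptor)
  if (keepCache)
    out$cache <- list(enc = caches, bott = bt, bottRelu = btr,
                      dec = decCaches, head = hd, headIn = cur2, prob = prob)
  out
}

concatC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

segNetBackward <- function(model, cache, dz) {
  cfg <- model@config; w <- model@weights
  d <- cfg$depth; acfg <- cfg$attention
  g <- list()
  dzt <- array(dz, dim = c(1L, nrow(dz), ncol(dz)))
  hb <- convBackward(dzt, NULL, w$head_K, cache$head)
  g$head_K <- hb$dK; g$head_b <- hb$db
  cur <- hb$dx
  for (i in seq_len(d)) {      # decoder stages, innermost-first is i=1
    dcx <- cache$dec[[i]]
    cur <- reluBackward(cur, dcx$relu)
    cb <- convBackward(cur, NULL, w[[paste0("dec", i, "_K")]], dcx$conv)
    g[[paste0("dec", i, "_K")]] <- cb$dK
    g[[paste0("dec", i, "_b")]] <- cb$db
    upC <- dcx$upC
    dUpPath <- cb$dx[seq_len(upC), , , drop = FALSE]
    dSkip <- cb$dx[upC + seq_len(dim(cb$dx)[1] - upC), , , drop = FALSE]
    dUp <- upBackward(fitBackward(dUpPath, dcx$fit), dcx$up)
    ## stash the skip-path gradient for encoder stage i
    g[[paste0(".skip", i)]] <- dSkip
    cur <- dUp
  }
  ## bottleneck (descriptor branch not trained through here; the
  ## segmentation loss does not touch it)
  cur <- reluBackward(cur, cache$bottRelu)
  bb <- convBackward(cur, NULL, w$bott_K, cache$bott)
  g$bott_K <- bb$dK; g$bott_b <- bb$db
  cur <- bb$dx
  for (i in rev(seq_len(d))) {
    enc <- cache$enc[[i]]
    dscm <- poolBackward(cur, enc$pool) + g[[paste0(".skip", i)]]
    g[[paste0(".skip", i)]] <- NULL
    sb <- scmBackwardT(dscm,
                       list(W0 = w[[paste0("attn", i, "_W0")]],
                            W1 = w[[paste0("attn", i, "_W1")]],
                            conv_kernel = w[[paste0("attn", i, "_kern")]]),
                       acfg, enc$scm)
    g[[paste0("attn", i, "_W0")]] <- sb$dW0
    g[[paste0("attn", i, "_W1")]] <- sb$dW1
    g[[paste0("attn", i, "_kern")]] <- sb$dkern
    cur2 <- reluBackward(sb$dx, enc$relu)
    cb <- convBackward(cur2, NULL, w[[paste0("enc", i, "_K")]], enc$conv)
    g[[paste0("enc", i, "_K")]] <- cb$dK
    g[[paste0("enc", i, "_b")]] <- cb$db
    cur <- cb$dx
  }
  g
}

#' Train the segmentation network
#'
#' Minimizes a Dice + binary-cross-entropy loss with Adam over
#' (enhanced plane, binary mask) pairs. Deterministic given the config
#' seed: sample order shuffles reproducibly each epoch.
#'
#' @param model a [SegNet-class].
#' @param samples list of `list(x = H x W plane, y = logical mask)` pairs.
#' @param epochs override of the config epoch count.
#' @param verbose print per-epoch loss.
#' @return the trained [SegNet-class] with an appended `lossTrace`.
#' @export
trainSegNet <- function(model, samples, epochs = NULL, verbose = FALSE) {
  cfg <- model@config
  if (length(samples) < 1) stop("empty training set")
  for (s in samples) {
    yv <- unique(as.vector(s$y * 1))
    if (!all(yv %in% c(0, 1))) stop("masks must be binary")
  }
  ep <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  if (ep == 0L) return(model)
  w <- model@weights
  mAdam <- lapply(w, function(p) p * 0)
  vAdam <- lapply(w, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; lr <- cfg$learning_rate
  step <- 0L
  trace <- model@lossTrace
  withSeed(cfg$seed + 17L, {
    for (e in seq_len(ep)) {
      ord <- sample.int(length(samples))
      eloss <- 0
      for (si in ord) {
        s <- samples[[si]]
        model@weights <- w
        fw <- segNetForward(model, s$x, keepCache = TRUE)
        ls <- diceBceLoss(fw$prob, s$y * 1)
        eloss <- eloss + ls$loss
        g <- segNetBackward(model, fw$cache, ls$dz)
        step <- step + 1L
        for (nm in names(w)) {
          if (is.null(g[[nm]])) next
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g[[nm]]
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g[[nm]]^2
          mh <- mAdam[[nm]] / (1 - b1^step)
          vh <- vAdam[[nm]] / (1 - b2^step)
          w[[nm]] <- w[[nm]] - lr * mh / (sqrt(vh) + epsA)
        }
      }
      trace <- c(trace, eloss / length(samples))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f", e, eloss / length(samples)))
    }
  })
  model@weights <- w
  model@trained <- model@trained + ep
  model@lossTrace <- trace
  model
}

#' Segment vessels in an image
#'
#' Runs the network on an enhanced plane (or computes it from a
#' [FundusImage-class] via [preprocessFundus()]) and thresholds the
#' probability raster. The mask is restricted to the field of view.
#'
#' @param model a trained [SegNet-class] (a warning is emitted otherwise).
#' @param image H x W numeric plane, [EnhancedImage-class] or
#'   [FundusImage-class]. Structured inputs are reduced to the
#'   contrast-gain enhanced green channel ([segmentationPlane()]), the
#'   network's input representation.
#' @param threshold probability cut in `[0,1]`; default from the config.
#' @param fov optional logical mask; defaults to all-`TRUE` (or the
#'   FundusImage FOV).
#' @return list with `mask` (logical) and `prob` (numeric raster in (0,1)).
#' @export
segmentVessels <- function(model, image, threshold = NULL, fov = NULL) {
  if (model@trained == 0L)
    warning("segmenting with an untrained model")
  if (is(image, "FundusImage")) {
    if (is.null(fov)) fov <- fovMask(image)
    image <- segmentationPlane(preprocessFundus(image))
  } else if (is(image, "EnhancedImage")) {
    image <- segmentationPlane(image)
  }
  if (is.null(threshold)) threshold <- model@config$threshold
  if (is.null(fov)) fov <- matrix(TRUE, nrow(image), ncol(image))
  fw <- segNetForward(model, image)
  mask <- (fw$prob >= threshold) & fov
  list(mask = mask, prob = fw$prob, descriptor = fw$descriptor)
}

#' Paired random augmentation of an image and its mask
#'
#' Applies one random rotation (within `rotation` degrees), shear and
#' translation, identically to the image (bilinear) and the mask
#' (nearest-neighbor, preserving binarity). Deterministic under `seed`.
#'
#' @param image H x W matrix or H x W x 3 array.
#' @param mask logical H x W matrix.
#' @param seed integer.
#' @param rotation,shear,translate maximal magnitudes (degrees, shear
#'   factor, fraction of the image size). Zero for all three returns the
#'   input unchanged.
#' @return list with `image`, `mask` and the sampled `params`.
#' @export
augmentPair <- function(image, mask, seed = 1L, rotation = 25,
                        shear = 0.15, translate = 0.10) {
  d <- if (is.matrix(image)) dim(image) else dim(image)[1:2]
  if (!identical(dim(mask), d)) stop("image and mask sizes differ")
  pars <- withSeed(seed, list(
    angle = runif(1, -rotation, rotation),
    shear = runif(1, -shear, shear),
    dy = runif(1, -translate, translate) * d[1],
    dx = runif(1, -translate, translate) * d[2]))
  out <- applyAffinePair(image, mask, pars)
  c(out, list(params = pars))
}

## Rotation-shear-translation about the raster center; image bilinear,
## mask nearest.
applyAffinePair <- function(image, mask, pars) {
  d <- dim(mask)
  th <- pars$angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  S <- matrix(c(1, 0, pars$shear, 1), 2)
  A <- R %*% S
  ctr <- (d[1:2] + 1) / 2
  off <- ctr - A %*% ctr + c(pars$dy, pars$dx)
  ## inverse map output -> input for resampling
  Ainv <- solve(A)
  warp <- function(plane, bilinear) {
    rows <- matrix(seq_len(d[1]), d[1], d[2])
    cols <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
    src <- Ainv %*% rbind(as.vector(rows) - off[1],
                          as.vector(cols) - off[2])
    sy <- matrix(src[1, ], d[1], d[2]); sx <- matrix(src[2, ], d[1], d[2])
    if (bilinear) bilinearSample(plane, sy, sx) else nearestSample(plane, sy, sx)
  }
  if (is.matrix(image)) {
    img2 <- warp(image, TRUE)
  } else {
    img2 <- image
    for (k in seq_len(dim(image)[3])) img2[, , k] <- warp(image[, , k], TRUE)
  }
  list(image = img2, mask = warp(mask * 1, FALSE) > 0.5)
}

bilinearSample <- function(plane, sy, sx) {
  h <- nrow(plane); w <- ncol(plane)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  gv <- function(yy, xx) {
    ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    v <- matrix(0, h, w)
    v[ok] <- plane[cbind(yy[ok], xx[ok])]
    v
  }
  gv(y0, x0) * (1 - fy) * (1 - fx) + gv(y0 + 1, x0) * fy * (1 - fx) +
    gv(y0, x0 + 1) * (1 - fy) * fx + gv(y0 + 1, x0 + 1) * fy * fx
}

nearestSample <- function(plane, sy, sx) {
  h <- nrow(plane); w <- ncol(plane)
  yy <- round(sy); xx <- round(sx)
  ok <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
  v <- matrix(0, h, w)
  v[ok] <- plane[cbind(yy[ok], xx[ok])]
  v
}

#' Detect and remove the optic disc by k-means clustering
#'
#' Clusters FOV pixels on (intensity, Gaussian-blurred intensity) with
#' k-means; the brightest cluster is the disc candidate if its mean
#' brightness exceeds the image mean, else a no-disc flag is returned.
#' The candidate's largest connected component is closed morphologically
#' and hole-filled into the disc mask; disc pixels are zeroed in the
#' working image and removed from the vessel mask (disc removal can only
#' shrink it).
#'
#' @param image a [FundusImage-class], H x W x 3 array or H x W matrix.
#' @param vesselMask optional logical mask to prune.
#' @param k number of clusters, at least 2 (default 3).
#' @param fov optional logical field-of-view mask.
#' @return list with `found`, `image` (disc zeroed), `disc` (list with
#'   `center`, `mask`, `mean_brightness`) and `vesselMask` (pruned).
#' @export
removeOpticDisc <- function(image, vesselMask = NULL, k = 3L, fov = NULL) {
  if (k < 2) stop("k must be at least 2")
  if (is(image, "FundusImage")) {
    if (is.null(fov)) fov <- fovMask(image)
    arr <- imageData(image)
  } else arr <- image
  gray <- if (is.matrix(arr)) arr else (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
  if (is.null(fov)) fov <- matrix(TRUE, nrow(gray), ncol(gray))
  blur <- gblurMat(gray, sigma = max(2, round(min(dim(gray)) / 60)))
  feat <- cbind(gray[fov], blur[fov])
  ## deterministic seeding: centers spread along the intensity range
  noDisc <- function() list(found = FALSE, image = arr, disc = NULL,
                            vesselMask = vesselMask)
  qs <- quantile(feat[, 1], probs = seq(0.05, 0.95, length.out = k))
  centers <- cbind(qs, quantile(feat[, 2],
                                probs = seq(0.05, 0.95, length.out = k)))
  if (nrow(unique(centers)) < k) return(noDisc())   # flat image
  km <- suppressWarnings(kmeans(feat, centers = centers, iter.max = 50))
  bright <- which.max(km$centers[, 1])
  if (km$centers[bright, 1] <= mean(gray[fov])) return(noDisc())
  cand <- matrix(FALSE, nrow(gray), ncol(gray))
  cand[fov] <- km$cluster == bright
  lab <- as.matrix(EBImage::bwlabel(cand * 1))
  if (max(lab) == 0) return(noDisc())
  sizes <- tabulate(lab[lab > 0])
  comp <- lab == which.max(sizes)
  ## close across the vessels that overlay the disc (a vessel-caliber
  ## brush), fill holes, then fit a circle to the recovered core
  br <- EBImage::makeBrush(max(7L, 2L * round(min(dim(gray)) / 24) + 1L),
                           "disc")
  core <- as.matrix(EBImage::fillHull(EBImage::closing(comp * 1, br))) > 0
  px <- which(core, arr.ind = TRUE)
  ctr0 <- colMeans(px)
  rad <- 1.05 * sqrt(quantile((px[, 1] - ctr0[1])^2 + (px[, 2] - ctr0[2])^2,
                              0.95, names = FALSE))
  disc <- stampDisc(matrix(FALSE, nrow(gray), ncol(gray)),
                    ctr0[1], ctr0[2], rad)
  disc <- (disc | core) & fov
  ctr <- c(mean(which(rowSums(disc) > 0)), mean(which(colSums(disc) > 0)))
  mb <- mean(gray[disc])
  if (!is.finite(mb) || mb <= mean(gray[fov])) return(noDisc())
  out <- arr
  if (is.matrix(out)) out[disc] <- 0
  else for (kk in 1:3) { p <- out[, , kk]; p[disc] <- 0; out[, , kk] <- p }
  vm <- if (is.null(vesselMask)) NULL else (vesselMask & !disc)
  list(found = TRUE, image = out,
       disc = list(center = ctr, mask = disc, mean_brightness = mb),
       vesselMask = vm)
}

gblurMat <- function(m, sigma) {
  k <- 2L * ceiling(2 * sigma) + 1L
  g <- dnorm(seq(-(k %/% 2), k %/% 2), sd = sigma)
  g <- g / sum(g)
  as.matrix(EBImage::filter2(m, outer(g, g), boundary = "replicate"))
}
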