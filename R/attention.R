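## Feature maps are arrays with dim c(C, H, W).

#' Configuration of the spatial-convolution attention block
#'
#' @param reduction_ratio hidden-size divisor `e`; hidden size is
#'   `max(1, floor(C/e))`.
#' @param pyramid_levels bins per side of each pyramid level.
#' @param spatial_kernel odd side of the spatial-attention convolution
#'   kernel (default 9).
#' @param arrangement `"sequential"` (channel gate then spatial gate, the
#'   shipped configuration) or `"parallel"` (both gates on the input,
#'   averaged).
#' @param activation hidden activation of the shared network: `"relu"`
#'   (default) or `"rbf"` (Gaussian unit `exp(-x^2)`).
#' @param pool `"both"` (average and max pooling concatenated per bin) or
#'   `"avg"`/`"max"` single pooling.
#' @return named list of class `"attentionConfig"`.
#' @export
attentionConfig <- function(reduction_ratio = 4, pyramid_levels = c(1, 2, 4),
                            spatial_kernel = 9L, arrangement = "sequential",
                            activation = "relu", pool = "both") {
  if (spatial_kernel %% 2 != 1) stop("spatial_kernel must be odd")
  if (!arrangement %in% c("sequential", "parallel"))
    stop("arrangement must be 'sequential' or 'parallel'")
  if (!activation %in% c("relu", "rbf"))
    stop("activation must be 'relu' or 'rbf'")
  if (any(pyramid_levels < 1)) stop("pyramid levels must be >= 1")
  structure(list(reduction_ratio = reduction_ratio,
                 pyramid_levels = as.integer(pyramid_levels),
                 spatial_kernel = as.integer(spatial_kernel),
                 arrangement = arrangement, activation = activation,
                 pool = pool),
            class = "attentionConfig")
}

pyramidBinCount <- function(levels) sum(as.integer(levels)^2)

#' Initialize attention weights
#'
#' He-uniform initialization of the shared two-layer network (`W0`, `W1`)
#' and the spatial-attention kernel, deterministic under `seed`.
#'
#' @param C number of channels of the feature maps the block will see.
#' @param cfg an [attentionConfig()].
#' @param seed integer seed.
#' @return list with `W0` (hidden x C*D), `W1` (C x hidden), `conv_kernel`
#'   (k x k x 2), where `D` is the per-channel single-branch descriptor
#'   length `sum(levels^2)`.
#' @export
attentionWeights <- function(C, cfg = attentionConfig(), seed = 1L) {
  D <- pyramidBinCount(cfg$pyramid_levels)
  hid <- max(1L, floor(C / cfg$reduction_ratio))
  k <- cfg$spatial_kernel
  withSeed(seed, {
    lim0 <- sqrt(6 / (C * D))
    lim1 <- sqrt(6 / hid)
    limk <- sqrt(6 / (k * k * 2))
    list(W0 = matrix(runif(hid * C * D, -lim0, lim0), hid, C * D),
         W1 = matrix(runif(C * hid, -lim1, lim1), C, hid),
         conv_kernel = array(runif(k * k * 2, -limk, limk), dim = c(k, k, 2)))
  })
}

#' Spatial pyramid pooling
#'
#' Partitions each channel's H x W plane into `L x L` bins per pyramid level
#' `L` using half-open boundaries `floor(i*H/L) .. floor((i+1)*H/L)`, pools
#' every bin (average and max), and concatenates over bins and levels. The
#' descriptor length per channel is `2 * sum(L^2)` (or `sum(L^2)` for a
#' single pooling), independent of H and W.
#'
#' @param M array `c(C, H, W)`.
#' @param levels integer vector of bins per side; every level must satisfy
#'   `level <= min(H, W)`.
#' @param pool `"both"`, `"avg"` or `"max"`.
#' @return list with matrices `avg` and `max` (D x C each, D = sum(L^2))
#'   and `descriptor` (the concatenated per-channel vectors as a
#'   (2D or D) x C matrix).
#' @export
spatialPyramidPool <- function(M, levels = c(1, 2, 4), pool = "both") {
  stopifnot(length(dim(M)) == 3)
  C <- dim(M)[1]; H <- dim(M)[2]; W <- dim(M)[3]
  levels <- as.integer(levels)
  if (any(levels > min(H, W)))
    stop("pyramid level exceeds the smaller image side (degenerate bins)")
  D <- pyramidBinCount(levels)
  avg <- matrix(0, D, C); mx <- matrix(0, D, C)
  row <- 0L
  for (L in levels) {
    rb <- floor((0:L) * H / L)   # 0-based half-open boundaries
    cb <- floor((0:L) * W / L)
    for (i in seq_len(L)) for (j in seq_len(L)) {
      rr <- (rb[i] + 1L):rb[i + 1L]
      cc <- (cb[j] + 1L):cb[j + 1L]
      row <- row + 1L
      sub <- M[, rr, cc, drop = FALSE]
      m2 <- matrix(sub, nrow = C)
      avg[row, ] <- rowMeans(m2)
      mx[row, ] <- apply(m2, 1, max)
    }
  }
  desc <- switch(pool,
    both = rbind(avg, mx),
    avg = avg,
    max = mx,
    stop("unknown pool mode"))
  list(avg = avg, max = mx, descriptor = desc)
}

#' Channel attention map
#'
#' Pools the feature map with [spatialPyramidPool()], flattens each
#' branch's descriptor across channels, passes both branches through the
#' shared two-layer network (same `W0`, `W1` for each input) and combines
#' them by element-wise summation before the sigmoid:
#' `DC = sigmoid(W1 act(W0 s_avg) + W1 act(W0 s_max))`.
#'
#' @param M array `c(C, H, W)`.
#' @param w weights from [attentionWeights()].
#' @param cfg an [attentionConfig()].
#' @return numeric vector of length C with entries strictly in (0,1).
#' @export
channelAttention <- function(M, w, cfg = attentionConfig()) {
  C <- dim(M)[1]
  sp <- spatialPyramidPool(M, cfg$pyramid_levels, pool = "both")
  act <- if (cfg$activation == "rbf") function(x) exp(-x^2)
         else function(x) pmax(x, 0)
  branch <- function(desc) {
    x <- as.vector(desc)                       # D*C, channel-major columns
    if (length(x) != ncol(w$W0))
      stop("attention weight shapes inconsistent with the feature map")
    w$W1 %*% act(w$W0 %*% x)
  }
  z <- branch(sp$avg) + branch(sp$max)
  as.vector(logistic(z))
}

#' Spatial attention map
#'
#' Stacks the channel-axis mean and max maps (2 x H x W), convolves them
#' with the k x k spatial kernel (same-size, zero padding) and applies the
#' sigmoid, yielding a 1 x H x W gate.
#'
#' @param M array `c(C, H, W)`.
#' @param w weights from [attentionWeights()] (`conv_kernel` used).
#' @return H x W matrix with entries strictly in (0,1).
#' @export
spatialAttention <- function(M, w) {
  C <- dim(M)[1]; H <- dim(M)[2]; W <- dim(M)[3]
  mmean <- apply(M, c(2, 3), mean)
  mmax <- apply(M, c(2, 3), max)
  k <- dim(w$conv_kernel)[1]
  z <- conv2dSame(mmean, w$conv_kernel[, , 1]) +
       conv2dSame(mmax, w$conv_kernel[, , 2])
  logistic(z)
}

## Same-size 2D cross-correlation with zero padding.
conv2dSame <- function(x, kern) {
  k <- nrow(kern); pad <- (k - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- matrix(0, h + 2 * pad, w + 2 * pad)
  xp[pad + seq_len(h), pad + seq_len(w)] <- x
  out <- matrix(0, h, w)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (kern[i, j] == 0) next
    out <- out + kern[i, j] *
      xp[(i - 1) + seq_len(h), (j - 1) + seq_len(w), drop = FALSE]
  }
  out
}

#' Spatial-convolution attention block
#'
#' Applies channel then spatial attention to a feature map. Sequential
#' arrangement (default, the shipped configuration):
#' `M' = DC(M) (x) M`, `M'' = DS(M') (x) M'`, with the channel gate
#' broadcast over H,W and the spatial gate broadcast over channels.
#' Parallel arrangement: `M'' = (DC(M) (x) M + DS(M) (x) M)/2`. Since both
#' gates lie in (0,1), the block can only attenuate magnitudes; output
#' shape equals input shape.
#'
#' @param M array `c(C, H, W)`.
#' @param w weights from [attentionWeights()].
#' @param cfg an [attentionConfig()].
#' @return array `c(C, H, W)`.
#' @export
scmBlock <- function(M, w, cfg = attentionConfig()) {
  C <- dim(M)[1]; H <- dim(M)[2]; W <- dim(M)[3]
  if (cfg$arrangement == "sequential") {
    dc <- channelAttention(M, w, cfg)
    M1 <- M * dc                       # recycling along C (first dim)
    ds <- spatialAttention(M1, w)
    M2 <- M1 * rep(ds, each = C)
    M2
  } else {
    dc <- channelAttention(M, w, cfg)
    ds <- spatialAttention(M, w)
    (M * dc + M * rep(ds, each = C)) / 2
  }
}
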