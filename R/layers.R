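## Minimal tensor layers with manual backpropagation. Tensors are arrays
## with dim c(C, H, W); convolutions are implemented as shift-and-add
## matrix products over kernel offsets (cheap at the network's sizes).
## Every backward pass is validated against finite differences in the
## test suite.

padCHW <- function(x, pad) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2] + 2 * pad, d[3] + 2 * pad))
  out[, pad + seq_len(d[2]), pad + seq_len(d[3])] <- x
  out
}

## 3x3 (or kxk, odd) same-padded convolution. K: (Cout, Cin, k, k).
convForward <- function(x, K, b) {
  dK <- dim(K); Cout <- dK[1]; Cin <- dK[2]; k <- dK[3]
  H <- dim(x)[2]; W <- dim(x)[3]
  pad <- (k - 1L) %/% 2L
  xp <- padCHW(x, pad)
  ymat <- matrix(b, Cout, H * W)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    xs <- matrix(xp[, (i - 1) + seq_len(H), (j - 1) + seq_len(W),
                    drop = FALSE], Cin)
    ymat <- ymat + matrix(K[, , i, j], Cout, Cin) %*% xs
  }
  list(y = array(ymat, dim = c(Cout, H, W)), xp = xp, dims = c(H, W))
}

convBackward <- function(dy, x, K, cache) {
  dK <- dim(K); Cout <- dK[1]; Cin <- dK[2]; k <- dK[3]
  H <- cache$dims[1]; W <- cache$dims[2]
  pad <- (k - 1L) %/% 2L
  dyMat <- matrix(dy, Cout, H * W)
  gK <- array(0, dim = dK)
  dxp <- array(0, dim = dim(cache$xp))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    rows <- (i - 1) + seq_len(H); cols <- (j - 1) + seq_len(W)
    xs <- matrix(cache$xp[, rows, cols, drop = FALSE], Cin)
    gK[, , i, j] <- dyMat %*% t(xs)
    dxp[, rows, cols] <- dxp[, rows, cols, drop = FALSE] +
      array(t(matrix(K[, , i, j], Cout, Cin)) %*% dyMat, dim = c(Cin, H, W))
  }
  list(dx = dxp[, pad + seq_len(H), pad + seq_len(W), drop = FALSE],
       dK = gK, db = rowSums(dyMat))
}

reluForward <- function(x) list(y = pmax(x, 0), mask = x > 0)
reluBackward <- function(dy, cache) dy * cache$mask

## 2x2 max pooling, stride 2; odd trailing row/col dropped.
poolForward <- function(x) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  a <- x[, seq_len(H2) * 2 - 1, seq_len(W2) * 2 - 1, drop = FALSE]
  b <- x[, seq_len(H2) * 2,     seq_len(W2) * 2 - 1, drop = FALSE]
  cc <- x[, seq_len(H2) * 2 - 1, seq_len(W2) * 2,    drop = FALSE]
  d <- x[, seq_len(H2) * 2,     seq_len(W2) * 2,     drop = FALSE]
  y <- pmax(a, b, cc, d)
  idx <- ifelse(a == y, 1L, ifelse(b == y, 2L, ifelse(cc == y, 3L, 4L)))
  list(y = y, idx = idx, inDim = c(C, H, W))
}

poolBackward <- function(dy, cache) {
  C <- cache$inDim[1]; H <- cache$inDim[2]; W <- cache$inDim[3]
  H2 <- dim(dy)[2]; W2 <- dim(dy)[3]
  dx <- array(0, dim = c(C, H, W))
  rows1 <- seq_len(H2) * 2 - 1; cols1 <- seq_len(W2) * 2 - 1
  for (q in 1:4) {
    sel <- (cache$idx == q) * dy
    rr <- if (q %% 2 == 1) rows1 else rows1 + 1
    cc <- if (q <= 2) cols1 else cols1 + 1
    dx[, rr, cc] <- dx[, rr, cc] + sel
  }
  dx
}

## Nearest-neighbor 2x upsampling.
upForward <- function(x) {
  H <- dim(x)[2]; W <- dim(x)[3]
  list(y = x[, rep(seq_len(H), each = 2), rep(seq_len(W), each = 2),
             drop = FALSE],
       inDim = dim(x))
}

upBackward <- function(dy, cache) {
  H <- cache$inDim[2]; W <- cache$inDim[3]
  dy[, seq_len(H) * 2 - 1, seq_len(W) * 2 - 1, drop = FALSE] +
    dy[, seq_len(H) * 2,     seq_len(W) * 2 - 1, drop = FALSE] +
    dy[, seq_len(H) * 2 - 1, seq_len(W) * 2,     drop = FALSE] +
    dy[, seq_len(H) * 2,     seq_len(W) * 2,     drop = FALSE]
}

## Crop or zero-pad bottom/right to a target spatial size (decoder paths
## of odd-sized inputs).
fitForward <- function(x, H, W) {
  d <- dim(x)
  out <- array(0, dim = c(d[1], H, W))
  rr <- seq_len(min(d[2], H)); cc <- seq_len(min(d[3], W))
  out[, rr, cc] <- x[, rr, cc, drop = FALSE]
  list(y = out, inDim = d)
}

fitBackward <- function(dy, cache) {
  d <- cache$inDim
  dx <- array(0, dim = d)
  rr <- seq_len(min(d[2], dim(dy)[2])); cc <- seq_len(min(d[3], dim(dy)[3]))
  dx[, rr, cc] <- dy[, rr, cc, drop = FALSE]
  dx
}

## --- scm attention block: forward with cache + exact backward ------------

scmForwardT <- function(M, w, cfg) {
  C <- dim(M)[1]; H <- dim(M)[2]; W <- dim(M)[3]
  sp <- sppForwardT(M, cfg$pyramid_levels)
  act <- cfg$activation
  s_a <- as.vector(sp$avg); s_m <- as.vector(sp$max)
  h_a <- as.vector(w$W0 %*% s_a); h_m <- as.vector(w$W0 %*% s_m)
  actf <- if (act == "rbf") function(x) exp(-x^2) else function(x) pmax(x, 0)
  a_a <- actf(h_a); a_m <- actf(h_m)
  z <- as.vector(w$W1 %*% a_a) + as.vector(w$W1 %*% a_m)
  dc <- logistic(z)
  M1 <- M * dc
  m2 <- matrix(M1, C)
  mmean <- matrix(colMeans(m2), H, W)
  amax <- max.col(t(m2), ties.method = "first")
  mmax <- matrix(m2[cbind(amax, seq_len(H * W))], H, W)
  k1 <- w$conv_kernel[, , 1]; k2 <- w$conv_kernel[, , 2]
  zs <- conv2dSame(mmean, k1) + conv2dSame(mmax, k2)
  ds <- logistic(zs)
  M2 <- M1 * rep(ds, each = C)
  list(y = M2,
       cache = list(M = M, sp = sp, s_a = s_a, s_m = s_m, h_a = h_a,
                    h_m = h_m, a_a = a_a, a_m = a_m, dc = dc, M1 = M1,
                    amax = amax, mmean = mmean, mmax = mmax, ds = ds,
                    dims = c(C, H, W)))
}

sppForwardT <- function(M, levels) {
  C <- dim(M)[1]; H <- dim(M)[2]; W <- dim(M)[3]
  levels <- as.integer(levels)
  D <- sum(levels^2)
  avg <- matrix(0, D, C); mx <- matrix(0, D, C)
  bins <- vector("list", D)
  argm <- matrix(0L, D, C)      # linear index into H*W plane per channel
  m2 <- matrix(M, C)
  row <- 0L
  for (L in levels) {
    rb <- floor((0:L) * H / L)
    cb <- floor((0:L) * W / L)
    for (i in seq_len(L)) for (j in seq_len(L)) {
      rr <- (rb[i] + 1L):rb[i + 1L]; cc <- (cb[j] + 1L):cb[j + 1L]
      row <- row + 1L
      lin <- as.vector(outer(rr, (cc - 1L) * H, "+"))
      sub <- m2[, lin, drop = FALSE]
      avg[row, ] <- rowMeans(sub)
      am <- max.col(sub, ties.method = "first")
      mx[row, ] <- sub[cbind(seq_len(C), am)]
      argm[row, ] <- lin[am]
      bins[[row]] <- lin
    }
  }
  list(avg = avg, max = mx, bins = bins, argmax = argm)
}

scmBackwardT <- function(dy, w, cfg, cache) {
  C <- cache$dims[1]; H <- cache$dims[2]; W <- cache$dims[3]
  M <- cache$M; M1 <- cache$M1; dc <- cache$dc; ds <- cache$ds
  ## M2 = M1 * ds
  dds <- matrix(colSums(matrix(dy * M1, C)), H, W)
  dM1 <- dy * rep(ds, each = C)
  ## ds = sigmoid(zs)
  dzs <- dds * ds * (1 - ds)
  k1 <- w$conv_kernel[, , 1]; k2 <- w$conv_kernel[, , 2]
  rot180 <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  dmmean <- conv2dSame(dzs, rot180(k1))
  dmmax <- conv2dSame(dzs, rot180(k2))
  dk1 <- convKernGrad(cache$mmean, dzs, nrow(k1))
  dk2 <- convKernGrad(cache$mmax, dzs, nrow(k2))
  ## channel-pool backward
  dM1mat <- matrix(dM1, C)
  dM1mat <- dM1mat + matrix(rep(as.vector(dmmean) / C, each = C), C)
  lin <- seq_len(H * W)
  dM1mat[cbind(cache$amax, lin)] <- dM1mat[cbind(cache$amax, lin)] +
    as.vector(dmmax)
  dM1 <- array(dM1mat, dim = c(C, H, W))
  ## M1 = M * dc
  ddc <- rowSums(matrix(dM1 * M, C))
  dM <- dM1 * dc
  ## dc = sigmoid(z), z = W1 a_a + W1 a_m
  dz <- ddc * dc * (1 - dc)
  da_a <- as.vector(t(w$W1) %*% dz); da_m <- da_a
  dW1 <- outer(dz, cache$a_a) + outer(dz, cache$a_m)
  dact <- function(h) {
    if (cfg$activation == "rbf") -2 * h * exp(-h^2) else as.numeric(h > 0)
  }
  dh_a <- da_a * dact(cache$h_a); dh_m <- da_m * dact(cache$h_m)
  dW0 <- outer(dh_a, cache$s_a) + outer(dh_m, cache$s_m)
  ds_a <- as.vector(t(w$W0) %*% dh_a)
  ds_m <- as.vector(t(w$W0) %*% dh_m)
  ## SPP backward
  D <- nrow(cache$sp$avg)
  ds_aM <- matrix(ds_a, D, C); ds_mM <- matrix(ds_m, D, C)
  dMmat <- matrix(dM, C)
  for (r in seq_len(D)) {
    linb <- cache$sp$bins[[r]]
    dMmat[, linb] <- dMmat[, linb] + ds_aM[r, ] / length(linb)
  }
  ## accumulate max-branch gradients row by row: argmax pixels can repeat
  ## across pyramid levels, so a single indexed assignment would drop terms
  for (r in seq_len(D)) {
    idx <- cbind(seq_len(C), cache$sp$argmax[r, ])
    dMmat[idx] <- dMmat[idx] + ds_mM[r, ]
  }
  list(dx = array(dMmat, dim = c(C, H, W)),
       dW0 = dW0, dW1 = dW1,
       dkern = array(c(dk1, dk2), dim = dim(w$conv_kernel)))
}

## Gradient of a same-padded 2D cross-correlation w.r.t. its kernel.
convKernGrad <- function(x, dz, k) {
  pad <- (k - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- matrix(0, h + 2 * pad, w + 2 * pad)
  xp[pad + seq_len(h), pad + seq_len(w)] <- x
  g <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    g[i, j] <- sum(dz * xp[(i - 1) + seq_len(h), (j - 1) + seq_len(w)])
  g
}

## Dice + binary cross-entropy loss on probabilities; returns the loss and
## the gradient w.r.t. the pre-sigmoid logits.
diceBceLoss <- function(prob, target, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  t <- target
  n <- length(p)
  bce <- -mean(t * log(p) + (1 - t) * log(1 - p))
  sp <- sum(p); st <- sum(t); inter <- sum(p * t)
  dice <- (2 * inter + eps) / (sp + st + eps)
  loss <- bce + (1 - dice)
  dbce_dp <- (p - t) / (p * (1 - p)) / n
  ddice_dp <- (2 * t * (sp + st + eps) - (2 * inter + eps)) / (sp + st + eps)^2
  dloss_dp <- dbce_dp - ddice_dp
  dz <- dloss_dp * prob * (1 - prob)
  list(loss = loss, dice = dice, bce = bce, dz = dz)
}
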