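## Independent, deliberately naive reference implementations used as
## oracles. These share no code with the package internals.

## Spatial pyramid pooling by explicit bin enumeration.
oracleSPP <- function(M, levels) {
  C <- dim(M)[1]; H <- dim(M)[2]; W <- dim(M)[3]
  avg <- NULL; mx <- NULL
  for (L in levels) {
    for (i in seq_len(L)) for (j in seq_len(L)) {
      r0 <- floor((i - 1) * H / L) + 1; r1 <- floor(i * H / L)
      c0 <- floor((j - 1) * W / L) + 1; c1 <- floor(j * W / L)
      arow <- numeric(C); mrow <- numeric(C)
      for (ch in seq_len(C)) {
        vals <- c()
        for (r in r0:r1) for (cc in c0:c1) vals <- c(vals, M[ch, r, cc])
        arow[ch] <- mean(vals); mrow[ch] <- max(vals)
      }
      avg <- rbind(avg, arow); mx <- rbind(mx, mrow)
    }
  }
  list(avg = avg, max = mx)
}

## Channel attention by scalar loops.
oracleChannelAttention <- function(M, w, levels, activation = "relu") {
  sp <- oracleSPP(M, levels)
  act <- function(x) if (activation == "rbf") exp(-x^2) else pmax(x, 0)
  net <- function(desc) {
    x <- as.vector(desc)
    h <- numeric(nrow(w$W0))
    for (i in seq_len(nrow(w$W0)))
      h[i] <- sum(w$W0[i, ] * x)
    a <- act(h)
    z <- numeric(nrow(w$W1))
    for (i in seq_len(nrow(w$W1)))
      z[i] <- sum(w$W1[i, ] * a)
    z
  }
  z <- net(sp$avg) + net(sp$max)
  1 / (1 + exp(-z))
}

## Spatial attention by scalar loops (same zero padding).
oracleSpatialAttention <- function(M, kern) {
  C <- dim(M)[1]; H <- dim(M)[2]; W <- dim(M)[3]
  k <- dim(kern)[1]; pad <- (k - 1) / 2
  mmean <- matrix(0, H, W); mmax <- matrix(0, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    mmean[r, cc] <- mean(M[, r, cc])
    mmax[r, cc] <- max(M[, r, cc])
  }
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    acc <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      rr <- r + i - 1 - pad; cj <- cc + j - 1 - pad
      if (rr >= 1 && rr <= H && cj >= 1 && cj <= W)
        acc <- acc + kern[i, j, 1] * mmean[rr, cj] +
          kern[i, j, 2] * mmax[rr, cj]
    }
    out[r, cc] <- 1 / (1 + exp(-acc))
  }
  out
}

## Sequential attention block by loops.
oracleScmBlock <- function(M, w, levels, activation = "relu") {
  C <- dim(M)[1]; H <- dim(M)[2]; W <- dim(M)[3]
  dc <- oracleChannelAttention(M, w, levels, activation)
  M1 <- M
  for (ch in seq_len(C)) M1[ch, , ] <- M[ch, , ] * dc[ch]
  ds <- oracleSpatialAttention(M1, w$conv_kernel)
  M2 <- M1
  for (ch in seq_len(C)) M2[ch, , ] <- M1[ch, , ] * ds
  M2
}

## The six metrics from first principles on one TP/TN/FP/FN tally.
oracleMetrics <- function(TP, TN, FP, FN) {
  TP <- unname(TP); TN <- unname(TN); FP <- unname(FP); FN <- unname(FN)
  div <- function(a, b) if (b == 0) 0 else a / b
  P <- div(TP, TP + FP); R <- div(TP, TP + FN)
  c(accuracy = div(TP + TN, TP + TN + FP + FN),
    precision = P, recall = R,
    f1 = if (P + R == 0) 0 else 2 * P * R / (P + R),
    dice = div(2 * TP, 2 * TP + FN),
    jaccard = div(TP, TP + FN + FP))
}

## Confusion tally by exhaustive pairwise comparison.
oracleConfusion <- function(pred, truth, cl) {
  TP <- TN <- FP <- FN <- 0
  for (i in seq_along(pred)) {
    if (truth[i] == cl && pred[i] == cl) TP <- TP + 1
    if (truth[i] != cl && pred[i] != cl) TN <- TN + 1
    if (truth[i] != cl && pred[i] == cl) FP <- FP + 1
    if (truth[i] == cl && pred[i] != cl) FN <- FN + 1
  }
  c(TP = TP, TN = TN, FP = FP, FN = FN)
}

## Majority-vote KNN by explicit neighbor enumeration.
oracleKnn <- function(train, labels, query, k) {
  out <- character(nrow(query))
  classes <- sort(unique(labels))
  for (i in seq_len(nrow(query))) {
    d <- numeric(nrow(train))
    for (j in seq_len(nrow(train)))
      d[j] <- sqrt(sum((query[i, ] - train[j, ])^2))
    nb <- order(d, seq_along(d))[seq_len(k)]
    tab <- sapply(classes, function(cl) sum(labels[nb] == cl))
    out[i] <- classes[which.max(tab)]
  }
  out
}

## GLCM by explicit pair tabulation (distance 1, four angles, symmetric).
oracleGLCM <- function(plane, levels) {
  q <- pmin(floor(plane * levels), levels - 1) + 1
  P <- matrix(0, levels, levels)
  h <- nrow(plane); w <- ncol(plane)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (d in offs) for (r in seq_len(h)) for (cc in seq_len(w)) {
    r2 <- r + d[1]; c2 <- cc + d[2]
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
      P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
      P[q[r2, c2], q[r, cc]] <- P[q[r2, c2], q[r, cc]] + 1
    }
  }
  P / sum(P)
}

## Nearest-centroid classifier (baseline oracle for separable tables).
oracleNearestCentroid <- function(trainX, trainY, testX) {
  classes <- sort(unique(trainY))
  cents <- t(sapply(classes, function(cl)
    colMeans(trainX[trainY == cl, , drop = FALSE])))
  pred <- character(nrow(testX))
  for (i in seq_len(nrow(testX))) {
    d <- apply(cents, 1, function(ct) sum((testX[i, ] - ct)^2))
    pred[i] <- classes[which.min(d)]
  }
  pred
}
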