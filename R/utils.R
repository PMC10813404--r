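#' Hypertensive retinopathy grades
#'
#' The five gradable HR classes, ordered by severity, plus the `"ungradable"`
#' label used only in label files (ungradable rows are excluded on read).
#'
#' @param withUngradable include the `"ungradable"` label.
#' @return character vector of grade names.
#' @export
hrGrades <- function(withUngradable = FALSE) {
  g <- c("normal", "mild", "moderate", "severe", "malignant")
  if (withUngradable) c(g, "ungradable") else g
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Evaluate `expr` under a seeded RNG without disturbing the caller's
## RNG state. All randomness in the package funnels through this.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Paint a filled disc of radius r at (row, col) into a logical matrix.
stampDisc <- function(mask, row, col, r) {
  h <- nrow(mask); w <- ncol(mask)
  r0 <- max(1L, floor(row - r)); r1 <- min(h, ceiling(row + r))
  c0 <- max(1L, floor(col - r)); c1 <- min(w, ceiling(col + r))
  if (r0 > r1 || c0 > c1) return(mask)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, "+")
  mask[rr, cc] <- mask[rr, cc] | (d2 <= r^2)
  mask
}

## Paint a thick polyline (linear interpolation between vertices, disc
## stamps of radius width/2 along it) into a logical matrix.
stampPolyline <- function(mask, pts, width) {
  r <- max(width / 2, 0.5)
  for (i in seq_len(nrow(pts) - 1L)) {
    p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((p1 - p0)^2)) * 2))
    t <- seq(0, 1, length.out = n)
    for (j in seq_len(n))
      mask <- stampDisc(mask, p0[1] + t[j] * (p1[1] - p0[1]),
                        p0[2] + t[j] * (p1[2] - p0[2]), r)
  }
  mask
}

## Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shiftMat <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  sr <- max(1, 1 + dr):min(h, h + dr)
  sc <- max(1, 1 + dc):min(w, w + dc)
  if (length(sr) && length(sc))
    out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

## Count 8-connected TRUE neighbors of every cell of a logical matrix.
neighborCount <- function(m) {
  num <- m * 1
  acc <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc + shiftMat(num, dr, dc)
  }
  acc
}

## 8-connected component labeling for sparse skeleton rasters (EBImage's
## bwlabel is 4-connected, which shatters diagonal pixel chains).
label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  px <- which(mask)
  if (!length(px)) return(lab)
  h <- nrow(mask)
  nlab <- 0L
  for (p in px) {
    if (lab[p] != 0L) next
    nlab <- nlab + 1L
    queue <- p
    lab[p] <- nlab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% h) + 1L
      cc <- ((cur - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > h || c2 < 1L || c2 > ncol(mask)) next
        q <- r2 + (c2 - 1L) * h
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nlab
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

## Population moments used by the enhancement chain.
popSd <- function(x) sqrt(mean(x^2) - mean(x)^2)

popSkew <- function(x) {
  m <- mean(x); s <- popSd(x)
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

logistic <- function(x) 1 / (1 + exp(-x))

## Standard pixel-overlap Dice for binary masks.
#' Dice and Jaccard overlap for binary masks
#'
#' Standard segmentation overlap between a predicted and a reference mask:
#' Dice `2|A∩B| / (|A|+|B|)` and Jaccard `|A∩B| / |A∪B|`. Two empty masks
#' count as perfect overlap.
#'
#' @param pred,truth logical matrices of equal size.
#' @return named numeric with `dice` and `jaccard`.
#' @export
maskOverlap <- function(pred, truth) {
  stopifnot(identical(dim(pred), dim(truth)))
  inter <- sum(pred & truth)
  a <- sum(pred); b <- sum(truth)
  dice <- if (a + b == 0) 1 else 2 * inter / (a + b)
  uni <- a + b - inter
  jac <- if (uni == 0) 1 else inter / uni
  c(dice = dice, jaccard = jac)
}
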