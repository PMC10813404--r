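## Zhang-Suen morphological thinning to one-pixel centerlines.
zhangSuenThin <- function(mask) {
  img <- mask * 1
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- lapply(list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                       c(1, 0), c(1, -1), c(0, -1), c(-1, -1)),
                  function(d) shiftMat(img, d[1], d[2]))
      ## p2..p9 clockwise from north
      B <- Reduce(`+`, p)
      seqs <- c(p, p[1])
      A <- Reduce(`+`, lapply(seq_len(8), function(i)
        (seqs[[i]] == 0) * (seqs[[i + 1]] == 1)))
      if (phase == 1) {
        c1 <- p[[1]] * p[[3]] * p[[5]]
        c2 <- p[[3]] * p[[5]] * p[[7]]
      } else {
        c1 <- p[[1]] * p[[3]] * p[[7]]
        c2 <- p[[1]] * p[[5]] * p[[7]]
      }
      del <- img == 1 & B >= 2 & B <= 6 & A == 1 & c1 == 0 & c2 == 0
      if (any(del)) {
        img[del] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img == 1
}

#' Skeletonize a vessel mask into a vessel graph
#'
#' Thins the binary mask to one-pixel centerlines (Zhang-Suen), estimates
#' per-pixel caliber as twice the distance transform sampled on the
#' centerline, detects junctions ([detectJunctions()]), splits the
#' centerline into segments at junction pixels, and records per-segment
#' mean widths.
#'
#' @param mask logical H x W vessel mask.
#' @param minSegment drop segments shorter than this many pixels
#'   (default 3; spur suppression).
#' @return a [VesselGraph-class]; an empty mask gives an empty graph.
#' @export
skeletonizeVessels <- function(mask, minSegment = 3L) {
  stopifnot(is.matrix(mask))
  mask <- mask > 0
  if (!any(mask))
    return(new("VesselGraph", centerline = mask,
               segments = list(),
               junctions = data.frame(row = integer(), col = integer(),
                                      type = character()),
               widths = numeric()))
  skel <- pruneSpurs(zhangSuenThin(mask))
  dm <- as.matrix(EBImage::distmap(mask * 1))
  widthMap <- 2 * dm
  jn <- detectJunctions(skel)
  ## remove the 3x3 neighborhood of junction pixels so that branches do
  ## not stay 8-connected around the removed junction
  cut <- skel
  if (nrow(jn$pixels)) {
    for (i in seq_len(nrow(jn$pixels)))
      cut <- cut & !stampDisc(matrix(FALSE, nrow(skel), ncol(skel)),
                              jn$pixels$row[i], jn$pixels$col[i], 1.5)
  }
  lab <- label8(cut)
  nseg <- max(lab)
  segments <- list(); widths <- numeric()
  for (s in seq_len(nseg)) {
    px <- which(lab == s, arr.ind = TRUE)
    if (nrow(px) < minSegment) next
    px <- orderChain(px)
    segments[[length(segments) + 1L]] <- px
    widths <- c(widths, max(mean(widthMap[px]), 1))
  }
  new("VesselGraph", centerline = skel, segments = segments,
      junctions = jn$typed, widths = widths)
}

## Remove short spur branches (thinning artifacts on wide or overlapping
## strokes): walk from each endpoint; if a junction is reached within
## `minLen` steps, delete the walked chain. Two passes.
pruneSpurs <- function(skel, minLen = 4L) {
  for (pass in 1:2) {
    nc <- neighborCount(skel)
    ends <- which(skel & nc == 1, arr.ind = TRUE)
    if (!nrow(ends)) return(skel)
    for (e in seq_len(nrow(ends))) {
      chain <- matrix(ends[e, ], 1)
      cur <- ends[e, ]
      prev <- c(NA, NA)
      hitJunction <- FALSE
      for (step in seq_len(minLen)) {
        nb <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r <- cur[1] + dr; cc <- cur[2] + dc
          if (r < 1 || r > nrow(skel) || cc < 1 || cc > ncol(skel)) next
          if (!skel[r, cc]) next
          if (!is.na(prev[1]) && r == prev[1] && cc == prev[2]) next
          if (any(chain[, 1] == r & chain[, 2] == cc)) next
          nb <- rbind(nb, c(r, cc))
        }
        if (is.null(nb)) break
        if (nrow(nb) > 1) { hitJunction <- TRUE; break }
        nxt <- nb[1, ]
        if (nc[nxt[1], nxt[2]] >= 3) {
          hitJunction <- TRUE; break
        }
        prev <- cur; cur <- nxt
        chain <- rbind(chain, cur)
      }
      if (hitJunction) skel[chain] <- FALSE
    }
  }
  skel
}

## Order a segment's pixels into a chain by nearest-neighbor walking from
## an endpoint (or an arbitrary pixel on loops).
orderChain <- function(px) {
  n <- nrow(px)
  if (n <= 2) return(px)
  d8 <- as.matrix(dist(px, method = "maximum"))
  deg <- rowSums(d8 <= 1) - 1
  start <- which(deg == 1)[1]
  if (is.na(start)) start <- 1L
  used <- logical(n); path <- integer(n)
  cur <- start
  for (i in seq_len(n)) {
    path[i] <- cur; used[cur] <- TRUE
    nb <- which(!used & d8[cur, ] <= 1.0)
    if (!length(nb)) {
      rest <- which(!used)
      if (!length(rest)) break
      nb <- rest[which.min(d8[cur, rest])]
    }
    cur <- nb[1]
  }
  px[path[path > 0], , drop = FALSE]
}

#' Detect and type skeletal junctions
#'
#' Centerline pixels with three 8-connected skeletal neighbors are
#' bifurcation candidates; four or more indicate a crossover. Candidates
#' are merged over 3x3 clusters (thinning often splits one anatomical
#' junction into adjacent pixels) and each merged cluster is typed by the
#' number of skeleton branches leaving its dilated neighborhood:
#' three branches give a bifurcation, four or more a crossover.
#'
#' @param skeleton logical centerline raster, or a [VesselGraph-class].
#' @return list with `typed` (data.frame row, col, type) and `pixels`
#'   (all junction-cluster pixels, used to split segments).
#' @export
detectJunctions <- function(skeleton) {
  if (is(skeleton, "VesselGraph")) skeleton <- centerline(skeleton)
  ## crossing number: 0->1 transitions around the 8-neighborhood. A line
  ## pixel has 2 (even on diagonal staircases, where the raw neighbor
  ## count over-triggers), a bifurcation 3, a crossover 4.
  p <- lapply(list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                   c(1, 0), c(1, -1), c(0, -1), c(-1, -1)),
              function(d) shiftMat(skeleton * 1, d[1], d[2]))
  seqs <- c(p, p[1])
  cross <- Reduce(`+`, lapply(seq_len(8), function(i)
    (seqs[[i]] == 0) * (seqs[[i + 1]] == 1)))
  cand <- skeleton & cross >= 3
  if (!any(cand))
    return(list(typed = data.frame(row = integer(), col = integer(),
                                   type = character()),
                pixels = data.frame(row = integer(), col = integer())))
  lab <- label8(cand)
  rows <- integer(); cols <- integer(); types <- character()
  allpix <- which(cand, arr.ind = TRUE)
  for (cl in seq_len(max(lab))) {
    px <- which(lab == cl, arr.ind = TRUE)
    ctr <- round(colMeans(px))
    ## count branches: distinct components of the skeleton outside the
    ## cluster's 3x3 dilation that touch the cluster (labeling the whole
    ## remainder counts a wiggly branch once even if its first contact
    ## with the ring is broken into pieces)
    dil <- matrix(FALSE, nrow(skeleton), ncol(skeleton))
    for (i in seq_len(nrow(px)))
      dil <- stampDisc(dil, px[i, 1], px[i, 2], 1.5)
    rest <- skeleton & !dil
    lab2 <- label8(rest)
    touching <- unique(lab2[rest & (neighborCount(dil) > 0)])
    nb <- length(setdiff(touching, 0L))
    rows <- c(rows, ctr[1]); cols <- c(cols, ctr[2])
    types <- c(types, if (nb >= 4) "crossover" else "bifurcation")
  }
  list(typed = data.frame(row = rows, col = cols, type = types),
       pixels = as.data.frame(allpix))
}

#' Erode crossover neighborhoods from a working mask
#'
#' Arteriovenous crossings are removed from the mask (radius-3 discs around
#' crossover junctions) before per-segment feature extraction, so that a
#' crossing does not contaminate the features of either vessel.
#'
#' @param mask logical vessel mask.
#' @param graph a [VesselGraph-class].
#' @param radius erosion radius in pixels (default 3).
#' @return the pruned logical mask.
#' @export
erodeCrossovers <- function(mask, graph, radius = 3) {
  jn <- junctions(graph)
  co <- jn[jn$type == "crossover", , drop = FALSE]
  if (!nrow(co)) return(mask)
  cut <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(co)))
    cut <- stampDisc(cut, co$row[i], co$col[i], radius)
  mask & !cut
}

#' Classify vessel segments as artery or vein
#'
#' Computes a per-segment feature bundle -- median centerline intensity in
#' the green plane, mean caliber, central-reflex contrast (centerline
#' intensity minus flank intensity at half the local caliber), and hue
#' variability -- and labels each segment. With a trained model (a
#' `knnVariant`/`svmVariant` fit from [fitClassifier()]) the model decides;
#' otherwise a threshold fallback is used: segments that are brighter,
#' thinner and reflex-positive (positive standardized score) are arteries.
#' If every segment presents identical features the labels degenerate to
#' one class and `degenerate` is flagged.
#'
#' @param image a [FundusImage-class] or H x W x 3 array.
#' @param graph a [VesselGraph-class].
#' @param model optional fitted classifier; `fallback = FALSE` with no
#'   model is a configuration error.
#' @param fallback allow the threshold rule when no model is given.
#' @return data.frame with one row per segment: `label` ("artery"/"vein"),
#'   `confidence` in `[0,1]`, and the four features.
#' @export
classifyArteryVein <- function(image, graph, model = NULL, fallback = TRUE) {
  if (is.null(model) && !fallback)
    stop("no trained model supplied and the threshold fallback is disabled")
  arr <- if (is(image, "FundusImage")) imageData(image) else image
  feats <- segmentFeatures(arr, graph)
  n <- nrow(feats)
  if (!n) return(cbind(feats, label = character(0), confidence = numeric(0)))
  if (!is.null(model)) {
    pred <- predictClassifier(model, as.matrix(feats))
    return(cbind(feats, label = pred, confidence = 1))
  }
  degenerate <- all(vapply(feats, function(x) max(x) - min(x), numeric(1)) <
                    1e-12)
  if (degenerate) {
    warning("all segments have identical features; labels degenerate")
    return(cbind(feats, label = "vein", confidence = 0.5))
  }
  z <- scale(as.matrix(feats[, c("brightness", "width", "reflex")]))
  z[is.nan(z)] <- 0
  score <- z[, "brightness"] - z[, "width"] + z[, "reflex"]
  cbind(feats,
        label = ifelse(score > 0, "artery", "vein"),
        confidence = logistic(abs(score)))
}

## Per-segment A/V features from the raster and graph.
segmentFeatures <- function(arr, graph) {
  segs <- vesselSegments(graph)
  wid <- segmentWidths(graph)
  green <- if (length(dim(arr)) == 3) arr[, , 2] else arr
  hsv <- if (length(dim(arr)) == 3) hsvTransform(arr) else NULL
  h <- nrow(green); w <- ncol(green)
  out <- data.frame(brightness = numeric(0), width = numeric(0),
                    reflex = numeric(0), hue_var = numeric(0))
  for (i in seq_along(segs)) {
    px <- segs[[i]]
    bright <- median(green[px])
    ## flank samples perpendicular to the local chain direction
    refl <- 0
    if (nrow(px) >= 3) {
      dirs <- diff(px)
      nrm <- cbind(-dirs[, 2], dirs[, 1])
      len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
      nrm <- nrm / len
      off <- max(1, round(wid[i] / 2) + 1)
      mid <- px[-1, , drop = FALSE]
      fl <- rbind(mid + off * nrm, mid - off * nrm)
      fl <- round(fl)
      ok <- fl[, 1] >= 1 & fl[, 1] <= h & fl[, 2] >= 1 & fl[, 2] <= w
      if (any(ok))
        refl <- bright - mean(green[fl[ok, , drop = FALSE]])
    }
    hv <- if (is.null(hsv)) 0 else popSd(hsv$beta_h[px])
    out[i, ] <- c(bright, wid[i], refl, hv)
  }
  out
}
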