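#' Gray-level co-occurrence texture features
#'
#' Quantizes a plane to `levels` gray levels and tabulates the symmetric
#' co-occurrence matrix at distance 1 averaged over the four standard
#' directions (0, 45, 90, 135 degrees). Returns the five classic Haralick
#' summaries: contrast, correlation, energy, homogeneity and entropy
#' (natural log). A constant plane has a single co-occurrence cell:
#' energy 1, contrast and entropy 0.
#'
#' @param plane numeric matrix in `[0,1]`.
#' @param levels gray levels (default 32).
#' @param mask optional logical matrix restricting the tabulated pixels
#'   (pairs with either pixel outside the mask are skipped).
#' @return named numeric vector of the five features.
#' @export
glcmFeatures <- function(plane, levels = 32L, mask = NULL) {
  q <- pmin(floor(plane * levels), levels - 1L) + 1L
  if (!is.null(mask)) q[!mask] <- NA_integer_
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  P <- matrix(0, levels, levels)
  h <- nrow(plane); w <- ncol(plane)
  for (d in offs) {
    r0 <- max(1, 1 - d[1]):min(h, h - d[1])
    c0 <- max(1, 1 - d[2]):min(w, w - d[2])
    a <- q[r0, c0, drop = FALSE]
    b <- q[r0 + d[1], c0 + d[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = seq_len(levels)),
                 factor(b[ok], levels = seq_len(levels)))
    P <- P + tab + t(tab)          # symmetric
  }
  if (sum(P) == 0) P[1, 1] <- 1
  P <- P / sum(P)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i * sd_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j) else 0
  nz <- P > 0
  c(contrast = sum((i - j)^2 * P),
    correlation = corr,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))),
    entropy = -sum(P[nz] * log(P[nz])))
}

#' Local binary pattern histogram summaries
#'
#' 8-neighbor radius-1 LBP codes of a plane; returns the mean, variance and
#' skewness of the 256-bin code histogram probabilities' underlying code
#' distribution (moments of the per-pixel codes, normalized to `[0,1]`).
#'
#' @param plane numeric matrix.
#' @param mask optional logical matrix; only masked pixels contribute.
#' @return named numeric vector `lbp_mean`, `lbp_var`, `lbp_skew`.
#' @export
lbpFeatures <- function(plane, mask = NULL) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0, nrow(plane), ncol(plane))
  for (b in seq_along(offs)) {
    nb <- shiftMat(plane, offs[[b]][1], offs[[b]][2], fill = 0)
    code <- code + (nb >= plane) * 2^(b - 1)
  }
  inner <- matrix(FALSE, nrow(plane), ncol(plane))
  inner[2:(nrow(plane) - 1), 2:(ncol(plane) - 1)] <- TRUE
  sel <- if (is.null(mask)) inner else (inner & mask)
  v <- code[sel] / 255
  if (!length(v)) v <- 0
  c(lbp_mean = mean(v), lbp_var = popSd(v)^2, lbp_skew = popSkew(v))
}

#' Extract the 24-feature HR descriptor
#'
#' Computes the canonical 24 features (order of [hrFeatureNames()]) in four
#' groups:
#' \describe{
#'   \item{texture (8)}{GLCM contrast, correlation, energy, homogeneity and
#'     entropy of the enhanced plane inside the FOV (distance 1, four
#'     symmetric angles averaged, 32 gray levels), plus LBP code-histogram
#'     mean, variance and skewness.}
#'   \item{color (6)}{mean and population sd of the hue, saturation and
#'     value planes inside the vessel mask.}
#'   \item{disc (4)}{disc area fraction of the FOV, disc mean brightness,
#'     disc boundary blur (mean gradient magnitude on the boundary ring),
#'     and disc obscuration (vessel pixels inside the disc over disc
#'     area).}
#'   \item{vascular (6)}{vessel density in the FOV, mean and sd of segment
#'     calibers, mean arc/chord tortuosity (>= 1), junction density
#'     (junctions per centerline pixel), and the artery-to-vein mean-width
#'     ratio (AVR proxy; 1 when either class is absent).}
#' }
#' An empty vessel mask yields zero vascular features with a warning.
#'
#' @param image a [FundusImage-class] or H x W x 3 array.
#' @param enhanced an [EnhancedImage-class] or H x W plane.
#' @param mask logical vessel mask.
#' @param disc logical disc mask (or `NULL` for none found).
#' @param graph a [VesselGraph-class] from the mask.
#' @param av data.frame from [classifyArteryVein()] (or `NULL`: AVR = 1).
#' @param fov optional logical field-of-view mask.
#' @return named numeric vector of length 24.
#' @export
extractFeatures <- function(image, enhanced, mask, disc = NULL, graph = NULL,
                            av = NULL, fov = NULL) {
  arr <- if (is(image, "FundusImage")) imageData(image) else image
  if (is(image, "FundusImage") && is.null(fov)) fov <- fovMask(image)
  plane <- if (is(enhanced, "EnhancedImage")) enhancedPlane(enhanced)
           else enhanced
  if (is.null(fov)) fov <- matrix(TRUE, nrow(plane), ncol(plane))
  if (is.null(graph)) graph <- skeletonizeVessels(mask)

  gl <- glcmFeatures(plane, mask = fov)
  lb <- lbpFeatures(plane, mask = fov)
  tex <- c(gl, lb)

  hsv <- hsvTransform(arr)
  col6 <- if (any(mask)) {
    c(mean(hsv$beta_h[mask]), mean(hsv$beta_s[mask]), mean(hsv$beta_v[mask]),
      popSd(hsv$beta_h[mask]), popSd(hsv$beta_s[mask]),
      popSd(hsv$beta_v[mask]))
  } else rep(0, 6)

  gray <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
  if (!is.null(disc) && any(disc)) {
    area <- sum(disc) / max(sum(fov), 1)
    mb <- mean(gray[disc])
    ring <- (as.matrix(EBImage::dilate(disc * 1, EBImage::makeBrush(3, "box"))) > 0) &
            !(as.matrix(EBImage::erode(disc * 1, EBImage::makeBrush(3, "box"))) > 0)
    gy <- shiftMat(gray, -1, 0) - shiftMat(gray, 1, 0)
    gx <- shiftMat(gray, 0, -1) - shiftMat(gray, 0, 1)
    blur <- mean(sqrt(gy^2 + gx^2)[ring]) / 2
    obsc <- sum(mask & disc) / sum(disc)
    disc4 <- c(area, mb, blur, obsc)
  } else disc4 <- c(0, 0, 0, 0)

  if (!any(mask)) {
    warning("empty vessel mask: vascular features set to 0")
    vasc <- rep(0, 6)
  } else {
    segs <- vesselSegments(graph)
    wid <- segmentWidths(graph)
    tort <- vapply(segs, function(px) {
      if (nrow(px) < 2) return(1)
      arc <- sum(sqrt(rowSums(diff(px)^2)))
      chord <- sqrt(sum((px[nrow(px), ] - px[1, ])^2))
      max(arc / max(chord, 1), 1)
    }, numeric(1))
    jd <- if (sum(centerline(graph)) > 0)
      nrow(junctions(graph)) / sum(centerline(graph)) else 0
    avr <- 1
    if (!is.null(av) && nrow(av) == length(wid) &&
        any(av$label == "artery") && any(av$label == "vein")) {
      avr <- mean(wid[av$label == "artery"]) / mean(wid[av$label == "vein"])
    }
    vasc <- c(sum(mask & fov) / max(sum(fov), 1),
              if (length(wid)) mean(wid) else 0,
              if (length(wid) > 1) sd(wid) else 0,
              if (length(tort)) mean(tort) else 1,
              jd, avr)
  }

  setNames(c(tex, col6, disc4, vasc), hrFeatureNames())
}

#' Full per-image feature computation
#'
#' Convenience wrapper: enhance, segment (with the supplied model or the
#' ground-truth mask), remove the optic disc, build the vessel graph,
#' classify artery/vein and extract the 24 features.
#'
#' @param sample a [SyntheticSample-class] or [FundusImage-class].
#' @param model optional [SegNet-class]; without one the sample's
#'   ground-truth vessel mask is used (synthetic samples only).
#' @return named numeric vector of length 24.
#' @export
imageFeatures <- function(sample, model = NULL) {
  fi <- if (is(sample, "SyntheticSample")) sample@fundus else sample
  enh <- preprocessFundus(fi)
  mask <- if (!is.null(model))
    segmentVessels(model, enh, fov = fovMask(fi))$mask
  else if (is(sample, "SyntheticSample")) vesselMask(sample)
  else stop("a segmentation model is required for non-synthetic input")
  od <- removeOpticDisc(fi, vesselMask = mask)
  if (od$found) mask <- od$vesselMask
  graph <- skeletonizeVessels(mask)
  wk <- erodeCrossovers(mask, graph)
  graph <- skeletonizeVessels(wk)
  av <- if (length(vesselSegments(graph)))
    classifyArteryVein(fi, graph) else NULL
  extractFeatures(fi, enh, mask,
                  disc = if (od$found) od$disc$mask else NULL,
                  graph = graph, av = av, fov = fovMask(fi))
}
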