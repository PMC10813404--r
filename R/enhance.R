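#' Per-pixel Gaussian response of an intensity channel
#'
#' Computes the channel mean `m`, population standard deviation `s` and the
#' Gaussian response raster
#' \deqn{G(x,y) = \frac{1}{2\pi s} \exp\!\left(-\frac{(o(x,y)-m)^2}{s}\right)}
#' used by the contrast gain. Note the first-power denominators `2*pi*s` and
#' `s`: this is the form the enhancement chain is defined with, not the
#' textbook normal density; set `textbookGaussian = TRUE` for the standard
#' `1/(s*sqrt(2*pi)) * exp(-(o-m)^2/(2*s^2))`.
#'
#' `G` is maximal where the intensity equals the channel mean.
#'
#' @param channel numeric matrix with values in `[0,1]`.
#' @param textbookGaussian use the standard normal density instead.
#' @return list with `m`, `s`, `n` (pixel count) and raster `G`.
#'   A constant channel (`s = 0`) raises a degenerate-channel error of class
#'   `"fundusHR_degenerate_channel"`.
#' @export
gaussianResponse <- function(channel, textbookGaussian = FALSE) {
  stopifnot(is.matrix(channel), length(channel) > 0)
  if (min(channel) < 0 || max(channel) > 1)
    stop("channel values must lie in [0,1]")
  m <- mean(channel)
  s <- popSd(channel)
  if (s == 0)
    stop(structure(class = c("fundusHR_degenerate_channel", "error",
                             "condition"),
                   list(message = "degenerate channel: zero variance",
                        call = sys.call(-1))))
  G <- if (textbookGaussian)
    exp(-(channel - m)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
  else
    exp(-(channel - m)^2 / s) / (2 * pi * s)
  list(m = m, s = s, n = length(channel), G = G)
}

#' Empirical per-pixel channel probability
#'
#' The probability of each pixel's own intensity: intensities are quantized
#' to 256 levels and every pixel receives the empirical histogram probability
#' of its bin (favorable pixels over total pixels). Summing the probabilities
#' of the distinct occupied bins gives 1.
#'
#' @param plane numeric matrix with values in `[0,1]`.
#' @return numeric matrix of per-pixel probabilities.
#' @export
channelProbability <- function(plane) {
  stopifnot(is.matrix(plane))
  if (min(plane) < 0 || max(plane) > 1)
    stop("plane values must lie in [0,1]")
  bin <- pmin(floor(plane * 256), 255)
  counts <- tabulate(bin + 1L, nbins = 256L)
  matrix(counts[bin + 1L] / length(plane), nrow(plane), ncol(plane))
}

#' Contrast gain from the Gaussian response
#'
#' Computes the enhancement gain `1 + f/g` with `g = 1 + G/lam` per pixel
#' and the scalar summand
#' \deqn{f = \frac{1}{n}\sum_{x,y} p(x,y)\,(1 - o(x,y))}
#' where `p` is the per-pixel histogram probability
#' ([channelProbability()]). Normalizing the sum by the pixel count keeps
#' `f` (and hence the gain) bounded and independent of the image size; the
#' `1 - o` term weights dark (lesion-prone) pixels more. Applying the gain
#' means multiplying the channel by the gain raster and clipping to `[0,1]`.
#'
#' @param channel numeric matrix in `[0,1]`.
#' @param stats result of [gaussianResponse()] on the same channel.
#' @param lam sampling parameter, positive; default 0.2.
#' @return list with `f` (scalar), `g` and `gain` rasters, `lam`, and the
#'   enhanced channel `enhanced = clip01(channel * gain)`. `F` records the
#'   count of unique intensity levels (kept for provenance, unused).
#' @export
contrastGain <- function(channel, stats, lam = 0.2) {
  if (lam <= 0) stop("lam must be positive")
  stopifnot(identical(dim(channel), dim(stats$G)))
  p <- channelProbability(channel)
  f <- mean(p * (1 - channel))
  g <- 1 + stats$G / lam
  gain <- 1 + f / g
  list(f = f, g = g, gain = gain, lam = lam,
       F = length(unique(as.vector(channel))),
       enhanced = clip01(channel * gain))
}

#' HSV transform via chromaticity coordinates
#'
#' Converts RGB to the hue/saturation/value planes used by the channel
#' selection. Chromaticities are `beta_r = r/(r+g+b)` etc. (summing to 1
#' wherever `r+g+b > 0`); saturation is `(max - min)/max` of the
#' chromaticities (0 where the max is 0); value is the chromaticity maximum;
#' hue is the arccos form
#' \deqn{\beta_h = \arccos\frac{\tfrac12(2\beta_r-\beta_g-\beta_b)}
#'   {\sqrt{(\beta_r-\beta_g)^2 + (\beta_r-\beta_b)(\beta_g-\beta_b)}}}
#' in radians in `[0, pi]`, with achromatic pixels (zero denominator) given
#' the sentinel hue 0 and flagged in `hueValid`.
#'
#' @param image a [FundusImage-class] or an H x W x 3 array in `[0,1]`.
#' @return list of rasters `beta_h`, `beta_s`, `beta_v`, `beta_r`, `beta_g`,
#'   `beta_b` and the logical `hueValid`.
#' @export
hsvTransform <- function(image) {
  img <- if (is(image, "FundusImage")) imageData(image) else image
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  d <- dim(img)
  r <- matrix(img[, , 1], d[1], d[2])
  g <- matrix(img[, , 2], d[1], d[2])
  b <- matrix(img[, , 3], d[1], d[2])
  tot <- r + g + b
  safe <- ifelse(tot > 0, tot, 1)
  br <- ifelse(tot > 0, r / safe, 0)
  bg <- ifelse(tot > 0, g / safe, 0)
  bb <- ifelse(tot > 0, b / safe, 0)
  mx <- pmax(br, bg, bb); mn <- pmin(br, bg, bb)
  bs <- ifelse(mx > 0, (mx - mn) / mx, 0)
  bv <- mx
  num <- 0.5 * (2 * br - bg - bb)
  den <- sqrt((br - bg)^2 + (br - bb) * (bg - bb))
  hueValid <- den > 1e-12
  arg <- ifelse(hueValid, pmin(pmax(num / ifelse(hueValid, den, 1), -1), 1), 1)
  bh <- ifelse(hueValid, acos(arg), 0)
  list(beta_h = bh, beta_s = bs, beta_v = bv,
       beta_r = br, beta_g = bg, beta_b = bb, hueValid = hueValid)
}

#' Doane-based plane normalization
#'
#' Normalizes a plane through the log form
#' \deqn{\psi_h = 1 + \log_2(\beta_h) + \log_2(k)}
#' where `k` is the plane's skewness computed from population central
#' moments, `k = E[(x-m)^3]/s^3`. Guards: both `log2` arguments are clamped
#' below at machine epsilon scale (1e-12) and `k` enters as `|k|`; the
#' resulting raster is rescaled to `[0,1]` by a robust min-max over the
#' 0.5--99.5 percentile range (values beyond it are clipped), so that a
#' handful of clamped pixels -- e.g. the hue sentinel of achromatic pixels,
#' whose log2 is around -40 -- cannot flatten the dynamic range of the
#' whole plane. A constant raster maps to 0.
#'
#' @param plane numeric matrix.
#' @return list with raster `psi_h` (in `[0,1]`), the skewness `skew`, and
#'   the unscaled raster `psi_raw`.
#' @export
doaneNormalize <- function(plane) {
  stopifnot(is.matrix(plane), length(plane) > 0)
  k <- popSkew(plane)
  eps <- 1e-12
  psi <- 1 + log2(pmax(plane, eps)) + log2(max(abs(k), eps))
  q <- quantile(psi, c(0.005, 0.995), names = FALSE)
  clipped <- pmin(pmax(psi, q[1]), q[2])
  rng <- range(clipped)
  scaled <- if (diff(rng) > 0) (clipped - rng[1]) / diff(rng)
            else matrix(0, nrow(plane), ncol(plane))
  list(psi_h = scaled, skew = k, psi_raw = psi)
}

#' Probability-threshold channel selection
#'
#' Selects, per pixel, the most suitable of the three HSV planes by the
#' probability cascade: with `f(.)` the per-pixel histogram probability of
#' each plane ([channelProbability()]) and `mp` the mean of the three
#' planes' probabilities at that pixel, the hue plane is chosen where
#' `f(beta_h) < mp`, else saturation where `f(beta_s) < mp`, else value
#' where `f(beta_v) <= mp`. The value branch always accepts when reached:
#' at least one of three numbers is less than or equal to their mean, so the
#' cascade covers every pixel (ties fall through to the value plane).
#'
#' @param hsv list with rasters `beta_h`, `beta_s`, `beta_v` (any planes of
#'   equal size in `[0,1]`; typically Doane-normalized).
#' @return list with `selected_plane`, `choice_map` (entries "h","s","v"),
#'   `mp` (mean-probability raster) and the three probability rasters.
#' @export
selectChannel <- function(hsv) {
  ph <- channelProbability(hsv$beta_h)
  ps <- channelProbability(hsv$beta_s)
  pv <- channelProbability(hsv$beta_v)
  mp <- (ph + ps + pv) / 3
  useH <- ph < mp
  useS <- !useH & (ps < mp)
  useV <- !useH & !useS
  sel <- hsv$beta_v
  sel[useH] <- hsv$beta_h[useH]
  sel[useS] <- hsv$beta_s[useS]
  cm <- matrix("v", nrow(sel), ncol(sel))
  cm[useH] <- "h"; cm[useS] <- "s"
  list(selected_plane = sel, choice_map = cm, mp = mp,
       p_h = ph, p_s = ps, p_v = pv)
}

#' Full pre-processing chain for a fundus image
#'
#' Runs the deterministic enhancement pipeline in narrative order:
#' per-RGB-channel Gaussian contrast gain ([gaussianResponse()] +
#' [contrastGain()]), HSV transform ([hsvTransform()]), Doane normalization
#' of each plane ([doaneNormalize()]), and probability-threshold channel
#' selection ([selectChannel()]). A constant input channel degrades to an
#' identity gain with a warning rather than failing.
#'
#' @param image a [FundusImage-class] or H x W x 3 array in `[0,1]`.
#' @param lam sampling parameter of the contrast gain; default 0.2.
#' @param resize resize to the 300 x 250 working size first (default
#'   `FALSE`: callers that batch images usually resize on read).
#' @param textbookGaussian passed to [gaussianResponse()].
#' @return an [EnhancedImage-class]: the selected plane (the analysis
#'   plane for texture and lesion features), the contrast-gain enhanced
#'   green channel (`gainGreen`, the vessel-segmentation input), and
#'   provenance holding per-channel `m`, `s`, `f`, `lam`, degeneracy flags
#'   and the Doane skewness of each HSV plane.
#' @export
preprocessFundus <- function(image, lam = 0.2, resize = FALSE,
                             textbookGaussian = FALSE) {
  img <- if (is(image, "FundusImage")) imageData(image) else image
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  if (resize) img <- resizeImage(img, width = 300L, height = 250L)
  prov <- list(lam = lam, channels = list())
  enh <- img
  for (k in 1:3) {
    ch <- img[, , k]
    st <- tryCatch(gaussianResponse(ch, textbookGaussian),
                   fundusHR_degenerate_channel = function(e) NULL)
    if (is.null(st)) {
      warning(sprintf("channel %d is constant; identity gain applied", k))
      prov$channels[[k]] <- list(m = mean(ch), s = 0, f = 0, degenerate = TRUE)
      next
    }
    cg <- contrastGain(ch, st, lam)
    enh[, , k] <- cg$enhanced
    prov$channels[[k]] <- list(m = st$m, s = st$s, f = cg$f,
                               degenerate = FALSE)
  }
  hsv <- hsvTransform(enh)
  dn <- lapply(hsv[c("beta_h", "beta_s", "beta_v")], doaneNormalize)
  prov$doane_skew <- vapply(dn, `[[`, numeric(1), "skew")
  sel <- selectChannel(list(beta_h = dn$beta_h$psi_h,
                            beta_s = dn$beta_s$psi_h,
                            beta_v = dn$beta_v$psi_h))
  new("EnhancedImage", plane = sel$selected_plane,
      choiceMap = sel$choice_map, gainGreen = enh[, , 2],
      provenance = prov)
}

#' Local RMS contrast of a plane
#'
#' Mean standard deviation over sliding square neighborhoods; used to check
#' that enhancement does not reduce local contrast.
#'
#' @param plane numeric matrix.
#' @param size odd window side, default 15.
#' @return scalar mean local standard deviation.
#' @export
localRMSContrast <- function(plane, size = 15L) {
  f <- matrix(1 / size^2, size, size)
  mu <- as.matrix(EBImage::filter2(plane, f, boundary = "replicate"))
  mu2 <- as.matrix(EBImage::filter2(plane^2, f, boundary = "replicate"))
  mean(sqrt(pmax(mu2 - mu^2, 0)))
}
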