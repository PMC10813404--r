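#' @import methods
#' @importFrom stats kmeans median quantile rnorm runif sd t.test var setNames dnorm predict
#' @importFrom utils read.csv write.csv head modifyList
NULL

## Raster convention used throughout the package: matrices are H x W,
## row-major, 0-based pixel coordinates with the origin at the top-left
## (row = y downwards, col = x rightwards). Color images are H x W x 3
## arrays in [0,1]. Conversion to/from EBImage's x-major layout happens
## only inside the I/O helpers.

#' FundusImage: an RGB fundus photograph
#'
#' Container for a color fundus photograph in `[0,1]` together with an
#' optional field-of-view (FOV) mask and an optional hypertensive-retinopathy
#' grade label.
#'
#' @slot image numeric H x W x 3 array, values in `[0,1]`.
#' @slot fov logical H x W matrix marking the circular field of view
#'   (`TRUE` inside); defaults to all-`TRUE`.
#' @slot grade character scalar, one of [hrGrades()] or `NA`.
#' @export
setClass("FundusImage",
  representation(image = "array", fov = "matrix", grade = "character"),
  prototype(grade = NA_character_)
)

setValidity("FundusImage", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    return("image must be an H x W x 3 array")
  if (any(!is.finite(object@image)))
    return("image must be finite")
  if (min(object@image) < 0 || max(object@image) > 1)
    return("image values must lie in [0,1]")
  if (!identical(dim(object@fov), d[1:2]))
    return("fov mask dimensions must match the image")
  if (!is.logical(object@fov))
    return("fov must be logical")
  if (!is.na(object@grade) && !object@grade %in% hrGrades())
    return(sprintf("unknown grade '%s'", object@grade))
  TRUE
})

#' SyntheticSample: a rendered fundus with ground truth
#'
#' Output of [generateFundus()]: the rendered image plus pixel-accurate
#' ground-truth masks for vessels (split into arteries and veins), the optic
#' disc, and the lesion layers used by grade-dependent findings.
#'
#' @slot fundus a [FundusImage-class].
#' @slot vesselMask,arteryMask,veinMask logical H x W matrices;
#'   `arteryMask | veinMask` is a subset of `vesselMask`.
#' @slot discMask logical H x W matrix; single connected component.
#' @slot hemorrhageMask,exudateMask logical H x W lesion layers.
#' @slot grade character scalar, one of [hrGrades()].
#' @slot spec the [syntheticSpec()] list that produced the sample.
#' @export
setClass("SyntheticSample",
  representation(
    fundus = "FundusImage",
    vesselMask = "matrix", arteryMask = "matrix", veinMask = "matrix",
    discMask = "matrix", hemorrhageMask = "matrix", exudateMask = "matrix",
    grade = "character", spec = "list"
  )
)

setValidity("SyntheticSample", function(object) {
  d <- dim(object@fundus@image)[1:2]
  for (nm in c("vesselMask", "arteryMask", "veinMask", "discMask",
               "hemorrhageMask", "exudateMask")) {
    m <- slot(object, nm)
    if (!identical(dim(m), d)) return(sprintf("%s dimensions differ", nm))
    if (!is.logical(m)) return(sprintf("%s must be logical", nm))
  }
  if (any((object@arteryMask | object@veinMask) & !object@vesselMask))
    return("artery/vein masks must be subsets of the vessel mask")
  if (!object@grade %in% hrGrades()) return("unknown grade")
  TRUE
})

#' EnhancedImage: output of the pre-processing chain
#'
#' Result of [preprocessFundus()]: a single enhanced plane in `[0,1]`, the
#' per-pixel channel-choice map from the probability-threshold selection, and
#' provenance (per-channel mean, standard deviation, contrast-gain summand and
#' sampling parameter).
#'
#' @slot plane numeric H x W matrix in `[0,1]`.
#' @slot choiceMap character H x W matrix with entries `"h"`, `"s"`, `"v"`.
#' @slot gainGreen numeric H x W matrix in `[0,1]`: the contrast-gain
#'   enhanced green channel, the input plane for vessel segmentation
#'   (the green channel carries the strongest vessel contrast).
#' @slot provenance named list of per-channel statistics.
#' @export
setClass("EnhancedImage",
  representation(plane = "matrix", choiceMap = "matrix",
                 gainGreen = "matrix", provenance = "list")
)

setValidity("EnhancedImage", function(object) {
  if (!identical(dim(object@plane), dim(object@choiceMap)))
    return("plane and choiceMap dimensions differ")
  if (!identical(dim(object@plane), dim(object@gainGreen)))
    return("plane and gainGreen dimensions differ")
  if (min(object@plane) < 0 || max(object@plane) > 1)
    return("plane must lie in [0,1]")
  if (!all(object@choiceMap %in% c("h", "s", "v")))
    return("choiceMap entries must be 'h', 's' or 'v'")
  TRUE
})

#' VesselGraph: centerlines, segments, junctions and calibers
#'
#' Result of [skeletonizeVessels()]: the one-pixel-wide centerline raster,
#' the list of centerline pixel chains (segments) split at junctions, the
#' typed junction list (bifurcation vs crossover) and the per-segment mean
#' caliber estimated from the distance transform.
#'
#' @slot centerline logical H x W matrix.
#' @slot segments list of integer matrices (row, col), one per segment chain.
#' @slot junctions data.frame with columns `row`, `col`,
#'   `type` (`"bifurcation"` or `"crossover"`).
#' @slot widths numeric vector, mean caliber in pixels per segment.
#' @export
setClass("VesselGraph",
  representation(centerline = "matrix", segments = "list",
                 junctions = "data.frame", widths = "numeric")
)

setValidity("VesselGraph", function(object) {
  if (length(object@segments) != length(object@widths))
    return("one width per segment required")
  if (length(object@widths) && any(object@widths <= 0))
    return("widths must be positive")
  TRUE
})

#' SegNet: the attention segmentation network
#'
#' A lightweight U-shaped encoder--decoder whose encoder stages each end in a
#' spatial-convolution attention block, with a spatial-pyramid-pooled
#' bottleneck descriptor of fixed length regardless of input size. Weights
#' live in a named list; `trained` records how many optimization epochs the
#' network has seen.
#'
#' @slot config list from [segNetConfig()].
#' @slot weights named list of parameter arrays.
#' @slot trained integer, epochs of training completed.
#' @slot lossTrace numeric vector of per-epoch mean losses.
#' @export
setClass("SegNet",
  representation(config = "list", weights = "list",
                 trained = "integer", lossTrace = "numeric"),
  prototype(trained = 0L, lossTrace = numeric(0))
)

#' ImprovedSVM: boosted one-vs-rest linear scorer
#'
#' Boosted multiclass linear scorer: each round fits one-vs-rest hinge-loss
#' weight vectors on the current sample weights, then up-weights samples with
#' positive multiclass hinge loss; prediction averages round score vectors
#' under the round weights.
#'
#' @slot rounds list; per round a list with `W` (C x (d+1) weights incl.
#'   intercept), `alpha` (round weight), `err` (weighted training error).
#' @slot classes character vector of class labels.
#' @slot featureNames character vector (length d).
#' @slot finalSampleWeights numeric, the sample weights after the last round.
#' @export
setClass("ImprovedSVM",
  representation(rounds = "list", classes = "character",
                 featureNames = "character", finalSampleWeights = "numeric")
)

#' ImprovedKNN: boosted ensemble of weak KNN learners
#'
#' Boosting-by-resampling over weak KNN learners, each restricted to a small
#' random feature subset with k drawn from \{1,3,5\}; prediction is the
#' alpha-weighted vote over learners. The learner with the lowest weighted
#' training error is recorded as `best`.
#'
#' @slot learners list; per learner features used, k, training subset,
#'   vote weight `alpha`, weighted training error `err`.
#' @slot classes character vector of class labels.
#' @slot best integer index of the best weak learner.
#' @slot trainX numeric matrix kept for neighbor queries.
#' @slot trainY character vector of training labels.
#' @export
setClass("ImprovedKNN",
  representation(learners = "list", classes = "character", best = "integer",
                 trainX = "matrix", trainY = "character")
)

setValidity("ImprovedKNN", function(object) {
  if (length(object@learners) < 1L) return("at least one learner required")
  errs <- vapply(object@learners, `[[`, numeric(1), "err")
  if (any(!is.finite(errs))) return("learner errors must be finite")
  if (abs(errs[object@best] - min(errs)) > 1e-12)
    return("best learner must have the least weighted training error")
  TRUE
})

#' CVResult: k-fold cross-validation outcome
#'
#' @slot k integer number of folds.
#' @slot folds list of integer test-index vectors (disjoint, exhaustive).
#' @slot perFold list of per-fold confusion-count objects.
#' @slot metrics data.frame of per-fold accuracy/precision/recall/F1 (macro).
#' @slot aggregate named numeric, mean of the per-fold metrics.
#' @slot seed integer.
#' @export
setClass("CVResult",
  representation(k = "integer", folds = "list", perFold = "list",
                 metrics = "data.frame", aggregate = "numeric", seed = "integer")
)

setValidity("CVResult", function(object) {
  idx <- sort(unlist(object@folds))
  if (anyDuplicated(idx)) return("folds must be disjoint")
  if (!identical(idx, seq_along(idx))) return("folds must exhaust the data")
  sizes <- lengths(object@folds)
  if (max(sizes) - min(sizes) > 1L)
    return("fold sizes must be within one of n/k")
  TRUE
})

setMethod("show", "FundusImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("FundusImage %d x %d, grade: %s, FOV coverage %.1f%%\n",
              d[1], d[2], object@grade, 100 * mean(object@fov)))
})

setMethod("show", "SyntheticSample", function(object) {
  d <- dim(object@fundus@image)
  cat(sprintf(
    "SyntheticSample %d x %d grade=%s | vessel %.1f%% artery %.1f%% vein %.1f%% disc %.1f%%\n",
    d[1], d[2], object@grade, 100 * mean(object@vesselMask),
    100 * mean(object@arteryMask), 100 * mean(object@veinMask),
    100 * mean(object@discMask)))
})

setMethod("show", "EnhancedImage", function(object) {
  tab <- table(factor(object@choiceMap, levels = c("h", "s", "v")))
  cat(sprintf("EnhancedImage %d x %d | channel choice h:%d s:%d v:%d\n",
              nrow(object@plane), ncol(object@plane),
              tab[["h"]], tab[["s"]], tab[["v"]]))
})

setMethod("show", "VesselGraph", function(object) {
  cat(sprintf("VesselGraph: %d segments, %d junctions (%d bifurcations, %d crossovers)\n",
              length(object@segments), nrow(object@junctions),
              sum(object@junctions$type == "bifurcation"),
              sum(object@junctions$type == "crossover")))
})

setMethod("show", "SegNet", function(object) {
  cat(sprintf("SegNet depth=%d base=%d | %d parameters | trained %d epochs\n",
              object@config$depth, object@config$base_channels,
              segNetParameterCount(object), object@trained))
})

setMethod("show", "ImprovedSVM", function(object) {
  cat(sprintf("ImprovedSVM: %d boosting rounds over %d classes (%d features)\n",
              length(object@rounds), length(object@classes),
              length(object@featureNames)))
})

setMethod("show", "ImprovedKNN", function(object) {
  cat(sprintf("ImprovedKNN: %d weak learners over %d classes; best learner #%d (err %.3f)\n",
              length(object@learners), length(object@classes), object@best,
              object@learners[[object@best]]$err))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d folds | accuracy %.3f, macro-F1 %.3f\n",
              object@k, object@aggregate[["accuracy"]],
              object@aggregate[["f1"]]))
})
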