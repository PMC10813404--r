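#' Accessors for fundusHR objects
#'
#' Slot access goes through these accessors rather than `@`.
#'
#' @param object an object from this package.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setMethod("imageData", "FundusImage", function(object) object@image)
#' @rdname accessors
#' @export
setMethod("imageData", "SyntheticSample", function(object) object@fundus@image)

#' @rdname accessors
#' @export
setGeneric("fovMask", function(object) standardGeneric("fovMask"))
#' @rdname accessors
#' @export
setMethod("fovMask", "FundusImage", function(object) object@fov)
#' @rdname accessors
#' @export
setMethod("fovMask", "SyntheticSample", function(object) object@fundus@fov)

#' @rdname accessors
#' @export
setGeneric("gradeLabel", function(object) standardGeneric("gradeLabel"))
#' @rdname accessors
#' @export
setMethod("gradeLabel", "FundusImage", function(object) object@grade)
#' @rdname accessors
#' @export
setMethod("gradeLabel", "SyntheticSample", function(object) object@grade)

#' @rdname accessors
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))
#' @rdname accessors
#' @export
setMethod("vesselMask", "SyntheticSample", function(object) object@vesselMask)

#' @rdname accessors
#' @export
setGeneric("arteryMask", function(object) standardGeneric("arteryMask"))
#' @rdname accessors
#' @export
setMethod("arteryMask", "SyntheticSample", function(object) object@arteryMask)

#' @rdname accessors
#' @export
setGeneric("veinMask", function(object) standardGeneric("veinMask"))
#' @rdname accessors
#' @export
setMethod("veinMask", "SyntheticSample", function(object) object@veinMask)

#' @rdname accessors
#' @export
setGeneric("discMask", function(object) standardGeneric("discMask"))
#' @rdname accessors
#' @export
setMethod("discMask", "SyntheticSample", function(object) object@discMask)

#' @rdname accessors
#' @export
setGeneric("lesionMasks", function(object) standardGeneric("lesionMasks"))
#' @rdname accessors
#' @export
setMethod("lesionMasks", "SyntheticSample", function(object)
  list(hemorrhage = object@hemorrhageMask, exudate = object@exudateMask))

#' @rdname accessors
#' @export
setGeneric("enhancedPlane", function(object) standardGeneric("enhancedPlane"))
#' @rdname accessors
#' @export
setMethod("enhancedPlane", "EnhancedImage", function(object) object@plane)

#' @rdname accessors
#' @export
setGeneric("segmentationPlane",
           function(object) standardGeneric("segmentationPlane"))
#' @rdname accessors
#' @export
setMethod("segmentationPlane", "EnhancedImage",
          function(object) object@gainGreen)

#' @rdname accessors
#' @export
setGeneric("choiceMap", function(object) standardGeneric("choiceMap"))
#' @rdname accessors
#' @export
setMethod("choiceMap", "EnhancedImage", function(object) object@choiceMap)

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setMethod("provenance", "EnhancedImage", function(object) object@provenance)

#' @rdname accessors
#' @export
setGeneric("centerline", function(object) standardGeneric("centerline"))
#' @rdname accessors
#' @export
setMethod("centerline", "VesselGraph", function(object) object@centerline)

#' @rdname accessors
#' @export
setGeneric("vesselSegments", function(object) standardGeneric("vesselSegments"))
#' @rdname accessors
#' @export
setMethod("vesselSegments", "VesselGraph", function(object) object@segments)

#' @rdname accessors
#' @export
setGeneric("junctions", function(object) standardGeneric("junctions"))
#' @rdname accessors
#' @export
setMethod("junctions", "VesselGraph", function(object) object@junctions)

#' @rdname accessors
#' @export
setGeneric("segmentWidths", function(object) standardGeneric("segmentWidths"))
#' @rdname accessors
#' @export
setMethod("segmentWidths", "VesselGraph", function(object) object@widths)

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setMethod("lossTrace", "SegNet", function(object) object@lossTrace)

#' @rdname accessors
#' @export
setGeneric("cvAggregate", function(object) standardGeneric("cvAggregate"))
#' @rdname accessors
#' @export
setMethod("cvAggregate", "CVResult", function(object) object@aggregate)

#' @rdname accessors
#' @export
setGeneric("cvFolds", function(object) standardGeneric("cvFolds"))
#' @rdname accessors
#' @export
setMethod("cvFolds", "CVResult", function(object) object@folds)

#' @rdname accessors
#' @export
setGeneric("cvPerFold", function(object) standardGeneric("cvPerFold"))
#' @rdname accessors
#' @export
setMethod("cvPerFold", "CVResult", function(object) object@perFold)
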