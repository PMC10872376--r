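#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("micronsPerPixel", "TissueCompartmentMasks",
          function(object) object@micronsPerPixel)

#' @rdname accessors
#' @export
setMethod("micronsPerPixel", "SyntheticSlide",
          function(object) object@micronsPerPixel)

#' @rdname accessors
#' @export
setMethod("tileSize", "TileGrid", function(object) object@tileSize)

#' @rdname accessors
#' @export
setMethod("tileLookup", "TileGrid", function(object) object@lookup)

#' @rdname accessors
#' @export
setMethod("annotationLabels", "AnnotationMask", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("annotationPalette", "AnnotationMask", function(object) object@palette)

#' @rdname accessors
#' @export
setMethod("lumenMask", "TissueCompartmentMasks", function(object) object@lumen)

#' @rdname accessors
#' @export
setMethod("epitheliumMask", "TissueCompartmentMasks",
          function(object) object@epithelium)

#' @rdname accessors
#' @export
setMethod("stromaMask", "TissueCompartmentMasks", function(object) object@stroma)

#' @rdname accessors
#' @export
setMethod("backgroundMask", "TissueCompartmentMasks",
          function(object) object@background)

#' @rdname accessors
#' @export
setMethod("slideImage", "SyntheticSlide", function(object) object@rgb)

#' @rdname accessors
#' @export
setMethod("slideAnnotation", "SyntheticSlide", function(object) object@annotation)

#' @rdname accessors
#' @export
setMethod("slideCompartments", "SyntheticSlide",
          function(object) object@compartments)

#' @rdname accessors
#' @export
setMethod("slideTruth", "SyntheticSlide", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("modelCoefficients", "ModelResult", function(object) object@coefficients)

#' @rdname accessors
#' @export
setMethod("modelAuc", "ModelResult", function(object) object@auc)

#' @rdname accessors
#' @export
setMethod("modelAccuracy", "ModelResult", function(object) object@accuracy)

#' @rdname accessors
#' @export
setMethod("rocPoints", "ModelResult", function(object) object@roc)

#' @rdname accessors
#' @export
setMethod("survivalCurves", "SurvivalResult", function(object) object@curves)

#' @rdname accessors
#' @export
setMethod("logrankP", "SurvivalResult", function(object) object@logrankP)

#' @rdname accessors
#' @export
setMethod("hazardRatios", "SurvivalResult", function(object) object@hazardRatios)

setMethod("show", "TileGrid", function(object) {
  cat(sprintf("TileGrid: %d x %d slide, tile %d px, %d tiles\n",
              object@slideDim[1], object@slideDim[2], object@tileSize,
              nrow(object@lookup)))
})

setMethod("show", "AnnotationMask", function(object) {
  cat(sprintf("AnnotationMask: %d x %d, classes: %s\n",
              nrow(object@labels), ncol(object@labels),
              paste(unique(object@palette), collapse = ", ")))
})

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("RegionOfInterest: class %s, component %d, %d px, bbox [%d:%d, %d:%d]\n",
              object@annotationClass, object@componentId, sum(object@support),
              object@bbox[1], object@bbox[2], object@bbox[3], object@bbox[4]))
})

setMethod("show", "TissueCompartmentMasks", function(object) {
  n <- prod(dim(object@lumen))
  cat(sprintf(paste0("TissueCompartmentMasks: %d x %d at %.3g um/px\n",
                     "  lumen %.1f%%, epithelium %.1f%%, stroma %.1f%%, ",
                     "background %.1f%%\n"),
              nrow(object@lumen), ncol(object@lumen), object@micronsPerPixel,
              100 * sum(object@lumen) / n, 100 * sum(object@epithelium) / n,
              100 * sum(object@stroma) / n, 100 * sum(object@background) / n))
})

setMethod("show", "SyntheticSlide", function(object) {
  cat(sprintf("SyntheticSlide: %d x %d px at %.3g um/px, %d glands\n",
              dim(object@rgb)[1], dim(object@rgb)[2], object@micronsPerPixel,
              nrow(object@truth)))
})

setMethod("show", "ModelResult", function(object) {
  cat(sprintf("ModelResult: accuracy %.1f%% at p>=%.2g, AUC %.3f (95%% CI %.3f-%.3f)\n",
              object@accuracy, object@threshold, object@auc,
              object@aucCI[1], object@aucCI[2]))
  if (object@separation) cat("  warning: complete separation flagged\n")
  print(object@coefficients, digits = 3)
})

setMethod("show", "SurvivalResult", function(object) {
  if (!is.na(object@logrankP))
    cat(sprintf("SurvivalResult: log-rank p = %.4g\n", object@logrankP))
  if (nrow(object@hazardRatios)) {
    cat("Hazard ratios:\n")
    print(object@hazardRatios, digits = 3)
  }
})
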