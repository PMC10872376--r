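#' @include AllClasses.R
NULL

#' Accessors for glandmetrics S4 objects
#'
#' @param object a glandmetrics S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("micronsPerPixel", function(object) standardGeneric("micronsPerPixel"))

#' @rdname accessors
#' @export
setGeneric("tileSize", function(object) standardGeneric("tileSize"))

#' @rdname accessors
#' @export
setGeneric("tileLookup", function(object) standardGeneric("tileLookup"))

#' @rdname accessors
#' @export
setGeneric("annotationLabels", function(object) standardGeneric("annotationLabels"))

#' @rdname accessors
#' @export
setGeneric("annotationPalette", function(object) standardGeneric("annotationPalette"))

#' @rdname accessors
#' @export
setGeneric("lumenMask", function(object) standardGeneric("lumenMask"))

#' @rdname accessors
#' @export
setGeneric("epitheliumMask", function(object) standardGeneric("epitheliumMask"))

#' @rdname accessors
#' @export
setGeneric("stromaMask", function(object) standardGeneric("stromaMask"))

#' @rdname accessors
#' @export
setGeneric("backgroundMask", function(object) standardGeneric("backgroundMask"))

#' @rdname accessors
#' @export
setGeneric("slideImage", function(object) standardGeneric("slideImage"))

#' @rdname accessors
#' @export
setGeneric("slideAnnotation", function(object) standardGeneric("slideAnnotation"))

#' @rdname accessors
#' @export
setGeneric("slideCompartments", function(object) standardGeneric("slideCompartments"))

#' @rdname accessors
#' @export
setGeneric("slideTruth", function(object) standardGeneric("slideTruth"))

#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(object) standardGeneric("modelCoefficients"))

#' @rdname accessors
#' @export
setGeneric("modelAuc", function(object) standardGeneric("modelAuc"))

#' @rdname accessors
#' @export
setGeneric("modelAccuracy", function(object) standardGeneric("modelAccuracy"))

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))

#' @rdname accessors
#' @export
setGeneric("survivalCurves", function(object) standardGeneric("survivalCurves"))

#' @rdname accessors
#' @export
setGeneric("logrankP", function(object) standardGeneric("logrankP"))

#' @rdname accessors
#' @export
setGeneric("hazardRatios", function(object) standardGeneric("hazardRatios"))
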