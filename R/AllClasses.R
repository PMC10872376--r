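#' @import methods
#' @importFrom stats rnorm rbinom runif rexp quantile sd var qlogis plogis
#'   pnorm qnorm pchisq integrate p.adjust t.test glm binomial coef vcov
#'   predict fitted complete.cases setNames aggregate
NULL

## Annotation class vocabulary -------------------------------------------

#' Annotation classes used throughout the package
#'
#' The eight tissue classes a pathologist assigns on whole-mount prostate
#' slides: non-atrophic benign tissue, atrophy, high-grade prostatic
#' intraepithelial neoplasia (HGPIN), Gleason 3, Gleason 4 non-cribriform,
#' Gleason 4 cribriform, Gleason 5, and seminal vesicle.
#'
#' @return `annotationClasses()` returns the full class vocabulary;
#'   `cancerClasses()` and `noncancerClasses()` return the default split used
#'   for the cancer / noncancer tile groups.
#' @export
annotationClasses <- function() {
  c("benign", "atrophy", "HGPIN", "G3", "G4NC", "G4CG", "G5",
    "seminal_vesicle")
}

#' @rdname annotationClasses
#' @export
cancerClasses <- function() c("G3", "G4NC", "G4CG", "G5")

#' @rdname annotationClasses
#' @export
noncancerClasses <- function() c("benign", "atrophy", "HGPIN", "seminal_vesicle")

## TileGrid ----------------------------------------------------------------

#' TileGrid: a non-overlapping tiling of a slide with xy lookup
#'
#' Tiles are named by their 0-based x (column) and y (row) grid indices.
#' Partial tiles at the right/bottom edges are kept; feature normalization
#' downstream uses actual tile area.
#'
#' @slot tileSize integer, nominal tile side in pixels.
#' @slot slideDim integer(2), slide height and width in pixels.
#' @slot lookup data.frame with columns `ix`, `iy`, `row0`, `row1`, `col0`,
#'   `col1` (1-based inclusive pixel bounds).
#' @export
setClass("TileGrid",
  representation(tileSize = "integer", slideDim = "integer",
                 lookup = "data.frame"))

setValidity("TileGrid", function(object) {
  lk <- object@lookup
  if (object@tileSize < 1L) return("tileSize must be positive")
  if (any(object@slideDim < 1L)) return("slideDim must be positive")
  area <- sum((lk$row1 - lk$row0 + 1L) * (lk$col1 - lk$col0 + 1L))
  if (area != prod(object@slideDim))
    return("tile boxes do not partition the slide")
  TRUE
})

## AnnotationMask ----------------------------------------------------------

#' AnnotationMask: indexed label raster with a class palette
#'
#' @slot labels integer matrix, 0 = unannotated, positive values index the
#'   palette.
#' @slot palette named character vector mapping label (name, as character
#'   integer) to annotation class.
#' @export
setClass("AnnotationMask",
  representation(labels = "matrix", palette = "character"))

setValidity("AnnotationMask", function(object) {
  lab <- unique(as.vector(object@labels))
  lab <- lab[lab != 0]
  if (length(lab) && !all(as.character(lab) %in% names(object@palette)))
    return("every nonzero label must appear in the palette")
  if (length(object@palette) &&
      !all(object@palette %in% annotationClasses()))
    return("palette values must be annotation classes")
  TRUE
})

## RegionOfInterest --------------------------------------------------------

#' RegionOfInterest: one connected lesion of one annotation class
#'
#' @slot annotationClass character, one of [annotationClasses()].
#' @slot componentId integer, component label within its class.
#' @slot bbox integer(4): row0, row1, col0, col1 (1-based inclusive) in the
#'   slide frame.
#' @slot support logical matrix cropped to `bbox`.
#' @slot slideDim integer(2), slide frame dimensions.
#' @export
setClass("RegionOfInterest",
  representation(annotationClass = "character", componentId = "integer",
                 bbox = "integer", support = "matrix", slideDim = "integer"))

setValidity("RegionOfInterest", function(object) {
  b <- object@bbox
  if (length(b) != 4L) return("bbox must be row0,row1,col0,col1")
  if (!all(dim(object@support) == c(b[2] - b[1] + 1L, b[4] - b[3] + 1L)))
    return("support dimensions must match bbox")
  TRUE
})

## TissueCompartmentMasks --------------------------------------------------

#' TissueCompartmentMasks: disjoint, exhaustive lumen/epithelium/stroma/background
#'
#' The four binary masks partition the image: every pixel belongs to exactly
#' one compartment.
#'
#' @slot lumen,epithelium,stroma,background logical matrices, common shape.
#' @slot micronsPerPixel numeric, physical pixel size.
#' @export
setClass("TissueCompartmentMasks",
  representation(lumen = "matrix", epithelium = "matrix", stroma = "matrix",
                 background = "matrix", micronsPerPixel = "numeric"))

setValidity("TissueCompartmentMasks", function(object) {
  d <- dim(object@lumen)
  if (!all(vapply(list(object@epithelium, object@stroma, object@background),
                  function(m) identical(dim(m), d), logical(1))))
    return("all masks must share one shape")
  tot <- object@lumen + object@epithelium + object@stroma + object@background
  if (any(tot != 1))
    return("masks must be pairwise disjoint and jointly exhaustive")
  if (object@micronsPerPixel <= 0)
    return("micronsPerPixel must be positive")
  TRUE
})

## SyntheticSlide ----------------------------------------------------------

#' SyntheticSlide: rendered H&E-like image with analytic ground truth
#'
#' @slot rgb numeric array height x width x 3, values in [0, 1].
#' @slot annotation [AnnotationMask-class] labeling each gland's bounding
#'   region with its annotation class.
#' @slot compartments [TissueCompartmentMasks-class] ground-truth masks.
#' @slot truth data.frame of per-gland analytic geometry (areas in um^2,
#'   thickness in um, plus rasterized pixel counts).
#' @slot micronsPerPixel numeric.
#' @slot spec list, the generating specification.
#' @export
setClass("SyntheticSlide",
  representation(rgb = "array", annotation = "AnnotationMask",
                 compartments = "TissueCompartmentMasks", truth = "data.frame",
                 micronsPerPixel = "numeric", spec = "list"))

setValidity("SyntheticSlide", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L) return("rgb must be H x W x 3")
  if (min(object@rgb) < 0 || max(object@rgb) > 1)
    return("rgb values must lie in [0, 1]")
  TRUE
})

## Model / survival results ------------------------------------------------

#' ModelResult: fitted logistic model with classification performance
#'
#' @slot coefficients data.frame: term, estimate, se, z, p.
#' @slot accuracy numeric, percent correctly classified at the probability
#'   threshold.
#' @slot threshold numeric, probability cutoff used for accuracy.
#' @slot roc data.frame of (fpr, tpr) points.
#' @slot auc numeric, area under the ROC curve.
#' @slot aucCI numeric(2), 95 percent confidence interval for the AUC.
#' @slot fitted numeric, fitted recurrence probabilities.
#' @slot labels integer, observed outcome labels (0/1).
#' @slot separation logical, TRUE if (quasi-)complete separation was flagged.
#' @slot nDropped integer, rows dropped listwise for missing values.
#' @export
setClass("ModelResult",
  representation(coefficients = "data.frame", accuracy = "numeric",
                 threshold = "numeric", roc = "data.frame", auc = "numeric",
                 aucCI = "numeric", fitted = "numeric", labels = "integer",
                 separation = "logical", nDropped = "integer"))

setValidity("ModelResult", function(object) {
  if (length(object@auc) && (object@auc < 0 || object@auc > 1))
    return("AUC must lie in [0, 1]")
  if (length(object@accuracy) &&
      (object@accuracy < 0 || object@accuracy > 100))
    return("accuracy is a percentage in [0, 100]")
  TRUE
})

#' SurvivalResult: Kaplan-Meier curves, log-rank test and Cox hazard ratios
#'
#' @slot curves data.frame: group, time, survival (product-limit estimate),
#'   nRisk, nEvent.
#' @slot logrankP numeric, log-rank test p-value (NA when not applicable).
#' @slot hazardRatios data.frame: term, hr, lower, upper, p (Wald).
#' @slot converged logical, FALSE when the Cox fit was flagged.
#' @export
setClass("SurvivalResult",
  representation(curves = "data.frame", logrankP = "numeric",
                 hazardRatios = "data.frame", converged = "logical"))

setValidity("SurvivalResult", function(object) {
  cv <- object@curves
  if (nrow(cv)) {
    if (any(cv$survival < 0 | cv$survival > 1))
      return("KM estimates must lie in [0, 1]")
    bad <- vapply(split(cv$survival[order(cv$time)],
                        cv$group[order(cv$time)]),
                  function(s) any(diff(s) > 1e-12), logical(1))
    if (any(bad)) return("KM estimates must be nonincreasing in time")
  }
  TRUE
})
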