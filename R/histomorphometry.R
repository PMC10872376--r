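#' @include AllClasses.R
NULL

#' Roundness of a region from its area and perimeter
#'
#' `4 * pi * Area / Perimeter^2`: 1 for a perfect circle, `pi/4` for an ideal
#' square of polygonal perimeter `4s`, smaller for irregular shapes. Values
#' measured on rasterized regions may slightly exceed 1 (no clamp is
#' applied); a tolerance of 1.1 is used for validity.
#'
#' @param area region area (any unit).
#' @param perimeter region perimeter (matching length unit).
#' @return unitless roundness.
#' @export
#' @examples
#' roundness(1, 4)          # unit square: pi/4
#' roundness(pi, 2 * pi)    # unit circle: 1
roundness <- function(area, perimeter) {
  stopifnot(all(area >= 0), all(perimeter > 0))
  4 * pi * area / perimeter^2
}

## Freeman chain perimeter with Kulpa's calibrated weights
## (0.948 per straight step, 1.340 per diagonal step); unbiased for smooth
## convex shapes, where raw chain length overestimates by ~5.5%.
.contourPerimeter <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1L)
  ocs <- EBImage::ocontour(lab)
  floorP <- 4 * 0.948                       # single-pixel perimeter floor
  sum(vapply(ocs, function(oc) {
    n <- nrow(oc)
    if (n < 3L) return(floorP)
    nxt <- rbind(oc[-1, , drop = FALSE], oc[1, , drop = FALSE])
    d <- abs(nxt - oc)
    0.948 * sum((d[, 1] + d[, 2]) == 1) + 1.340 * sum(d[, 1] == 1 & d[, 2] == 1)
  }, numeric(1)))
}

#' Measure area, perimeter and roundness of a binary region
#'
#' Area is the pixel count scaled by the squared pixel size; perimeter is the
#' traced boundary length of the region contour (Freeman chain with
#' corner-calibrated step weights, so rasterized disks measure close to their
#' true circumference); roundness is `4 pi A / P^2`. Multi-component masks
#' sum areas and perimeters.
#'
#' @param mask logical/0-1 matrix; must contain at least one pixel.
#' @param micronsPerPixel physical pixel size (um).
#' @return list with `area_mm2`, `perimeter_mm`, `roundness`.
#' @export
#' @examples
#' m <- matrix(FALSE, 40, 40); m[10:30, 10:30] <- TRUE
#' measureShape(m, micronsPerPixel = 2)
measureShape <- function(mask, micronsPerPixel = 1) {
  stopifnot(micronsPerPixel > 0)
  mask <- mask > 0
  npx <- sum(mask)
  if (npx == 0) stop("empty region")
  areaUm2 <- npx * micronsPerPixel^2
  perimUm <- .contourPerimeter(mask) * micronsPerPixel
  list(area_mm2 = areaUm2 * 1e-6,
       perimeter_mm = perimUm * 1e-3,
       roundness = roundness(areaUm2, perimUm))
}

#' Identify gland instances by pairing lumina with epithelium
#'
#' Lumen components are assigned to the epithelium component whose filled
#' hull contains them; several lumina inside one epithelium (cribriform-like)
#' form a single gland. Epithelium components without a lumen become glands
#' with zero lumen area; lumina with no surrounding epithelium are excluded
#' and tallied in the diagnostics.
#'
#' @param masks a [TissueCompartmentMasks-class].
#' @return list with `glands` (a list; each gland has `epitheliumId`,
#'   `lumenIds`, `bbox`, and logical `lumen`/`epithelium` masks cropped to
#'   the bbox) and `diagnostics` (`unpairedLumina` count).
#' @export
labelGlands <- function(masks) {
  stopifnot(is(masks, "TissueCompartmentMasks"))
  lumLab <- EBImage::bwlabel(masks@lumen * 1L)
  epiLab <- EBImage::bwlabel(masks@epithelium * 1L)
  epiFilled <- EBImage::fillHull(epiLab)
  nLum <- max(lumLab); nEpi <- max(epiLab)

  lumenOwner <- integer(nLum)
  for (k in seq_len(nLum)) {
    owners <- epiFilled[lumLab == k]
    owners <- owners[owners > 0]
    lumenOwner[k] <- if (length(owners)) as.integer(names(which.max(table(owners))))
                     else 0L
  }
  unpaired <- sum(lumenOwner == 0L)

  glands <- vector("list", nEpi)
  for (e in seq_len(nEpi)) {
    lids <- which(lumenOwner == e)
    sel <- epiLab == e
    if (length(lids)) sel <- sel | array(lumLab %in% lids, dim = dim(lumLab))
    px <- which(sel, arr.ind = TRUE)
    b <- c(range(px[, 1]), range(px[, 2]))
    glands[[e]] <- list(
      epitheliumId = e, lumenIds = lids, bbox = as.integer(b),
      epithelium = epiLab[b[1]:b[2], b[3]:b[4], drop = FALSE] == e,
      lumen = array(lumLab[b[1]:b[2], b[3]:b[4], drop = FALSE] %in% lids,
                    dim = c(b[2] - b[1] + 1L, b[4] - b[3] + 1L)))
  }
  list(glands = glands, diagnostics = list(unpairedLumina = unpaired))
}

#' Epithelial wall thickness of a gland
#'
#' The minimum distance between the inner (lumen) boundary and the outer
#' boundary of the gland (the contour of lumen plus epithelium, holes
#' filled), scaled to millimetres. Glands without a lumen have no inner edge
#' and return NA.
#'
#' @param gland one element of `labelGlands()$glands`.
#' @param micronsPerPixel physical pixel size (um).
#' @return thickness in mm, or NA when the gland has no lumen.
#' @export
wallThickness <- function(gland, micronsPerPixel = 1) {
  if (!any(gland$lumen)) return(NA_real_)
  outerRegion <- EBImage::fillHull((gland$lumen | gland$epithelium) * 1L) > 0
  innerPts <- EBImage::ocontour(EBImage::bwlabel(gland$lumen * 1L))
  outerPts <- EBImage::ocontour(EBImage::bwlabel(outerRegion * 1L))
  inner <- do.call(rbind, innerPts)
  outer <- do.call(rbind, outerPts)
  ## min over inner-boundary pixels of distance to nearest outer-boundary pixel
  best <- Inf
  chunk <- 2048L
  for (s in seq(1L, nrow(inner), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(inner))
    d2 <- outer(inner[idx, 1], outer[, 1], "-")^2 +
          outer(inner[idx, 2], outer[, 2], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best) * micronsPerPixel * 1e-3
}

#' Cell fraction of a gland
#'
#' The proportion of the gland area occupied by epithelium:
#' `epithelial_area / (epithelial_area + lumen_area)`. A gland with no lumen
#' has cell fraction 1.
#'
#' @param epithelialArea,lumenArea areas in any common unit.
#' @return unitless fraction in `[0, 1]`.
#' @export
cellFraction <- function(epithelialArea, lumenArea) {
  stopifnot(epithelialArea >= 0, lumenArea >= 0)
  tot <- epithelialArea + lumenArea
  if (tot == 0) stop("gland has zero area")
  epithelialArea / tot
}

#' Measure all glands on a segmented image
#'
#' Runs [labelGlands()] and computes the per-gland feature set: lumen area
#' and roundness, epithelial area and roundness, wall thickness, and cell
#' fraction, all in physical units.
#'
#' @param masks a [TissueCompartmentMasks-class].
#' @return list with `measurements` (data.frame, one row per gland) and
#'   `diagnostics` from [labelGlands()].
#' @export
measureGlands <- function(masks) {
  mpp <- masks@micronsPerPixel
  lg <- labelGlands(masks)
  rows <- lapply(lg$glands, function(g) {
    epiShape <- measureShape(g$epithelium, mpp)
    lum <- if (any(g$lumen)) measureShape(g$lumen, mpp) else
      list(area_mm2 = 0, perimeter_mm = NA_real_, roundness = NA_real_)
    data.frame(gland_id = g$epitheliumId,
               lumen_area_mm2 = lum$area_mm2,
               lumen_roundness = lum$roundness,
               epithelial_area_mm2 = epiShape$area_mm2,
               epithelial_roundness = epiShape$roundness,
               wall_thickness_mm = wallThickness(g, mpp),
               cell_fraction = cellFraction(epiShape$area_mm2, lum$area_mm2))
  })
  meas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gland_id = integer(), lumen_area_mm2 = numeric(),
               lumen_roundness = numeric(), epithelial_area_mm2 = numeric(),
               epithelial_roundness = numeric(), wall_thickness_mm = numeric(),
               cell_fraction = numeric())
  list(measurements = meas, diagnostics = lg$diagnostics)
}

.featureCols <- c("lumen_area_mm2", "lumen_roundness", "epithelial_area_mm2",
                  "epithelial_roundness", "wall_thickness_mm", "cell_fraction")

#' Summarize gland measurements over one tile
#'
#' Per-feature unweighted means over the glands of the tile, plus stromal and
#' epithelial area fractions normalized by the actual tile area (so partial
#' edge tiles are comparable to full tiles) and the gland count.
#'
#' @param measurements data.frame from [measureGlands()].
#' @param masks the tile's [TissueCompartmentMasks-class].
#' @param ix,iy tile grid indices.
#' @param annotationClass class label carried by the tile.
#' @return one-row data.frame.
#' @export
summarizeTile <- function(measurements, masks, ix = 0L, iy = 0L,
                          annotationClass = NA_character_) {
  n <- prod(dim(masks@lumen))
  means <- if (nrow(measurements))
    colMeans(measurements[, .featureCols, drop = FALSE], na.rm = TRUE)
  else setNames(rep(NA_real_, length(.featureCols)), .featureCols)
  out <- data.frame(ix = ix, iy = iy, annotation_class = annotationClass,
                    gland_count = nrow(measurements),
                    stroma_area_fraction = sum(masks@stroma) / n,
                    epithelial_area_fraction = sum(masks@epithelium) / n,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(as.list(means)))
}

#' Aggregate tile summaries to a patient feature vector
#'
#' Unweighted mean of tile-level features over the tiles of the requested
#' group. For `grouping = "wsi"` tiles are first averaged within each slide
#' and the slide means are then averaged, so every slide carries equal
#' weight.
#'
#' @param tileSummaries data.frame of [summarizeTile()] rows with an
#'   `annotation_class` column (and a `slide` column when
#'   `grouping = "wsi"`).
#' @param grouping `"all"`, `"cancer"`, `"noncancer"` or `"wsi"`.
#' @return named numeric vector of aggregated features, or NULL when the
#'   group is empty.
#' @export
aggregatePatient <- function(tileSummaries,
                             grouping = c("all", "cancer", "noncancer", "wsi")) {
  grouping <- match.arg(grouping)
  cols <- c(.featureCols, "stroma_area_fraction", "epithelial_area_fraction")
  keep <- switch(grouping,
    all = , wsi = rep(TRUE, nrow(tileSummaries)),
    cancer = tileSummaries$annotation_class %in% cancerClasses(),
    noncancer = tileSummaries$annotation_class %in% noncancerClasses())
  sel <- tileSummaries[keep, , drop = FALSE]
  if (!nrow(sel)) return(NULL)
  if (grouping == "wsi") {
    if (is.null(sel$slide)) stop("wsi grouping needs a 'slide' column")
    perSlide <- aggregate(sel[, cols, drop = FALSE], by = list(slide = sel$slide),
                          FUN = mean, na.rm = TRUE)
    colMeans(perSlide[, cols, drop = FALSE], na.rm = TRUE)
  } else {
    colMeans(sel[, cols, drop = FALSE], na.rm = TRUE)
  }
}
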