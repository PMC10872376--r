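#' @include synthetic-slide.R synthetic-cohort.R tiling.R stain.R
#'   histomorphometry.R tumor-volume.R recurrence.R
NULL

#' Segment a rendered RGB image into tissue compartments
#'
#' Convenience wrapper chaining white-space removal, optical-density
#' conversion, color deconvolution and compartment segmentation.
#'
#' @param rgb RGB array (H x W x 3) in `[0, 1]`.
#' @param micronsPerPixel physical pixel size (um).
#' @param vectors stain matrix.
#' @param odThreshold white-space mean-OD cutoff.
#' @param downsampleFactor integer block-mean reduction applied before
#'   segmentation (1 = native resolution).
#' @param ... passed to [segmentCompartments()].
#' @return a [TissueCompartmentMasks-class].
#' @export
segmentSlide <- function(rgb, micronsPerPixel = 1,
                         vectors = hemEosStainVectors(),
                         odThreshold = 0.05, downsampleFactor = 1, ...) {
  if (downsampleFactor > 1) {
    rgb <- downsampleImage(rgb, downsampleFactor)
    micronsPerPixel <- micronsPerPixel * downsampleFactor
  }
  white <- computeWhiteMask(rgb, odThreshold)
  conc <- deconvolveStains(rgbToOd(rgb), vectors)
  segmentCompartments(conc, white, micronsPerPixel, ...)
}

.cropMasks <- function(masks, r, cc) {
  new("TissueCompartmentMasks",
      lumen = masks@lumen[r, cc, drop = FALSE],
      epithelium = masks@epithelium[r, cc, drop = FALSE],
      stroma = masks@stroma[r, cc, drop = FALSE],
      background = masks@background[r, cc, drop = FALSE],
      micronsPerPixel = masks@micronsPerPixel)
}

#' Extract per-gland and per-tile features from one slide
#'
#' Tiles the slide, selects tiles per annotated lesion under the sampling
#' quotas, segments each selected tile, and computes gland measurements and
#' tile summaries.
#'
#' @param rgb RGB array in `[0, 1]`.
#' @param annotation an [AnnotationMask-class] on the same frame.
#' @param micronsPerPixel physical pixel size (um).
#' @param tileSizePx tile side in pixels.
#' @param seed integer seed for tile selection.
#' @param slideId identifier recorded on every output row.
#' @param ... passed to [segmentSlide()].
#' @return list with `glands` (data.frame over all selected tiles), `tiles`
#'   (tile summaries), `manifest` (selected tiles per lesion) and
#'   `cancerRatio` for the slide.
#' @export
extractSlideFeatures <- function(rgb, annotation, micronsPerPixel = 1,
                                 tileSizePx = 256, seed = 1,
                                 slideId = "slide1", ...) {
  grid <- buildTileGrid(dim(rgb)[1:2], tileSizePx)
  white <- computeWhiteMask(rgb)
  masks <- segmentSlide(rgb, micronsPerPixel, ...)

  manifest <- list(); tiles <- list(); glandRows <- list()
  present <- unique(annotation@palette[as.character(
    sort(unique(annotation@labels[annotation@labels > 0])))])
  for (cls in present) {
    rois <- splitMaskToRois(annotation, cls)
    for (roi in rois) {
      selected <- selectTilesForRoi(roi, grid, white, seed = seed)
      if (!nrow(selected)) next
      selected$annotation_class <- cls
      selected$component_id <- roi@componentId
      selected$slide <- slideId
      manifest[[length(manifest) + 1L]] <- selected
      for (i in seq_len(nrow(selected))) {
        b <- .tileBox(grid, selected$ix[i], selected$iy[i])
        r <- b[1]:b[2]; cc <- b[3]:b[4]
        tileMasks <- .cropMasks(masks, r, cc)
        mg <- measureGlands(tileMasks)
        summ <- summarizeTile(mg$measurements, tileMasks,
                              selected$ix[i], selected$iy[i], cls)
        summ$slide <- slideId
        tiles[[length(tiles) + 1L]] <- summ
        if (nrow(mg$measurements)) {
          gm <- mg$measurements
          gm$ix <- selected$ix[i]; gm$iy <- selected$iy[i]
          gm$annotation_class <- cls; gm$slide <- slideId
          glandRows[[length(glandRows) + 1L]] <- gm
        }
      }
    }
  }
  tissue <- !backgroundMask(masks)
  list(glands = if (length(glandRows)) do.call(rbind, glandRows) else NULL,
       tiles = if (length(tiles)) do.call(rbind, tiles) else NULL,
       manifest = if (length(manifest)) do.call(rbind, manifest) else NULL,
       cancerRatio = slideCancerRatio(annotation, tissue))
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' End-to-end smoke path: generates a synthetic slide, extracts tiles and
#' pathomic features, computes a tumor volume from a synthetic prostate voxel
#' mask, generates a synthetic cohort, fits the logistic recurrence model per
#' feature, and writes the feature, volume and coefficient tables as CSV when
#' `outDir` is given. The coefficient table mirrors the per-feature beta (SE)
#' / p layout used for reporting feature importance.
#'
#' @param slideSpec a [syntheticSlideSpec()]; a small default slide is used
#'   when NULL.
#' @param cohortSpec a [syntheticCohortSpec()]; defaults to 200 patients.
#' @param seed integer seed for tile selection and model reproducibility.
#' @param tileSizePx tile side used on the synthetic slide.
#' @param outDir optional output directory for `features.csv`, `volume.csv`
#'   and `coefficients.csv`.
#' @return list with `features`, `tiles`, `volume`, `coefficients`, `model`.
#' @export
runPipeline <- function(slideSpec = NULL, cohortSpec = NULL, seed = 1,
                        tileSizePx = 40, outDir = NULL) {
  if (is.null(slideSpec)) {
    glands <- list(
      glandSpec(c(150, 150), c(45, 45), 18, annotationClass = "G3"),
      glandSpec(c(150, 420), c(55, 40), 15, annotationClass = "G4NC"),
      glandSpec(c(430, 160), c(60, 60), 20, annotationClass = "benign"),
      glandSpec(c(430, 430), c(40, 50), 16, annotationClass = "benign"))
    slideSpec <- syntheticSlideSpec(600, 600, micronsPerPixel = 1,
                                    glands = glands, backgroundMargin = 30,
                                    seed = seed)
  }
  if (is.null(cohortSpec)) cohortSpec <- syntheticCohortSpec(200, seed = seed)

  slide <- generateSyntheticSlide(slideSpec)
  feats <- extractSlideFeatures(slideImage(slide), slideAnnotation(slide),
                                micronsPerPixel = micronsPerPixel(slide),
                                tileSizePx = tileSizePx, seed = seed,
                                slideId = "synthetic1")

  ## synthetic prostate: 20 mm sphere in a 40^3 1-mm grid
  g <- seq_len(40) - 20.5
  voxels <- outer(outer(g^2, g^2, "+"), g^2, "+") <= 15^2
  pvol <- prostateVolume(voxels, c(1, 1, 1))
  vol <- patientTumorVolume(
    data.frame(cancer_area = feats$cancerRatio, tissue_area = 1), pvol)
  volume <- data.frame(patient = "synthetic1", prostate_volume_mm3 = pvol,
                       cancer_ratio = vol$cancerRatio,
                       tumor_volume_mm3 = vol$tumorVolumeMm3)

  cohort <- generateSyntheticCohort(cohortSpec)
  featCols <- names(cohortSpec$logisticCoefficients)
  model <- fitLogistic(cohort$patients[, featCols, drop = FALSE],
                       cohort$patients$recurrence)
  coefs <- modelCoefficients(model)
  coefTable <- data.frame(group = "all tiles", feature = coefs$term,
                          beta = coefs$estimate, se = coefs$se, p = coefs$p,
                          stringsAsFactors = FALSE)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(feats$glands, file.path(outDir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(feats$tiles, file.path(outDir, "tile_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(volume, file.path(outDir, "volume.csv"), row.names = FALSE)
    utils::write.csv(coefTable, file.path(outDir, "coefficients.csv"),
                     row.names = FALSE)
  }
  list(features = feats$glands, tiles = feats$tiles, manifest = feats$manifest,
       volume = volume, coefficients = coefTable, model = model)
}
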