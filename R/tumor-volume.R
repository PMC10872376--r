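#' @include AllClasses.R
NULL

#' Prostate volume from a binary voxel mask
#'
#' `volume = number of nonzero voxels x dx * dy * dz`.
#'
#' @param mask logical/0-1 array (any dimensionality), or an RNifti image
#'   whose pixel dimensions are read from the header when `voxelDims` is
#'   missing.
#' @param voxelDims numeric(3), voxel size in mm.
#' @return volume in mm^3.
#' @export
#' @examples
#' prostateVolume(array(1, c(10, 10, 10)), c(1, 1, 1))  # 1000
prostateVolume <- function(mask, voxelDims = NULL) {
  if (is.null(voxelDims) && inherits(mask, "niftiImage"))
    voxelDims <- RNifti::pixdim(mask)[1:3]
  stopifnot(length(voxelDims) == 3L, all(voxelDims > 0))
  sum(mask != 0) * prod(voxelDims)
}

#' Read a prostate voxel mask from a NIfTI file
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return list with `mask` (array) and `voxelDims` (mm).
#' @export
readProstateMask <- function(path) {
  img <- RNifti::readNifti(path)
  list(mask = as.array(img) != 0, voxelDims = RNifti::pixdim(img)[1:3])
}

#' Cancer-to-tissue area ratio of one slide
#'
#' Sums the area annotated with any cancer class (G3, G4NC, G4CG, G5) and
#' normalizes by the total tissue area of the slide. Seminal vesicle, HGPIN
#' and atrophy count as tissue but not cancer.
#'
#' @param annotation an [AnnotationMask-class] co-registered with the tissue
#'   mask.
#' @param tissueMask logical matrix, TRUE = tissue (non-white) pixels.
#' @return ratio in `[0, 1]`.
#' @export
slideCancerRatio <- function(annotation, tissueMask) {
  stopifnot(is(annotation, "AnnotationMask"),
            identical(dim(annotation@labels), dim(tissueMask)))
  tissueArea <- sum(tissueMask)
  if (tissueArea == 0) stop("slide has zero tissue area")
  ids <- as.integer(names(annotation@palette)[
    annotation@palette %in% cancerClasses()])
  cancerArea <- sum(annotation@labels %in% ids & tissueMask)
  cancerArea / tissueArea
}

#' Approximate tumor volume for a patient
#'
#' Pools cancer and tissue areas across the patient's slides (area-weighted:
#' total cancer area over total tissue area) and multiplies the pooled ratio
#' by the prostate volume. `pooling = "mean"` instead averages the per-slide
#' ratios.
#'
#' @param slideAreas data.frame with columns `cancer_area` and `tissue_area`,
#'   one row per slide (any common unit).
#' @param prostateVolumeMm3 prostate volume in mm^3.
#' @param pooling `"pooled"` (default) or `"mean"`.
#' @return list with `cancerRatio` and `tumorVolumeMm3`.
#' @export
#' @examples
#' patientTumorVolume(data.frame(cancer_area = c(10, 0),
#'                               tissue_area = c(100, 100)), 1000)
patientTumorVolume <- function(slideAreas, prostateVolumeMm3,
                               pooling = c("pooled", "mean")) {
  pooling <- match.arg(pooling)
  stopifnot(nrow(slideAreas) >= 1, all(slideAreas$tissue_area > 0),
            all(slideAreas$cancer_area >= 0),
            all(slideAreas$cancer_area <= slideAreas$tissue_area),
            prostateVolumeMm3 >= 0)
  ratio <- if (pooling == "pooled")
    sum(slideAreas$cancer_area) / sum(slideAreas$tissue_area)
  else mean(slideAreas$cancer_area / slideAreas$tissue_area)
  list(cancerRatio = ratio, tumorVolumeMm3 = ratio * prostateVolumeMm3)
}
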