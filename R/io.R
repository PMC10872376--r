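#' @include AllClasses.R
NULL

#' Read and write slide rasters and annotation masks
#'
#' Slides are plain raster TIFF or PNG with values in `[0, 1]`; annotation
#' masks are indexed 8-bit PNG (label/255) with a JSON palette sidecar
#' mapping labels to annotation classes.
#'
#' @param image RGB array (H x W x 3) in `[0, 1]`.
#' @param path file path; format chosen by extension (.tif/.tiff/.png).
#' @name slide-io
NULL

#' @rdname slide-io
#' @export
writeSlideImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(image, path)
  else if (ext == "png") png::writePNG(image, path)
  else stop("unsupported extension: ", ext)
  invisible(path)
}

#' @rdname slide-io
#' @export
readSlideImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported extension: ", ext)
  img
}

#' @rdname slide-io
#' @param mask an [AnnotationMask-class].
#' @export
writeAnnotationMask <- function(mask, path) {
  stopifnot(is(mask, "AnnotationMask"), tolower(tools::file_ext(path)) == "png")
  png::writePNG(mask@labels / 255, path)
  sidecar <- paste0(tools::file_path_sans_ext(path), "_palette.json")
  jsonlite::write_json(as.list(mask@palette), sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname slide-io
#' @export
readAnnotationMask <- function(path) {
  lab <- round(png::readPNG(path) * 255)
  storage.mode(lab) <- "integer"
  sidecar <- paste0(tools::file_path_sans_ext(path), "_palette.json")
  pal <- unlist(jsonlite::read_json(sidecar))
  new("AnnotationMask", labels = lab, palette = pal)
}
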