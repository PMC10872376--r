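#' @include AllClasses.R stain.R
NULL

#' Build the tile grid for a slide
#'
#' Divides the slide into `tileSize` x `tileSize` tiles named by their
#' 0-based x (column) and y (row) indices. Partial tiles at the right and
#' bottom edges are kept. The grid covers every pixel exactly once, so
#' [stitchTiles()] is a byte-exact inverse of [extractTile()].
#'
#' @param image the slide raster (matrix or H x W x C array), or an
#'   integer(2) of (height, width).
#' @param tileSize tile side in pixels; whole-slide scans are conventionally
#'   tiled at 3000 px (0.34 um/px scanners) or 5100 px (0.2 um/px scanners).
#' @return a [TileGrid-class].
#' @export
#' @examples
#' buildTileGrid(c(9000L, 9000L), 3000)   # a 3 x 3 grid
buildTileGrid <- function(image, tileSize) {
  stopifnot(tileSize >= 1)
  d <- if (is.numeric(image) && length(image) == 2L && is.null(dim(image)))
    as.integer(image) else dim(image)[1:2]
  if (any(d < 1L)) stop("empty image")
  tileSize <- as.integer(tileSize)
  ny <- ceiling(d[1] / tileSize); nx <- ceiling(d[2] / tileSize)
  lk <- expand.grid(ix = seq_len(nx) - 1L, iy = seq_len(ny) - 1L)
  lk$row0 <- lk$iy * tileSize + 1L
  lk$row1 <- pmin(lk$row0 + tileSize - 1L, d[1])
  lk$col0 <- lk$ix * tileSize + 1L
  lk$col1 <- pmin(lk$col0 + tileSize - 1L, d[2])
  new("TileGrid", tileSize = tileSize, slideDim = as.integer(d), lookup = lk)
}

.tileBox <- function(grid, ix, iy) {
  lk <- grid@lookup
  row <- lk[lk$ix == ix & lk$iy == iy, ]
  if (!nrow(row)) stop(sprintf("tile (x=%d, y=%d) not in grid", ix, iy))
  unlist(row[1, c("row0", "row1", "col0", "col1")])
}

#' Extract one tile from a slide
#'
#' @param image slide raster (matrix or H x W x C array).
#' @param grid a [TileGrid-class] built on the same frame.
#' @param ix,iy 0-based tile indices.
#' @return the tile raster.
#' @export
extractTile <- function(image, grid, ix, iy) {
  b <- .tileBox(grid, ix, iy)
  if (length(dim(image)) == 3L) image[b[1]:b[2], b[3]:b[4], , drop = FALSE]
  else image[b[1]:b[2], b[3]:b[4], drop = FALSE]
}

#' Stitch tiles back into the full slide
#'
#' @param tiles named list of tile rasters, names `"x{ix}_y{iy}"` as produced
#'   by [tileName()].
#' @param grid the [TileGrid-class] the tiles were cut with.
#' @return the reassembled slide, byte-identical to the original.
#' @export
stitchTiles <- function(tiles, grid) {
  d <- grid@slideDim
  first <- tiles[[1]]
  nc <- if (length(dim(first)) == 3L) dim(first)[3] else 1L
  out <- if (nc > 1L) array(first[1] * 0, dim = c(d, nc)) else
    matrix(first[1] * 0, d[1], d[2])
  lk <- grid@lookup
  for (i in seq_len(nrow(lk))) {
    nm <- tileName(lk$ix[i], lk$iy[i])
    tl <- tiles[[nm]]
    if (is.null(tl)) stop("missing tile ", nm)
    if (nc > 1L) out[lk$row0[i]:lk$row1[i], lk$col0[i]:lk$col1[i], ] <- tl
    else out[lk$row0[i]:lk$row1[i], lk$col0[i]:lk$col1[i]] <- tl
  }
  out
}

#' Tile naming by grid coordinates
#' @param ix,iy 0-based tile indices.
#' @return character, `"x{ix}_y{iy}"`.
#' @export
tileName <- function(ix, iy) sprintf("x%d_y%d", ix, iy)

#' Flag white (non-tissue) pixels by mean optical density
#'
#' A pixel is background white space when its channel-mean optical density
#' falls below `odThreshold`. This plays the role of the averaged
#' white-image background removal used on scanned slides.
#'
#' @param image RGB array (H x W x 3).
#' @param odThreshold mean-OD cutoff; the default 0.05 separates blank glass
#'   from stained tissue for typical H&E intensities.
#' @param io white level of the image.
#' @return logical matrix, TRUE = background/white.
#' @export
computeWhiteMask <- function(image, odThreshold = 0.05, io = 1) {
  stopifnot(length(dim(image)) == 3L)
  od <- rgbToOd(image, io = io)
  (od[, , 1] + od[, , 2] + od[, , 3]) / 3 < odThreshold
}

#' Split an annotation mask into per-lesion regions of interest
#'
#' Each 8-connected component of the requested class becomes one
#' [RegionOfInterest-class].
#'
#' @param mask an [AnnotationMask-class].
#' @param annotationClass class to extract; must be in the palette (a class
#'   absent from the slide but present in the vocabulary yields an empty
#'   list).
#' @return list of [RegionOfInterest-class] objects.
#' @export
splitMaskToRois <- function(mask, annotationClass) {
  stopifnot(is(mask, "AnnotationMask"))
  annotationClass <- match.arg(annotationClass, annotationClasses())
  ids <- as.integer(names(mask@palette)[mask@palette == annotationClass])
  sel <- array(mask@labels %in% ids, dim = dim(mask@labels))
  if (!any(sel)) return(list())
  lab <- EBImage::bwlabel(sel * 1L)
  lapply(seq_len(max(lab)), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    b <- c(range(px[, 1]), range(px[, 2]))
    sup <- lab[b[1]:b[2], b[3]:b[4], drop = FALSE] == k
    new("RegionOfInterest", annotationClass = annotationClass,
        componentId = as.integer(k), bbox = as.integer(b),
        support = sup, slideDim = dim(mask@labels))
  })
}

#' Select tiles for a region of interest under the sampling quotas
#'
#' A tile is eligible when, after white-space removal, more than half of its
#' tissue pixels fall inside the ROI. Five tiles are drawn uniformly without
#' replacement per lesion (15 for non-atrophic benign tissue, to balance the
#' benign and cancer tile pools); lesions offering fewer than five eligible
#' tiles are skipped entirely and return no tiles.
#'
#' @param roi a [RegionOfInterest-class].
#' @param grid a [TileGrid-class] on the same frame.
#' @param whiteMask logical background matrix on the same frame.
#' @param seed integer seed for the uniform draw.
#' @param coverageDenominator `"tissue"` (default: non-background pixels of
#'   the tile) or `"all"` (all tile pixels).
#' @param quota,quotaBenign tiles drawn per lesion for non-benign and benign
#'   classes.
#' @param minTiles minimum eligible tiles below which the lesion is skipped.
#' @return data.frame with columns ix, iy, coverage (empty when skipped).
#' @export
selectTilesForRoi <- function(roi, grid, whiteMask, seed = 1,
                              coverageDenominator = c("tissue", "all"),
                              quota = 5L, quotaBenign = 15L, minTiles = 5L) {
  stopifnot(is(roi, "RegionOfInterest"), is(grid, "TileGrid"))
  coverageDenominator <- match.arg(coverageDenominator)
  if (!identical(as.integer(dim(whiteMask)), grid@slideDim) ||
      !identical(roi@slideDim, grid@slideDim))
    stop("grid, white mask and ROI must share the slide frame")

  lk <- grid@lookup
  b <- roi@bbox
  cand <- lk[lk$row1 >= b[1] & lk$row0 <= b[2] &
             lk$col1 >= b[3] & lk$col0 <= b[4], ]
  cov <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand$row0[i]:cand$row1[i]; cc <- cand$col0[i]:cand$col1[i]
    tissue <- !whiteMask[r, cc, drop = FALSE]
    ## ROI support restricted to this tile
    rr <- pmax(r[1], b[1]):pmin(r[length(r)], b[2])
    ccl <- pmax(cc[1], b[3]):pmin(cc[length(cc)], b[4])
    inroi <- matrix(FALSE, length(r), length(cc))
    inroi[rr - r[1] + 1L, ccl - cc[1] + 1L] <-
      roi@support[rr - b[1] + 1L, ccl - b[3] + 1L, drop = FALSE]
    num <- sum(inroi & tissue)
    den <- if (coverageDenominator == "tissue") sum(tissue) else length(tissue)
    if (den == 0) 0 else num / den
  }, numeric(1))
  eligible <- cand[cov > 0.5, c("ix", "iy")]
  eligible$coverage <- cov[cov > 0.5]
  if (nrow(eligible) < minTiles)
    return(eligible[0, , drop = FALSE])
  q <- if (roi@annotationClass == "benign") quotaBenign else quota
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  take <- sample(nrow(eligible), min(q, nrow(eligible)))
  out <- eligible[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rescale an annotation mask by nearest-neighbor resampling
#'
#' Brings a low-resolution annotation into a higher-resolution frame (or
#' back) by pure geometric rescaling with nearest-neighbor label lookup, so
#' the label set is preserved exactly.
#'
#' @param mask an [AnnotationMask-class].
#' @param scaleFactor positive scale; 2 doubles each side.
#' @return the rescaled [AnnotationMask-class].
#' @export
rescaleAnnotation <- function(mask, scaleFactor) {
  stopifnot(is(mask, "AnnotationMask"), scaleFactor > 0)
  d <- dim(mask@labels)
  nd <- pmax(1L, as.integer(round(d * scaleFactor)))
  src <- function(i, n, m) pmin(m, pmax(1L, floor((i - 0.5) / scaleFactor) + 1L))
  ri <- src(seq_len(nd[1]), nd[1], d[1])
  ci <- src(seq_len(nd[2]), nd[2], d[2])
  new("AnnotationMask", labels = mask@labels[ri, ci, drop = FALSE],
      palette = mask@palette)
}
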