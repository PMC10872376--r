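#' @include AllClasses.R
NULL

#' Hematoxylin and eosin optical-density stain vectors
#'
#' Returns the conventional Ruifrok-Johnston unit optical-density vectors for
#' hematoxylin and eosin, with the residual channel taken as their unit cross
#' product so the matrix is well conditioned. Rows are stains (H, E,
#' residual), columns are (R, G, B).
#'
#' @return a 3 x 3 numeric matrix with unit-norm rows.
#' @export
#' @examples
#' M <- hemEosStainVectors()
#' rowSums(M^2)  # all 1
hemEosStainVectors <- function() {
  h <- c(0.65, 0.70, 0.29)
  e <- c(0.07, 0.99, 0.11)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, eosin = e, residual = r)
  colnames(m) <- c("R", "G", "B")
  m
}

.checkStainVectors <- function(vectors) {
  stopifnot(is.matrix(vectors), all(dim(vectors) == c(3L, 3L)))
  if (kappa(vectors, exact = TRUE) >= 100)
    stop("stain vector matrix is ill conditioned (condition number >= 100)")
  invisible(vectors)
}

#' Convert RGB intensities to optical densities
#'
#' Applies the Beer-Lambert transform `OD = -log10((I + eps) / io)` per
#' channel. Intensities at the white level map to OD 0; zeros are clamped to a
#' finite maximum through `eps`.
#'
#' @param rgb numeric array (H x W x 3), matrix, or vector of intensities in
#'   `[0, io]`.
#' @param io white level (default 1 for images scaled to `[0, 1]`; use 255
#'   for 8-bit data).
#' @param eps small positive clamp avoiding infinite densities at zero
#'   intensity.
#' @return optical densities, same shape as `rgb`, all `>= 0`.
#' @export
#' @examples
#' rgbToOd(c(1, 0.1, 0.01))        # 0, 1, 2
rgbToOd <- function(rgb, io = 1, eps = 1e-6 * io) {
  stopifnot(io > 0)
  od <- -log10((rgb + eps) / io)
  od[od < 0] <- 0
  od
}

#' Render stain concentrations back to RGB
#'
#' Inverse of the deconvolution model: `I = io * 10^-(c %*% M)`. Used by the
#' synthetic-slide renderer so segmentation inverts it exactly.
#'
#' @param concentrations numeric matrix (n pixels x 3 stains) or array
#'   (H x W x 3).
#' @param vectors stain matrix as from [hemEosStainVectors()].
#' @param io white level of the output image.
#' @return RGB values in `[0, io]`, same leading shape as the input.
#' @export
odToRgb <- function(concentrations, vectors = hemEosStainVectors(), io = 1) {
  .checkStainVectors(vectors)
  d <- dim(concentrations)
  flat <- matrix(concentrations, ncol = 3L)
  od <- flat %*% vectors
  rgb <- io * 10^(-od)
  rgb[rgb > io] <- io
  if (length(d) == 3L) array(rgb, dim = d)
  else if (is.null(d)) drop(rgb) else rgb
}

#' Color deconvolution of an optical-density image
#'
#' Solves `od = c %*% M` per pixel for the stain concentrations `c`
#' (hematoxylin, eosin, residual) and clips them at zero.
#'
#' @param od optical densities, array (H x W x 3) or matrix (n x 3).
#' @param vectors stain matrix, rows = stains, columns = RGB.
#' @return concentrations with the same shape as `od`; channels ordered
#'   (hematoxylin, eosin, residual).
#' @export
#' @examples
#' M <- hemEosStainVectors()
#' deconvolveStains(0.7 * M[1, ], M)  # (0.7, 0, 0)
deconvolveStains <- function(od, vectors = hemEosStainVectors()) {
  .checkStainVectors(vectors)
  minv <- tryCatch(solve(vectors),
                   error = function(e) stop("singular stain matrix"))
  d <- dim(od)
  flat <- matrix(od, ncol = 3L)
  conc <- flat %*% minv
  conc[conc < 0] <- 0
  if (length(d) == 3L) array(conc, dim = d)
  else if (is.null(d)) drop(conc) else conc
}

#' Block-mean downsampling
#'
#' Reduces an image by an integer factor using block means; partial blocks at
#' the right/bottom edges average over the available pixels. The physical
#' pixel size of the result is `factor` times larger.
#'
#' @param image numeric matrix or H x W x C array.
#' @param factor integer `>= 1`.
#' @return the reduced image.
#' @export
downsampleImage <- function(image, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  ds2d <- function(m) {
    gi <- ceiling(seq_len(nrow(m)) / factor)
    gj <- ceiling(seq_len(ncol(m)) / factor)
    sums <- rowsum(t(rowsum(m, gi)), gj)      # col-group sums of row-group sums
    cnt <- outer(tabulate(gj), tabulate(gi))
    out <- t(sums / cnt)
    dimnames(out) <- NULL
    out
  }
  if (length(dim(image)) == 3L) {
    ch <- lapply(seq_len(dim(image)[3]), function(k) ds2d(image[, , k]))
    array(unlist(ch), dim = c(dim(ch[[1]]), length(ch)))
  } else ds2d(image)
}

#' Segment lumen, epithelium, stroma and background
#'
#' Classifies tissue pixels by their dominant deconvolved stain (hematoxylin
#' wins: epithelium; eosin wins: stroma), then applies morphological
#' smoothing, and separates white space into lumen (white fully enclosed by
#' tissue, found by hole filling) and background (white connected to the
#' image border). The four output masks are disjoint and exhaustive.
#'
#' @param concentrations H x W x 3 stain-concentration array from
#'   [deconvolveStains()].
#' @param whiteMask logical matrix flagging white (non-tissue) pixels, as
#'   from [computeWhiteMask()].
#' @param micronsPerPixel physical pixel size of the image.
#' @param closingRadius radius (pixels) of the disc used for morphological
#'   closing of the epithelium mask; 0 disables smoothing.
#' @param minObject minimum object size in pixels: smaller epithelium islands
#'   are reassigned to stroma, smaller lumina to epithelium.
#' @return a [TissueCompartmentMasks-class].
#' @export
segmentCompartments <- function(concentrations, whiteMask,
                                micronsPerPixel = 1,
                                closingRadius = 2, minObject = 30) {
  stopifnot(length(dim(concentrations)) == 3L,
            identical(dim(concentrations)[1:2], dim(whiteMask)))
  tissue <- !whiteMask
  h <- concentrations[, , 1]
  e <- concentrations[, , 2]
  epi <- tissue & (h >= e)

  if (closingRadius > 0 && any(epi)) {
    brush <- EBImage::makeBrush(2L * as.integer(closingRadius) + 1L, "disc")
    epi <- EBImage::closing(epi * 1L, brush) > 0
    epi <- epi & tissue
  }
  epi <- .dropSmall(epi, minObject)
  stroma <- tissue & !epi

  filled <- EBImage::fillHull((tissue) * 1L) > 0
  lumen <- filled & whiteMask
  small <- lumen & !.dropSmall(lumen, minObject)
  lumen <- lumen & !small
  epi <- epi | small                       # specks inside glands join epithelium
  stroma <- stroma & !epi
  background <- whiteMask & !lumen & !epi

  new("TissueCompartmentMasks",
      lumen = lumen, epithelium = epi, stroma = stroma,
      background = background, micronsPerPixel = micronsPerPixel)
}

## remove connected components smaller than minPx
.dropSmall <- function(mask, minPx) {
  if (minPx <= 1 || !any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minPx)
  array(lab %in% keep, dim = dim(mask))
}
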