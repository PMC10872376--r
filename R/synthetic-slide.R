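#' @include stain.R
NULL

#' Specify one synthetic gland
#'
#' A gland is an elliptical lumen surrounded by a uniform epithelial ring of
#' constant thickness (the Minkowski dilation of the lumen by the thickness),
#' which makes lumen area, epithelial area, perimeter, roundness and wall
#' thickness analytic.
#'
#' @param center numeric(2), (row, col) of the lumen center in pixels.
#' @param lumenSemiAxes numeric(2), lumen ellipse semi-axes (a, b) in pixels.
#' @param epithelialThickness ring thickness in pixels.
#' @param orientation lumen major-axis angle in radians.
#' @param annotationClass one of [annotationClasses()].
#' @return a `GlandSpec` list.
#' @export
#' @examples
#' glandSpec(c(100, 100), c(50, 50), 20, annotationClass = "G3")
glandSpec <- function(center, lumenSemiAxes, epithelialThickness,
                      orientation = 0, annotationClass = "G3") {
  stopifnot(length(center) == 2L, length(lumenSemiAxes) == 2L,
            all(lumenSemiAxes > 0), epithelialThickness > 0)
  annotationClass <- match.arg(annotationClass, annotationClasses())
  structure(list(center = as.numeric(center),
                 lumenSemiAxes = as.numeric(lumenSemiAxes),
                 epithelialThickness = as.numeric(epithelialThickness),
                 orientation = as.numeric(orientation),
                 annotationClass = annotationClass),
            class = "GlandSpec")
}

#' Specify a synthetic H&E-like slide
#'
#' @param height,width image size in pixels.
#' @param micronsPerPixel physical pixel size (um).
#' @param glands list of [glandSpec()] objects; must not overlap.
#' @param backgroundMargin width in pixels of the white border around the
#'   tissue rectangle (used when `stromaFraction` is NULL).
#' @param stromaFraction optional target fraction of tissue (stroma +
#'   epithelium) that is stroma; when supplied, the tissue rectangle is sized
#'   so the realized fraction matches and `backgroundMargin` is ignored.
#' @param seed integer; fixed seed gives byte-identical output.
#' @param noiseSd standard deviation of additive Gaussian pixel noise on the
#'   `[0, 1]` intensity scale (default 0, so closed forms hold exactly).
#' @param epitheliumConcentration,stromaConcentration numeric(2) of
#'   (hematoxylin, eosin) stain concentrations used for rendering; epithelium
#'   is hematoxylin-dominant and stroma eosin-dominant by default.
#' @param stainVectors stain matrix used for rendering, inverted exactly by
#'   [deconvolveStains()].
#' @return a `SyntheticSlideSpec` list.
#' @export
syntheticSlideSpec <- function(height, width, micronsPerPixel = 1,
                               glands = list(), backgroundMargin = 25,
                               stromaFraction = NULL, seed = 1, noiseSd = 0,
                               epitheliumConcentration = c(0.9, 0.15),
                               stromaConcentration = c(0.1, 0.7),
                               stainVectors = hemEosStainVectors()) {
  stopifnot(height >= 1, width >= 1, micronsPerPixel > 0,
            backgroundMargin >= 0, noiseSd >= 0)
  if (!is.null(stromaFraction))
    stopifnot(stromaFraction > 0, stromaFraction < 1)
  if (inherits(glands, "GlandSpec")) glands <- list(glands)
  structure(list(height = as.integer(height), width = as.integer(width),
                 micronsPerPixel = micronsPerPixel, glands = glands,
                 backgroundMargin = as.integer(backgroundMargin),
                 stromaFraction = stromaFraction, seed = as.integer(seed),
                 noiseSd = noiseSd,
                 epitheliumConcentration = epitheliumConcentration,
                 stromaConcentration = stromaConcentration,
                 stainVectors = stainVectors),
            class = "SyntheticSlideSpec")
}

## perimeter of an ellipse with semi-axes a, b (numeric elliptic integral)
.ellipsePerimeter <- function(a, b) {
  4 * integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                0, pi / 2, rel.tol = 1e-10)$value
}

## rasterize one gland into local masks over its padded bounding box
.rasterizeGland <- function(g, height, width) {
  a <- g$lumenSemiAxes[1]; b <- g$lumenSemiAxes[2]
  t <- g$epithelialThickness
  pad <- ceiling(max(a, b) + t) + 2L
  r0 <- floor(g$center[1] - pad); r1 <- ceiling(g$center[1] + pad)
  c0 <- floor(g$center[2] - pad); c1 <- ceiling(g$center[2] + pad)
  rows <- r0:r1; cols <- c0:c1
  u <- outer(rows - g$center[1], rep(1, length(cols)))
  v <- outer(rep(1, length(rows)), cols - g$center[2])
  x <- u * cos(g$orientation) + v * sin(g$orientation)
  y <- -u * sin(g$orientation) + v * cos(g$orientation)
  lumen <- (x / a)^2 + (y / b)^2 <= 1
  ## +0.25 px centers the discretization error of measuring the dilation
  ## between pixel centers; ring pixel counts then track the analytic
  ## Minkowski area P*t + pi*t^2 to within ~1% for semi-axes >= 20 px
  d <- EBImage::distmap((!lumen) * 1L)
  epi <- !lumen & d <= t + 0.25
  ring <- lumen | epi
  keep <- which(ring, arr.ind = TRUE)
  rr <- range(keep[, 1]); cc <- range(keep[, 2])
  list(rows = rows, cols = cols, lumen = lumen, epi = epi,
       bbox = c(rows[rr[1]], rows[rr[2]], cols[cc[1]], cols[cc[2]]))
}

#' Generate a synthetic H&E-like slide with known ground truth
#'
#' Renders each gland as a white elliptical lumen inside a
#' hematoxylin-dominant epithelial ring on an eosin-dominant stroma
#' rectangle, surrounded by a white background border. Colors are produced by
#' mixing stain concentrations through the Beer-Lambert model that
#' [deconvolveStains()] inverts, so segmentation is exact by construction at
#' zero noise.
#'
#' @param spec a [syntheticSlideSpec()].
#' @return a [SyntheticSlide-class] carrying the rendered image, an
#'   [AnnotationMask-class] marking each gland's bounding region with its
#'   class, ground-truth [TissueCompartmentMasks-class], and a per-gland
#'   truth table with analytic areas (um^2), wall thickness (um), roundness,
#'   cell fraction and rasterized pixel counts.
#' @export
#' @examples
#' sp <- syntheticSlideSpec(220, 220,
#'   glands = list(glandSpec(c(110, 110), c(50, 50), 20)))
#' slide <- generateSyntheticSlide(sp)
#' slideTruth(slide)$lumen_area_um2  # pi * 50^2
generateSyntheticSlide <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSlideSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  H <- spec$height; W <- spec$width
  mpp <- spec$micronsPerPixel
  glands <- spec$glands
  nG <- length(glands)

  lumen <- matrix(FALSE, H, W)
  epi <- matrix(FALSE, H, W)
  labels <- matrix(0L, H, W)
  classes <- annotationClasses()

  rasters <- lapply(glands, .rasterizeGland, height = H, width = W)
  truth <- vector("list", nG)
  for (k in seq_len(nG)) {
    g <- glands[[k]]; rk <- rasters[[k]]
    bb <- rk$bbox
    if (bb[1] < 1 || bb[3] < 1 || bb[2] > H || bb[4] > W)
      stop(sprintf("gland %d extends out of image bounds", k))
    sel <- rk$lumen | rk$epi
    sub <- cbind(rep(rk$rows, length(rk$cols))[as.vector(sel)],
                 rep(rk$cols, each = length(rk$rows))[as.vector(sel)])
    if (any(lumen[sub] | epi[sub]))
      stop(sprintf("gland %d overlaps a previously placed gland", k))
    lumen[cbind(rep(rk$rows, length(rk$cols))[as.vector(rk$lumen)],
                rep(rk$cols, each = length(rk$rows))[as.vector(rk$lumen)])] <- TRUE
    epi[cbind(rep(rk$rows, length(rk$cols))[as.vector(rk$epi)],
              rep(rk$cols, each = length(rk$rows))[as.vector(rk$epi)])] <- TRUE

    a <- g$lumenSemiAxes[1]; b <- g$lumenSemiAxes[2]
    t <- g$epithelialThickness
    pL <- .ellipsePerimeter(a, b)
    aL <- pi * a * b
    aE <- pL * t + pi * t^2                 # Minkowski ring area
    truth[[k]] <- data.frame(
      gland_id = k, annotation_class = g$annotationClass,
      center_row = g$center[1], center_col = g$center[2],
      semi_axis_a_px = a, semi_axis_b_px = b, thickness_px = t,
      lumen_area_um2 = aL * mpp^2, lumen_perimeter_um = pL * mpp,
      lumen_roundness = 4 * pi * aL / pL^2,
      epithelial_area_um2 = aE * mpp^2,
      wall_thickness_um = t * mpp,
      cell_fraction = aE / (aE + aL),
      lumen_px = sum(rk$lumen), epithelium_px = sum(rk$epi),
      stringsAsFactors = FALSE)
    labels[bb[1]:bb[2], bb[3]:bb[4]] <- match(g$annotationClass, classes)
  }
  truth <- if (nG) do.call(rbind, truth) else
    data.frame(gland_id = integer(), annotation_class = character(),
               center_row = numeric(), center_col = numeric(),
               semi_axis_a_px = numeric(), semi_axis_b_px = numeric(),
               thickness_px = numeric(), lumen_area_um2 = numeric(),
               lumen_perimeter_um = numeric(), lumen_roundness = numeric(),
               epithelial_area_um2 = numeric(), wall_thickness_um = numeric(),
               cell_fraction = numeric(), lumen_px = integer(),
               epithelium_px = integer(), stringsAsFactors = FALSE)

  ## tissue rectangle
  tissueRect <- matrix(FALSE, H, W)
  if (nG) {
    if (is.null(spec$stromaFraction)) {
      m <- spec$backgroundMargin
      if (2 * m >= min(H, W)) stop("backgroundMargin leaves no tissue")
      tissueRect[(m + 1):(H - m), (m + 1):(W - m)] <- TRUE
    } else {
      f <- spec$stromaFraction
      ## stroma/(stroma+epithelium) = f  =>  rect area = lumen + epi/(1-f)
      targetArea <- sum(truth$lumen_px) + sum(truth$epithelium_px) / (1 - f)
      bb <- do.call(rbind, lapply(rasters, `[[`, "bbox"))
      cr <- (H + 1) / 2; cc <- (W + 1) / 2
      minH <- 2 * max(cr - min(bb[, 1]), max(bb[, 2]) - cr) + 2
      minW <- 2 * max(cc - min(bb[, 3]), max(bb[, 4]) - cc) + 2
      h <- min(H, max(round(sqrt(targetArea * H / W)), ceiling(minH)))
      w <- min(W, max(round(targetArea / h), ceiling(minW)))
      r0 <- max(1L, round(cr - h / 2)); r1 <- min(H, r0 + h - 1L)
      c0 <- max(1L, round(cc - w / 2)); c1 <- min(W, c0 + w - 1L)
      tissueRect[r0:r1, c0:c1] <- TRUE
    }
    if (any((lumen | epi) & !tissueRect))
      stop("glands must lie inside the tissue rectangle")
  }
  stroma <- tissueRect & !lumen & !epi
  background <- !(lumen | epi | stroma)

  ## render through the stain model
  conc <- array(0, dim = c(H, W, 3))
  eC <- spec$epitheliumConcentration; sC <- spec$stromaConcentration
  for (ch in 1:2) {
    plane <- matrix(0, H, W)
    plane[epi] <- eC[ch]
    plane[stroma] <- sC[ch]
    conc[, , ch] <- plane
  }
  rgb <- odToRgb(conc, spec$stainVectors, io = 1)
  if (spec$noiseSd > 0) {
    rgb <- rgb + array(rnorm(length(rgb), 0, spec$noiseSd), dim = dim(rgb))
    rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  }

  palette <- setNames(classes, as.character(seq_along(classes)))
  used <- sort(unique(labels[labels > 0]))
  ann <- new("AnnotationMask", labels = labels,
             palette = palette[as.character(used)])
  cm <- new("TissueCompartmentMasks", lumen = lumen, epithelium = epi,
            stroma = stroma, background = background,
            micronsPerPixel = mpp)
  new("SyntheticSlide", rgb = rgb, annotation = ann, compartments = cm,
      truth = truth, micronsPerPixel = mpp, spec = unclass(spec))
}
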