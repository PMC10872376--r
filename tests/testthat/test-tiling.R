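test_that("tile grid partitions the slide with the documented edge policy", {
  g <- buildTileGrid(c(9000L, 9000L), 3000)
  expect_equal(nrow(tileLookup(g)), 9L)
  b <- glandmetrics:::.tileBox(g, 0L, 0L)
  expect_equal(unname(b), c(1L, 3000L, 1L, 3000L))

  g2 <- buildTileGrid(c(3100L, 3000L), 3000)
  lk <- tileLookup(g2)
  expect_equal(nrow(lk), 2L)
  edge <- lk[lk$iy == 1L, ]
  expect_equal(edge$row1 - edge$row0 + 1L, 100L)  # 100-px partial edge tile

  expect_error(buildTileGrid(c(0L, 10L), 100), "empty")
})

test_that("stitching tiles reproduces the slide byte-identically", {
  set.seed(4)
  img <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  grid <- buildTileGrid(img, 24)             # partial tiles at both edges
  lk <- tileLookup(grid)
  tiles <- list()
  for (i in seq_len(nrow(lk)))
    tiles[[tileName(lk$ix[i], lk$iy[i])]] <-
      extractTile(img, grid, lk$ix[i], lk$iy[i])
  expect_identical(stitchTiles(tiles, grid), img)
})

test_that("white mask flags blank glass but not tissue", {
  white <- array(1, dim = c(8, 8, 3))
  expect_true(all(computeWhiteMask(white)))
  black <- array(0, dim = c(8, 8, 3))
  expect_false(any(computeWhiteMask(black)))

  # 40% white border by construction: margin m on side n leaves (n-2m)^2 tissue
  n <- 500; m <- round(n * (1 - sqrt(0.6)) / 2)
  ctr <- (n + 1) / 2
  sp <- syntheticSlideSpec(n, n, glands = list(
    glandSpec(c(ctr, ctr), c(8, 8), 6)), backgroundMargin = m)
  slide <- generateSyntheticSlide(sp)
  wm <- computeWhiteMask(slideImage(slide))
  cm <- slideCompartments(slide)
  expect_identical(wm, backgroundMask(cm) | lumenMask(cm))
  expect_equal(sum(backgroundMask(cm)) / n^2, 0.40, tolerance = 0.025)
})

test_that("ROIs are the 8-connected components of one class", {
  lab <- matrix(0L, 40, 40)
  lab[5:10, 5:10] <- 4L          # G3 blob 1
  lab[25:32, 20:30] <- 4L        # G3 blob 2
  lab[15:20, 30:35] <- 1L        # benign blob
  pal <- c(`1` = "benign", `4` = "G3")
  mask <- new("AnnotationMask", labels = lab, palette = pal)

  rois <- splitMaskToRois(mask, "G3")
  expect_length(rois, 2L)
  expect_setequal(vapply(rois, function(r) sum(r@support), integer(1)),
                  c(36L, 88L))
  expect_equal(rois[[1]]@bbox, c(5L, 10L, 5L, 10L))
  expect_length(splitMaskToRois(mask, "G5"), 0L)
})

test_that("tile selection enforces quotas, coverage and determinism", {
  # ROI covering a 4x4 block of 10px tiles exactly; no white space
  lab <- matrix(0L, 100, 100)
  lab[21:60, 21:60] <- 4L
  mask <- new("AnnotationMask", labels = lab, palette = c(`4` = "G3"))
  grid <- buildTileGrid(c(100L, 100L), 10)
  white <- matrix(FALSE, 100, 100)
  roi <- splitMaskToRois(mask, "G3")[[1]]

  sel <- selectTilesForRoi(roi, grid, white, seed = 7)
  expect_equal(nrow(sel), 5L)                       # cancer quota
  expect_true(all(sel$coverage > 0.5))
  expect_identical(sel, selectTilesForRoi(roi, grid, white, seed = 7))

  # benign quota on the same geometry: 15 of 16 eligible tiles
  roiB <- new("RegionOfInterest", annotationClass = "benign",
              componentId = 1L, bbox = roi@bbox, support = roi@support,
              slideDim = roi@slideDim)
  selB <- selectTilesForRoi(roiB, grid, white, seed = 7)
  expect_equal(nrow(selB), 15L)

  # ROI spanning only 3 full tiles is skipped
  lab2 <- matrix(0L, 100, 100)
  lab2[21:30, 21:50] <- 4L
  roi2 <- splitMaskToRois(new("AnnotationMask", labels = lab2,
                              palette = c(`4` = "G3")), "G3")[[1]]
  expect_equal(nrow(selectTilesForRoi(roi2, grid, white, seed = 1)), 0L)
})

test_that("coverage uses tissue pixels after white-space removal", {
  # tile is mostly white, but all its tissue lies in the ROI: eligible
  lab <- matrix(0L, 50, 50)
  lab[1:50, 1:30] <- 4L
  mask <- new("AnnotationMask", labels = lab, palette = c(`4` = "G3"))
  grid <- buildTileGrid(c(50L, 50L), 10)
  white <- matrix(TRUE, 50, 50)
  white[, 26:30] <- FALSE          # thin tissue band inside the ROI
  roi <- splitMaskToRois(mask, "G3")[[1]]
  sel <- selectTilesForRoi(roi, grid, white, seed = 2)
  expect_equal(nrow(sel), 5L)
  expect_true(all(sel$coverage == 1))
  # with the all-pixels denominator those tiles fall below 50%
  selAll <- selectTilesForRoi(roi, grid, white, seed = 2,
                              coverageDenominator = "all")
  expect_equal(nrow(selAll), 0L)
})

test_that("annotation rescaling preserves labels and inverts on aligned grids", {
  lab <- matrix(0L, 10, 10)
  lab[3:6, 4:8] <- 2L
  mask <- new("AnnotationMask", labels = lab, palette = c(`2` = "atrophy"))
  expect_identical(annotationLabels(rescaleAnnotation(mask, 1)), lab)
  up <- rescaleAnnotation(mask, 2)
  expect_equal(dim(annotationLabels(up)), c(20L, 20L))
  expect_equal(sum(annotationLabels(up) == 2L), 4L * sum(lab == 2L))
  expect_setequal(unique(as.vector(annotationLabels(up))), c(0L, 2L))
  back <- rescaleAnnotation(up, 0.5)
  expect_identical(annotationLabels(back), lab)
})
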