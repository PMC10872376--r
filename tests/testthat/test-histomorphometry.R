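test_that("roundness closed forms", {
  s <- 37
  expect_identical(roundness(s^2, 4 * s), pi / 4)   # ideal square, exact
  expect_equal(roundness(pi, 2 * pi), 1)
  expect_error(roundness(1, 0))
})

test_that("measured shapes match closed forms on digital regions", {
  disk <- diskMask(50)
  sh <- measureShape(disk, micronsPerPixel = 1)
  expect_gte(sh$roundness, 0.9)
  expect_lte(sh$roundness, 1.1)
  expect_equal(sh$area_mm2, pi * 50^2 * 1e-6, tolerance = 0.02)
  expect_equal(sh$perimeter_mm, 2 * pi * 50 * 1e-3, tolerance = 0.02)

  # unit conversion: 100 px at 2 um/px -> 4e-4 mm^2
  m <- matrix(FALSE, 20, 20); m[6:15, 6:15] <- TRUE
  expect_equal(measureShape(m, micronsPerPixel = 2)$area_mm2, 4e-4)

  expect_error(measureShape(matrix(FALSE, 5, 5)), "empty")
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_true(is.finite(measureShape(single)$roundness))  # perimeter floor
})

test_that("gland labeling pairs lumina with their epithelium", {
  slide <- generateSyntheticSlide(oneGlandSpec(r = 40, t = 15))
  lg <- labelGlands(slideCompartments(slide))
  expect_length(lg$glands, 1L)
  expect_equal(lg$diagnostics$unpairedLumina, 0L)

  two <- syntheticSlideSpec(400, 400, glands = list(
    glandSpec(c(120, 120), c(40, 40), 15),
    glandSpec(c(280, 280), c(35, 35), 12)), backgroundMargin = 10)
  lg2 <- labelGlands(slideCompartments(generateSyntheticSlide(two)))
  expect_length(lg2$glands, 2L)

  # lumen with no adjacent epithelium: excluded, tallied
  lum <- matrix(FALSE, 60, 60); lum[20:30, 20:30] <- TRUE
  epi <- matrix(FALSE, 60, 60); epi[45:55, 45:55] <- TRUE
  stroma <- !(lum | epi); stroma[1:5, ] <- FALSE
  bg <- !(lum | epi | stroma)
  masks <- new("TissueCompartmentMasks", lumen = lum, epithelium = epi,
               stroma = stroma, background = bg, micronsPerPixel = 1)
  lg3 <- labelGlands(masks)
  expect_equal(lg3$diagnostics$unpairedLumina, 1L)
  expect_length(lg3$glands, 1L)
  expect_false(any(lg3$glands[[1]]$lumen))
})

test_that("wall thickness is the inner-to-outer minimum distance", {
  mk <- function(n, innerC, rIn, outerC, rOut) {
    idx <- expand.grid(i = 1:n, j = 1:n)
    dIn <- sqrt((idx$i - innerC[1])^2 + (idx$j - innerC[2])^2)
    dOut <- sqrt((idx$i - outerC[1])^2 + (idx$j - outerC[2])^2)
    lum <- matrix(dIn <= rIn, n, n)
    epi <- matrix(dOut <= rOut, n, n) & !lum
    list(lumen = lum, epithelium = epi)
  }
  # concentric 50/70 at 1 um/px -> 0.020 mm, +-1 px
  g <- mk(161, c(81, 81), 50, c(81, 81), 70)
  expect_equal(wallThickness(g, 1), 0.020, tolerance = 0.0011 / 0.020)
  # eccentric: inner offset 10 px -> 10 um
  g2 <- mk(161, c(91, 81), 50, c(81, 81), 70)
  expect_equal(wallThickness(g2, 1), 0.010, tolerance = 0.0011 / 0.010)
  # touching boundaries -> 0 within 1 px
  g3 <- mk(161, c(101, 81), 50, c(81, 81), 70)
  expect_lte(wallThickness(g3, 1), 0.0011)
  # no lumen -> missing
  g4 <- list(lumen = matrix(FALSE, 5, 5), epithelium = matrix(TRUE, 5, 5))
  expect_true(is.na(wallThickness(g4, 1)))
})

test_that("cell fraction follows the adopted definition", {
  expect_equal(cellFraction(75, 25), 0.75)
  expect_equal(cellFraction(10, 0), 1.0)
  expect_error(cellFraction(0, 0), "zero")
  set.seed(2)
  for (k in 1:50) {
    cf <- cellFraction(runif(1, 0, 100), runif(1, 0, 100))
    expect_gte(cf, 0); expect_lte(cf, 1)
  }
})

test_that("gland measurements recover generator truth within 5%", {
  slide <- generateSyntheticSlide(oneGlandSpec(r = 45, t = 18, mpp = 0.5))
  meas <- measureGlands(segmentSlide(slideImage(slide),
                                     micronsPerPixel = 0.5))$measurements
  tr <- slideTruth(slide)
  expect_equal(meas$lumen_area_mm2, tr$lumen_area_um2 * 1e-6,
               tolerance = 0.05)
  expect_equal(meas$epithelial_area_mm2, tr$epithelial_area_um2 * 1e-6,
               tolerance = 0.05)
  expect_equal(meas$wall_thickness_mm, tr$wall_thickness_um * 1e-3,
               tolerance = 0.06)
  expect_gte(meas$lumen_roundness, 0.9)
  expect_lte(meas$lumen_roundness, 1.1)
})

test_that("measured wall thickness increases with generated thickness", {
  thicknesses <- c(8, 12, 16, 20, 24)
  measured <- vapply(thicknesses, function(t) {
    slide <- generateSyntheticSlide(oneGlandSpec(r = 40, t = t))
    measureGlands(slideCompartments(slide))$measurements$wall_thickness_mm
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("roundness is scale invariant", {
  r1 <- measureShape(diskMask(40))$roundness
  r2 <- measureShape(diskMask(80))$roundness
  expect_equal(r1, r2, tolerance = 0.02)
})

test_that("tile summaries average glands and normalize by tile area", {
  slide <- generateSyntheticSlide(syntheticSlideSpec(400, 400, glands = list(
    glandSpec(c(120, 120), c(40, 40), 15),
    glandSpec(c(280, 280), c(35, 35), 12)), backgroundMargin = 10))
  masks <- slideCompartments(slide)
  mg <- measureGlands(masks)
  summ <- summarizeTile(mg$measurements, masks, 0L, 0L, "G3")
  expect_equal(summ$gland_count, 2L)
  expect_equal(summ$lumen_area_mm2, mean(mg$measurements$lumen_area_mm2))
  expect_equal(summ$stroma_area_fraction,
               sum(stromaMask(masks)) / prod(dim(stromaMask(masks))))
  # zero glands: fractions still computed, feature means missing
  empty <- mg$measurements[0, ]
  s0 <- summarizeTile(empty, masks)
  expect_equal(s0$gland_count, 0L)
  expect_true(is.na(s0$lumen_area_mm2))
  expect_gt(s0$stroma_area_fraction, 0)
})

test_that("patient aggregation filters groups and weights slides equally", {
  ts <- data.frame(ix = 0:3, iy = 0L,
                   annotation_class = c("G3", "G4CG", "benign", "atrophy"),
                   gland_count = 1L, stroma_area_fraction = c(.1, .2, .3, .4),
                   epithelial_area_fraction = .2,
                   lumen_area_mm2 = c(1, 3, 5, 7) * 1e-3,
                   lumen_roundness = .9, epithelial_area_mm2 = 2e-3,
                   epithelial_roundness = .5, wall_thickness_mm = .02,
                   cell_fraction = .5, slide = c("s1", "s1", "s1", "s2"))
  allv <- aggregatePatient(ts, "all")
  expect_equal(unname(allv["lumen_area_mm2"]), 4e-3)
  cav <- aggregatePatient(ts, "cancer")
  expect_equal(unname(cav["lumen_area_mm2"]), 2e-3)   # G3 + G4CG only
  ncv <- aggregatePatient(ts, "noncancer")
  expect_equal(unname(ncv["lumen_area_mm2"]), 6e-3)
  # single tile: aggregate equals the tile
  one <- aggregatePatient(ts[1, ], "all")
  expect_equal(unname(one["lumen_area_mm2"]), 1e-3)
  # wsi: slide means first (s1 mean 3e-3, s2 7e-3), then slide average
  wsi <- aggregatePatient(ts, "wsi")
  expect_equal(unname(wsi["lumen_area_mm2"]), mean(c(3e-3, 7e-3)))
  # equal tiles per slide: mean of means equals brute-force mean
  ts2 <- ts; ts2$slide <- c("s1", "s1", "s2", "s2")
  expect_equal(unname(aggregatePatient(ts2, "wsi")["lumen_area_mm2"]),
               mean(ts2$lumen_area_mm2))
  expect_null(aggregatePatient(ts[ts$annotation_class == "G3", ], "noncancer"))
})
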