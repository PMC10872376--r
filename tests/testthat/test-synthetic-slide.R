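test_that("circular gland truth matches closed forms and rasterization", {
  slide <- generateSyntheticSlide(oneGlandSpec(r = 50, t = 20, mpp = 1))
  tr <- slideTruth(slide)
  expect_equal(tr$lumen_area_um2, pi * 50^2, tolerance = 1e-8)
  expect_equal(tr$wall_thickness_um, 20)
  expect_equal(tr$lumen_roundness, 1, tolerance = 1e-8)
  # rasterized pixel counts within 2% of analytic areas
  expect_lt(abs(tr$lumen_px - pi * 50^2) / (pi * 50^2), 0.02)
  epiAnalytic <- 2 * pi * 50 * 20 + pi * 20^2
  expect_lt(abs(tr$epithelium_px - epiAnalytic) / epiAnalytic, 0.02)
})

test_that("zero glands gives an all-white image and empty truth", {
  slide <- generateSyntheticSlide(syntheticSlideSpec(64, 64))
  expect_equal(nrow(slideTruth(slide)), 0L)
  expect_true(all(slideImage(slide) == 1))
  expect_true(all(backgroundMask(slideCompartments(slide))))
})

test_that("generation is seed-deterministic", {
  sp <- oneGlandSpec(r = 30, t = 10, seed = 11, noiseSd = 0.02)
  a <- generateSyntheticSlide(sp)
  b <- generateSyntheticSlide(sp)
  expect_identical(slideImage(a), slideImage(b))
  expect_identical(slideTruth(a), slideTruth(b))
  expect_identical(annotationLabels(slideAnnotation(a)),
                   annotationLabels(slideAnnotation(b)))
})

test_that("overlapping or out-of-bounds glands are rejected", {
  overlapping <- syntheticSlideSpec(300, 300, glands = list(
    glandSpec(c(150, 120), c(40, 40), 15),
    glandSpec(c(150, 180), c(40, 40), 15)), backgroundMargin = 10)
  expect_error(generateSyntheticSlide(overlapping), "overlap")
  outOfBounds <- syntheticSlideSpec(120, 120, glands = list(
    glandSpec(c(60, 110), c(40, 40), 15)), backgroundMargin = 0)
  expect_error(generateSyntheticSlide(outOfBounds), "bounds|tissue")
})

test_that("raster areas track analytic ellipse/annulus areas across shapes", {
  cases <- list(c(a = 20, b = 20, t = 8), c(a = 40, b = 25, t = 12),
                c(a = 60, b = 30, t = 15), c(a = 35, b = 35, t = 25))
  for (cs in cases) {
    side <- 2 * (max(cs["a"], cs["b"]) + cs["t"]) + 60
    ctr <- (side + 1) / 2
    sp <- syntheticSlideSpec(side, side, glands = list(
      glandSpec(c(ctr, ctr), c(cs[["a"]], cs[["b"]]), cs[["t"]],
                orientation = 0.4)), backgroundMargin = 5)
    tr <- slideTruth(generateSyntheticSlide(sp))
    expect_lt(abs(tr$lumen_px - tr$lumen_area_um2) / tr$lumen_area_um2, 0.02)
    expect_lt(abs(tr$epithelium_px - tr$epithelial_area_um2) /
                tr$epithelial_area_um2, 0.02)
  }
})

test_that("stroma fraction target is realized when requested", {
  sp <- syntheticSlideSpec(500, 500, glands = list(
    glandSpec(c(250, 250), c(45, 45), 18)), stromaFraction = 0.6)
  cm <- slideCompartments(generateSyntheticSlide(sp))
  realized <- sum(stromaMask(cm)) /
    (sum(stromaMask(cm)) + sum(epitheliumMask(cm)))
  expect_lt(abs(realized - 0.6), 0.02)
})

test_that("rendered colors invert exactly through the stain model", {
  slide <- generateSyntheticSlide(oneGlandSpec(r = 25, t = 10))
  conc <- deconvolveStains(rgbToOd(slideImage(slide)))
  cm <- slideCompartments(slide)
  expect_true(all(conc[, , 1][epitheliumMask(cm)] >
                  conc[, , 2][epitheliumMask(cm)]))
  expect_true(all(conc[, , 2][stromaMask(cm)] > conc[, , 1][stromaMask(cm)]))
})
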