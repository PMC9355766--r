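# Morphometry: Hough orientation, valley-spacing width, structure-tensor
# structural dispersion.

shgOf <- function(field, nPx = 512) MPImage(
  field * 1000 + 1, "SHG",
  pixelSizeUm = if (nPx == 512) 180 / 512 else stdPx)

test_that("Hough voting recovers the stripe orientation within a degree", {
  for (ori in c(0, 30)) {
    f <- smallField(5, ori, nPx = 256)
    est <- estimateOrientationHough(shgOf(f, 256))
    expect_lt(min(abs(est - ori), 180 - abs(est - ori)), 1)
  }
  # intensity-scale invariance
  f <- smallField(5, 30, nPx = 256)
  a <- estimateOrientationHough(shgOf(f, 256))
  b <- estimateOrientationHough(MPImage(f * 52000, "SHG",
                                        pixelSizeUm = 180 / 256))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("degenerate images raise a 'no dominant orientation' error", {
  expect_error(estimateOrientationHough(uniformImage(7, nPx = 64)),
               "no dominant orientation")
  set.seed(3)
  noise <- MPImage(matrix(stats::runif(128^2), 128), "SHG",
                   pixelSizeUm = 180 / 128)
  expect_error(estimateOrientationHough(noise), "no dominant orientation")
})

test_that("valley spacing recovers the stripe period", {
  f <- generateTubuleField(tubuleFieldParams(5, 0, nPx = 512), seed = 1)
  tm <- peritubuleWidth(shgOf(f, 512), 0)
  expect_lt(abs(tm$widthUm - 5), 0.35)
  expect_gte(tm$nValleys, 2 * tm$sectionsUsed)
  expect_gt(tm$sectionsUsed, 0)
})

test_that("width estimation requires an orientation and enough valleys", {
  f <- smallField(5, 0, nPx = 128)
  expect_error(peritubuleWidth(shgOf(f, 128), NULL), "orientationDeg")
  expect_error(peritubuleWidth(shgOf(f, 128), NA), "orientationDeg")
  expect_error(peritubuleWidth(uniformImage(5, nPx = 64), 0), "valleys")
})

test_that("width is rotation-invariant across periods and orientations", {
  px <- 180 / 512
  for (period in c(3, 5, 7)) {
    for (ori in c(0, 60, 137)) {
      f <- generateTubuleField(tubuleFieldParams(period, ori, nPx = 512),
                               seed = 1)
      w <- peritubuleWidth(shgOf(f, 512), ori)$widthUm
      expect_lt(abs(w - period), px)
    }
  }
})

test_that("structural dispersion tracks the generator's jitter", {
  # parallel stripes: near-zero dispersion, organized
  f <- smallField(5, 30, nPx = 256)
  om <- structureTensorSD(shgOf(f, 256))
  expect_lt(om$sdDeg, 5)
  expect_identical(om$orgClass, "organized")
  expect_lt(min(abs(om$preferredOrientationDeg - 30),
                180 - abs(om$preferredOrientationDeg - 30)), 3)
  # jitter sd 10 degrees -> SD close to 10
  sds <- vapply(1:3, function(s) {
    fj <- generateTubuleField(
      tubuleFieldParams(5, 30, jitterDeg = 10, nPx = 512), seed = s)
    structureTensorSD(shgOf(fj, 512))$sdDeg
  }, numeric(1))
  expect_lt(abs(mean(sds) - 10), 2)
})

test_that("random-orientation patchworks are disorganized", {
  for (s in 1:3) {
    fp <- generatePatchworkField(tubuleFieldParams(5, nPx = 256), 8,
                                 seed = s)
    om <- structureTensorSD(shgOf(fp, 256))
    expect_gt(om$sdDeg, 40)
    expect_identical(om$orgClass, "disorganized")
  }
})

test_that("organization class boundaries sit exactly at 20 and 40", {
  expect_identical(classifyOrganization(20), "organized")
  expect_identical(classifyOrganization(20.001), "partial")
  expect_identical(classifyOrganization(40), "partial")
  expect_identical(classifyOrganization(40.001), "disorganized")
  expect_error(structureTensorSD(uniformImage(3, nPx = 32)), "constant")
})

test_that("Hough and structure-tensor orientations agree on aligned
           fields", {
  for (ori in c(20, 75, 140)) {
    f <- smallField(5, ori, nPx = 256)
    img <- shgOf(f, 256)
    h <- estimateOrientationHough(img)
    st <- structureTensorSD(img)$preferredOrientationDeg
    expect_lt(min(abs(h - st), 180 - abs(h - st)), 3)
  }
})
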