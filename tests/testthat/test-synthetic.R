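# Synthetic generator: stripe geometry, channel rendering, polarimetric
# forward model, cohort ground truth.

test_that("stripe period is reproduced along the normal axis", {
  # independent oracle: lag of the autocorrelation peak of the mean
  # row profile (orientation 0 varies along rows)
  px <- 180 / 512
  f <- generateTubuleField(tubuleFieldParams(5, 0, nPx = 512), seed = 1)
  prof <- rowMeans(f)
  prof <- prof - mean(prof)
  ac <- stats::acf(prof, lag.max = 40, plot = FALSE)$acf[-1]
  lags <- seq_along(ac)
  # first local max beyond half the expected period
  cand <- lags[lags * px > 2.5 & lags * px < 7.5]
  peak <- cand[which.max(ac[cand])]
  expect_lt(abs(peak * px - 5), 0.35 + 1e-9)
})

test_that("orientation 90 is the transpose of orientation 0", {
  f0 <- smallField(5, 0)
  f90 <- smallField(5, 90)
  expect_equal(f90, t(f0))
})

test_that("width-line period at age 19 places valleys 4.04 um apart", {
  period <- 0.03 * 19 + 3.47
  expect_equal(period, 4.04)
  f <- generateTubuleField(tubuleFieldParams(period, 0, nPx = 512),
                           seed = 1)
  img <- MPImage(f * 1000, channel = "SHG", pixelSizeUm = 180 / 512)
  expect_lt(abs(peritubuleWidth(img, 0)$widthUm - 4.04), 0.35)
})

test_that("sub-Nyquist periods are rejected with a diagnostic", {
  expect_error(tubuleFieldParams(0.5, nPx = 128), "Nyquist")
  expect_error(tubuleFieldParams(5, duty = 1.2), "duty")
  expect_error(tubuleFieldParams(5, jitterDeg = -1), "jitterDeg")
})

test_that("field generation is deterministic and bounded", {
  a <- smallField(5, 30, jitterDeg = 8, seed = 7)
  b <- smallField(5, 30, jitterDeg = 8, seed = 7)
  expect_identical(a, b)
  c <- smallField(5, 30, jitterDeg = 8, seed = 8)
  expect_false(identical(a, c))
  expect_gte(min(a), 0)
  expect_lte(max(a), 1)
})

test_that("noiseless channel pairs conserve the configured ratio exactly", {
  for (r in c(1, 0.57, 0.39)) {
    pair <- smallPair(ratio = r)
    got <- mean(intensity(pair$shg)) / mean(intensity(pair$tpef))
    expect_equal(got, r, tolerance = 1e-12)
  }
  # ratio 1, zero noise: channels identical
  pair <- smallPair(ratio = 1)
  expect_equal(intensity(pair$shg), intensity(pair$tpef))
})

test_that("invalid render ratios are rejected", {
  expect_error(channelRenderParams(shgTpefRatio = 0), "must be in")
  expect_error(channelRenderParams(shgTpefRatio = 1.2), "must be in")
})

test_that("noisy ratio is unbiased and tightens with photon gain", {
  f <- smallField(5, nPx = 64)
  measure <- function(gain, seed) {
    p <- renderChannelPair(
      f, channelRenderParams(shgTpefRatio = 0.39, photonGain = gain,
                             tpefMean = 500), seed = seed)
    mean(intensity(p$shg)) / mean(intensity(p$tpef))
  }
  lo <- vapply(1:10, function(s) measure(0.5, s), numeric(1))
  hi <- vapply(1:10, function(s) measure(50, s), numeric(1))
  expect_lt(abs(mean(lo) - 0.39), 0.02)
  expect_lt(abs(mean(hi) - 0.39), 0.002)
  expect_lt(stats::sd(hi), stats::sd(lo))
  # quantization to integer counts once noise is on
  p <- renderChannelPair(f, channelRenderParams(photonGain = 10),
                         seed = 1)
  expect_true(all(intensity(p$shg) == round(intensity(p$shg))))
})

test_that("polarimetric forward model matches hand-computed values", {
  resp <- dentineMP:::shgPolResponse
  expect_equal(resp(0, 0, -1.25), 1.5625)        # rho^2 at parallel
  expect_equal(resp(90, 0, -1.25), 1)            # perpendicular
  expect_equal(resp(60, 0, -1.25), 0.94140625)   # 0.75 + (0.75 - 0.3125)^2
  # 180-degree periodicity and theta -> theta + 90 swap
  expect_equal(resp(37, 10, -2), resp(37 + 180, 10, -2))
  f <- matrix(1, 8, 8)
  pp <- polarimetricRenderParams(rho = -1.25, scale = 1)
  st0 <- renderPolarimetricStack(f, pp, fiberOrientationDeg = 0)
  st90 <- renderPolarimetricStack(f, pp, fiberOrientationDeg = 90)
  i <- function(st, k) intensity(st@images[[k]])[1]
  expect_equal(i(st0, 1), i(st90, 2))   # parallel <-> perpendicular swap
  expect_equal(i(st0, 2), i(st90, 1))
})

test_that("polarimetric render parameters are validated", {
  expect_error(polarimetricRenderParams(rho = 0), "nonzero")
  expect_error(polarimetricRenderParams(rho = 1, anglesDeg = c(0, 30, 60)),
               "orthogonal")
})

test_that("cohort ground truth sits on the configured lines", {
  cfg <- cohortConfig(agesYears = c(24, 50, 82), regionsPerSpecimen = 1,
                      nPx = 64, fieldUm = 64 * stdPx)
  co <- generateCohort(cfg, what = "pairs")
  tr <- co$truth
  expect_equal(tr$inag_true[1], -0.003 * 24 - 0.25)  # -0.322
  expect_equal(tr$ratio_true[1], 0.678 / 1.322, tolerance = 1e-12)
  expect_equal(tr$width_true_um[3], 0.03 * 82 + 3.47) # 5.93
  # zero residual: exact collinearity of (age, width)
  cfgBig <- cohortConfig(regionsPerSpecimen = 1, nPx = 64,
                         fieldUm = 64 * stdPx)
  trBig <- generateCohort(cfgBig, what = "pairs")$truth
  expect_equal(stats::cor(trBig$age_years, trBig$width_true_um), 1,
               tolerance = 1e-12)
})

test_that("cohorts are bit-identical under a fixed seed", {
  cfg <- cohortConfig(agesYears = c(20, 60), regionsPerSpecimen = 2,
                      nPx = 48, fieldUm = 48 * stdPx, photonGain = 20, seed = 5)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(intensity(a$specimens[[2]]@regions[[2]]$shg),
                   intensity(b$specimens[[2]]@regions[[2]]$shg))
  expect_identical(
    intensity(a$specimens[[1]]@regions[[1]]$stack@images[[3]]),
    intensity(b$specimens[[1]]@regions[[1]]$stack@images[[3]]))
})

test_that("unrepresentable INAG ground truth is rejected", {
  expect_error(ratioFromInag(-1), "undefined")
  expect_error(ratioFromInag(1.1), "undefined")
  cfg <- cohortConfig(agesYears = c(20, 50, 80),
                      inagLine = c(-0.02, 0.6), nPx = 64,
                      fieldUm = 64 * stdPx)
  expect_error(generateCohort(cfg), "INAG")
})
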