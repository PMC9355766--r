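# Signed rho inversion from three-polarization stacks.

stackFor <- function(rho, theta = 0, nPx = 64, seed = 1, gain = 0,
                     pattern = NULL) {
  if (is.null(pattern)) pattern <- smallField(5, theta %% 180, nPx = nPx)
  renderPolarimetricStack(
    pattern, polarimetricRenderParams(rho = rho, photonGain = gain),
    fiberOrientationDeg = theta, seed = seed, pixelSizeUm = stdPx)
}

test_that("magnitude is the square root of the parallel/perpendicular
           ratio", {
  mk <- function(val, pol) uniformImage(val, "SHG", 8, pol)
  st <- PolarimetricStack(list(mk(4, 0), mk(1, 90), mk(2, 60)))
  expect_true(all(abs(rhoMagnitude(st, 0) - 2) < 1e-12))
  stEq <- PolarimetricStack(list(mk(3, 0), mk(3, 90), mk(3, 60)))
  expect_true(all(abs(rhoMagnitude(stEq, 0) - 1) < 1e-12))
  # round-trip through the renderer
  st269 <- stackFor(-2.69, 0)
  m <- rhoMagnitude(st269, 0)
  expect_lt(max(abs(m[!is.na(m)] - 2.69)), 1e-9)
})

test_that("the oblique state resolves the sign", {
  stNeg <- stackFor(-1.25, 0)
  sNeg <- rhoSign(stNeg, rhoMagnitude(stNeg, 0), 0)
  expect_true(all(sNeg[!is.na(sNeg)] == -1))
  stPos <- stackFor(1.25, 0)
  sPos <- rhoSign(stPos, rhoMagnitude(stPos, 0), 0)
  expect_true(all(sPos[!is.na(sPos)] == 1))
  # |rho| ~ 0 pixels are masked, not signed
  mk <- function(val, pol) uniformImage(val, "SHG", 8, pol)
  stZero <- PolarimetricStack(list(mk(0, 0), mk(1, 90), mk(1, 60)))
  s0 <- rhoSign(stZero, rhoMagnitude(stZero, 0), 0)
  expect_true(all(is.na(s0)))
})

test_that("noiseless rho maps invert the forward model exactly", {
  for (rho in c(-3, -2, -1.25, -0.5, 0.5, 2)) {
    for (theta in c(0, 15, 50, 105)) {
      rm <- rhoMap(stackFor(rho, theta, nPx = 48), thetaDeg = theta)
      v <- rm@values[rm@mask]
      expect_gt(length(v), 0)
      expect_lt(max(abs(v - rho)) / abs(rho), 1e-6)
      expect_lt(abs(rm@summaryMean - rho) / abs(rho), 1e-6)
    }
  }
})

test_that("mirror-symmetric fiber orientations are flagged as
           unidentifiable", {
  for (theta in c(30, 120))
    expect_error(rhoMap(stackFor(-1.25, theta, nPx = 32),
                        thetaDeg = theta), "unidentifiable")
})

test_that("noisy rho maps stay close to truth on average", {
  means <- vapply(1:10, function(s) {
    st <- stackFor(-1.25, 0, nPx = 64, seed = s, gain = 100)
    rhoMap(st, thetaDeg = 0)@summaryMean
  }, numeric(1))
  expect_lt(abs(mean(means) + 1.25), 0.05)
})

test_that("sign is stable under global intensity rescaling and masking is
           monotone in the floor", {
  st <- stackFor(-1.25, 0, nPx = 48)
  rm1 <- rhoMap(st, 0)
  scaled <- PolarimetricStack(lapply(st@images, function(x)
    MPImage(intensity(x) * 37.5, "SHG", pixelSizeUm = pixelSize(x),
            polarizationDeg = polarizationAngle(x))),
    anglesDeg = st@anglesDeg)
  rm2 <- rhoMap(scaled, 0)
  expect_identical(sign(rm1@values), sign(rm2@values))
  expect_equal(rm1@summaryMean, rm2@summaryMean, tolerance = 1e-9)
  # raising the floor never unmasks
  iPerp <- intensity(st@images[[2]])
  lo <- rhoMap(st, 0, floor = 0.02 * max(iPerp))
  hi <- rhoMap(st, 0, floor = 0.2 * max(iPerp))
  expect_true(all(!hi@mask | lo@mask))
  expect_lte(sum(hi@mask), sum(lo@mask))
})

test_that("identical images give |rho| = 1 with a consistent sign", {
  mk <- function(pol) uniformImage(500, "SHG", 16, pol)
  st <- PolarimetricStack(list(mk(0), mk(90), mk(60)))
  rm <- rhoMap(st, 0)
  expect_true(all(abs(abs(rm@values[rm@mask]) - 1) < 1e-9))
  expect_equal(rm@summaryMean, -1, tolerance = 1e-9)
})

test_that("theta defaults to the Hough estimate from the stack", {
  f <- smallField(5, 0, nPx = 256)
  st <- renderPolarimetricStack(
    f, polarimetricRenderParams(rho = -1.25),
    fiberOrientationDeg = 0, pixelSizeUm = stdPx)
  rm <- rhoMap(st)
  expect_lt(min(rm@fiberOrientationDeg, 180 - rm@fiberOrientationDeg), 1)
  expect_lt(abs(rm@summaryMean + 1.25), 0.01)
})
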