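# Shared in-code fixtures. Images are generated at small sizes for unit
# tests; acceptance tests build their own full-size cohorts.

# Unit-test images keep the standard 0.3516 um pixel and shrink the field
# with the pixel count, so stripe periods stay well above Nyquist.
stdPx <- 180 / 512

smallField <- function(periodUm = 5, orientationDeg = 0, nPx = 128,
                       jitterDeg = 0, seed = 1) {
  generateTubuleField(
    tubuleFieldParams(periodUm, orientationDeg, jitterDeg = jitterDeg,
                      nPx = nPx, fieldUm = nPx * stdPx), seed = seed)
}

smallPair <- function(ratio = 0.57, nPx = 64, periodUm = 5, seed = 1,
                      photonGain = 0) {
  f <- smallField(periodUm, nPx = nPx, seed = seed)
  renderChannelPair(f, channelRenderParams(shgTpefRatio = ratio,
                                           photonGain = photonGain),
                    seed = seed, pixelSizeUm = stdPx)
}

uniformImage <- function(value, channel = "SHG", nPx = 32,
                         polarizationDeg = NA_real_) {
  MPImage(matrix(value, nPx, nPx), channel = channel,
          pixelSizeUm = 180 / nPx, polarizationDeg = polarizationDeg)
}

# Memoized full-scale noiseless cohort analysis shared by the acceptance
# tests (one pipeline run serves the width and INAG criteria).
.acceptanceCache <- new.env(parent = emptyenv())

acceptancePairsRun <- function() {
  if (is.null(.acceptanceCache$pairs)) {
    cfg <- runConfig(cohortConfig(seed = 20210729L),
                     orientation = "hough", withPolarimetry = FALSE)
    .acceptanceCache$pairs <- runPipeline(cfg)
  }
  .acceptanceCache$pairs
}
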