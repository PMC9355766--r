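#' Channel rendering parameters
#'
#' Controls how a geometric stripe pattern is turned into a TPEF/SHG
#' intensity pair: the TPEF intensity scale, the SHG/TPEF mean-intensity
#' ratio, the additive background, and the photomultiplier noise model
#' (Poisson photon noise plus Gaussian read noise, quantized to the
#' detector bit depth).
#'
#' With \code{photonGain = 0} and \code{readNoiseSd = 0} the render is
#' noiseless: images are continuous-valued and the measured mean(SHG) /
#' mean(TPEF) equals \code{shgTpefRatio} to machine precision. With any
#' noise on, counts are quantized to integers in \code{[0, 2^bitDepth - 1]}.
#'
#' @param tpefMean TPEF intensity scale in detector counts.
#' @param shgTpefRatio target ratio of spatial means, in (0, 1]; dentine
#'   SHG is weaker than TPEF so values below 1 are typical.
#' @param background additive background as a fraction of the channel mean.
#' @param photonGain counts per intensity unit for Poisson noise (0 = off).
#' @param readNoiseSd Gaussian read noise sd in counts (0 = off).
#' @param bitDepth detector bit depth (default 16).
#' @return a validated list of class \code{"ChannelRenderParams"}.
#' @export
channelRenderParams <- function(tpefMean = 1000, shgTpefRatio = 0.57,
                                background = 0.05, photonGain = 0,
                                readNoiseSd = 0, bitDepth = 16L) {
  if (!is.finite(shgTpefRatio) || shgTpefRatio <= 0 || shgTpefRatio > 1)
    stop("'shgTpefRatio' must be in (0, 1]")
  if (tpefMean <= 0) stop("'tpefMean' must be positive")
  if (background < 0 || background >= 1)
    stop("'background' must be in [0, 1)")
  if (photonGain < 0 || readNoiseSd < 0)
    stop("noise parameters must be >= 0")
  structure(list(tpefMean = tpefMean, shgTpefRatio = shgTpefRatio,
                 background = background, photonGain = photonGain,
                 readNoiseSd = readNoiseSd, bitDepth = as.integer(bitDepth)),
            class = "ChannelRenderParams")
}

# Apply the PMT noise model to a clean intensity field (counts).
applyNoise <- function(clean, photonGain, readNoiseSd, bitDepth) {
  if (photonGain <= 0 && readNoiseSd <= 0) return(clean)
  x <- if (photonGain > 0)
    matrix(stats::rpois(length(clean), photonGain * clean) / photonGain,
           nrow(clean))
  else clean
  if (readNoiseSd > 0)
    x <- x + matrix(stats::rnorm(length(x), sd = readNoiseSd), nrow(x))
  pmin(pmax(round(x), 0), 2^bitDepth - 1)
}

#' Render a co-registered TPEF/SHG image pair
#'
#' Both channels share the geometry of \code{pattern}; the TPEF channel is
#' \code{tpefMean * (background + (1 - background) * pattern)} and the SHG
#' channel is that times \code{shgTpefRatio}, so the expected ratio of
#' spatial means equals \code{shgTpefRatio} by construction.
#'
#' @param pattern matrix in [0, 1] from [generateTubuleField()].
#' @param params a [channelRenderParams()] object.
#' @param seed RNG seed for the noise model.
#' @param pixelSizeUm pixel size recorded in the image metadata.
#' @param meta extra metadata stored on both images.
#' @return list with elements \code{tpef} and \code{shg}, both
#'   \linkS4class{MPImage}.
#' @examples
#' f <- generateTubuleField(tubuleFieldParams(5, nPx = 64), seed = 1)
#' pair <- renderChannelPair(f, channelRenderParams(shgTpefRatio = 0.57))
#' mean(intensity(pair$shg)) / mean(intensity(pair$tpef))
#' @export
renderChannelPair <- function(pattern, params = channelRenderParams(),
                              seed = 1L, pixelSizeUm = 180 / nrow(pattern),
                              meta = list()) {
  stopifnot(inherits(params, "ChannelRenderParams"))
  if (min(pattern) < 0 || max(pattern) > 1)
    stop("'pattern' must lie in [0, 1]")
  tpefClean <- params$tpefMean *
    (params$background + (1 - params$background) * pattern)
  shgClean <- params$shgTpefRatio * tpefClean
  withSeed(seed, {
    tpef <- applyNoise(tpefClean, params$photonGain, params$readNoiseSd,
                       params$bitDepth)
    shg <- applyNoise(shgClean, params$photonGain, params$readNoiseSd,
                      params$bitDepth)
    list(
      tpef = MPImage(tpef, channel = "TPEF", pixelSizeUm = pixelSizeUm,
                     meta = meta),
      shg = MPImage(shg, channel = "SHG", pixelSizeUm = pixelSizeUm,
                    meta = meta)
    )
  })
}

#' Polarimetric rendering parameters
#'
#' The forward model of polarization-resolved SHG under cylindrical
#' symmetry: for incident linear polarization at angle \eqn{\alpha} and
#' fibers at \eqn{\theta}, the SHG intensity is
#' \deqn{I(\alpha) = K \, p \, \{\sin^2[2(\alpha-\theta)] +
#'   [\sin^2(\alpha-\theta) + \rho\cos^2(\alpha-\theta)]^2\}}
#' where \eqn{p} is the underlying pattern and \eqn{\rho} the signed
#' hyperpolarizability ratio. Parallel excitation gives \eqn{K p \rho^2},
#' perpendicular gives \eqn{K p}.
#'
#' @param rho signed hyperpolarizability ratio (nonzero for a
#'   sign-resolvable render).
#' @param anglesDeg the three incident polarization angles; must contain
#'   two orthogonal states (default 0, 90, 60).
#' @param scale overall intensity constant K in counts.
#' @param photonGain,readNoiseSd,bitDepth PMT noise model as in
#'   [channelRenderParams()] (defaults noiseless).
#' @return a validated list of class \code{"PolarimetricRenderParams"}.
#' @export
polarimetricRenderParams <- function(rho, anglesDeg = c(0, 90, 60),
                                     scale = 1000, photonGain = 0,
                                     readNoiseSd = 0, bitDepth = 16L) {
  if (!is.finite(rho) || rho == 0)
    stop("'rho' must be finite and nonzero")
  if (length(anglesDeg) != 3L) stop("exactly three polarization angles")
  d <- abs(outer(anglesDeg, anglesDeg, "-")) %% 180
  d <- pmin(d, 180 - d)
  if (!any(abs(d[upper.tri(d)] - 90) < 1e-6))
    stop("'anglesDeg' must contain two mutually orthogonal states")
  if (scale <= 0) stop("'scale' must be positive")
  structure(list(rho = rho, anglesDeg = anglesDeg, scale = scale,
                 photonGain = photonGain, readNoiseSd = readNoiseSd,
                 bitDepth = as.integer(bitDepth)),
            class = "PolarimetricRenderParams")
}

# Cylindrical-symmetry SHG polarization response for a polarization angle
# alpha and fiber orientation theta (both degrees).
shgPolResponse <- function(alphaDeg, thetaDeg, rho) {
  d <- deg2rad(alphaDeg - thetaDeg)
  sin(2 * d)^2 + (sin(d)^2 + rho * cos(d)^2)^2
}

#' Render a three-polarization SHG stack
#'
#' Applies the cylindrical-symmetry polarization response (see
#' [polarimetricRenderParams()]) to a shared pattern at each of the three
#' polarization angles, producing a co-registered
#' \linkS4class{PolarimetricStack}.
#'
#' @param pattern matrix in [0, 1].
#' @param pparams a [polarimetricRenderParams()] object.
#' @param fiberOrientationDeg fiber (stripe) orientation theta in
#'   [0, 180) degrees.
#' @param seed RNG seed for the noise model.
#' @param pixelSizeUm pixel size recorded in metadata.
#' @param meta extra metadata.
#' @return a \linkS4class{PolarimetricStack}.
#' @export
renderPolarimetricStack <- function(pattern, pparams,
                                    fiberOrientationDeg = 0, seed = 1L,
                                    pixelSizeUm = 180 / nrow(pattern),
                                    meta = list()) {
  stopifnot(inherits(pparams, "PolarimetricRenderParams"))
  theta <- fiberOrientationDeg %% 180
  withSeed(seed, {
    imgs <- lapply(pparams$anglesDeg, function(a) {
      clean <- pparams$scale * pattern * shgPolResponse(a, theta,
                                                        pparams$rho)
      img <- applyNoise(clean, pparams$photonGain, pparams$readNoiseSd,
                        pparams$bitDepth)
      MPImage(img, channel = "SHG", pixelSizeUm = pixelSizeUm,
              polarizationDeg = a, meta = meta)
    })
    PolarimetricStack(imgs, anglesDeg = pparams$anglesDeg)
  })
}
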