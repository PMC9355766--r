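# Peritubular morphometry: dominant orientation by Hough voting, width by
# perpendicular cross-section valley spacing, and external organization by
# the structure tensor (structural dispersion, SD).
#
# Angle convention (recorded in all outputs): axial angles in [0, 180)
# degrees, counter-clockwise from the image row axis, origin top-left.

# Smoothed-gradient structure tensor. Returns per-pixel orientation
# (degrees, axial), coherence in [0, 1], tensor energy, and a border
# margin to exclude from statistics (the FFT convolution wraps).
structureTensor <- function(img, pixelSizeUm, gradSigmaUm = 0.5,
                            tensorSigmaUm = 2) {
  if (max(img) - min(img) <= 0)
    stop("constant image: the structure tensor is undefined")
  gradSigmaPx <- max(gradSigmaUm / pixelSizeUm, 0.5)
  tensorSigmaPx <- max(tensorSigmaUm / pixelSizeUm, 1)
  sm <- EBImage::gblur(img / max(img), sigma = gradSigmaPx)
  nr <- nrow(sm); nc <- ncol(sm)
  # central differences; gx along columns (u), gy along rows (v)
  gx <- (sm[, c(2:nc, nc)] - sm[, c(1, 1:(nc - 1))]) / 2
  gy <- (sm[c(2:nr, nr), ] - sm[c(1, 1:(nr - 1)), ]) / 2
  Jxx <- EBImage::gblur(gx * gx, sigma = tensorSigmaPx)
  Jyy <- EBImage::gblur(gy * gy, sigma = tensorSigmaPx)
  Jxy <- EBImage::gblur(gx * gy, sigma = tensorSigmaPx)
  energy <- Jxx + Jyy
  phiDeg <- (rad2deg(0.5 * atan2(2 * Jxy, Jyy - Jxx))) %% 180
  coh <- sqrt((Jyy - Jxx)^2 + 4 * Jxy^2) /
    (energy + .Machine$double.eps)
  list(orientationDeg = phiDeg, coherence = coh, energy = energy,
       margin = ceiling(3 * tensorSigmaPx))
}

# Peakiness of the vote histogram for each candidate projection angle.
# Votes are splatted linearly over the two adjacent 1-px bins (integer
# rounding creates resonance spikes at rational slopes) and the histogram
# is averaged over 3 bins before taking its spread: aliasing combs live at
# the 1-2 bin scale while true stripe bands span ~period*cos(angle) bins,
# so smoothing suppresses only the former.
houghScore <- function(anglesDeg, colPx, rowPx) {
  vapply(anglesDeg, function(a) {
    th <- deg2rad(a)
    t <- colPx * sin(th) + rowPx * cos(th)
    t <- t - floor(min(t))
    i0 <- floor(t)
    fr <- t - i0
    h <- numeric(max(i0) + 2L)
    acc <- rowsum(c(1 - fr, fr), c(i0 + 1L, i0 + 2L))
    h[as.integer(rownames(acc))] <- acc
    h <- stats::filter(h, rep(1 / 3, 3), sides = 2)
    stats::sd(h[!is.na(h)])
  }, numeric(1))
}

#' Dominant tubule orientation by Hough voting
#'
#' Thresholds the image (Otsu by default) and finds the axial angle whose
#' line family best explains the foreground by voting: foreground pixels
#' are projected onto candidate normals and the angle giving the most
#' sharply banded projection (largest spread of the 1-px-bin vote
#' histogram) wins, refined to 0.1 degree. Invariant to intensity scaling.
#'
#' @param shg an SHG \linkS4class{MPImage} (any channel is accepted; the
#'   tubule structure is usually measured on SHG).
#' @param thresholdMethod \code{"otsu"} (parameter-free) or
#'   \code{"median"}.
#' @param coherenceFloor minimum mean structure-tensor coherence for the
#'   image to count as anisotropic; below it a "no dominant orientation"
#'   error is raised.
#' @param maxVotes at most this many foreground pixels vote (evenly
#'   subsampled, deterministic).
#' @return dominant axial orientation in [0, 180) degrees.
#' @examples
#' f <- generateTubuleField(tubuleFieldParams(5, 30, nPx = 128), seed = 1)
#' img <- renderChannelPair(f)$shg
#' estimateOrientationHough(img)
#' @export
estimateOrientationHough <- function(shg,
                                     thresholdMethod = c("otsu", "median"),
                                     coherenceFloor = 0.3,
                                     maxVotes = 20000L) {
  stopifnot(is(shg, "MPImage"))
  thresholdMethod <- match.arg(thresholdMethod)
  img <- shg@intensity
  rng <- max(img) - min(img)
  if (rng <= 0)
    stop("no dominant orientation: image is uniform")
  st <- structureTensor(img, shg@pixelSizeUm)
  m <- st$margin
  inner <- st$coherence[(m + 1):(nrow(img) - m), (m + 1):(ncol(img) - m)]
  meanCoh <- stats::weighted.mean(
    inner, st$energy[(m + 1):(nrow(img) - m), (m + 1):(ncol(img) - m)])
  if (!is.finite(meanCoh) || meanCoh < coherenceFloor)
    stop(sprintf(
      "no dominant orientation: structure-tensor coherence %.3f below floor %.3f",
      meanCoh, coherenceFloor))
  norm <- (img - min(img)) / rng
  thr <- switch(thresholdMethod,
                otsu = EBImage::otsu(EBImage::Image(norm)),
                median = stats::median(norm))
  fg <- which(norm > thr)
  if (length(fg) < 10L)
    stop("no dominant orientation: threshold leaves too few pixels")
  if (length(fg) > maxVotes)
    fg <- fg[seq(1L, length(fg), length.out = maxVotes)]
  rowPx <- (fg - 1L) %% nrow(img) + 1L
  colPx <- (fg - 1L) %/% nrow(img) + 1L
  coarse <- seq(0, 179, by = 1)
  best <- coarse[which.max(houghScore(coarse, colPx, rowPx))]
  fine <- seq(best - 1.5, best + 1.5, by = 0.1) %% 180
  fine[which.max(houghScore(fine, colPx, rowPx))] %% 180
}

#' Peritubular width from perpendicular cross-sections
#'
#' Samples intensity profiles along the normal to the tubule orientation
#' (bilinear interpolation, 1-px steps), median-filters them, detects
#' local minima (the valleys between peritubular ridges) with a prominence
#' requirement and sub-pixel parabolic refinement, and returns the robust
#' center (median) of consecutive-valley spacings in microns -- the
#' peritubule size.
#'
#' @param shg an SHG \linkS4class{MPImage}.
#' @param orientationDeg tubule orientation in degrees (from
#'   [estimateOrientationHough()] or metadata); required.
#' @param nSections number of parallel cross-sections, spread along the
#'   stripe direction over the central 60 percent of the field.
#' @param prominence minimum valley prominence as a fraction of the
#'   profile dynamic range.
#' @param medianK odd window of the median prefilter in px (1 disables).
#' @return list of class \code{"TubuleMetrics"}: \code{widthUm} (median
#'   spacing), \code{widthSdUm}, \code{nValleys}, \code{sectionsUsed},
#'   \code{dominantOrientationDeg}, \code{spacingsUm}.
#' @examples
#' f <- generateTubuleField(tubuleFieldParams(5, 0, nPx = 256), seed = 1)
#' img <- renderChannelPair(f)$shg
#' peritubuleWidth(img, orientationDeg = 0)$widthUm
#' @export
peritubuleWidth <- function(shg, orientationDeg, nSections = 10L,
                            prominence = 0.1, medianK = 3L) {
  stopifnot(is(shg, "MPImage"))
  if (missing(orientationDeg) || is.null(orientationDeg) ||
      !is.finite(orientationDeg))
    stop("'orientationDeg' is required (estimate it with ",
         "estimateOrientationHough or supply it from metadata)")
  img <- shg@intensity
  px <- shg@pixelSizeUm
  nr <- nrow(img); nc <- ncol(img)
  th <- deg2rad(orientationDeg %% 180)
  nvec <- c(cos(th), sin(th))    # (row, col) step along the stripe normal
  tvec <- c(-sin(th), cos(th))   # along the stripes
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  half <- 0.3 * min(nr, nc)
  offsets <- if (nSections == 1L) 0 else
    seq(-half, half, length.out = nSections)
  reach <- ceiling(sqrt(nr^2 + nc^2) / 2)
  ms <- seq(-reach, reach)
  spacings <- numeric(0)
  nValleys <- 0L
  used <- 0L
  for (o in offsets) {
    p0 <- ctr + o * tvec
    rows <- p0[1] + ms * nvec[1]
    cols <- p0[2] + ms * nvec[2]
    y <- bilinear(img, rows, cols)
    keep <- !is.na(y)
    if (sum(keep) < 8L) next
    yRaw <- y[keep]
    y <- if (medianK > 1L) stats::runmed(yRaw, medianK) else yRaw
    dr <- max(y) - min(y)
    if (dr <= 0) next
    pos <- findValleys(y, prominence * dr, yRaw)
    if (length(pos) >= 2L) {
      spacings <- c(spacings, diff(pos) * px)
      nValleys <- nValleys + length(pos)
      used <- used + 1L
    }
  }
  if (!length(spacings))
    stop("fewer than 2 valleys detected on every cross-section; ",
         "cannot measure the peritubule width")
  structure(list(
    widthUm = stats::median(spacings),
    widthSdUm = if (length(spacings) > 1) stats::sd(spacings) else 0,
    nValleys = nValleys, sectionsUsed = used,
    dominantOrientationDeg = orientationDeg %% 180,
    spacingsUm = spacings), class = "TubuleMetrics")
}

#' Classify external organization from structural dispersion
#'
#' Quasi-aligned fibers give SD at or below 20 degrees (organized); a
#' non-organized distribution gives SD above 40 degrees; values in between
#' are partially organized.
#'
#' @param sdDeg structural dispersion in degrees.
#' @return \code{"organized"}, \code{"partial"} or \code{"disorganized"}.
#' @export
classifyOrganization <- function(sdDeg) {
  if (!is.finite(sdDeg) || sdDeg < 0) stop("'sdDeg' must be >= 0")
  if (sdDeg <= 20) "organized" else if (sdDeg > 40) "disorganized"
  else "partial"
}

#' Structural dispersion from the structure tensor
#'
#' Computes the per-pixel fiber orientation from the Gaussian-smoothed
#' gradient outer-product tensor, then the coherence-weighted axial
#' circular standard deviation of those orientations (structural
#' dispersion, SD, degrees) and the weighted axial circular mean
#' (preferred orientation). A border margin of three tensor sigmas is
#' excluded from the statistics.
#'
#' @param shg an SHG \linkS4class{MPImage}.
#' @param gradSigmaUm Gaussian sigma (microns) for pre-gradient smoothing.
#' @param tensorSigmaUm Gaussian sigma (microns) for tensor smoothing.
#' @param energyFloor pixels with tensor energy at or below this fraction
#'   of the maximum are excluded.
#' @return list of class \code{"OrganizationMetrics"}: \code{sdDeg},
#'   \code{preferredOrientationDeg}, \code{orgClass}, \code{meanCoherence}.
#' @examples
#' f <- generateTubuleField(tubuleFieldParams(5, 30, nPx = 128), seed = 1)
#' img <- renderChannelPair(f)$shg
#' structureTensorSD(img)$sdDeg
#' @export
structureTensorSD <- function(shg, gradSigmaUm = 0.5, tensorSigmaUm = 2,
                              energyFloor = 1e-3) {
  stopifnot(is(shg, "MPImage"))
  st <- structureTensor(shg@intensity, shg@pixelSizeUm, gradSigmaUm,
                        tensorSigmaUm)
  nr <- nrow(shg@intensity); nc <- ncol(shg@intensity)
  m <- min(st$margin, floor(min(nr, nc) / 4))
  idx <- matrix(FALSE, nr, nc)
  idx[(m + 1):(nr - m), (m + 1):(nc - m)] <- TRUE
  idx <- idx & st$energy > energyFloor * max(st$energy)
  if (!any(idx))
    stop("no pixels above the energy floor; structural dispersion undefined")
  stats <- axialStats(st$orientationDeg[idx], st$coherence[idx])
  structure(list(
    sdDeg = stats$sd,
    preferredOrientationDeg = stats$mean,
    orgClass = classifyOrganization(stats$sd),
    meanCoherence = mean(st$coherence[idx])), class = "OrganizationMetrics")
}
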