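#' Parameters of a synthetic peritubular stripe field
#'
#' Describes the geometry of a field of parallel elongated peritubular
#' ridges: the peak-to-peak stripe period ("peritubule size"), the axial
#' orientation of the stripes, the amount of smooth local orientation
#' jitter, the ridge/valley contrast and the duty cycle (fraction of each
#' period occupied by the bright ridge, at half maximum).
#'
#' @param periodUm stripe period in microns (peak-to-peak = valley-to-valley).
#' @param orientationDeg axial stripe orientation in [0, 180), degrees
#'   counter-clockwise from the image row axis.
#' @param jitterDeg standard deviation of the smooth local orientation
#'   perturbation, in degrees (0 = perfectly parallel).
#' @param ridgeContrast fraction in (0, 1]: valley floor sits at
#'   \code{1 - ridgeContrast}, ridge peaks at 1.
#' @param fieldUm field width in microns (square field).
#' @param nPx pixels per side.
#' @param duty fraction of the period occupied by the ridge (FWHM), in
#'   (0, 1).
#' @param jitterScaleUm correlation length of the orientation jitter field
#'   in microns.
#' @return a validated list of class \code{"TubuleFieldParams"}.
#' @examples
#' p <- tubuleFieldParams(periodUm = 5, orientationDeg = 30)
#' @export
tubuleFieldParams <- function(periodUm, orientationDeg = 0, jitterDeg = 0,
                              ridgeContrast = 0.9, fieldUm = 180,
                              nPx = 512L, duty = 0.5,
                              jitterScaleUm = 10) {
  px <- fieldUm / nPx
  if (!is.finite(periodUm) || periodUm <= 2 * px)
    stop(sprintf(
      "stripe period %.3g um is at or below the Nyquist limit 2 px = %.3g um (field %g um / %d px)",
      periodUm, 2 * px, fieldUm, nPx))
  if (jitterDeg < 0) stop("'jitterDeg' must be >= 0")
  if (ridgeContrast <= 0 || ridgeContrast > 1)
    stop("'ridgeContrast' must be in (0, 1]")
  if (duty <= 0 || duty >= 1) stop("'duty' must be in (0, 1)")
  structure(list(periodUm = periodUm,
                 orientationDeg = orientationDeg %% 180,
                 jitterDeg = jitterDeg, ridgeContrast = ridgeContrast,
                 fieldUm = fieldUm, nPx = as.integer(nPx), duty = duty,
                 jitterScaleUm = jitterScaleUm),
            class = "TubuleFieldParams")
}

# Ridge profile on the unit phase: raised cosine raised to the power that
# sets the ridge full width at half maximum to `duty` periods. Valleys are
# unique smooth minima at integer phase.
ridgeProfile <- function(phase, duty) {
  p <- log(0.5) / log((1 + cos(pi * duty)) / 2)
  ((1 - cos(2 * pi * phase)) / 2)^p
}

#' Generate a synthetic peritubular stripe field
#'
#' Renders a unit-amplitude pattern in [0, 1] of parallel raised-cosine
#' ridges with the requested period, orientation and smooth orientation
#' jitter. This is the geometric layer all synthetic channels share; the
#' dominant spatial period along the normal to the stripe orientation
#' equals \code{periodUm}, and valleys (the local minima the width
#' estimator measures) are spaced exactly one period apart.
#'
#' Orientation jitter is applied by warping the stripe phase with a smooth
#' Gaussian random field whose along-stripe slope has standard deviation
#' \code{tan(jitterDeg)}, so the local stripe orientation deviates from the
#' nominal axis with sd close to \code{jitterDeg}.
#'
#' @param params a [tubuleFieldParams()] object.
#' @param seed RNG seed (only consumed when \code{jitterDeg > 0});
#'   identical params + seed give a bit-identical field.
#' @return numeric \code{nPx x nPx} matrix in [0, 1].
#' @examples
#' f <- generateTubuleField(tubuleFieldParams(5, 0, nPx = 128), seed = 1)
#' range(f)
#' @export
generateTubuleField <- function(params, seed = 1L) {
  stopifnot(inherits(params, "TubuleFieldParams"))
  n <- params$nPx
  px <- params$fieldUm / n
  # pixel-centre coordinates in microns: u along columns, v along rows
  u <- ((seq_len(n)) - 0.5) * px
  v <- ((seq_len(n)) - 0.5) * px
  th <- deg2rad(params$orientationDeg)
  # coordinate along the stripe normal; theta = 0 gives horizontal stripes
  s <- outer(v * cos(th), u * sin(th), "+")
  if (params$jitterDeg > 0) {
    d <- withSeed(seed, {
      w <- smoothNoiseField(n, n, sigmaPx = params$jitterScaleUm / px)
      gx <- (cbind(w[, -1], w[, ncol(w)]) - cbind(w[, 1], w[, -ncol(w)])) /
        (2 * px)
      sdDir <- stats::sd(as.vector(gx))  # isotropic field
      w * (tan(deg2rad(params$jitterDeg)) / sdDir)
    })
    s <- s + d
  }
  phase <- (s / params$periodUm) %% 1
  (1 - params$ridgeContrast) +
    params$ridgeContrast * ridgeProfile(phase, params$duty)
}

#' Generate a disorganized patchwork of stripe fields
#'
#' Tiles the field into an \code{nTiles x nTiles} grid and fills each tile
#' with a stripe pattern at an independent uniformly random orientation in
#' [0, 180). Used to emulate a non-organized fiber arrangement (structural
#' dispersion above the disorganized threshold).
#'
#' @param params a [tubuleFieldParams()] object; its \code{orientationDeg}
#'   is ignored.
#' @param nTiles tiles per side (default 8).
#' @param seed RNG seed.
#' @return numeric \code{nPx x nPx} matrix in [0, 1].
#' @export
generatePatchworkField <- function(params, nTiles = 8L, seed = 1L) {
  stopifnot(inherits(params, "TubuleFieldParams"))
  n <- params$nPx
  edges <- floor(seq(0, n, length.out = nTiles + 1))
  withSeed(seed, {
    out <- matrix(0, n, n)
    for (i in seq_len(nTiles)) for (j in seq_len(nTiles)) {
      ori <- stats::runif(1, 0, 180)
      rows <- (edges[i] + 1):edges[i + 1]
      cols <- (edges[j] + 1):edges[j + 1]
      sub <- params
      sub$orientationDeg <- ori
      sub$nPx <- n  # keep global coordinates so pixel size is unchanged
      px <- params$fieldUm / n
      u <- (cols - 0.5) * px
      v <- (rows - 0.5) * px
      th <- deg2rad(ori)
      s <- outer(v * cos(th), u * sin(th), "+")
      phase <- (s / params$periodUm) %% 1
      out[rows, cols] <- (1 - params$ridgeContrast) +
        params$ridgeContrast * ridgeProfile(phase, params$duty)
    }
    out
  })
}
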