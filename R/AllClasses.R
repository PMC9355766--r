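#' @import methods
NULL

#' MPImage: one multiphoton intensity field
#'
#' A single 2-D grayscale intensity image from one multiphoton channel
#' (TPEF or SHG), with the acquisition metadata needed downstream: the
#' channel tag, the incident linear polarization angle (SHG polarimetry
#' only, \code{NA} otherwise) and the pixel size in microns.
#'
#' Intensities are non-negative and in arbitrary detector units (counts).
#' Orientation convention throughout the package: angles are axial
#' (180-degree periodic), measured counter-clockwise from the image row
#' axis, origin at the top-left pixel.
#'
#' @slot intensity numeric matrix of non-negative intensities.
#' @slot channel \code{"TPEF"} or \code{"SHG"}.
#' @slot polarizationDeg incident linear polarization angle in degrees, or
#'   \code{NA_real_} for non-polarimetric acquisitions.
#' @slot pixelSizeUm pixel size in microns (square pixels).
#' @slot meta named list of free-form metadata (specimen id, age, seed...).
#'
#' @seealso [MPImage()] for the constructor, [intensity()], [channel()],
#'   [pixelSize()] for accessors.
#' @export
setClass("MPImage",
  representation(
    intensity = "matrix",
    channel = "character",
    polarizationDeg = "numeric",
    pixelSizeUm = "numeric",
    meta = "list"
  ),
  prototype(
    channel = "SHG",
    polarizationDeg = NA_real_,
    pixelSizeUm = 1,
    meta = list()
  )
)

setValidity("MPImage", function(object) {
  msg <- NULL
  if (!is.numeric(object@intensity))
    msg <- c(msg, "'intensity' must be a numeric matrix")
  else {
    if (any(!is.finite(object@intensity)))
      msg <- c(msg, "'intensity' contains non-finite values")
    else if (any(object@intensity < 0))
      msg <- c(msg, "'intensity' contains negative values")
  }
  if (length(object@channel) != 1L ||
      !object@channel %in% c("TPEF", "SHG"))
    msg <- c(msg, "'channel' must be \"TPEF\" or \"SHG\"")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (length(object@polarizationDeg) != 1L)
    msg <- c(msg, "'polarizationDeg' must be length 1")
  if (is.null(msg)) TRUE else msg
})

#' PolarimetricStack: three co-registered polarization-resolved SHG images
#'
#' Holds the three SHG acquisitions of the same field at three incident
#' linear polarization states (default 0, 90 and 60 degrees) required to
#' invert the signed hyperpolarizability ratio rho: the two mutually
#' orthogonal states give the magnitude and the third gives the sign.
#'
#' @slot images list of three \linkS4class{MPImage} objects, all SHG, same
#'   dimensions and pixel size.
#' @slot anglesDeg the three polarization angles in degrees; must contain
#'   two states 90 degrees apart (mod 180).
#'
#' @seealso [PolarimetricStack()], [rhoMap()]
#' @export
setClass("PolarimetricStack",
  representation(images = "list", anglesDeg = "numeric")
)

setValidity("PolarimetricStack", function(object) {
  msg <- NULL
  if (length(object@images) != 3L)
    msg <- c(msg, "a stack holds exactly 3 images")
  else {
    if (!all(vapply(object@images, is, logical(1), class2 = "MPImage")))
      msg <- c(msg, "all elements of 'images' must be MPImage objects")
    else {
      dims <- vapply(object@images, function(x) dim(x@intensity),
                     integer(2))
      if (any(dims != dims[, 1]))
        msg <- c(msg, "images are not co-registered (dimension mismatch)")
      if (!all(vapply(object@images, function(x) x@channel, character(1))
               == "SHG"))
        msg <- c(msg, "all images in a stack must be SHG channel")
    }
  }
  if (length(object@anglesDeg) != 3L ||
      any(!is.finite(object@anglesDeg)))
    msg <- c(msg, "'anglesDeg' must be 3 finite angles")
  else {
    d <- abs(outer(object@anglesDeg, object@anglesDeg, "-")) %% 180
    d <- pmin(d, 180 - d)
    if (!any(abs(d[upper.tri(d)] - 90) < 1e-6))
      msg <- c(msg, "stack must contain two mutually orthogonal states")
  }
  if (is.null(msg)) TRUE else msg
})

#' SpecimenRecord: one tooth and its imaged regions
#'
#' Age, sex and the imaged dentinal regions of one specimen. Each region is
#' a list with elements \code{tpef}, \code{shg} (an \linkS4class{MPImage}
#' pair) and optionally \code{stack} (a \linkS4class{PolarimetricStack}).
#'
#' @slot specimenId character id.
#' @slot ageYears age in years.
#' @slot sex \code{"M"}, \code{"F"} or \code{NA}.
#' @slot regions list of imaged regions.
#' @slot truth named list of ground-truth values for synthetic specimens
#'   (empty for real data).
#' @export
setClass("SpecimenRecord",
  representation(
    specimenId = "character",
    ageYears = "numeric",
    sex = "character",
    regions = "list",
    truth = "list"
  ),
  prototype(sex = NA_character_, regions = list(), truth = list())
)

setValidity("SpecimenRecord", function(object) {
  msg <- NULL
  if (length(object@ageYears) != 1L || !is.finite(object@ageYears) ||
      object@ageYears <= 0)
    msg <- c(msg, "'ageYears' must be a single positive number")
  if (!object@sex %in% c("M", "F", NA_character_))
    msg <- c(msg, "'sex' must be \"M\", \"F\" or NA")
  if (is.null(msg)) TRUE else msg
})

#' INAGMap: spatially resolved INAG contrast
#'
#' Per-pixel normalized SHG/TPEF contrast (S - T)/(S + T), bounded in
#' [-1, 1], with a validity mask excluding pixels where both channels sit
#' at or below the background floor.
#'
#' @slot values numeric matrix in [-1, 1] (NA where masked).
#' @slot mask logical matrix, TRUE where valid.
#' @slot summaryMean mean of the map over unmasked pixels.
#' @slot summarySd sd of the map over unmasked pixels.
#' @slot pixelSizeUm pixel size in microns.
#' @seealso [inagMap()]
#' @export
setClass("INAGMap",
  representation(values = "matrix", mask = "matrix",
                 summaryMean = "numeric", summarySd = "numeric",
                 pixelSizeUm = "numeric")
)

setValidity("INAGMap", function(object) {
  msg <- NULL
  v <- object@values[object@mask]
  if (length(v) && (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9))
    msg <- c(msg, "unmasked INAG values must lie in [-1, 1]")
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "'values' and 'mask' dimensions differ")
  if (is.null(msg)) TRUE else msg
})

#' RhoMap: signed hyperpolarizability-ratio field
#'
#' Pixelwise signed rho inverted from a three-polarization SHG stack:
#' magnitude from the parallel/perpendicular intensity ratio, sign from
#' the discrepancy vote on the oblique state.
#'
#' @slot values numeric matrix of signed rho (NA where masked).
#' @slot mask logical matrix, TRUE where valid.
#' @slot summaryMean mean signed rho over unmasked pixels.
#' @slot summarySd sd over unmasked pixels.
#' @slot fiberOrientationDeg the fiber orientation theta (degrees) used in
#'   the inversion.
#' @seealso [rhoMap()]
#' @export
setClass("RhoMap",
  representation(values = "matrix", mask = "matrix",
                 summaryMean = "numeric", summarySd = "numeric",
                 fiberOrientationDeg = "numeric")
)

#' AgeRegression: one metric-versus-age linear fit
#'
#' Ordinary least squares fit of a per-specimen metric on age, with the
#' Pearson correlation and its two-sided t-test p-value.
#'
#' @slot metricName label of the regressed metric.
#' @slot slope slope in metric units per year.
#' @slot intercept intercept in metric units.
#' @slot pearsonR Pearson correlation coefficient.
#' @slot pValue two-sided p-value of the correlation t-test.
#' @slot n number of specimens.
#' @slot residualSd residual standard deviation of the fit.
#' @seealso [fitAgeRegression()]
#' @export
setClass("AgeRegression",
  representation(
    metricName = "character", slope = "numeric", intercept = "numeric",
    pearsonR = "numeric", pValue = "numeric", n = "integer",
    residualSd = "numeric"
  )
)

setValidity("AgeRegression", function(object) {
  msg <- NULL
  if (is.finite(object@pearsonR) && abs(object@pearsonR) > 1 + 1e-12)
    msg <- c(msg, "|pearsonR| must be <= 1")
  if (is.finite(object@slope) && is.finite(object@pearsonR) &&
      object@slope != 0 && sign(object@slope) != sign(object@pearsonR))
    msg <- c(msg, "sign(slope) must equal sign(pearsonR)")
  if (is.null(msg)) TRUE else msg
})
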