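#' Construct an MPImage
#'
#' @param intensity numeric matrix of non-negative intensities (detector
#'   counts).
#' @param channel \code{"TPEF"} or \code{"SHG"}.
#' @param pixelSizeUm pixel size in microns.
#' @param polarizationDeg incident linear polarization angle in degrees
#'   (SHG polarimetry), \code{NA} otherwise.
#' @param meta named list of metadata.
#' @return an \linkS4class{MPImage}.
#' @examples
#' img <- MPImage(matrix(runif(64), 8), channel = "SHG",
#'                pixelSizeUm = 0.3516)
#' channel(img)
#' @export
MPImage <- function(intensity, channel = c("SHG", "TPEF"),
                    pixelSizeUm = 1, polarizationDeg = NA_real_,
                    meta = list()) {
  channel <- match.arg(channel)
  new("MPImage", intensity = intensity, channel = channel,
      pixelSizeUm = as.numeric(pixelSizeUm),
      polarizationDeg = as.numeric(polarizationDeg), meta = meta)
}

#' Construct a PolarimetricStack
#'
#' @param images list of three SHG \linkS4class{MPImage} objects.
#' @param anglesDeg polarization angles; taken from the images'
#'   \code{polarizationDeg} when omitted.
#' @return a \linkS4class{PolarimetricStack}.
#' @export
PolarimetricStack <- function(images, anglesDeg = NULL) {
  if (is.null(anglesDeg))
    anglesDeg <- vapply(images, function(x) x@polarizationDeg, numeric(1))
  new("PolarimetricStack", images = images,
      anglesDeg = as.numeric(anglesDeg))
}

#' Construct a SpecimenRecord
#'
#' @param specimenId character id.
#' @param ageYears age in years.
#' @param sex \code{"M"}, \code{"F"} or \code{NA}.
#' @param regions list of regions (each a list with \code{tpef},
#'   \code{shg}, optional \code{stack}).
#' @param truth named list of synthetic ground-truth values.
#' @return a \linkS4class{SpecimenRecord}.
#' @export
SpecimenRecord <- function(specimenId, ageYears, sex = NA_character_,
                           regions = list(), truth = list()) {
  new("SpecimenRecord", specimenId = as.character(specimenId),
      ageYears = as.numeric(ageYears), sex = as.character(sex),
      regions = regions, truth = truth)
}

#' @rdname MPImage-class
#' @export
setMethod("intensity", "MPImage", function(object) object@intensity)

#' @rdname MPImage-class
#' @export
setMethod("channel", "MPImage", function(object) object@channel)

#' @rdname MPImage-class
#' @export
setMethod("pixelSize", "MPImage", function(object) object@pixelSizeUm)

#' @rdname MPImage-class
#' @export
setMethod("polarizationAngle", "MPImage",
          function(object) object@polarizationDeg)

#' @rdname MPImage-class
#' @export
setMethod("dim", "MPImage", function(x) dim(x@intensity))

#' @rdname PolarimetricStack-class
#' @export
setMethod("polarizationAngles", "PolarimetricStack",
          function(object) object@anglesDeg)

#' @rdname SpecimenRecord-class
#' @export
setMethod("specimenAge", "SpecimenRecord", function(object) object@ageYears)

#' @rdname SpecimenRecord-class
#' @export
setMethod("regions", "SpecimenRecord", function(object) object@regions)

setMethod("show", "MPImage", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("MPImage [%s] %d x %d px, %.4g um/px", object@channel,
              d[1], d[2], object@pixelSizeUm))
  if (!is.na(object@polarizationDeg))
    cat(sprintf(", polarization %g deg", object@polarizationDeg))
  cat(sprintf("\n  intensity range [%.4g, %.4g]\n",
              min(object@intensity), max(object@intensity)))
})

setMethod("show", "PolarimetricStack", function(object) {
  d <- dim(object@images[[1]]@intensity)
  cat(sprintf("PolarimetricStack: 3 SHG images %d x %d px at %s deg\n",
              d[1], d[2], paste(object@anglesDeg, collapse = "/")))
})

setMethod("show", "SpecimenRecord", function(object) {
  cat(sprintf("SpecimenRecord %s: age %g, sex %s, %d region(s)\n",
              object@specimenId, object@ageYears, object@sex,
              length(object@regions)))
})

setMethod("show", "INAGMap", function(object) {
  cat(sprintf(
    "INAGMap %d x %d px: mean %.4f, sd %.4f (%.1f%% pixels masked)\n",
    nrow(object@values), ncol(object@values), object@summaryMean,
    object@summarySd, 100 * mean(!object@mask)))
})

setMethod("show", "RhoMap", function(object) {
  cat(sprintf(
    "RhoMap %d x %d px: mean %.4f, sd %.4f, theta %.1f deg (%.1f%% masked)\n",
    nrow(object@values), ncol(object@values), object@summaryMean,
    object@summarySd, object@fiberOrientationDeg,
    100 * mean(!object@mask)))
})

setMethod("show", "AgeRegression", function(object) {
  cat(sprintf(
    "AgeRegression [%s]: %s = %.4g * age + %.4g  (R = %.3f, p = %.3g, n = %d)\n",
    object@metricName, object@metricName, object@slope, object@intercept,
    object@pearsonR, object@pValue, object@n))
})
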