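#' @rdname MPImage-class
#' @param object an object.
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname MPImage-class
#' @export
setGeneric("channel", function(object) standardGeneric("channel"))

#' @rdname MPImage-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname MPImage-class
#' @export
setGeneric("polarizationAngle",
           function(object) standardGeneric("polarizationAngle"))

#' @rdname PolarimetricStack-class
#' @param object an object.
#' @export
setGeneric("polarizationAngles",
           function(object) standardGeneric("polarizationAngles"))

#' @rdname SpecimenRecord-class
#' @param object an object.
#' @export
setGeneric("specimenAge", function(object) standardGeneric("specimenAge"))

#' @rdname SpecimenRecord-class
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))
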