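#' Pixel scale accessor
#'
#' Returns the spatial calibration of an image-like object in pixels per
#' micrometre.
#'
#' @param x a frame, mask or result object carrying calibration metadata.
#' @return numeric scalar, pixels per micrometre.
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))

#' Total stack height of an insert
#'
#' Sum of the three section heights (top plus-sign section, middle cylinder,
#' bottom foot) in millimetres.
#'
#' @param geom an [InsertGeometry-class] object.
#' @return numeric scalar, millimetres.
#' @export
setGeneric("totalHeight", function(geom) standardGeneric("totalHeight"))

#' @rdname frameData
#' @export
setGeneric("frameData", function(x) standardGeneric("frameData"))

#' @rdname maskData
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname AreaResult-class
#' @export
setGeneric("areaUm2", function(x) standardGeneric("areaUm2"))

#' @rdname AreaResult-class
#' @export
setGeneric("areaMm2", function(x) standardGeneric("areaMm2"))

#' @rdname AreaResult-class
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname AreaResult-class
#' @export
setGeneric("componentMask", function(x) standardGeneric("componentMask"))

#' @rdname AreaResult-class
#' @export
setGeneric("resultFlags", function(x) standardGeneric("resultFlags"))
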