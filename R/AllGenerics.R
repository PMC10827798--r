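#' Accessors for ChoroidStrat classes
#'
#' Small accessor generics: \code{pixels} returns the gray-level matrix,
#' \code{lateralScale}/\code{axialScale} the physical pixel pitch in um,
#' \code{bitDepth} the acquisition depth, \code{maskLabels} the 0/1/2
#' outside/stroma/lumen label matrix, \code{thresholdRecord} the binarization
#' parameter record, and \code{boundaryRows} the four boundary curves of a
#' \code{LayerBoundaries} as a data.frame.
#'
#' @param object an object of the documented classes.
#' @return See details above.
#' @name accessors
#' @aliases pixels lateralScale axialScale bitDepth maskLabels
#'   thresholdRecord boundaryRows
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("lateralScale", function(object) standardGeneric("lateralScale"))
#' @rdname accessors
#' @export
setGeneric("axialScale", function(object) standardGeneric("axialScale"))
#' @rdname accessors
#' @export
setGeneric("bitDepth", function(object) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setGeneric("maskLabels", function(object) standardGeneric("maskLabels"))
#' @rdname accessors
#' @export
setGeneric("thresholdRecord", function(object) standardGeneric("thresholdRecord"))
#' @rdname accessors
#' @export
setGeneric("boundaryRows", function(object) standardGeneric("boundaryRows"))

#' @rdname accessors
setMethod("pixels", "BScan", function(object) object@pixels)
#' @rdname accessors
setMethod("pixels", "ChoroidWindow", function(object) object@pixels)
#' @rdname accessors
setMethod("lateralScale", "BScan", function(object) object@lateralScale)
#' @rdname accessors
setMethod("lateralScale", "ChoroidWindow", function(object) object@lateralScale)
#' @rdname accessors
setMethod("axialScale", "BScan", function(object) object@axialScale)
#' @rdname accessors
setMethod("axialScale", "ChoroidWindow", function(object) object@axialScale)
#' @rdname accessors
setMethod("bitDepth", "BScan", function(object) object@bitDepth)
#' @rdname accessors
setMethod("maskLabels", "ChoroidMask", function(object) object@labels)
#' @rdname accessors
setMethod("thresholdRecord", "ChoroidMask", function(object) object@thresholdRecord)
#' @rdname accessors
setMethod("boundaryRows", "LayerBoundaries", function(object) {
  data.frame(column_index = object@cols, rpe_row = object@rpeLower,
             ccsl_row = object@ccSl, slhl_row = object@slHl,
             csi_row = object@csi)
})
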