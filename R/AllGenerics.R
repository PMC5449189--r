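#' @include AllClasses.R
NULL

#' Accessors for dualTat result objects
#'
#' Small accessor family shared by the S4 result classes: protein identity,
#' transmembrane segments, orientation and scores, screen verdicts and
#' feature flags. Accessors are the supported interface; slots are internal.
#'
#' @param x a dualTat S4 object.
#' @return the corresponding component; see the class documentation.
#' @name accessors
#' @aliases proteinId tmSegments orientation nInScore topologySource
#'   classification rrPosition finalTmd reportFlags dgApp rejectionReason
#' @examples
#' scale <- defaultScale("uniform")
#' seg <- segmentDG(paste(rep("L", 21), collapse = ""), 1, 21, scale,
#'                  lengthCorrection = FALSE)
#' dgApp(seg)
NULL

#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname accessors
#' @export
setGeneric("tmSegments", function(x) standardGeneric("tmSegments"))

#' @rdname accessors
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @rdname accessors
#' @export
setGeneric("nInScore", function(x) standardGeneric("nInScore"))

#' @rdname accessors
#' @export
setGeneric("topologySource", function(x) standardGeneric("topologySource"))

#' @rdname accessors
#' @export
setGeneric("classification", function(x) standardGeneric("classification"))

#' @rdname accessors
#' @export
setGeneric("rrPosition", function(x) standardGeneric("rrPosition"))

#' @rdname accessors
#' @export
setGeneric("finalTmd", function(x) standardGeneric("finalTmd"))

#' @rdname accessors
#' @export
setGeneric("reportFlags", function(x) standardGeneric("reportFlags"))

#' @rdname accessors
#' @export
setGeneric("rejectionReason", function(x) standardGeneric("rejectionReason"))

#' @rdname accessors
#' @export
dgApp <- function(x) {
    if (is(x, "DualCandidate")) x <- x@finalTmd
    stopifnot(is(x, "IRanges"))
    mcols(x)$dg_app
}
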