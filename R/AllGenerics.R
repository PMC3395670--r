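#' @rdname CytoFrame-accessors
#' @export
setGeneric("intensities", function(object, ...) standardGeneric("intensities"))

#' @rdname CytoFrame-accessors
#' @export
setGeneric("channelData", function(object) standardGeneric("channelData"))

#' @rdname CytoFrame-accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname CytoFrame-accessors
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))

#' @rdname CytoFrame-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname CytoFrame-accessors
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' Evaluate a gate expression on an event table
#'
#' @param table a \linkS4class{CytoFrame}.
#' @param expr a \linkS4class{Region} or \linkS4class{GateExpr}.
#' @return logical vector, one entry per event.
#' @export
setGeneric("evaluateGate", function(table, expr) standardGeneric("evaluateGate"))

#' Assign events to the steps of a region chain
#'
#' @param table a \linkS4class{CytoFrame} holding the chain's gated
#'   population.
#' @param chain a \linkS4class{RegionChain}.
#' @return integer vector, one entry per event: the step index, or NA when
#'   the event falls outside every step.
#' @export
setGeneric("assignChain", function(table, chain) standardGeneric("assignChain"))

#' Evaluate a piecewise-linear expression profile
#'
#' Uses the two-point line form
#' y = ((y2 - y1) / (x2 - x1)) * x + y1 - ((y2 - y1) / (x2 - x1)) * x1
#' on the knot interval containing each query point.
#'
#' @param profile an \linkS4class{ExpressionProfile}.
#' @param x numeric query positions within the profile's x range.
#' @return numeric vector of interpolated expression values.
#' @export
setGeneric("evaluateProfile", function(profile, x) standardGeneric("evaluateProfile"))

#' Apply a same-scale affine map to an expression profile
#'
#' @param profile an \linkS4class{ExpressionProfile}.
#' @param map a \linkS4class{ScalingMap}.
#' @return the rescaled profile, scale tag set to "samescale".
#' @export
setGeneric("applyScaling", function(profile, map) standardGeneric("applyScaling"))
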