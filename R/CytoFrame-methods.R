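#' Construct a CytoFrame event table
#'
#' @param intensities numeric matrix or data.frame, one row per event, one
#'   column per channel; column names become channel names.
#' @param roles named character vector of channel roles; channels not named
#'   default to "epitope", except names starting with \code{truth_} which
#'   default to "truth".
#' @param units optional named character vector of unit tags (default
#'   "a.u.").
#' @param provenance optional starting provenance log.
#' @return a \linkS4class{CytoFrame}.
#' @examples
#' m <- cbind(dna = c(100, 200), cycA = c(1, 5))
#' cf <- CytoFrame(m, roles = c(dna = "dna_integral"))
#' channelRoles(cf)
#' @export
CytoFrame <- function(intensities, roles = character(), units = character(),
                      provenance = list()) {
  m <- as.matrix(intensities)
  storage.mode(m) <- "double"
  if (is.null(colnames(m)))
    stop("intensity columns must be named")
  nm <- colnames(m)
  role <- ifelse(startsWith(nm, "truth_"), "truth", "epitope")
  names(role) <- nm
  role[names(roles)] <- roles
  un <- rep("a.u.", length(nm)); names(un) <- nm
  un[names(units)] <- units
  cd <- S4Vectors::DataFrame(name = nm, role = unname(role[nm]),
                             units = unname(un[nm]))
  methods::new("CytoFrame", intensities = m, channelData = cd,
               provenance = provenance)
}

#' Accessors for CytoFrame
#'
#' \code{intensities} returns the event-by-channel matrix (optionally a
#' subset of channels); \code{channelData} the channel metadata;
#' \code{channelNames} and \code{channelRoles} the obvious vectors;
#' \code{provenance} the ordered transform log; \code{nEvents} the row
#' count; \code{channelByRole} the names of channels carrying a given role.
#'
#' @param object a \linkS4class{CytoFrame}.
#' @param channels optional character vector of channel names to extract.
#' @param ... unused.
#' @name CytoFrame-accessors
#' @aliases intensities channelData channelNames channelRoles provenance
#'   nEvents
NULL

#' @rdname CytoFrame-accessors
#' @export
setMethod("intensities", "CytoFrame", function(object, channels = NULL, ...) {
  if (is.null(channels)) return(object@intensities)
  missing <- setdiff(channels, colnames(object@intensities))
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  object@intensities[, channels, drop = FALSE]
})

#' @rdname CytoFrame-accessors
#' @export
setMethod("channelData", "CytoFrame", function(object) object@channelData)

#' @rdname CytoFrame-accessors
#' @export
setMethod("channelNames", "CytoFrame",
          function(object) as.character(object@channelData$name))

#' @rdname CytoFrame-accessors
#' @export
setMethod("channelRoles", "CytoFrame", function(object) {
  stats::setNames(as.character(object@channelData$role),
                  as.character(object@channelData$name))
})

#' @rdname CytoFrame-accessors
#' @export
setMethod("provenance", "CytoFrame", function(object) object@provenance)

#' @rdname CytoFrame-accessors
#' @export
setMethod("nEvents", "CytoFrame", function(object) nrow(object@intensities))

#' @rdname CytoFrame-accessors
#' @param role a channel role string.
#' @export
channelByRole <- function(object, role) {
  cr <- channelRoles(object)
  names(cr)[cr == role]
}

## Internal: return a copy with one provenance record appended.
.log_step <- function(object, fmt, ...) {
  object@provenance <- c(object@provenance, sprintf(fmt, ...))
  object
}

## Internal: replace the intensity matrix, keeping metadata.
.set_intensities <- function(object, m) {
  colnames(m) <- channelNames(object)
  object@intensities <- m
  methods::validObject(object)
  object
}

## Internal: row-subset preserving metadata and provenance.
.subset_events <- function(object, keep) {
  object@intensities <- object@intensities[keep, , drop = FALSE]
  object
}

#' Subset events of a CytoFrame
#'
#' @param x a \linkS4class{CytoFrame}.
#' @param i event (row) index or logical mask.
#' @param j channel names or indices.
#' @param ... unused.
#' @param drop ignored.
#' @export
setMethod("[", "CytoFrame", function(x, i, j, ..., drop = FALSE) {
  if (!missing(j)) {
    x@intensities <- x@intensities[, j, drop = FALSE]
    x@channelData <- x@channelData[match(colnames(x@intensities),
                                         x@channelData$name), , drop = FALSE]
  }
  if (!missing(i)) x@intensities <- x@intensities[i, , drop = FALSE]
  methods::validObject(x)
  x
})

setMethod("show", "CytoFrame", function(object) {
  cat(sprintf("CytoFrame: %d events x %d channels\n",
              nrow(object@intensities), ncol(object@intensities)))
  cd <- object@channelData
  cat(sprintf("  channels: %s\n",
              paste(sprintf("%s[%s]", cd$name, cd$role), collapse = " ")))
  if (length(object@provenance))
    cat(sprintf("  provenance: %d step(s); last: %s\n",
                length(object@provenance),
                object@provenance[[length(object@provenance)]]))
})

setMethod("show", "Region", function(object) {
  cat(sprintf("Region '%s' (%s) on <%s, %s>\n", object@id, object@geometry,
              object@view[1], object@view[2]))
})

setMethod("show", "RegionChain", function(object) {
  cat(sprintf("RegionChain (%s): %d steps [%s]\n", object@kind,
              length(object@steps),
              paste(table(object@roles)[unique(object@roles)],
                    unique(object@roles), collapse = ", ")))
})

setMethod("show", "ComponentFit", function(object) {
  cat(sprintf("ComponentFit: %d components, R^2 = %.4f, converged = %s\n",
              length(object@components), object@r.squared, object@converged))
  for (g in object@components)
    cat(sprintf("  mean = %.4f  sd = %.4f  weight = %.1f  [%s]\n",
                g@mean, g@sd, g@weight, g@constraint))
})

setMethod("show", "ExpressionProfile", function(object) {
  cat(sprintf("ExpressionProfile '%s' (%s axis, %s scale): %d knots on [%.3f, %.3f]\n",
              object@marker, object@axisKind, object@scaleTag,
              length(object@x), min(object@x), max(object@x)))
})

setMethod("show", "ScalingMap", function(object) {
  cat(sprintf("ScalingMap '%s': single = %.4f * multi + %.4f (R^2 = %.4f)\n",
              object@marker, object@slope, object@intercept, object@r.squared))
})
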