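#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## Channel roles understood throughout the package.  "truth" marks generator
## ground-truth columns that analysis operations must never touch.
.CHANNEL_ROLES <- c("dna_integral", "dna_height", "epitope", "scatter", "truth")

#' CytoFrame: an event-by-channel intensity table
#'
#' The universal data currency of the package: a numeric matrix with one row
#' per cytometric event and one column per measurement channel, together with
#' per-channel metadata (name, role, units) and an append-only provenance log
#' recording every transform applied.
#'
#' @slot intensities numeric matrix, events x channels, finite values.
#' @slot channelData a \link[S4Vectors]{DataFrame} with columns \code{name},
#'   \code{role} (one of \code{dna_integral}, \code{dna_height},
#'   \code{epitope}, \code{scatter}, \code{truth}) and \code{units}.
#' @slot provenance list of character strings, ordered, append-only.
#'
#' @exportClass CytoFrame
setClass("CytoFrame",
  representation(
    intensities = "matrix",
    channelData = "DataFrame",
    provenance  = "list"
  )
)

setValidity("CytoFrame", function(object) {
  msg <- character()
  m <- object@intensities
  cd <- object@channelData
  if (!is.numeric(m)) msg <- c(msg, "intensities must be numeric")
  if (ncol(m) != nrow(cd))
    msg <- c(msg, "channelData rows must match intensity columns")
  if (!all(c("name", "role", "units") %in% colnames(cd)))
    msg <- c(msg, "channelData needs columns name, role, units")
  else {
    if (anyDuplicated(cd$name))
      msg <- c(msg, "channel names must be unique")
    if (!all(cd$role %in% .CHANNEL_ROLES))
      msg <- c(msg, sprintf("channel roles must be one of: %s",
                            paste(.CHANNEL_ROLES, collapse = ", ")))
    if (!identical(colnames(m), as.character(cd$name)))
      msg <- c(msg, "intensity column names must equal channelData$name")
  }
  if (nrow(m) > 0 && any(!is.finite(m)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Region: a 2-D gate geometry
#'
#' A named geometric region defined on an ordered pair of channels (the
#' "view").  Supported geometries are axis-aligned rectangles, simple
#' polygons, and rotated ellipses.  Membership uses half-open boundaries
#' (lower/left edge inclusive) so that abutting regions partition the plane.
#'
#' @slot id character identifier.
#' @slot view character(2), the (x, y) channel names.
#' @slot geometry one of "rectangle", "polygon", "ellipse".
#' @slot params numeric parameter list in channel units: rectangle
#'   \code{c(xmin, xmax, ymin, ymax)}; polygon a 2-column vertex matrix;
#'   ellipse \code{c(cx, cy, rx, ry, theta)} with \code{theta} in radians.
#'
#' @aliases Region
#' @exportClass Region
setClass("Region",
  representation(
    id       = "character",
    view     = "character",
    geometry = "character",
    params   = "ANY"
  )
)

setValidity("Region", function(object) {
  msg <- character()
  if (length(object@view) != 2L) msg <- c(msg, "view must name two channels")
  if (!object@geometry %in% c("rectangle", "polygon", "ellipse"))
    msg <- c(msg, "geometry must be rectangle, polygon or ellipse")
  p <- object@params
  if (object@geometry == "rectangle") {
    if (!is.numeric(p) || length(p) != 4L || p[1] >= p[2] || p[3] >= p[4])
      msg <- c(msg, "rectangle params must be c(xmin < xmax, ymin < ymax)")
  } else if (object@geometry == "polygon") {
    if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
      msg <- c(msg, "polygon needs a 2-column matrix of >= 3 vertices")
    else if (nrow(unique(p)) < 3L)
      msg <- c(msg, "polygon vertices are degenerate")
  } else if (object@geometry == "ellipse") {
    if (!is.numeric(p) || length(p) != 5L || p[3] <= 0 || p[4] <= 0)
      msg <- c(msg, "ellipse params must be c(cx, cy, rx > 0, ry > 0, theta)")
  }
  if (length(msg)) msg else TRUE
})

#' GateExpr: Boolean expression tree over Regions
#'
#' Nodes are either a leaf wrapping a \linkS4class{Region} or a Boolean
#' operator (\code{and}, \code{or}, \code{not}) over child expressions.
#'
#' @slot op one of "region", "and", "or", "not".
#' @slot region the wrapped Region for leaves, otherwise NULL.
#' @slot children list of child GateExpr nodes for operators.
#'
#' @aliases GateExpr
#' @exportClass GateExpr
setClass("GateExpr",
  representation(op = "character", region = "ANY", children = "list")
)

setValidity("GateExpr", function(object) {
  op <- object@op
  if (!op %in% c("region", "and", "or", "not"))
    return("op must be region/and/or/not")
  if (op == "region") {
    if (!is(object@region, "Region")) return("region leaf needs a Region")
  } else {
    n <- length(object@children)
    if (op == "not" && n != 1L) return("not takes one child")
    if (op %in% c("and", "or") && n < 2L)
      return("and/or take at least two children")
    if (!all(vapply(object@children, is, logical(1), "GateExpr")))
      return("children must be GateExpr nodes")
  }
  TRUE
})

#' RegionChain: an ordered, view-aware traversal of cell-cycle data space
#'
#' An ordered list of regions tracing the average cell's trajectory through
#' one or more bivariate views, in cell-cycle order (a cell cannot re-enter a
#' step).  The chain carries the deterministic assignment machinery
#' (backbone knots and cut positions for interphase; stage thresholds and
#' quantile cuts for mitosis) so that event-to-step assignment is a pure
#' function of the chain.
#'
#' @slot steps list of \linkS4class{Region} objects in traversal order.
#' @slot roles character, per step: "phase_cluster", "segment" or
#'   "transition_oval".
#' @slot kind "interphase" or "mitosis".
#' @slot assign_params list: everything needed to re-assign events.
#'
#' @aliases RegionChain
#' @exportClass RegionChain
setClass("RegionChain",
  representation(
    steps = "list",
    roles = "character",
    kind  = "character",
    assign_params = "list"
  )
)

setValidity("RegionChain", function(object) {
  msg <- character()
  if (length(object@steps) != length(object@roles))
    msg <- c(msg, "one role per step required")
  if (length(object@steps) &&
      !all(vapply(object@steps, is, logical(1), "Region")))
    msg <- c(msg, "steps must be Region objects")
  if (!all(object@roles %in% c("phase_cluster", "segment", "transition_oval")))
    msg <- c(msg, "invalid step role")
  if (!object@kind %in% c("interphase", "mitosis"))
    msg <- c(msg, "kind must be interphase or mitosis")
  if (length(msg)) msg else TRUE
})

#' GaussianComponent: one constrained Gaussian of a mixture fit
#'
#' Mean and SD are in log10-intensity units; weight is the event-mass
#' fraction carried by the component.  The constraint tag records how the
#' component was anchored during fitting.
#'
#' @slot mean numeric, log10 intensity.
#' @slot sd numeric, log10 intensity, > 0.
#' @slot weight numeric >= 0 (event-mass fraction).
#' @slot constraint one of "fixed_mean", "midpoint_mean", "fixed_sd",
#'   "shared_cv", "free".
#'
#' @aliases GaussianComponent
#' @exportClass GaussianComponent
setClass("GaussianComponent",
  representation(mean = "numeric", sd = "numeric", weight = "numeric",
                 constraint = "character"),
  prototype(weight = NA_real_, constraint = "free")
)

setValidity("GaussianComponent", function(object) {
  msg <- character()
  if (object@sd <= 0) msg <- c(msg, "sd must be > 0")
  if (!is.na(object@weight) && object@weight < 0)
    msg <- c(msg, "weight must be >= 0")
  if (!object@constraint %in%
      c("fixed_mean", "midpoint_mean", "fixed_sd", "shared_cv", "free"))
    msg <- c(msg, "unknown constraint tag")
  if (length(msg)) msg else TRUE
})

#' ComponentFit: a constrained multi-Gaussian histogram deconvolution
#'
#' @slot components list of \linkS4class{GaussianComponent}.
#' @slot breaks histogram bin breaks (log10 units) used for the fit.
#' @slot counts observed bin counts.
#' @slot fitted fitted bin counts (sum of weighted components).
#' @slot r.squared coefficient of determination between counts and fit.
#' @slot mse mean squared error over bins.
#' @slot converged logical optimizer convergence flag.
#'
#' @aliases ComponentFit
#' @exportClass ComponentFit
setClass("ComponentFit",
  representation(
    components = "list",
    breaks = "numeric",
    counts = "numeric",
    fitted = "numeric",
    r.squared = "numeric",
    mse = "numeric",
    converged = "logical"
  )
)

setValidity("ComponentFit", function(object) {
  msg <- character()
  if (length(object@components) &&
      !all(vapply(object@components, is, logical(1), "GaussianComponent")))
    msg <- c(msg, "components must be GaussianComponent objects")
  if (length(object@counts) &&
      length(object@breaks) != length(object@counts) + 1L)
    msg <- c(msg, "breaks must be one longer than counts")
  if (length(object@counts) && length(object@fitted) &&
      length(object@fitted) != length(object@counts))
    msg <- c(msg, "fitted and counts lengths differ")
  tot <- sum(object@counts)
  wts <- sum(vapply(object@components, function(g) g@weight, numeric(1)))
  if (tot > 0 && is.finite(wts) && abs(wts - tot) > 0.01 * tot)
    msg <- c(msg, "component weights must sum to histogram mass within 1%")
  if (length(object@r.squared) && object@r.squared > 1 + 1e-12)
    msg <- c(msg, "r.squared cannot exceed 1")
  if (length(msg)) msg else TRUE
})

#' ExpressionProfile: ordered piecewise-linear expression knots
#'
#' An ordered set of (x, y) knots with strictly increasing x, evaluated by
#' connecting consecutive knots with straight lines.  The x axis is either
#' cumulative event frequency F in [0, 1] or cell-cycle time t in [0, 1].
#'
#' @slot x numeric, strictly increasing, in [0, 1].
#' @slot y numeric expression values, finite.
#' @slot axisKind "frequency" or "time".
#' @slot marker channel/marker name.
#' @slot scaleTag free-text scale annotation (e.g. "raw", "samescale",
#'   "genomes").
#' @slot source character per knot: "region_median", "component_mean" or
#'   "heuristic".
#'
#' @aliases ExpressionProfile
#' @exportClass ExpressionProfile
setClass("ExpressionProfile",
  representation(
    x = "numeric", y = "numeric",
    axisKind = "character", marker = "character", scaleTag = "character",
    source = "character"
  ),
  prototype(scaleTag = "raw")
)

setValidity("ExpressionProfile", function(object) {
  msg <- character()
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y lengths differ")
  if (length(object@x) < 2L) msg <- c(msg, "need at least two knots")
  if (any(diff(object@x) <= 0)) msg <- c(msg, "x must be strictly increasing")
  if (length(object@x) && (min(object@x) < -1e-9 || max(object@x) > 1 + 1e-9))
    msg <- c(msg, "x must lie in [0, 1]")
  if (any(!is.finite(object@y))) msg <- c(msg, "y must be finite")
  if (!object@axisKind %in% c("frequency", "time"))
    msg <- c(msg, "axisKind must be frequency or time")
  if (length(object@source) &&
      length(object@source) != length(object@x))
    msg <- c(msg, "source must annotate every knot")
  if (length(msg)) msg else TRUE
})

#' DnaRescale: two-point linear DNA rescaling transform
#'
#' The exact linear map taking a file's G1 and G2 DNA modal channels onto
#' fixed target channels (defaults 350 and 700) so S-phase gates can be laid
#' down equivalently across files.
#'
#' @slot g1Mode,g2Mode source modal channels.
#' @slot targetG1,targetG2 target modal channels.
#' @slot a,b the implied linear coefficients: new = a * old + b.
#'
#' @aliases DnaRescale
#' @exportClass DnaRescale
setClass("DnaRescale",
  representation(g1Mode = "numeric", g2Mode = "numeric",
                 targetG1 = "numeric", targetG2 = "numeric",
                 a = "numeric", b = "numeric")
)

setValidity("DnaRescale", function(object) {
  msg <- character()
  if (object@a <= 0) msg <- c(msg, "slope a must be > 0")
  if (abs(object@a * object@g1Mode + object@b - object@targetG1) > 1e-6 ||
      abs(object@a * object@g2Mode + object@b - object@targetG2) > 1e-6)
    msg <- c(msg, "coefficients do not map modes onto targets")
  if (length(msg)) msg else TRUE
})

#' EquivalentGates: equal-width DNA intervals centred in S phase
#'
#' @slot intervals numeric matrix, one row per gate, columns lo and hi;
#'   disjoint, contiguous, symmetric about the centre.
#' @slot center the S-phase midpoint channel.
#'
#' @aliases EquivalentGates
#' @exportClass EquivalentGates
setClass("EquivalentGates",
  representation(intervals = "matrix", center = "numeric")
)

setValidity("EquivalentGates", function(object) {
  iv <- object@intervals
  msg <- character()
  if (ncol(iv) != 2L) msg <- c(msg, "intervals must have two columns")
  if (any(iv[, 2] <= iv[, 1])) msg <- c(msg, "intervals must have hi > lo")
  if (nrow(iv) > 1L) {
    if (any(abs(iv[-1, 1] - iv[-nrow(iv), 2]) > 1e-9))
      msg <- c(msg, "intervals must be contiguous")
    w <- iv[, 2] - iv[, 1]
    if (max(w) - min(w) > 1e-9 * max(w))
      msg <- c(msg, "intervals must be equal width")
  }
  mid <- (iv[1, 1] + iv[nrow(iv), 2]) / 2
  if (abs(mid - object@center) > 1e-6 * max(1, abs(object@center)))
    msg <- c(msg, "intervals must be symmetric about the centre")
  if (length(msg)) msg else TRUE
})

#' ScalingMap: affine map onto the common single-colour scale
#'
#' Per-epitope linear transform taking multi-colour intensities onto the
#' single-colour (shared secondary antibody) intensity scale, with the
#' regression diagnostics retained.
#'
#' @slot slope,intercept map: single = slope * multi + intercept.
#' @slot r.squared regression coefficient of determination.
#' @slot residuals regression residuals on the calibration medians.
#' @slot marker epitope name.
#'
#' @aliases ScalingMap
#' @exportClass ScalingMap
setClass("ScalingMap",
  representation(slope = "numeric", intercept = "numeric",
                 r.squared = "numeric", residuals = "numeric",
                 marker = "character")
)

setValidity("ScalingMap", function(object) {
  if (object@slope <= 0) "slope must be > 0" else TRUE
})

#' TruthProfiles: ground-truth marker kinetics for the synthetic generator
#'
#' Per-marker piecewise-linear functions of cell-cycle time t in [0, 1],
#' plus the phase boundary times.  DNA is in C units (2 through G1, linear
#' 2 -> 4 across S, 4 through G2/M).
#'
#' @slot knots named list of 2-column matrices (t, value), one per marker.
#' @slot phaseTimes named numeric: t_G1S, t_SG2, t_G2M.
#'
#' @aliases TruthProfiles
#' @exportClass TruthProfiles
setClass("TruthProfiles",
  representation(knots = "list", phaseTimes = "numeric")
)

setValidity("TruthProfiles", function(object) {
  msg <- character()
  pt <- object@phaseTimes
  if (!all(c("t_G1S", "t_SG2", "t_G2M") %in% names(pt)))
    msg <- c(msg, "phaseTimes needs t_G1S, t_SG2, t_G2M")
  else if (!(0 < pt["t_G1S"] && pt["t_G1S"] < pt["t_SG2"] &&
             pt["t_SG2"] < pt["t_G2M"] && pt["t_G2M"] < 1))
    msg <- c(msg, "phase times must satisfy 0 < t_G1S < t_SG2 < t_G2M < 1")
  for (nm in names(object@knots)) {
    k <- object@knots[[nm]]
    if (!is.matrix(k) || ncol(k) != 2L || nrow(k) < 2L) {
      msg <- c(msg, sprintf("knots for %s must be a 2-column matrix", nm))
      next
    }
    if (any(diff(k[, 1]) < 0))
      msg <- c(msg, sprintf("knot times for %s must be non-decreasing", nm))
    if (any(k[, 2] < 0))
      msg <- c(msg, sprintf("profile values for %s must be >= 0", nm))
  }
  if (all(c("dna") %in% names(object@knots)) && !length(msg)) {
    f <- .pwl_fun(object@knots[["dna"]])
    if (abs(f(0) - 2) > 1e-9 || abs(f(pt[["t_SG2"]]) - 4) > 1e-9 ||
        abs(f(1) - 4) > 1e-9)
      msg <- c(msg, "DNA truth must be exactly 2 at t=0 and 4 from t_SG2 on")
  }
  if (length(msg)) msg else TRUE
})

#' NoiseModel: measurement-process model for the synthetic generator
#'
#' @slot cv named per-channel lognormal coefficient of variation, in (0, 0.5).
#' @slot spillover list of triplets list(from=, into=, coef=) with
#'   coef in [0, 0.5).
#' @slot offset named per-channel additive background offset (applied before
#'   the multiplicative noise, emulating nonspecific staining).
#' @slot gain named per-channel multiplicative assay gain, > 0.
#' @slot doubletFrac,debrisFrac contamination fractions in [0, 0.2].
#' @slot nEvents number of (singlet) events to draw.
#' @slot seed integer RNG seed; identical seed implies identical output.
#'
#' @aliases NoiseModel
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(cv = "numeric", spillover = "list", offset = "numeric",
                 gain = "numeric", doubletFrac = "numeric",
                 debrisFrac = "numeric", nEvents = "numeric",
                 seed = "numeric")
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (any(object@cv <= 0 | object@cv >= 0.5))
    msg <- c(msg, "channel CVs must lie in (0, 0.5)")
  for (sp in object@spillover) {
    if (!all(c("from", "into", "coef") %in% names(sp)))
      msg <- c(msg, "spillover entries need from/into/coef")
    else if (sp$coef < 0 || sp$coef >= 0.5)
      msg <- c(msg, "spillover coefficients must lie in [0, 0.5)")
  }
  if (any(object@gain <= 0)) msg <- c(msg, "gains must be > 0")
  if (object@doubletFrac < 0 || object@doubletFrac > 0.2 ||
      object@debrisFrac < 0 || object@debrisFrac > 0.2)
    msg <- c(msg, "contamination fractions must lie in [0, 0.2]")
  if (object@nEvents < 1) msg <- c(msg, "nEvents must be >= 1")
  if (length(msg)) msg else TRUE
})
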