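#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Section: one unbranched run of traced points
#'
#' A `Section` is an ordered polyline of 3D points with diameters (microns)
#' of a single structural kind (`soma`, `axon`, `basal_dendrite`,
#' `apical_dendrite`, or `custom_<code>`).  Non-root sections whose parent is
#' not the soma carry a copy of the parent's attachment point as their first
#' point, so that consecutive point pairs always describe real cable.
#'
#' @slot id integer section identifier, unique within a [Morphology].
#' @slot kind character structural kind.
#' @slot points numeric matrix with columns `x`, `y`, `z`, `diam` (microns).
#' @slot parentId integer id of the parent section, or `NA` for a root.
#' @slot parentPoint integer index of the attachment point within the parent
#'   section's `points`, or `NA`.
#' @slot name character label (e.g. `"dend[3]"`).
#' @exportClass Section
setClass("Section", representation(
  id = "integer",
  kind = "character",
  points = "matrix",
  parentId = "integer",
  parentPoint = "integer",
  name = "character"
))

setValidity("Section", function(object) {
  msg <- character()
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 4L)
    msg <- c(msg, "points must be a numeric matrix with 4 columns (x,y,z,diam)")
  else {
    if (nrow(p) < 1L) msg <- c(msg, "a section needs at least one point")
    if (any(!is.finite(p))) msg <- c(msg, "coordinates and diameters must be finite")
  }
  if (length(object@kind) != 1L) msg <- c(msg, "kind must be a single string")
  if (length(msg)) msg else TRUE
})

#' Morphology: a traced neuronal reconstruction
#'
#' A tree of typed [Section]s in microns, plus an optional traced soma
#' contour and bookkeeping for detached roots flagged at load time.
#'
#' @slot sections list of [Section] objects, parents before children.
#' @slot somaOutline numeric matrix (columns `x`, `y`, `z`) of a closed soma
#'   contour, or `NULL`.
#' @slot sourceFormat `"swc"`, `"asc"` or `"synthetic"`.
#' @slot detachedRoots integer ids of sections whose attachment to the tree
#'   was missing in the source file (see [repairDetached]).
#' @slot metadata free-form list (generator ground truth, provenance, ...).
#' @exportClass Morphology
setClass("Morphology", representation(
  sections = "list",
  somaOutline = "matrixOrNULL",
  sourceFormat = "character",
  detachedRoots = "integer",
  metadata = "list"
))

setValidity("Morphology", function(object) {
  msg <- character()
  ids <- vapply(object@sections, function(s) s@id, integer(1))
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate section ids")
  par <- vapply(object@sections, function(s) s@parentId, integer(1))
  if (any(!is.na(par) & !(par %in% ids)))
    msg <- c(msg, "parentId refers to a missing section")
  # acyclicity: walking up from every section must terminate
  idx <- match(par, ids)
  for (i in seq_along(ids)) {
    seen <- integer(); j <- i
    while (!is.na(j)) {
      if (j %in% seen) return("section graph contains a cycle")
      seen <- c(seen, j); j <- idx[j]
    }
  }
  if (length(msg)) msg else TRUE
})

#' MorphStats: basic morphometrics of a reconstruction
#'
#' Branch points are non-soma topological nodes with at least two children;
#' stems are neurite sections attached directly to the soma (or unattached
#' roots); branches are maximal unbranched neurite paths between
#' soma/branch point/termination.  For purely bifurcating trees
#' `nBranches == 2 * nBranchPoints + nStems`.
#'
#' @slot nBranchPoints,nBranches,nStems,nPoints integer counts.
#' @slot totalLength numeric, summed 3D point-to-point distance in microns.
#' @exportClass MorphStats
setClass("MorphStats", representation(
  nBranchPoints = "integer",
  nBranches = "integer",
  nStems = "integer",
  totalLength = "numeric",
  nPoints = "integer"
))

#' DiameterPolicy: how neurite diameters are adjusted before printing
#'
#' Modes: `fixed` (impose one diameter), `scale` (multiply), `floor` (impose
#' a minimum), or `per_kind` (a map from structural kind to a (mode, value)
#' pair; the keys `axon`, `dendrite` -- matching both basal and apical --,
#' `basal_dendrite`, `apical_dendrite` and `custom` are understood).  The
#' soma is never touched by a diameter policy; use [scaleSoma].
#'
#' @slot mode character, one of `fixed`, `scale`, `floor`, `per_kind`.
#' @slot value numeric, microns (fixed/floor) or unitless factor (scale).
#' @slot perKind named list of `list(mode=, value=)` entries.
#' @exportClass DiameterPolicy
setClass("DiameterPolicy", representation(
  mode = "character",
  value = "numeric",
  perKind = "list"
))

setValidity("DiameterPolicy", function(object) {
  msg <- character()
  if (!object@mode %in% c("fixed", "scale", "floor", "per_kind"))
    msg <- c(msg, "mode must be fixed, scale, floor or per_kind")
  if (object@mode != "per_kind" && (length(object@value) != 1L || object@value <= 0))
    msg <- c(msg, "value must be a single positive number")
  if (object@mode == "per_kind") {
    if ("soma" %in% names(object@perKind))
      msg <- c(msg, "per-kind policies never target the soma (use scaleSoma)")
    ok <- vapply(object@perKind, function(e)
      is.list(e) && e$mode %in% c("fixed", "scale", "floor") && e$value > 0,
      logical(1))
    if (!all(ok)) msg <- c(msg, "each per-kind entry needs a valid mode and positive value")
  }
  if (length(msg)) msg else TRUE
})

#' PrintSpec: coordinate scaling and printer thickness constraints
#'
#' Coordinates in `inputUnit` are multiplied by `coordinateScale` and then
#' read by printer software in `outputUnit`.  For microns in, millimeters
#' out, a coordinate scale of 0.2 corresponds to a 200x magnification.
#' Thickness thresholds are in output units (mm): commercial SLS services
#' typically impose a 1 mm minimum for wirey structures, and 1.2 mm is a
#' safer submission target.
#'
#' @slot coordinateScale positive unitless multiplier.
#' @slot inputUnit,outputUnit `"um"` or `"mm"`.
#' @slot minThickness,recommendedThickness numeric, mm.
#' @exportClass PrintSpec
setClass("PrintSpec", representation(
  coordinateScale = "numeric",
  inputUnit = "character",
  outputUnit = "character",
  minThickness = "numeric",
  recommendedThickness = "numeric"
))

setValidity("PrintSpec", function(object) {
  msg <- character()
  if (object@coordinateScale <= 0) msg <- c(msg, "coordinateScale must be positive")
  if (!object@inputUnit %in% c("um", "mm")) msg <- c(msg, "inputUnit must be um or mm")
  if (!object@outputUnit %in% c("um", "mm")) msg <- c(msg, "outputUnit must be um or mm")
  if (object@minThickness > object@recommendedThickness)
    msg <- c(msg, "minThickness must not exceed recommendedThickness")
  if (length(msg)) msg else TRUE
})

#' MeshResolution: sampling resolution for surface tessellation
#'
#' @slot spatialStep grid pitch in microns; must resolve the thinnest
#'   neurite radius after diameter adjustment.
#' @slot angularStep radians, reserved for direct per-frustum tessellation
#'   backends.
#' @exportClass MeshResolution
setClass("MeshResolution", representation(
  spatialStep = "numeric",
  angularStep = "numeric"
))

setValidity("MeshResolution", function(object) {
  if (object@spatialStep <= 0) "spatialStep must be positive" else TRUE
})

#' TriangleMesh: indexed triangle surface
#'
#' Faces are triples of 1-based vertex indices, counter-clockwise when seen
#' from outside.  `faceSegment` and `faceColor` are either zero-length or
#' have one entry (row) per face.
#'
#' @slot vertices numeric matrix, one 3D point per row.
#' @slot faces integer matrix, one vertex-index triple per row.
#' @slot faceSegment integer vector of section ids (possibly empty).
#' @slot faceColor numeric matrix of RGB rows in \[0,1\] (possibly 0-row).
#' @slot metadata free-form list (resolution, component count, units, ...).
#' @exportClass TriangleMesh
setClass("TriangleMesh", representation(
  vertices = "matrix",
  faces = "matrix",
  faceSegment = "integer",
  faceColor = "matrix",
  metadata = "list"
))

setValidity("TriangleMesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must have 3 columns")
  f <- object@faces
  if (ncol(f) != 3L) msg <- c(msg, "faces must have 3 columns")
  else if (nrow(f) && (min(f) < 1L || max(f) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (length(object@faceSegment) && length(object@faceSegment) != nrow(f))
    msg <- c(msg, "faceSegment must have one entry per face")
  if (nrow(object@faceColor) && nrow(object@faceColor) != nrow(f))
    msg <- c(msg, "faceColor must have one row per face")
  if (nrow(object@faceColor) &&
      (min(object@faceColor) < 0 || max(object@faceColor) > 1))
    msg <- c(msg, "face colors must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' MeshStats: printed volume, surface area, bounding box, components
#'
#' Volume is computed by the divergence theorem (signed tetrahedra) and is
#' only defined for watertight, consistently oriented meshes; the axis
#' aligned bounding box and the printed volume are the main cost drivers at
#' commercial printing services.
#'
#' @slot volume numeric (unit^3, `NA` when not computed).
#' @slot surfaceArea numeric (unit^2).
#' @slot bbox 2x3 numeric matrix, rows `min`, `max`.
#' @slot nComponents integer, connected components by face adjacency.
#' @slot unit character label for the linear unit.
#' @exportClass MeshStats
setClass("MeshStats", representation(
  volume = "numeric",
  surfaceArea = "numeric",
  bbox = "matrix",
  nComponents = "integer",
  unit = "character"
))

#' ColorScheme: how faces are colored from their segment assignment
#'
#' @slot mode `"by_kind"`, `"by_section_name"` or `"by_scalar"`.
#' @slot colors named list of RGB vectors (kind or section-name keys).
#' @slot scalar named numeric vector keyed by section id (as character).
#' @slot stops numeric matrix of RGB rows; the scalar's observed range is
#'   mapped linearly across the stops.
#' @exportClass ColorScheme
setClass("ColorScheme", representation(
  mode = "character",
  colors = "list",
  scalar = "numeric",
  stops = "matrix"
))

setValidity("ColorScheme", function(object) {
  msg <- character()
  if (!object@mode %in% c("by_kind", "by_section_name", "by_scalar"))
    msg <- c(msg, "mode must be by_kind, by_section_name or by_scalar")
  rgbok <- function(v) is.numeric(v) && length(v) == 3L && all(v >= 0 & v <= 1)
  if (length(object@colors) && !all(vapply(object@colors, rgbok, logical(1))))
    msg <- c(msg, "colors must be RGB triples in [0,1]")
  if (nrow(object@stops) && (ncol(object@stops) != 3L ||
      min(object@stops) < 0 || max(object@stops) > 1))
    msg <- c(msg, "stops must be RGB rows in [0,1]")
  if (length(msg)) msg else TRUE
})

#' ThicknessReport: result of a printed-thickness validation
#'
#' @slot violations data.frame (`sectionId`, `pointIndex`,
#'   `printedDiameter`) of points below the hard minimum.
#' @slot advisories data.frame of points meeting the minimum but below the
#'   recommended thickness, plus structural-risk notes in `metadata`.
#' @slot perSection data.frame (`sectionId`, `minPrintedDiameter`).
#' @slot passFlag logical, `TRUE` iff no violations.
#' @slot minThickness,recommendedThickness thresholds used (mm).
#' @slot metadata list (structural advisories etc).
#' @exportClass ThicknessReport
setClass("ThicknessReport", representation(
  violations = "data.frame",
  advisories = "data.frame",
  perSection = "data.frame",
  passFlag = "logical",
  minThickness = "numeric",
  recommendedThickness = "numeric",
  metadata = "list"
))

setValidity("ThicknessReport", function(object) {
  if (object@passFlag != (nrow(object@violations) == 0L))
    "passFlag must be TRUE exactly when there are no violations" else TRUE
})

#' PrintableVersion: catalogue metadata for one printable model
#'
#' Mirrors the record kept for each printable version of a cell: name,
#' comment, magnification (if known), printed volume, bounding box, the
#' algorithm that defined the surface, creator, date added, and a unique id.
#'
#' @slot name,comment,algorithm,creator,dateAdded,uniqueId character.
#' @slot magnification numeric (NA when unknown).
#' @slot printedVolume numeric, mm^3.
#' @slot bbox 2x3 numeric matrix in mm.
#' @exportClass PrintableVersion
setClass("PrintableVersion", representation(
  name = "character",
  comment = "character",
  magnification = "numeric",
  printedVolume = "numeric",
  bbox = "matrix",
  algorithm = "character",
  creator = "character",
  dateAdded = "character",
  uniqueId = "character"
))

#' TreeSpec: parameters for the synthetic morphology generator
#'
#' @slot seed integer PRNG seed; fixed seed gives byte-identical SWC output.
#' @slot nBifurcations,nStems integer tree topology counts.
#' @slot segmentLengthRange length-2 numeric, microns.
#' @slot taper per-branch-order diameter ratio in (0, 1].
#' @slot somaDiameter,stemDiameter microns.
#' @slot planarity `"planar"` (dendrites in the xy plane) or `"3d"`.
#' @exportClass TreeSpec
setClass("TreeSpec", representation(
  seed = "integer",
  nBifurcations = "integer",
  nStems = "integer",
  segmentLengthRange = "numeric",
  taper = "numeric",
  somaDiameter = "numeric",
  stemDiameter = "numeric",
  planarity = "character"
))

setValidity("TreeSpec", function(object) {
  msg <- character()
  if (object@nStems < 1L && object@nBifurcations > 0L)
    msg <- c(msg, "cannot place bifurcations on a tree with no stems")
  if (object@taper <= 0 || object@taper > 1)
    msg <- c(msg, "taper must lie in (0, 1]")
  if (any(object@segmentLengthRange <= 0) ||
      length(object@segmentLengthRange) != 2L)
    msg <- c(msg, "segmentLengthRange must be two positive numbers")
  if (object@somaDiameter <= 0 || object@stemDiameter <= 0)
    msg <- c(msg, "diameters must be positive")
  if (!object@planarity %in% c("planar", "3d"))
    msg <- c(msg, "planarity must be 'planar' or '3d'")
  if (length(msg)) msg else TRUE
})
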