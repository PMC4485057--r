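# Diameter policies, soma rescaling about its center of mass, and scaling
# to print units.

#' Construct a diameter policy
#'
#' @param mode `"fixed"`, `"scale"`, `"floor"` or `"per_kind"`.
#' @param value microns (fixed/floor) or unitless factor (scale).
#' @param perKind named list of `list(mode=, value=)` entries, e.g.
#'   `list(axon = list(mode = "fixed", value = 6),
#'         dendrite = list(mode = "fixed", value = 9))`.
#' @return a [DiameterPolicy]
#' @examples
#' diameterPolicy("fixed", 9)
#' diameterPolicy("per_kind", perKind = list(
#'   axon = list(mode = "fixed", value = 6),
#'   dendrite = list(mode = "fixed", value = 9)))
#' @export
diameterPolicy <- function(mode, value = numeric(1), perKind = list()) {
  new("DiameterPolicy", mode = mode, value = as.numeric(value),
      perKind = perKind)
}

applyMode <- function(d, mode, value) {
  switch(mode,
         fixed = rep(value, length(d)),
         scale = d * value,
         floor = pmax(d, value),
         stop("unknown diameter mode: ", mode))
}

resolveKindEntry <- function(kind, perKind) {
  if (!is.null(perKind[[kind]])) return(perKind[[kind]])
  if (kind %in% c("basal_dendrite", "apical_dendrite") &&
      !is.null(perKind[["dendrite"]])) return(perKind[["dendrite"]])
  if (grepl("^custom_", kind)) {
    if (!is.null(perKind[["custom"]])) return(perKind[["custom"]])
    if (!is.null(perKind[["dendrite"]])) return(perKind[["dendrite"]])
  }
  NULL
}

#' @describeIn applyDiameterPolicy Transform non-soma point diameters; all
#'   coordinates (hence all lengths) are left untouched, as is the soma.
#' @export
setMethod("applyDiameterPolicy", c("Morphology", "DiameterPolicy"),
          function(m, policy) {
  for (i in seq_along(m@sections)) {
    s <- m@sections[[i]]
    if (isSomaKind(s@kind)) next
    d <- s@points[, 4]
    d2 <- if (policy@mode == "per_kind") {
      e <- resolveKindEntry(s@kind, policy@perKind)
      if (is.null(e)) d else applyMode(d, e$mode, e$value)
    } else applyMode(d, policy@mode, policy@value)
    if (any(d2 <= 0))
      stop("diameter policy yields non-positive diameter in section ", s@id)
    s@points[, 4] <- d2
    m@sections[[i]] <- s
  }
  m
})

#' @describeIn scaleSoma Multiply soma point positions and diameters by
#'   `factor` about the origin, then rigidly translate the soma so its
#'   volume-weighted center of mass is back at its pre-scaling location.
#'   Neurite sections keep their measured coordinates; the watertight
#'   tessellation absorbs any surface gap or overlap at the attachment.
#' @export
setMethod("scaleSoma", "Morphology", function(m, factor) {
  if (factor <= 0) stop("factor must be positive")
  if (!hasSoma(m)) stop("morphology has no soma")
  com0 <- somaCentroid(m)
  shift <- com0 - factor * com0        # restores the center of mass exactly
  for (i in seq_along(m@sections)) {
    s <- m@sections[[i]]
    if (!isSomaKind(s@kind)) next
    s@points[, 1:3] <- s@points[, 1:3, drop = FALSE] * factor +
      rep(shift, each = nrow(s@points))
    s@points[, 4] <- s@points[, 4] * factor
    m@sections[[i]] <- s
  }
  if (!is.null(m@somaOutline))
    m@somaOutline <- m@somaOutline * factor + rep(shift, each = nrow(m@somaOutline))
  m
})

#' Construct a print specification
#'
#' @param coordinateScale unitless coordinate multiplier (e.g. 0.2).
#' @param inputUnit,outputUnit `"um"` or `"mm"`.
#' @param minThickness,recommendedThickness printed-thickness thresholds in
#'   mm (defaults 1.0 and 1.2, typical of commercial SLS nylon services).
#' @return a [PrintSpec]
#' @examples
#' spec <- printSpec(0.2)
#' magnification(spec)   # 200
#' @export
printSpec <- function(coordinateScale = 0.2, inputUnit = "um",
                      outputUnit = "mm", minThickness = 1.0,
                      recommendedThickness = 1.2) {
  new("PrintSpec", coordinateScale = coordinateScale, inputUnit = inputUnit,
      outputUnit = outputUnit, minThickness = minThickness,
      recommendedThickness = recommendedThickness)
}

unitFactor <- function(unit) switch(unit, um = 1e-6, mm = 1e-3,
                                    stop("unsupported unit: ", unit))

#' Magnification implied by a print spec
#'
#' Ratio of printed size to biological size: the coordinate scale times the
#' output/input unit ratio.  Microns in, millimeters out, with coordinate
#' scale 0.2 gives a 200x magnification.
#'
#' @param spec a [PrintSpec]
#' @return numeric magnification
#' @export
magnification <- function(spec) {
  spec@coordinateScale * unitFactor(spec@outputUnit) / unitFactor(spec@inputUnit)
}

setMethod("show", "PrintSpec", function(object) {
  cat(sprintf(paste0("PrintSpec: scale %g (%s -> %s, %gx magnification), ",
                     "min thickness %g mm, recommended %g mm\n"),
              object@coordinateScale, object@inputUnit, object@outputUnit,
              magnification(object), object@minThickness,
              object@recommendedThickness))
})

#' @describeIn scaleModel Multiply all coordinates and diameters of a
#'   morphology by the coordinate scale; returns
#'   `list(model=, magnification=)`.
#' @export
setMethod("scaleModel", c("Morphology", "PrintSpec"), function(x, spec) {
  s <- spec@coordinateScale
  for (i in seq_along(x@sections))
    x@sections[[i]]@points <- x@sections[[i]]@points * s
  if (!is.null(x@somaOutline)) x@somaOutline <- x@somaOutline * s
  list(model = x, magnification = magnification(spec))
})

#' @describeIn scaleModel Multiply mesh vertex coordinates by the coordinate
#'   scale; returns `list(model=, magnification=)`.
#' @export
setMethod("scaleModel", c("TriangleMesh", "PrintSpec"), function(x, spec) {
  x@vertices <- x@vertices * spec@coordinateScale
  x@metadata$unit <- spec@outputUnit
  list(model = x, magnification = magnification(spec))
})
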