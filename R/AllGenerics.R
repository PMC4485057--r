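#' @rdname Morphology-class
#' @param x a [Morphology]
#' @export
setGeneric("sections", function(x) standardGeneric("sections"))

#' @rdname Morphology-class
#' @export
setGeneric("detachedRoots", function(x) standardGeneric("detachedRoots"))

#' @rdname Morphology-class
#' @export
setGeneric("somaOutline", function(x) standardGeneric("somaOutline"))

#' @rdname TriangleMesh-class
#' @param x a [TriangleMesh]
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("faceColor", function(x) standardGeneric("faceColor"))

#' @rdname TriangleMesh-class
#' @export
setGeneric("faceSegment", function(x) standardGeneric("faceSegment"))

#' Repair detached neurite roots
#'
#' @param m a [Morphology]
#' @param ... further arguments for methods
#' @export
setGeneric("repairDetached", function(m, ...) standardGeneric("repairDetached"))

#' Remove the axon (and everything attached to it)
#' @param m a [Morphology]
#' @export
setGeneric("removeAxon", function(m) standardGeneric("removeAxon"))

#' Basic morphometrics
#' @param m a [Morphology]
#' @export
setGeneric("branchStats", function(m) standardGeneric("branchStats"))

#' Apply a diameter-adjustment policy to the neurites
#' @param m a [Morphology]
#' @param policy a [DiameterPolicy]
#' @export
setGeneric("applyDiameterPolicy",
           function(m, policy) standardGeneric("applyDiameterPolicy"))

#' Rescale the soma about its center of mass
#' @param m a [Morphology]
#' @param factor positive scale factor
#' @export
setGeneric("scaleSoma", function(m, factor) standardGeneric("scaleSoma"))

#' Scale a model to printed size
#' @param x a [Morphology] or [TriangleMesh]
#' @param spec a [PrintSpec]
#' @export
setGeneric("scaleModel", function(x, spec) standardGeneric("scaleModel"))

#' Decompose a morphology into frusta and spheres
#' @param m a [Morphology]
#' @export
setGeneric("skeletonToFrusta", function(m) standardGeneric("skeletonToFrusta"))

#' Validate printed thickness of wirey structures
#' @param m a [Morphology]
#' @param spec a [PrintSpec]
#' @export
setGeneric("checkThickness", function(m, spec) standardGeneric("checkThickness"))
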