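#' Evaluate a membrane transition function
#'
#' Value of the geometry's hydration field at one or more positions, before
#' any pore composition. 0 = hydrophobic core, 1 = aqueous.
#'
#' @param geometry a \linkS4class{MembraneGeometry}.
#' @param pos numeric length-3 vector or n x 3 matrix of positions (Angstrom),
#'   in membrane coordinates.
#' @param params a \linkS4class{TransitionParams}.
#' @return numeric vector of field values in [0, 1], one per position.
#' @examples
#' transitionValue(slabGeometry(), c(0, 0, 15))
#' @export
setGeneric("transitionValue",
    function(geometry, pos, params = TransitionParams()) {
        standardGeneric("transitionValue")
    })

#' Analytic gradient of a membrane transition function
#'
#' @inheritParams transitionValue
#' @return n x 3 numeric matrix of gradients (1/Angstrom). At removable
#'   singularities (e.g. a sphere center) the gradient is defined as zero and
#'   a warning is issued.
#' @examples
#' transitionGradient(slabGeometry(), c(0, 0, 10))
#' @export
setGeneric("transitionGradient",
    function(geometry, pos, params = TransitionParams()) {
        standardGeneric("transitionGradient")
    })

#' @rdname TransitionParams-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("halfThickness", function(object) standardGeneric("halfThickness"))

#' @rdname TransitionParams-class
#' @export
setGeneric("steepness", function(object) standardGeneric("steepness"))

#' @rdname MembraneStructure-class
#' @param object,x a \linkS4class{MembraneStructure}.
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' @rdname MembraneStructure-class
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname MembraneStructure-class
#' @export
setGeneric("bFactors", function(object) standardGeneric("bFactors"))

#' @rdname MembraneStructure-class
#' @param value replacement value.
#' @export
setGeneric("bFactors<-", function(object, value) {
    standardGeneric("bFactors<-")
})

#' @rdname MembraneStructure-class
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' @rdname MembraneStructure-class
#' @export
setGeneric("nResidues", function(object) standardGeneric("nResidues"))

#' @rdname HydrationResult-class
#' @param object a \linkS4class{HydrationResult}.
#' @export
setGeneric("fThk", function(object) standardGeneric("fThk"))

#' @rdname HydrationResult-class
#' @export
setGeneric("fCavity", function(object) standardGeneric("fCavity"))

#' @rdname HydrationResult-class
#' @export
setGeneric("fHyd", function(object) standardGeneric("fHyd"))

#' @rdname SpanFile-class
#' @param object a \linkS4class{SpanFile}.
#' @export
setGeneric("spanResidues", function(object) standardGeneric("spanResidues"))

#' @rdname SpanFile-class
#' @export
setGeneric("spans", function(object) standardGeneric("spans"))
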