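#' Evaluate the hydration field on a structure
#'
#' Computes per-atom membrane (\code{fThk}), pore (\code{fCavity}) and
#' composed (\code{fHyd}) hydration values for every atom of a structure,
#' dispatching on the geometry. When a pore is supplied and enabled, the
#' geometry field composes with it as
#' \eqn{f_{hyd} = f_{thk} + f_{cavity} - f_{thk} f_{cavity}}; the pore can be
#' combined with any geometry.
#'
#' @param structure a \linkS4class{MembraneStructure} in membrane coordinates
#'   (membrane normal = z, membrane center at the origin).
#' @param geometry a \linkS4class{MembraneGeometry}.
#' @param pore a \linkS4class{PoreSpec}, or NULL for no pore.
#' @param params a \linkS4class{TransitionParams}.
#' @return a \linkS4class{HydrationResult}.
#' @examples
#' helix <- makeTMHelix(21)
#' hyd <- hydration(helix$structure, slabGeometry())
#' range(fHyd(hyd))
#' @export
hydration <- function(structure, geometry, pore = NULL,
                      params = TransitionParams()) {
    stopifnot(is(structure, "MembraneStructure"),
              is(geometry, "MembraneGeometry"),
              is(params, "TransitionParams"))
    validObject(structure)
    validObject(params)
    if (nAtoms(structure) == 0L) stop("structure contains no atoms")
    pos <- coords(structure)
    fg <- transitionValue(geometry, pos, params)
    fc <- if (is.null(pore)) {
        numeric(length(fg))
    } else {
        poreTransition(pore, pos)
    }
    new("HydrationResult",
        fThk = fg, fCavity = fc, fHyd = composePore(fg, fc),
        geometry = geometry, pore = pore, params = params)
}

#' @rdname HydrationResult-class
#' @export
setMethod("fThk", "HydrationResult", function(object) object@fThk)

#' @rdname HydrationResult-class
#' @export
setMethod("fCavity", "HydrationResult", function(object) object@fCavity)

#' @rdname HydrationResult-class
#' @export
setMethod("fHyd", "HydrationResult", function(object) object@fHyd)

setMethod("show", "HydrationResult", function(object) {
    cat(sprintf("HydrationResult: %d atoms, geometry %s, pore %s\n",
                length(object@fHyd), class(object@geometry),
                if (is.null(object@pore) || !object@pore@enabled) "off"
                else "on"))
    if (length(object@fHyd)) {
        cat(sprintf("  fHyd: min %.3f, median %.3f, max %.3f\n",
                    min(object@fHyd), stats::median(object@fHyd),
                    max(object@fHyd)))
    }
})
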