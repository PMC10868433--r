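#' @import methods
NULL

## ---------------------------------------------------------------------------
## Transition parameters
## ---------------------------------------------------------------------------

#' Transition-function parameters
#'
#' Half-thickness and steepness shared by all membrane transition functions.
#' The hydration field follows the rational sigmoid
#' \eqn{g(s) = s^n / (1 + s^n)} evaluated at the normalised distance
#' \eqn{s = |z| / t}, so \code{halfThickness} is the depth (in Angstrom) at
#' which the field crosses 0.5 and \code{steepness} controls how sharp the
#' hydrophobic-to-aqueous transition is.
#'
#' @slot halfThickness numeric(1). Hydrophobic half-thickness t in Angstrom
#'   (default 15): half the hydrophobic core of a typical bilayer.
#' @slot steepness numeric(1). Dimensionless exponent n (default 10).
#'
#' @examples
#' p <- TransitionParams()
#' halfThickness(p)
#' @export
setClass("TransitionParams",
    representation(halfThickness = "numeric", steepness = "numeric"),
    prototype(halfThickness = 15, steepness = 10)
)

setValidity("TransitionParams", function(object) {
    msg <- character()
    t <- object@halfThickness
    n <- object@steepness
    if (length(t) != 1L || !is.finite(t) || t <= 0) {
        msg <- c(msg, "halfThickness must be a single positive finite number")
    }
    if (length(n) != 1L || !is.finite(n) || n <= 0) {
        msg <- c(msg, "steepness must be a single positive finite number")
    }
    if (length(msg)) msg else TRUE
})

#' @param halfThickness hydrophobic half-thickness t in Angstrom.
#' @param steepness dimensionless steepness exponent n.
#' @rdname TransitionParams-class
#' @export
TransitionParams <- function(halfThickness = 15, steepness = 10) {
    new("TransitionParams",
        halfThickness = as.numeric(halfThickness),
        steepness = as.numeric(steepness))
}

## ---------------------------------------------------------------------------
## Membrane geometries
## ---------------------------------------------------------------------------

#' Membrane geometry classes
#'
#' Virtual base class \code{MembraneGeometry} with one concrete subclass per
#' supported geometry. All geometries assume the structure is in membrane
#' coordinates: membrane normal along z, membrane center (mid-plane) through
#' the origin.
#'
#' \describe{
#'   \item{\code{SlabGeometry}}{Flat bilayer; hydration depends only on depth
#'     \eqn{|z|}.}
#'   \item{\code{EllipsoidGeometry}}{Micelle/bicelle mimetic: a planar disc of
#'     radius \code{innerRadius} capped by a hemispherical rim of width equal
#'     to the membrane half-thickness. \code{innerRadius = 0} is a micelle.
#'     The outer radius is derived as \code{innerRadius + halfThickness}.}
#'   \item{\code{VesicleGeometry}}{Spherical bilayer of mid-surface radius
#'     \code{radius}, sphere center at \eqn{(0, 0, -R)} (curvature
#'     \code{"down"}, the default) or \eqn{(0, 0, +R)} (\code{"up"}); the
#'     protein-embedding origin lies on the mid-surface.}
#'   \item{\code{DoubleVesicleGeometry}}{Two concentric spherical bilayers
#'     centered at the origin: inner mid-surface radius \code{innerRadius},
#'     outer mid-surface radius \code{innerRadius + 2 t + distance}, where
#'     \code{distance} is measured from the outer edge of the inner membrane
#'     to the inner edge of the outer membrane (so the membranes can never
#'     overlap). At large radius this approximates two parallel flat
#'     membranes.}
#' }
#'
#' @aliases SlabGeometry-class EllipsoidGeometry-class VesicleGeometry-class
#'   DoubleVesicleGeometry-class
#' @name MembraneGeometry-class
#' @export
setClass("MembraneGeometry", representation("VIRTUAL"))

#' @rdname MembraneGeometry-class
#' @export
setClass("SlabGeometry", contains = "MembraneGeometry")

#' @rdname MembraneGeometry-class
#' @export
setClass("EllipsoidGeometry",
    contains = "MembraneGeometry",
    representation(innerRadius = "numeric"),
    prototype(innerRadius = 0)
)

setValidity("EllipsoidGeometry", function(object) {
    r <- object@innerRadius
    if (length(r) != 1L || !is.finite(r) || r < 0) {
        "innerRadius must be a single finite number >= 0"
    } else TRUE
})

#' @rdname MembraneGeometry-class
#' @export
setClass("VesicleGeometry",
    contains = "MembraneGeometry",
    representation(radius = "numeric", curvature = "character"),
    prototype(radius = 100, curvature = "down")
)

setValidity("VesicleGeometry", function(object) {
    msg <- character()
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0) {
        msg <- c(msg, "radius must be a single positive finite number")
    }
    if (length(object@curvature) != 1L ||
        !object@curvature %in% c("down", "up")) {
        msg <- c(msg, "curvature must be \"down\" or \"up\"")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname MembraneGeometry-class
#' @export
setClass("DoubleVesicleGeometry",
    contains = "MembraneGeometry",
    representation(innerRadius = "numeric", distance = "numeric"),
    prototype(innerRadius = 1000, distance = 40)
)

setValidity("DoubleVesicleGeometry", function(object) {
    msg <- character()
    if (length(object@innerRadius) != 1L || !is.finite(object@innerRadius) ||
        object@innerRadius <= 0) {
        msg <- c(msg, "innerRadius must be a single positive finite number")
    }
    if (length(object@distance) != 1L || !is.finite(object@distance) ||
        object@distance < 0) {
        msg <- c(msg, "distance must be a single finite number >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' @param innerRadius planar-disc radius (ellipsoid, Angstrom, >= 0; 0 =
#'   micelle) or inner mid-surface radius (double vesicle, Angstrom, > 0).
#' @rdname MembraneGeometry-class
#' @export
slabGeometry <- function() new("SlabGeometry")

#' @rdname MembraneGeometry-class
#' @export
ellipsoidGeometry <- function(innerRadius = 0) {
    new("EllipsoidGeometry", innerRadius = as.numeric(innerRadius))
}

#' @param radius vesicle mid-surface radius R in Angstrom (> 0).
#' @param curvature \code{"down"} (sphere center at (0,0,-R)) or \code{"up"}.
#' @rdname MembraneGeometry-class
#' @export
vesicleGeometry <- function(radius, curvature = c("down", "up")) {
    curvature <- match.arg(curvature)
    new("VesicleGeometry", radius = as.numeric(radius), curvature = curvature)
}

#' @param distance edge-to-edge gap d between the two membranes in Angstrom
#'   (>= 0).
#' @rdname MembraneGeometry-class
#' @export
doubleVesicleGeometry <- function(innerRadius, distance) {
    new("DoubleVesicleGeometry",
        innerRadius = as.numeric(innerRadius),
        distance = as.numeric(distance))
}

## ---------------------------------------------------------------------------
## Aqueous pore
## ---------------------------------------------------------------------------

#' Aqueous-pore specification
#'
#' A water-filled channel modelled as a radially symmetric sigmoid around an
#' axis parallel to z through (x0, y0):
#' \eqn{f_{cavity} = 1 / (1 + (\rho/\rho_0)^m)} with \eqn{\rho} the lateral
#' distance to the axis. The pore field composes with any membrane geometry
#' via \code{\link{composePore}}.
#'
#' @slot x0,y0 numeric(1). Pore-axis intercept in the z = 0 plane (Angstrom).
#' @slot radius numeric(1). Pore radius \eqn{\rho_0} in Angstrom (> 0), the
#'   lateral distance at which the pore field crosses 0.5.
#' @slot steepness numeric(1). Dimensionless exponent m (default 10).
#' @slot enabled logical(1). Whether the pore contributes to hydration.
#'
#' @examples
#' poreSpec(radius = 6)
#' @export
setClass("PoreSpec",
    representation(x0 = "numeric", y0 = "numeric", radius = "numeric",
                   steepness = "numeric", enabled = "logical"),
    prototype(x0 = 0, y0 = 0, radius = 5, steepness = 10, enabled = TRUE)
)

setValidity("PoreSpec", function(object) {
    msg <- character()
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0) {
        msg <- c(msg, "radius must be a single positive finite number")
    }
    if (length(object@steepness) != 1L || !is.finite(object@steepness) ||
        object@steepness <= 0) {
        msg <- c(msg, "steepness must be a single positive finite number")
    }
    for (s in c("x0", "y0")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v)) {
            msg <- c(msg, sprintf("%s must be a single finite number", s))
        }
    }
    if (length(object@enabled) != 1L || is.na(object@enabled)) {
        msg <- c(msg, "enabled must be TRUE or FALSE")
    }
    if (length(msg)) msg else TRUE
})

#' @param x0,y0 pore-axis intercept in the z = 0 plane (Angstrom).
#' @param radius pore radius rho0 in Angstrom (> 0).
#' @param steepness dimensionless steepness exponent m.
#' @param enabled logical; disabled pores contribute f_cavity = 0.
#' @rdname PoreSpec-class
#' @export
poreSpec <- function(radius = 5, x0 = 0, y0 = 0, steepness = 10,
                     enabled = TRUE) {
    new("PoreSpec", x0 = as.numeric(x0), y0 = as.numeric(y0),
        radius = as.numeric(radius), steepness = as.numeric(steepness),
        enabled = as.logical(enabled))
}

## ---------------------------------------------------------------------------
## Structures
## ---------------------------------------------------------------------------

#' Protein structure container
#'
#' An ordered atom table in membrane coordinates with a writable B-factor
#' slot. Residues carry both their original PDB numbering (\code{resNo},
#' preserved for output) and a 1-based pose numbering (\code{poseResNo},
#' order of first appearance), which is what spanfiles refer to.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{atomName},
#'   \code{altLoc}, \code{resName}, \code{chainID}, \code{resNo},
#'   \code{poseResNo}, \code{x}, \code{y}, \code{z}, \code{bFactor},
#'   \code{element}, \code{isHet}.
#'
#' @seealso [readPDB()], [writePDB()], [coords()], [bFactors()]
#' @export
setClass("MembraneStructure", representation(atoms = "data.frame"))

.STRUCTURE_COLS <- c("serial", "atomName", "altLoc", "resName", "chainID",
                     "resNo", "poseResNo", "x", "y", "z", "bFactor",
                     "element", "isHet")

setValidity("MembraneStructure", function(object) {
    a <- object@atoms
    msg <- character()
    if (!all(.STRUCTURE_COLS %in% names(a))) {
        msg <- c(msg, paste("atoms must have columns:",
                            paste(.STRUCTURE_COLS, collapse = ", ")))
    } else {
        if (nrow(a) == 0L) msg <- c(msg, "structure must contain >= 1 atom")
        if (nrow(a) > 0L && !all(is.finite(c(a$x, a$y, a$z)))) {
            msg <- c(msg, "coordinates must be finite")
        }
        if (nrow(a) > 0L &&
            !identical(sort(unique(a$poseResNo)),
                       seq_len(max(a$poseResNo)))) {
            msg <- c(msg, "poseResNo must cover 1..N without gaps")
        }
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Spanfile
## ---------------------------------------------------------------------------

#' Membrane-spanning annotation
#'
#' Residue ranges (1-based pose numbering, inclusive) expected to span the
#' membrane, as read from / written to Rosetta-style spanfiles.
#'
#' @slot nRes integer(1). Total residue count of the annotated protein.
#' @slot spans integer matrix with columns \code{start}, \code{end};
#'   normalised to be sorted and non-overlapping.
#'
#' @seealso [readSpanfile()], [writeSpanfile()], [spanResidues()]
#' @export
setClass("SpanFile", representation(nRes = "integer", spans = "matrix"))

setValidity("SpanFile", function(object) {
    s <- object@spans
    msg <- character()
    if (length(object@nRes) != 1L || is.na(object@nRes) || object@nRes < 1L) {
        msg <- c(msg, "nRes must be a positive integer")
    }
    if (!is.numeric(s) || ncol(s) != 2L || nrow(s) < 1L) {
        msg <- c(msg, "spans must be a matrix with >= 1 row and 2 columns")
    } else {
        if (any(s[, 1L] < 1L) || any(s[, 2L] > object@nRes) ||
            any(s[, 1L] > s[, 2L])) {
            msg <- c(msg, "each span must satisfy 1 <= start <= end <= nRes")
        }
        if (nrow(s) > 1L && any(s[-1L, 1L] <= s[-nrow(s), 2L])) {
            msg <- c(msg, "spans must be sorted and non-overlapping")
        }
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Hydration result
## ---------------------------------------------------------------------------

#' Per-atom hydration field values
#'
#' Result of evaluating a membrane geometry (and optionally a pore) on every
#' atom of a structure. All values lie in [0, 1]: 0 = fully hydrophobic
#' (membrane core), 1 = fully aqueous.
#'
#' @slot fThk numeric. Membrane-geometry transition value per atom.
#' @slot fCavity numeric. Pore field per atom (0 when the pore is off).
#' @slot fHyd numeric. Composed hydration
#'   \eqn{f_{hyd} = f_{thk} + f_{cavity} - f_{thk} f_{cavity}}.
#' @slot geometry the \linkS4class{MembraneGeometry} used.
#' @slot pore the \linkS4class{PoreSpec} used, or NULL.
#' @slot params the \linkS4class{TransitionParams} used.
#'
#' @seealso [hydration()]
#' @export
setClass("HydrationResult",
    representation(fThk = "numeric", fCavity = "numeric", fHyd = "numeric",
                   geometry = "MembraneGeometry", pore = "ANY",
                   params = "TransitionParams")
)

setValidity("HydrationResult", function(object) {
    msg <- character()
    n <- length(object@fHyd)
    if (length(object@fThk) != n || length(object@fCavity) != n) {
        msg <- c(msg, "fThk, fCavity and fHyd must have equal length")
    }
    vals <- c(object@fThk, object@fCavity, object@fHyd)
    if (length(vals) && (any(!is.finite(vals)) || any(vals < -1e-12) ||
                         any(vals > 1 + 1e-12))) {
        msg <- c(msg, "all hydration values must lie in [0, 1]")
    }
    if (!is.null(object@pore) && !is(object@pore, "PoreSpec")) {
        msg <- c(msg, "pore must be NULL or a PoreSpec")
    }
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Energy table and burial score
## ---------------------------------------------------------------------------

#' Water-to-bilayer transfer energy table
#'
#' Maps atom classes to water-to-bilayer transfer free energies
#' (kcal/mol; negative = favours the bilayer). Rows are matched in order of
#' decreasing specificity: (resName, atomName), then residue-level rows
#' (atomName NA, spread over side-chain heavy atoms), then element-level
#' fallbacks (resName \code{"*"}, atomName = element symbol); unmatched atoms
#' score 0 with a warning.
#'
#' @slot table data.frame with columns \code{resName}, \code{atomName},
#'   \code{dG}.
#'
#' @seealso [defaultEnergyTable()], [burialEnergy()]
#' @export
setClass("EnergyTable", representation(table = "data.frame"))

setValidity("EnergyTable", function(object) {
    tb <- object@table
    msg <- character()
    if (!all(c("resName", "atomName", "dG") %in% names(tb))) {
        msg <- c(msg, "table needs columns resName, atomName, dG")
    } else {
        if (nrow(tb) == 0L) msg <- c(msg, "energy table must not be empty")
        if (nrow(tb) > 0L && !all(is.finite(tb$dG))) {
            msg <- c(msg, "dG values must be finite")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Geometry-dependent burial free energy
#'
#' Total and per-residue membrane burial free energy
#' \eqn{\Delta G_{memb} = \sum_{atoms} (1 - f_{hyd}) \Delta G_{w,l}}.
#'
#' @slot total numeric(1). Total burial free energy in kcal/mol.
#' @slot perResidue data.frame with columns \code{poseResNo}, \code{resName},
#'   \code{dG}.
#'
#' @seealso [burialEnergy()]
#' @export
setClass("BurialScore",
    representation(total = "numeric", perResidue = "data.frame"))

setValidity("BurialScore", function(object) {
    pr <- object@perResidue
    if (!all(c("poseResNo", "resName", "dG") %in% names(pr))) {
        return("perResidue needs columns poseResNo, resName, dG")
    }
    tot <- sum(pr$dG)
    denom <- max(1, abs(object@total))
    if (abs(object@total - tot) > 1e-9 * denom) {
        return("total must equal the sum of per-residue terms")
    }
    TRUE
})
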