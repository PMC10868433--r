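## Core transition-function algebra: the rational sigmoid family, per-geometry
## hydration fields, the aqueous-pore field, their composition, and analytic
## gradients.

## Rational sigmoid g(s) = s^n / (1 + s^n) on s >= 0, overflow-safe.
rationalSigmoid <- function(s, n) {
    out <- numeric(length(s))
    hi <- s > 1
    out[!hi] <- s[!hi]^n / (1 + s[!hi]^n)
    out[hi] <- 1 / (1 + s[hi]^(-n))
    out
}

## g'(s) = n s^(n-1) / (1 + s^n)^2, overflow-safe.
rationalSigmoidDeriv <- function(s, n) {
    out <- numeric(length(s))
    hi <- s > 1
    out[!hi] <- n * s[!hi]^(n - 1) / (1 + s[!hi]^n)^2
    out[hi] <- n * s[hi]^(-n - 1) / (1 + s[hi]^(-n))^2
    out
}

## Soft-OR used by both the pore composition and the ellipsoid field:
## a + b - a*b = 1 - (1-a)(1-b). Guarded so the algebraic identities hold
## exactly in floating point: identity 0, absorbing 1, result in [0, 1] and
## never below either input.
softUnion <- function(a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n)
    b <- rep_len(b, n)
    out <- pmax(a, b, pmin(1, a + b - a * b))
    out[a == 1 | b == 1] <- 1
    out
}

#' Slab depth transition
#'
#' Hydration of the flat-bilayer model as a function of signed membrane depth:
#' \eqn{f_{thk}(z) = (|z|/t)^n / (1 + (|z|/t)^n)}. Zero at the membrane
#' center, 0.5 at depth \eqn{|z| = t}, approaching 1 far from the membrane.
#'
#' @param z numeric vector of signed depths along the membrane normal
#'   (Angstrom).
#' @param params a \linkS4class{TransitionParams}.
#' @return numeric vector of hydration values in [0, 1].
#' @examples
#' fThkSlab(c(0, 15, 30))
#' @export
fThkSlab <- function(z, params = TransitionParams()) {
    stopifnot(is(params, "TransitionParams"))
    validObject(params)
    if (!is.numeric(z) || any(!is.finite(z))) {
        stop("'z' must be finite numeric")
    }
    rationalSigmoid(abs(z) / params@halfThickness, params@steepness)
}

## Derivative of the slab field with respect to z (scalar chain rule).
fThkSlabDeriv <- function(z, params) {
    t <- params@halfThickness
    rationalSigmoidDeriv(abs(z) / t, params@steepness) * sign(z) / t
}

## ---------------------------------------------------------------------------
## transitionValue methods
## ---------------------------------------------------------------------------

#' @rdname transitionValue
setMethod("transitionValue", "SlabGeometry", function(geometry, pos, params) {
    pos <- asPositionMatrix(pos)
    fThkSlab(pos[, 3L], params)
})

## Effective radial coordinate of the ellipsoid (disc + hemispherical rim):
## r = innerRadius + sqrt(max(0, rho - innerRadius)^2 + z^2), rho lateral.
## Inside the planar disc (rho <= innerRadius) this reduces to inner + |z|;
## for a micelle (innerRadius = 0) it is the plain spherical distance.
ellipsoidRadialDistance <- function(pos, innerRadius) {
    rho <- sqrt(pos[, 1L]^2 + pos[, 2L]^2)
    q <- pmax(0, rho - innerRadius)
    innerRadius + sqrt(q^2 + pos[, 3L]^2)
}

#' @rdname transitionValue
setMethod("transitionValue", "EllipsoidGeometry",
    function(geometry, pos, params) {
        validObject(geometry)
        pos <- asPositionMatrix(pos)
        outer <- geometry@innerRadius + params@halfThickness
        if (outer <= 0) stop("outer radius must be > 0")
        r <- ellipsoidRadialDistance(pos, geometry@innerRadius)
        h <- rationalSigmoid(r / outer, params@steepness)
        softUnion(fThkSlab(pos[, 3L], params), h)
    })

vesicleCenter <- function(geometry) {
    c(0, 0, if (geometry@curvature == "down") -geometry@radius
            else geometry@radius)
}

## Signed radial depth relative to the sphere mid-surface.
sphereDepth <- function(pos, center, radius) {
    dx <- sweep(pos, 2L, center)
    sqrt(rowSums(dx^2)) - radius
}

#' @rdname transitionValue
setMethod("transitionValue", "VesicleGeometry",
    function(geometry, pos, params) {
        validObject(geometry)
        pos <- asPositionMatrix(pos)
        d <- sphereDepth(pos, vesicleCenter(geometry), geometry@radius)
        fThkSlab(d, params)
    })

doubleVesicleRadii <- function(geometry, params) {
    c(inner = geometry@innerRadius,
      outer = geometry@innerRadius + 2 * params@halfThickness +
          geometry@distance)
}

#' @rdname transitionValue
setMethod("transitionValue", "DoubleVesicleGeometry",
    function(geometry, pos, params) {
        validObject(geometry)
        pos <- asPositionMatrix(pos)
        rr <- doubleVesicleRadii(geometry, params)
        d <- sqrt(rowSums(pos^2))
        ## hydrophobic inside either membrane: intersection of the two
        ## aqueous fields (product rule)
        fThkSlab(d - rr[["inner"]], params) *
            fThkSlab(d - rr[["outer"]], params)
    })

## ---------------------------------------------------------------------------
## Pore field and composition
## ---------------------------------------------------------------------------

#' Aqueous-pore transition field
#'
#' \eqn{f_{cavity} = 1 / (1 + (\rho/\rho_0)^m)} with \eqn{\rho} the lateral
#' distance to the pore axis: 1 on the axis, 0.5 at \eqn{\rho = \rho_0},
#' approaching 0 far from the pore. A disabled pore yields 0 everywhere.
#'
#' @param pore a \linkS4class{PoreSpec}.
#' @param pos numeric length-3 vector or n x 3 matrix of positions (Angstrom).
#' @return numeric vector of pore field values in [0, 1].
#' @examples
#' poreTransition(poreSpec(radius = 5), c(5, 0, 0))
#' @export
poreTransition <- function(pore, pos) {
    stopifnot(is(pore, "PoreSpec"))
    validObject(pore)
    pos <- asPositionMatrix(pos)
    if (!pore@enabled) return(numeric(nrow(pos)))
    rho <- sqrt((pos[, 1L] - pore@x0)^2 + (pos[, 2L] - pore@y0)^2)
    1 - rationalSigmoid(rho / pore@radius, pore@steepness)
}

#' Compose membrane and pore hydration fields
#'
#' \eqn{f_{hyd} = f_{thk} + f_{cavity} - f_{thk} f_{cavity}}: the soft union
#' of the two aqueous fields. Commutative, with identity 0 and absorbing
#' element 1; the result is never smaller than either input.
#'
#' @param fThk numeric vector in [0, 1] (membrane field).
#' @param fCavity numeric vector in [0, 1] (pore field).
#' @return numeric vector \code{fHyd} in [0, 1].
#' @examples
#' composePore(0.5, 0.5)  # 0.75
#' @export
composePore <- function(fThk, fCavity) {
    if (!is.numeric(fThk) || !is.numeric(fCavity) ||
        any(!is.finite(fThk)) || any(!is.finite(fCavity)) ||
        any(fThk < 0 | fThk > 1) || any(fCavity < 0 | fCavity > 1)) {
        stop("both inputs must be numeric in [0, 1]")
    }
    softUnion(fThk, fCavity)
}

## ---------------------------------------------------------------------------
## Analytic gradients
## ---------------------------------------------------------------------------

#' @rdname transitionGradient
setMethod("transitionGradient", "SlabGeometry",
    function(geometry, pos, params) {
        pos <- asPositionMatrix(pos)
        g <- matrix(0, nrow(pos), 3L)
        g[, 3L] <- fThkSlabDeriv(pos[, 3L], params)
        g
    })

#' @rdname transitionGradient
setMethod("transitionGradient", "EllipsoidGeometry",
    function(geometry, pos, params) {
        validObject(geometry)
        pos <- asPositionMatrix(pos)
        a <- geometry@innerRadius
        outer <- a + params@halfThickness
        rho <- sqrt(pos[, 1L]^2 + pos[, 2L]^2)
        q <- pmax(0, rho - a)
        s <- sqrt(q^2 + pos[, 3L]^2)
        r <- a + s
        fz <- fThkSlab(pos[, 3L], params)
        h <- rationalSigmoid(r / outer, params@steepness)
        dh <- rationalSigmoidDeriv(r / outer, params@steepness) / outer
        ## grad r: z-part z/s; lateral part (q/s) * unit lateral vector
        gradR <- matrix(0, nrow(pos), 3L)
        ok <- s > 0
        gradR[ok, 3L] <- pos[ok, 3L] / s[ok]
        lat <- ok & q > 0 & rho > 0
        scale <- ifelse(lat, q / (s * rho), 0)
        gradR[, 1L] <- scale * pos[, 1L]
        gradR[, 2L] <- scale * pos[, 2L]
        if (any(!ok)) {
            warning("gradient evaluated at the ellipsoid center; defined 0")
        }
        ## f = fz + h - fz*h  =>  grad f = (1-h) grad fz + (1-fz) grad h
        gfz <- matrix(0, nrow(pos), 3L)
        gfz[, 3L] <- fThkSlabDeriv(pos[, 3L], params)
        (1 - h) * gfz + (1 - fz) * dh * gradR
    })

## Gradient of a single-sphere field about `center` with mid-surface `radius`.
sphereFieldGradient <- function(pos, center, radius, params) {
    dx <- sweep(pos, 2L, center)
    dist <- sqrt(rowSums(dx^2))
    d <- dist - radius
    g <- matrix(0, nrow(pos), 3L)
    ok <- dist > 0
    if (any(!ok)) {
        warning("gradient evaluated at a sphere center; defined 0")
    }
    fac <- ifelse(ok, fThkSlabDeriv(d, params) / pmax(dist, .Machine$double.eps),
                  0)
    fac * dx
}

#' @rdname transitionGradient
setMethod("transitionGradient", "VesicleGeometry",
    function(geometry, pos, params) {
        validObject(geometry)
        pos <- asPositionMatrix(pos)
        sphereFieldGradient(pos, vesicleCenter(geometry), geometry@radius,
                            params)
    })

#' @rdname transitionGradient
setMethod("transitionGradient", "DoubleVesicleGeometry",
    function(geometry, pos, params) {
        validObject(geometry)
        pos <- asPositionMatrix(pos)
        rr <- doubleVesicleRadii(geometry, params)
        d <- sqrt(rowSums(pos^2))
        f1 <- fThkSlab(d - rr[["inner"]], params)
        f2 <- fThkSlab(d - rr[["outer"]], params)
        g1 <- sphereFieldGradient(pos, c(0, 0, 0), rr[["inner"]], params)
        g2 <- sphereFieldGradient(pos, c(0, 0, 0), rr[["outer"]], params)
        f2 * g1 + f1 * g2
    })

## Gradient of the pore field (zero when disabled; defined 0 on the axis,
## where the field has a smooth maximum for m > 1).
poreTransitionGradient <- function(pore, pos) {
    pos <- asPositionMatrix(pos)
    g <- matrix(0, nrow(pos), 3L)
    if (!pore@enabled) return(g)
    dx <- pos[, 1L] - pore@x0
    dy <- pos[, 2L] - pore@y0
    rho <- sqrt(dx^2 + dy^2)
    ok <- rho > 0
    ## f_cavity = 1 - g(rho/rho0)  =>  d/drho = -g'(rho/rho0)/rho0
    fac <- ifelse(ok,
                  -rationalSigmoidDeriv(rho / pore@radius, pore@steepness) /
                      (pore@radius * pmax(rho, .Machine$double.eps)),
                  0)
    g[, 1L] <- fac * dx
    g[, 2L] <- fac * dy
    g
}

#' Gradient of the composed hydration field
#'
#' Analytic gradient of \eqn{f_{hyd}} (geometry field composed with the pore
#' field when one is supplied), suitable for force calculations.
#'
#' @param pos numeric length-3 vector or n x 3 matrix of positions (Angstrom).
#' @param geometry a \linkS4class{MembraneGeometry}.
#' @param pore a \linkS4class{PoreSpec} or NULL.
#' @param params a \linkS4class{TransitionParams}.
#' @return n x 3 numeric matrix of gradients (1/Angstrom).
#' @examples
#' gradientFHyd(c(3, 2, 10), slabGeometry(), poreSpec(radius = 5))
#' @export
gradientFHyd <- function(pos, geometry, pore = NULL,
                         params = TransitionParams()) {
    pos <- asPositionMatrix(pos)
    gG <- transitionGradient(geometry, pos, params)
    if (is.null(pore) || !pore@enabled) return(gG)
    fG <- transitionValue(geometry, pos, params)
    fC <- poreTransition(pore, pos)
    gC <- poreTransitionGradient(pore, pos)
    (1 - fC) * gG + (1 - fG) * gC
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "TransitionParams", function(object) {
    cat(sprintf("TransitionParams: half-thickness t = %g A, steepness n = %g\n",
                object@halfThickness, object@steepness))
})

setMethod("show", "SlabGeometry", function(object) {
    cat("SlabGeometry: flat bilayer, hydration depends on |z|\n")
})

setMethod("show", "EllipsoidGeometry", function(object) {
    kind <- if (object@innerRadius == 0) "micelle" else "bicelle"
    cat(sprintf("EllipsoidGeometry (%s): inner radius = %g A\n",
                kind, object@innerRadius))
})

setMethod("show", "VesicleGeometry", function(object) {
    cat(sprintf(
        "VesicleGeometry: mid-surface radius R = %g A, curved %s (center at (0, 0, %+g))\n",
        object@radius, object@curvature,
        vesicleCenter(object)[3L]))
})

setMethod("show", "DoubleVesicleGeometry", function(object) {
    cat(sprintf(
        "DoubleVesicleGeometry: inner radius = %g A, edge-to-edge gap d = %g A\n",
        object@innerRadius, object@distance))
})

setMethod("show", "PoreSpec", function(object) {
    cat(sprintf(
        "PoreSpec: axis through (%g, %g), radius rho0 = %g A, m = %g, %s\n",
        object@x0, object@y0, object@radius, object@steepness,
        if (object@enabled) "enabled" else "disabled"))
})

#' @rdname TransitionParams-class
#' @export
setMethod("halfThickness", "TransitionParams",
          function(object) object@halfThickness)

#' @rdname TransitionParams-class
#' @export
setMethod("steepness", "TransitionParams", function(object) object@steepness)
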