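## Geometry-parameter estimation and sanity checks.

## Largest pairwise distance among rows of a coordinate matrix (0 or 1 row
## gives 0).
maxPairwiseDistance <- function(xyz) {
    if (nrow(xyz) < 2L) return(0)
    max(stats::dist(xyz))
}

#' Default bicelle radius heuristic
#'
#' Estimates a bicelle inner radius from the transmembrane cross-section of
#' the protein: the largest distance between two alpha carbons within
#' \code{zWindow} Angstrom of the membrane center, halved and multiplied by
#' three. This keeps the protein from being modelled in a bicelle smaller
#' than itself.
#'
#' @param structure a \linkS4class{MembraneStructure} in membrane coordinates.
#' @param zWindow half-width of the slice around z = 0 (default 3 Angstrom).
#' @return estimated inner radius in Angstrom.
#' @examples
#' helix <- makeTMHelix(21)$structure
#' defaultBicelleRadius(helix)
#' @export
defaultBicelleRadius <- function(structure, zWindow = 3) {
    stopifnot(is(structure, "MembraneStructure"))
    a <- structure@atoms
    ca <- caIndices(structure, warnMissing = FALSE)
    ca <- ca[abs(a$z[ca]) <= zWindow]
    if (length(ca) < 2L) {
        stop("fewer than 2 CA atoms within ", zWindow, " A of the membrane ",
             "center; set the bicelle inner radius explicitly")
    }
    maxD <- maxPairwiseDistance(coords(structure)[ca, , drop = FALSE])
    maxD / 2 * 3
}

#' Check that an ellipsoid membrane is large enough
#'
#' Computes the greatest distance between any two atoms within
#' \code{zWindow} Angstrom of the membrane-center plane; if the ellipsoid
#' inner radius is smaller than half that distance, the protein may be larger
#' than the bicelle/micelle and a warning is issued.
#'
#' @param structure a \linkS4class{MembraneStructure}.
#' @param geometry an \linkS4class{EllipsoidGeometry}.
#' @param zWindow half-width of the slice around z = 0 (default 3 Angstrom).
#' @return invisibly, a list with \code{ok}, \code{maxDistance} and
#'   \code{innerRadius}.
#' @export
checkBicelleSize <- function(structure, geometry, zWindow = 3) {
    stopifnot(is(structure, "MembraneStructure"),
              is(geometry, "EllipsoidGeometry"))
    a <- structure@atoms
    sel <- abs(a$z) <= zWindow
    maxD <- maxPairwiseDistance(coords(structure)[sel, , drop = FALSE])
    ok <- geometry@innerRadius >= maxD / 2
    if (!ok) {
        warning(sprintf(
            "protein may be larger than the bicelle/micelle: inner radius %g A < half the maximal cross-section %g A",
            geometry@innerRadius, maxD / 2))
    }
    invisible(list(ok = ok, maxDistance = maxD,
                   innerRadius = geometry@innerRadius))
}

## Default parameter grids per geometry kind.
defaultGeometryGrid <- function(kind) {
    switch(kind,
        slab = data.frame(dummy = 0),
        ellipsoid = data.frame(innerRadius = seq(10, 100, by = 5)),
        vesicle = expand.grid(radius = c(seq(80, 600, by = 20), 1000, 1e6),
                              curvature = c("down", "up"),
                              stringsAsFactors = FALSE),
        double_vesicle = data.frame(distance = seq(10, 300, by = 10),
                                    innerRadius = 1000),
        stop("unknown geometry kind: ", kind)
    )
}

geometryFromGridRow <- function(kind, row) {
    switch(kind,
        slab = slabGeometry(),
        ellipsoid = ellipsoidGeometry(innerRadius = row$innerRadius),
        vesicle = vesicleGeometry(radius = row$radius,
                                  curvature = row$curvature),
        double_vesicle = doubleVesicleGeometry(
            innerRadius = row$innerRadius, distance = row$distance)
    )
}

jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0L) return(0)
    length(intersect(a, b)) / u
}

#' Optimize geometry parameters against a spanfile
#'
#' Exhaustive grid search over the kind-specific geometry parameters,
#' matching the residues the hydration field scores as hydrophobic
#' (CA \code{fHyd < 0.5}) to the residues annotated as membrane-spanning.
#' The default objective is the Jaccard index between the two residue sets
#' (\code{"balanced_accuracy"} is available as an alternative). Ties are
#' broken deterministically toward the smallest parameter values (grid
#' order).
#'
#' The result is sensitive to which residues the spanfile marks; small
#' boundary shifts can move the optimum.
#'
#' @param structure a \linkS4class{MembraneStructure} in membrane coordinates.
#' @param span a \linkS4class{SpanFile} over the structure's pose residues.
#' @param kind one of \code{"slab"}, \code{"ellipsoid"}, \code{"vesicle"},
#'   \code{"double_vesicle"}.
#' @param grid data.frame of candidate parameters (one column per parameter;
#'   defaults: ellipsoid innerRadius 10-100 step 5; vesicle radius 80-600
#'   step 20 plus 1000 and 1e6, both curvature signs; double vesicle distance
#'   10-300 step 10 at innerRadius 1000).
#' @param params a \linkS4class{TransitionParams}.
#' @param objective \code{"jaccard"} or \code{"balanced_accuracy"}.
#' @return a list of class \code{"OptimizationReport"} with elements
#'   \code{kind}, \code{best} (the winning grid row), \code{bestGeometry},
#'   \code{objective}, \code{objectiveName} and \code{grid} (all candidates
#'   with their scores).
#' @examples
#' cb <- makeCurvedBundle(120, nHelices = 5)
#' rep <- optimizeGeometryParams(cb$structure, cb$span, "vesicle",
#'                               grid = data.frame(radius = c(100, 120, 140),
#'                                                 curvature = "down"))
#' rep$best
#' @export
optimizeGeometryParams <- function(structure, span, kind, grid = NULL,
                                   params = TransitionParams(),
                                   objective = c("jaccard",
                                                 "balanced_accuracy")) {
    objective <- match.arg(objective)
    stopifnot(is(structure, "MembraneStructure"), is(span, "SpanFile"))
    kind <- match.arg(kind, c("slab", "ellipsoid", "vesicle",
                              "double_vesicle"))
    if (span@nRes != nResidues(structure)) {
        stop("spanfile annotates ", span@nRes, " residues but the structure ",
             "has ", nResidues(structure))
    }
    if (is.null(grid)) grid <- defaultGeometryGrid(kind)
    if (!is.data.frame(grid) || nrow(grid) == 0L) {
        stop("parameter grid is empty")
    }
    a <- structure@atoms
    ca <- caIndices(structure)
    caPos <- coords(structure)[ca, , drop = FALSE]
    caRes <- a$poseResNo[ca]
    spanSet <- spanResidues(span)
    allRes <- sort(unique(caRes))

    scoreCandidate <- function(geom) {
        f <- transitionValue(geom, caPos, params)
        hydrophobic <- caRes[f < 0.5]
        if (objective == "jaccard") {
            jaccard(hydrophobic, spanSet)
        } else {
            pos <- intersect(allRes, spanSet)
            neg <- setdiff(allRes, spanSet)
            tpr <- if (length(pos)) {
                length(intersect(hydrophobic, pos)) / length(pos)
            } else 1
            tnr <- if (length(neg)) {
                length(setdiff(neg, hydrophobic)) / length(neg)
            } else 1
            (tpr + tnr) / 2
        }
    }

    scores <- vapply(seq_len(nrow(grid)), function(i) {
        scoreCandidate(geometryFromGridRow(kind, grid[i, , drop = FALSE]))
    }, numeric(1L))
    best <- which.max(scores)  # first max = smallest parameters (grid order)
    out <- list(
        kind = kind,
        best = grid[best, , drop = FALSE],
        bestGeometry = geometryFromGridRow(kind, grid[best, , drop = FALSE]),
        objective = scores[best],
        objectiveName = objective,
        grid = cbind(grid, score = scores)
    )
    class(out) <- "OptimizationReport"
    out
}

#' @export
print.OptimizationReport <- function(x, ...) {
    cat(sprintf("OptimizationReport (%s geometry, objective = %s)\n",
                x$kind, x$objectiveName))
    cat(sprintf("  candidates evaluated: %d\n", nrow(x$grid)))
    cat(sprintf("  best objective: %.4f at\n", x$objective))
    print(x$best, row.names = FALSE)
    invisible(x)
}

#' Write an optimization report to a text file
#'
#' Deterministic plain-text rendering of an [optimizeGeometryParams()]
#' result: recommended parameters first, then every candidate with its score.
#'
#' @param report an \code{"OptimizationReport"}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeOptimizationReport <- function(report, path) {
    stopifnot(inherits(report, "OptimizationReport"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("geometry: %s", report$kind), con)
    writeLines(sprintf("objective: %s = %.6f", report$objectiveName,
                       report$objective), con)
    bestParams <- report$best
    for (nm in names(bestParams)) {
        writeLines(sprintf("recommended %s: %s", nm,
                           format(bestParams[[nm]])), con)
    }
    writeLines("", con)
    writeLines("candidates:", con)
    g <- report$grid
    header <- paste(names(g), collapse = "\t")
    writeLines(header, con)
    for (i in seq_len(nrow(g))) {
        writeLines(paste(vapply(g[i, ], function(v) format(v, digits = 10),
                                character(1L)), collapse = "\t"), con)
    }
    invisible(path)
}
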