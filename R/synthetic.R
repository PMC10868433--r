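## Synthetic structures and ensembles with known ground truth, so geometry,
## scoring, parameter-estimation and metrics code is testable without any
## external structure downloads. CA-only traces are used throughout (they
## carry everything the hydration field sees); burial-energy mechanics work
## on them through the CA fallback of the energy table.

## Assemble a CA-only MembraneStructure from a coordinate matrix.
caTraceStructure <- function(xyz, chainID, resNo, residueName = "ALA") {
    n <- nrow(xyz)
    newMembraneStructure(data.frame(
        serial = seq_len(n),
        atomName = "CA",
        altLoc = "",
        resName = residueName,
        chainID = chainID,
        resNo = resNo,
        insert = "",
        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
        bFactor = 0,
        element = "C",
        isHet = FALSE,
        stringsAsFactors = FALSE
    ))
}

## Ideal alpha-helical CA wind around a vertical axis through (cx, cy):
## 100 degrees and `rise` Angstrom per residue, helix radius `helixRadius`,
## centered on z = 0 before the zShift.
helixCACoords <- function(nRes, rise, helixRadius, cx = 0, cy = 0,
                          phase = 0) {
    i <- seq_len(nRes) - 1
    theta <- phase + i * 100 * pi / 180
    z <- i * rise
    cbind(cx + helixRadius * cos(theta),
          cy + helixRadius * sin(theta),
          z - mean(z))
}

#' Synthetic single transmembrane helix
#'
#' Ideal alpha-helical CA trace along the membrane normal, centered at the
#' origin, with the matching membrane-spanning annotation (residues with
#' \code{|z| <= 15} Angstrom). Optional Gaussian coordinate jitter.
#'
#' @param nRes number of residues (>= 5).
#' @param rise helical rise per residue in Angstrom (default 1.5).
#' @param radius helix radius in Angstrom (default 2.3).
#' @param noise standard deviation of optional Gaussian coordinate jitter in
#'   Angstrom (default 0 = ideal trace).
#' @param seed RNG seed for the jitter; identical seeds give identical
#'   structures.
#' @return list with elements \code{structure}
#'   (\linkS4class{MembraneStructure}) and \code{span}
#'   (\linkS4class{SpanFile}).
#' @examples
#' helix <- makeTMHelix(21)
#' range(atoms(helix$structure)$z)
#' @export
makeTMHelix <- function(nRes, rise = 1.5, radius = 2.3, noise = 0, seed = 1) {
    stopifnotScalar(nRes, "nRes")
    if (nRes < 5) stop("'nRes' must be >= 5")
    xyz <- helixCACoords(nRes, rise, radius)
    if (noise > 0) {
        xyz <- xyz + withSeed(seed, matrix(stats::rnorm(3 * nRes, 0, noise),
                                           ncol = 3L))
    }
    xyz <- sweep(xyz, 2L, colMeans(xyz))
    st <- caTraceStructure(xyz, chainID = "A", resNo = seq_len(nRes))
    inMem <- which(abs(xyz[, 3L]) <= 15)
    span <- spanFile(c(min(inMem), max(inMem)), nRes = nRes)
    list(structure = st, span = span)
}

#' Synthetic helix bundle around an aqueous pore
#'
#' Vertical helices placed on a circle of radius \code{poreRadius + 3}
#' Angstrom around the z-axis, so CA atoms on the inward face of each helix
#' sit close enough to the pore axis to be ground-truth pore-facing while
#' outward CAs face the lipid. Returns the matching pore specification,
#' spanfile and per-residue inward/outward truth labels.
#'
#' @param nHelices number of helices (>= 3).
#' @param poreRadius pore radius rho0 in Angstrom (> 0).
#' @param nRes residues per helix (default 20).
#' @param helixRadius helix winding radius in Angstrom (default 2.3).
#' @param seed RNG seed (kept for interface symmetry; the construction is
#'   deterministic).
#' @return list with \code{structure}, \code{pore}
#'   (\linkS4class{PoreSpec}), \code{span} (\linkS4class{SpanFile}) and
#'   \code{truth} (data.frame: \code{poseResNo}, \code{inward}).
#' @examples
#' pb <- makePoreBundle(4, poreRadius = 5)
#' pb$pore
#' @export
makePoreBundle <- function(nHelices, poreRadius, nRes = 20,
                           helixRadius = 2.3, seed = 1) {
    stopifnotScalar(nHelices, "nHelices")
    if (nHelices < 3) stop("'nHelices' must be >= 3")
    stopifnotScalar(poreRadius, "poreRadius", positive = TRUE)
    if (nRes < 5) stop("'nRes' must be >= 5")
    ringRadius <- poreRadius + 3
    phi <- 2 * pi * (seq_len(nHelices) - 1) / nHelices
    pieces <- lapply(seq_len(nHelices), function(k) {
        ## phase points the first CA of each helix at the pore axis
        helixCACoords(nRes, rise = 1.5, helixRadius = helixRadius,
                      cx = ringRadius * cos(phi[k]),
                      cy = ringRadius * sin(phi[k]),
                      phase = phi[k] + pi)
    })
    xyz <- do.call(rbind, pieces)
    st <- caTraceStructure(
        xyz,
        chainID = rep(LETTERS[seq_len(nHelices)], each = nRes),
        resNo = rep(seq_len(nRes), nHelices))
    a <- st@atoms
    spansPerHelix <- do.call(rbind, lapply(seq_len(nHelices), function(k) {
        sel <- which(a$chainID == LETTERS[k] & abs(a$z) <= 15)
        c(min(a$poseResNo[sel]), max(a$poseResNo[sel]))
    }))
    rho <- sqrt(a$x^2 + a$y^2)
    list(
        structure = st,
        pore = poreSpec(radius = poreRadius),
        span = spanFile(spansPerHelix, nRes = nHelices * nRes),
        ## inward = CAs pointing into the pore (within 0.3 A of the closest
        ## possible approach ringRadius - helixRadius): these are the
        ## ground-truth pore-facing residues
        truth = data.frame(poseResNo = a$poseResNo,
                           inward = rho <= ringRadius - helixRadius + 0.3)
    )
}

#' Synthetic helix bundle on a curved membrane
#'
#' Straight CA traces whose midpoints lie on the sphere of radius
#' \code{RTrue} centered at \eqn{(0, 0, -R_{true})} (membrane curved down),
#' each trace along the local sphere normal, so every residue is
#' membrane-spanning in the true vesicle geometry. One helix sits at the
#' embedding origin; the others are spread on a ring of lateral extent
#' \code{lateralExtent}.
#'
#' @param RTrue true curvature radius in Angstrom (>= 50, below which the
#'   construction is not a meaningful membrane).
#' @param nHelices number of helices (>= 2).
#' @param nRes residues per helix (default 20).
#' @param lateralExtent lateral diameter of the bundle in Angstrom
#'   (default 200; must be smaller than \code{2 * RTrue}).
#' @param seed RNG seed (kept for interface symmetry; the construction is
#'   deterministic).
#' @return list with \code{structure}, \code{span} (all residues) and
#'   \code{radius} (= \code{RTrue}).
#' @examples
#' cb <- makeCurvedBundle(120, nHelices = 5)
#' cb$structure
#' @export
makeCurvedBundle <- function(RTrue, nHelices = 7, nRes = 20,
                             lateralExtent = 200, seed = 1) {
    stopifnotScalar(RTrue, "RTrue", positive = TRUE)
    if (RTrue < 50) stop("'RTrue' must be >= 50 Angstrom")
    if (nHelices < 2) stop("'nHelices' must be >= 2")
    if (lateralExtent / 2 >= RTrue) {
        stop("'lateralExtent'/2 must be smaller than 'RTrue'")
    }
    center <- c(0, 0, -RTrue)
    alpha <- asin((lateralExtent / 2) / RTrue)
    phi <- 2 * pi * (seq_len(nHelices - 1) - 1) / max(1, nHelices - 1)
    dirs <- rbind(
        c(0, 0, 1),
        cbind(sin(alpha) * cos(phi), sin(alpha) * sin(phi),
              rep(cos(alpha), length(phi)))
    )
    offsets <- (seq_len(nRes) - (nRes + 1) / 2) * 1.5
    pieces <- lapply(seq_len(nHelices), function(k) {
        mid <- center + RTrue * dirs[k, ]
        t(vapply(offsets, function(o) mid + o * dirs[k, ], numeric(3L)))
    })
    xyz <- do.call(rbind, pieces)
    st <- caTraceStructure(
        xyz,
        chainID = rep(LETTERS[seq_len(nHelices)], each = nRes),
        resNo = rep(seq_len(nRes), nHelices))
    list(
        structure = st,
        span = spanFile(cbind((seq_len(nHelices) - 1) * nRes + 1,
                              seq_len(nHelices) * nRes),
                        nRes = nHelices * nRes),
        radius = RTrue
    )
}

#' Synthetic score/RMSD funnel ensemble
#'
#' Models decoy-discrimination data with a tunable funnel quality:
#' \code{rmsd ~ |Normal(0, rmsdSd)|} and
#' \code{score = q * slope * rmsd + (1 - q) * Normal(0, slope * rmsdSd)}.
#' \code{q = 1} gives a perfect funnel (score rank = RMSD rank), \code{q = 0}
#' a score uncorrelated with RMSD.
#'
#' @param nModels number of models (>= 20).
#' @param q funnel quality in [0, 1].
#' @param seed RNG seed; identical seeds give identical tables.
#' @param slope score units per Angstrom of RMSD (default 1).
#' @param rmsdSd scale of the RMSD distribution in Angstrom (default 5).
#' @return an ensemble table (see [ensembleTable()]).
#' @examples
#' enrichment(makeFunnelEnsemble(100, q = 1))  # 10
#' @export
makeFunnelEnsemble <- function(nModels, q, seed = 1, slope = 1, rmsdSd = 5) {
    stopifnotScalar(nModels, "nModels")
    if (nModels < 20) stop("'nModels' must be >= 20")
    stopifnotScalar(q, "q")
    if (q < 0 || q > 1) stop("'q' must be in [0, 1]")
    withSeed(seed, {
        rmsd <- abs(stats::rnorm(nModels, 0, rmsdSd))
        noise <- stats::rnorm(nModels, 0, slope * rmsdSd)
        score <- q * slope * rmsd + (1 - q) * noise
        ensembleTable(score, rmsd)
    })
}
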