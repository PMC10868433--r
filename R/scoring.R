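## Burial free energy (geometry-weighted water-to-bilayer transfer) and
## residue environment classification.

## Backbone heavy atoms excluded from side-chain spreading.
.BACKBONE <- c("N", "CA", "C", "O", "OXT")

#' Construct an energy table
#'
#' @param table data.frame with columns \code{resName}, \code{atomName}
#'   (NA for residue-level rows) and \code{dG} (kcal/mol).
#' @return an \linkS4class{EnergyTable}.
#' @rdname EnergyTable-class
#' @export
energyTable <- function(table) {
    table$resName <- as.character(table$resName)
    table$atomName <- as.character(table$atomName)
    table$dG <- as.numeric(table$dG)
    new("EnergyTable", table = table[, c("resName", "atomName", "dG")])
}

#' Default water-to-bilayer transfer energies
#'
#' A residue-level side-chain transfer scale (kcal/mol, water to bilayer;
#' negative = favours the membrane core) in the style of published
#' hydrophobicity scales. These are demonstration values ("default-demo"):
#' they exercise the burial-energy mechanics and have the expected sign
#' structure (aliphatics/aromatics negative, charged residues positive), but
#' are not the parameterization of any production energy function; load a
#' calibrated table with [readEnergyTable()] for production scoring.
#'
#' @return an \linkS4class{EnergyTable} of residue-level rows.
#' @examples
#' defaultEnergyTable()
#' @export
defaultEnergyTable <- function() {
    dg <- c(
        ILE = -1.8, LEU = -1.8, PHE = -1.7, TRP = -1.9, VAL = -1.2,
        MET = -1.0, ALA = -0.3, CYS = -0.3, TYR = -0.7, GLY = 0.0,
        THR = 0.4, SER = 0.5, PRO = 0.2, HIS = 1.0, GLN = 1.5,
        ASN = 1.6, GLU = 2.0, ASP = 2.5, LYS = 2.8, ARG = 3.0
    )
    energyTable(data.frame(resName = names(dg), atomName = NA_character_,
                           dG = unname(dg), stringsAsFactors = FALSE))
}

#' Read an energy table from a file
#'
#' Whitespace- or tab-separated columns \code{resName}, \code{atomName},
#' \code{dG}; use \code{NA} or \code{.} as \code{atomName} for residue-level
#' rows and \code{resName = "*"} with \code{atomName} = element symbol for
#' element-level fallbacks.
#'
#' @param path path to the table file (with a header line).
#' @return an \linkS4class{EnergyTable}.
#' @export
readEnergyTable <- function(path) {
    tb <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    tb$atomName[tb$atomName %in% c(".", "NA", "")] <- NA_character_
    energyTable(tb)
}

## Per-atom dG assignment. Precedence: exact (resName, atomName) row;
## residue-level row spread evenly over side-chain heavy atoms (or put on CA
## when the residue has no side-chain heavy atoms, e.g. GLY or CA-only
## traces); element fallback ("*", element); otherwise 0 with a warning.
atomEnergies <- function(structure, table) {
    a <- structure@atoms
    tb <- table@table
    dG <- rep(NA_real_, nrow(a))

    atomRows <- tb[!is.na(tb$atomName) & tb$resName != "*", , drop = FALSE]
    if (nrow(atomRows)) {
        key <- paste(a$resName, a$atomName)
        m <- match(key, paste(atomRows$resName, atomRows$atomName))
        dG[!is.na(m)] <- atomRows$dG[m[!is.na(m)]]
    }

    resRows <- tb[is.na(tb$atomName), , drop = FALSE]
    if (nrow(resRows)) {
        todo <- is.na(dG) & !a$isHet
        m <- match(a$resName, resRows$resName)
        for (res in unique(a$poseResNo[todo & !is.na(m)])) {
            sel <- which(a$poseResNo == res & todo)
            resDG <- resRows$dG[m[sel[1L]]]
            heavy <- sel[!(a$atomName[sel] %in% .BACKBONE) &
                         a$element[sel] != "H"]
            if (length(heavy)) {
                dG[sel] <- 0
                dG[heavy] <- resDG / length(heavy)
            } else {
                ca <- sel[a$atomName[sel] == "CA"]
                dG[sel] <- 0
                dG[if (length(ca)) ca[1L] else sel[1L]] <- resDG
            }
        }
    }

    elemRows <- tb[tb$resName == "*" & !is.na(tb$atomName), , drop = FALSE]
    if (nrow(elemRows)) {
        todo <- is.na(dG)
        m <- match(a$element[todo], elemRows$atomName)
        dG[todo][!is.na(m)] <- elemRows$dG[m[!is.na(m)]]
    }

    if (anyNA(dG)) {
        miss <- unique(paste(a$resName, a$atomName)[is.na(dG)])
        warning("no energy-table entry for atom class(es): ",
                paste(utils::head(miss, 5L), collapse = ", "),
                if (length(miss) > 5L) ", ..." else "",
                "; scored as 0")
        dG[is.na(dG)] <- 0
    }
    dG
}

#' Membrane burial free energy
#'
#' The geometry-dependent burial free energy
#' \deqn{\Delta G_{memb} = \sum_{r=1}^{N_{res}} \sum_{a=1}^{N_{atom}^r}
#'   (1 - f_{hyd}) \, \Delta G^{atom}_{w,l},}
#' the water-to-bilayer transfer energy of each atom weighted by how buried
#' the hydration field says it is. Atoms with \eqn{f_{hyd} = 1} (fully
#' aqueous) contribute exactly zero.
#'
#' @param structure a \linkS4class{MembraneStructure}.
#' @param hydr a \linkS4class{HydrationResult} computed on \code{structure}.
#' @param table an \linkS4class{EnergyTable}
#'   (default [defaultEnergyTable()]).
#' @return a \linkS4class{BurialScore}.
#' @examples
#' helix <- makeTMHelix(21)$structure
#' burialEnergy(helix, hydration(helix, slabGeometry()))
#' @export
burialEnergy <- function(structure, hydr, table = defaultEnergyTable()) {
    stopifnot(is(structure, "MembraneStructure"),
              is(hydr, "HydrationResult"), is(table, "EnergyTable"))
    validObject(table)
    if (nrow(table@table) == 0L) stop("energy table is empty")
    if (length(hydr@fHyd) != nAtoms(structure)) {
        stop("hydration result does not match the structure")
    }
    a <- structure@atoms
    contrib <- (1 - hydr@fHyd) * atomEnergies(structure, table)
    per <- stats::aggregate(contrib,
                            by = list(poseResNo = a$poseResNo), FUN = sum)
    names(per)[2L] <- "dG"
    per$resName <- a$resName[match(per$poseResNo, a$poseResNo)]
    per <- per[order(per$poseResNo), c("poseResNo", "resName", "dG")]
    rownames(per) <- NULL
    new("BurialScore", total = sum(contrib), perResidue = per)
}

setMethod("show", "BurialScore", function(object) {
    cat(sprintf("BurialScore: dG_memb = %.3f kcal/mol over %d residues\n",
                object@total, nrow(object@perResidue)))
})

#' Classify residue membrane environments
#'
#' Labels each residue by the hydration field at a representative atom
#' (CA by default, or the side-chain heavy-atom centroid value):
#' \describe{
#'   \item{pore_facing}{\code{fCavity > 0.1} and \code{fThk < 0.75}: inside
#'     the membrane but lining the aqueous channel.}
#'   \item{lipid_facing}{otherwise, \code{fHyd < 0.25}.}
#'   \item{aqueous}{otherwise, \code{fHyd > 0.75}.}
#'   \item{interface}{the remaining residues.}
#' }
#'
#' @param structure a \linkS4class{MembraneStructure}.
#' @param hydr a \linkS4class{HydrationResult} computed on \code{structure},
#'   normally with a pore enabled (without one no residue can be pore-facing).
#' @param representative \code{"CA"} (default) or \code{"centroid"}
#'   (mean field value over side-chain heavy atoms, falling back to CA).
#' @param lipidMax,aqueousMin \code{fHyd} cut-offs for the lipid-facing and
#'   aqueous labels (defaults 0.25 / 0.75, symmetric about 0.5).
#' @return data.frame with columns \code{poseResNo}, \code{resName},
#'   \code{label} (factor with the four levels above).
#' @examples
#' pb <- makePoreBundle(4, poreRadius = 5)
#' hyd <- hydration(pb$structure, slabGeometry(), pore = pb$pore)
#' table(classifyResidues(pb$structure, hyd)$label)
#' @export
classifyResidues <- function(structure, hydr,
                             representative = c("CA", "centroid"),
                             lipidMax = 0.25, aqueousMin = 0.75) {
    representative <- match.arg(representative)
    stopifnot(is(structure, "MembraneStructure"), is(hydr, "HydrationResult"))
    if (length(hydr@fHyd) != nAtoms(structure)) {
        stop("hydration result does not match the structure")
    }
    a <- structure@atoms
    nres <- max(a$poseResNo)
    rep_fThk <- rep_fCav <- rep_fHyd <- rep(NA_real_, nres)
    ca <- caIndices(structure)
    rep_fThk[a$poseResNo[ca]] <- hydr@fThk[ca]
    rep_fCav[a$poseResNo[ca]] <- hydr@fCavity[ca]
    rep_fHyd[a$poseResNo[ca]] <- hydr@fHyd[ca]
    if (representative == "centroid") {
        sc <- !(a$atomName %in% .BACKBONE) & a$element != "H" & !a$isHet
        if (any(sc)) {
            for (res in unique(a$poseResNo[sc])) {
                sel <- sc & a$poseResNo == res
                rep_fThk[res] <- mean(hydr@fThk[sel])
                rep_fCav[res] <- mean(hydr@fCavity[sel])
                rep_fHyd[res] <- mean(hydr@fHyd[sel])
            }
        }
    }
    label <- rep("interface", nres)
    label[rep_fHyd < lipidMax] <- "lipid_facing"
    label[rep_fHyd > aqueousMin] <- "aqueous"
    label[rep_fCav > 0.1 & rep_fThk < 0.75] <- "pore_facing"
    label[is.na(rep_fHyd)] <- NA
    data.frame(
        poseResNo = seq_len(nres),
        resName = a$resName[match(seq_len(nres), a$poseResNo)],
        label = factor(label, levels = c("pore_facing", "lipid_facing",
                                         "aqueous", "interface")),
        stringsAsFactors = FALSE
    )
}
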