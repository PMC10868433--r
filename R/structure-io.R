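## PDB structure input/output and B-factor annotation. Reading goes through
## bio3d; a pre-validation pass supplies line-numbered errors for malformed
## ATOM/HETATM records, and the writer emits fixed-column PDB v3.3 records
## (coordinates %8.3f in columns 31-54, B-factor %6.2f in columns 61-66).

## Build a MembraneStructure from a raw atom data.frame, assigning 1-based
## pose residue numbering by order of first appearance of (chain, resNo,
## insert code).
newMembraneStructure <- function(df) {
    key <- paste(df$chainID, df$resNo, df$insert %||% "", sep = "|")
    df$poseResNo <- as.integer(factor(key, levels = unique(key)))
    df$insert <- NULL
    df <- df[, .STRUCTURE_COLS]
    rownames(df) <- NULL
    new("MembraneStructure", atoms = df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records into a
#' \linkS4class{MembraneStructure}. HETATM records are retained and flagged
#' via the \code{isHet} column. Only the first alternate location of an atom
#' is kept (others dropped with a warning). Malformed ATOM records raise an
#' error naming the offending line.
#'
#' @param path path to a PDB file with at least one ATOM record.
#' @return a \linkS4class{MembraneStructure}.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writePDB(makeTMHelix(11)$structure, pdb)
#' readPDB(pdb)
#' @export
readPDB <- function(path) {
    if (!file.exists(path)) stop("PDB file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    rec <- substr(lines, 1L, 6L)
    isAtom <- rec %in% c("ATOM  ", "HETATM")
    if (!any(isAtom)) stop("no ATOM/HETATM records in ", path)
    for (i in which(isAtom)) {
        ln <- lines[i]
        coordsTxt <- c(substr(ln, 31L, 38L), substr(ln, 39L, 46L),
                       substr(ln, 47L, 54L))
        vals <- suppressWarnings(as.numeric(coordsTxt))
        if (nchar(ln) < 54L || any(is.na(vals))) {
            stop(sprintf("malformed ATOM record at line %d of %s", i, path))
        }
    }
    pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    a <- pdb$atom
    ## keep the first altloc per (chain, resNo, insert, atom name)
    alt <- ifelse(is.na(a$alt), "", a$alt)
    if (any(alt != "")) {
        key <- paste(a$chain, a$resno, ifelse(is.na(a$insert), "", a$insert),
                     a$elety, sep = "|")
        keep <- !duplicated(key)
        if (any(!keep)) {
            warning(sum(!keep), " alternate-location atom(s) dropped")
            a <- a[keep, , drop = FALSE]
        }
    }
    element <- ifelse(is.na(a$elesy) | a$elesy == "",
                      substr(gsub("[^A-Za-z].*", "", a$elety), 1L, 1L),
                      a$elesy)
    df <- data.frame(
        serial = as.integer(a$eleno),
        atomName = a$elety,
        altLoc = ifelse(is.na(a$alt), "", a$alt),
        resName = a$resid,
        chainID = ifelse(is.na(a$chain), "A", a$chain),
        resNo = as.integer(a$resno),
        insert = ifelse(is.na(a$insert), "", a$insert),
        x = a$x, y = a$y, z = a$z,
        bFactor = ifelse(is.na(a$b), 0, a$b),
        element = element,
        isHet = a$type == "HETATM",
        stringsAsFactors = FALSE
    )
    newMembraneStructure(df)
}

#' Write a PDB file
#'
#' Emits fixed-column PDB v3.3 ATOM/HETATM records (occupancy 1.00,
#' B-factor \code{\%6.2f}) followed by END.
#'
#' @param structure a \linkS4class{MembraneStructure}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writePDB <- function(structure, path) {
    stopifnot(is(structure, "MembraneStructure"))
    validObject(structure)
    a <- structure@atoms
    ## PDB atom-name column quirk: names of up to 3 characters start in
    ## column 14; 4-character names fill columns 13-16.
    name4 <- ifelse(nchar(a$atomName) >= 4L,
                    substr(a$atomName, 1L, 4L),
                    sprintf(" %-3s", a$atomName))
    lines <- sprintf(
        "%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ifelse(a$isHet, "HETATM", "ATOM"),
        a$serial %% 100000L, name4, "", a$resName, a$chainID,
        a$resNo %% 10000L, "", a$x, a$y, a$z, 1, a$bFactor,
        substr(a$element, 1L, 2L))
    writeLines(c(lines, "END"), path)
    invisible(path)
}

#' Annotate B-factors with hydration values
#'
#' Writes the composed hydration value \code{fHyd} of each atom into the
#' structure's B-factor slot, rounded to the PDB \code{\%6.2f} precision, so
#' the membrane placement can be inspected in a molecular viewer (color by
#' B-factor: 0 = hydrophobic core, 1 = aqueous). Coordinates and all other
#' fields are untouched.
#'
#' @param structure a \linkS4class{MembraneStructure}.
#' @param hydr a \linkS4class{HydrationResult} computed on \code{structure}.
#' @return the annotated \linkS4class{MembraneStructure}.
#' @examples
#' helix <- makeTMHelix(11)$structure
#' annotated <- mapTransitionToBfactor(helix, hydration(helix, slabGeometry()))
#' range(bFactors(annotated))
#' @export
mapTransitionToBfactor <- function(structure, hydr) {
    stopifnot(is(structure, "MembraneStructure"), is(hydr, "HydrationResult"))
    if (length(hydr@fHyd) != nAtoms(structure)) {
        stop("hydration result has ", length(hydr@fHyd),
             " values but structure has ", nAtoms(structure), " atoms")
    }
    bFactors(structure) <- round(hydr@fHyd, 2L)
    structure
}

## ---------------------------------------------------------------------------
## Accessors and show
## ---------------------------------------------------------------------------

#' @rdname MembraneStructure-class
#' @export
setMethod("atoms", "MembraneStructure", function(object) object@atoms)

#' @rdname MembraneStructure-class
#' @export
setMethod("coords", "MembraneStructure", function(object) {
    as.matrix(object@atoms[, c("x", "y", "z")])
})

#' @rdname MembraneStructure-class
#' @export
setMethod("bFactors", "MembraneStructure",
          function(object) object@atoms$bFactor)

#' @rdname MembraneStructure-class
#' @export
setReplaceMethod("bFactors", "MembraneStructure", function(object, value) {
    if (length(value) != nrow(object@atoms)) {
        stop("replacement B-factors must match the atom count")
    }
    object@atoms$bFactor <- as.numeric(value)
    object
})

#' @rdname MembraneStructure-class
#' @export
setMethod("nAtoms", "MembraneStructure",
          function(object) nrow(object@atoms))

#' @rdname MembraneStructure-class
#' @export
setMethod("nResidues", "MembraneStructure",
          function(object) max(object@atoms$poseResNo))

setMethod("show", "MembraneStructure", function(object) {
    a <- object@atoms
    cat(sprintf(
        "MembraneStructure: %d atoms, %d residues, %d chain(s)%s\n",
        nrow(a), max(a$poseResNo), length(unique(a$chainID)),
        if (any(a$isHet)) sprintf(" (%d HETATM)", sum(a$isHet)) else ""))
    cat(sprintf("  z range: [%.1f, %.1f] A\n", min(a$z), max(a$z)))
})

## CA row indices per pose residue; residues without a CA are skipped with a
## warning (they cannot take part in CA-based operations).
caIndices <- function(structure, warnMissing = TRUE) {
    a <- structure@atoms
    idx <- which(a$atomName == "CA" & !a$isHet)
    found <- a$poseResNo[idx]
    idx <- idx[!duplicated(found)]
    nres <- max(a$poseResNo)
    if (warnMissing && length(idx) < nres) {
        warning(nres - length(idx),
                " residue(s) without a CA atom excluded")
    }
    idx
}
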