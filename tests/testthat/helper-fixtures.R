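## Shared fixtures: all built in code at test time.

## Central finite-difference gradient of a scalar field over an n x 3 matrix.
fdGradientField <- function(f, pos, h = 1e-4) {
    g <- matrix(0, nrow(pos), 3L)
    for (j in 1:3) {
        e <- matrix(0, nrow(pos), 3L)
        e[, j] <- h
        g[, j] <- (f(pos + e) - f(pos - e)) / (2 * h)
    }
    g
}

## Write a CA-only PDB for arbitrary coordinates and read it back, giving a
## MembraneStructure with full control over positions.
caStructure <- function(xyz, chainID = "A", resName = "ALA") {
    xyz <- matrix(xyz, ncol = 3L)
    n <- nrow(xyz)
    if (length(chainID) == 1L) chainID <- rep(chainID, n)
    lines <- sprintf(
        "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_len(n), resName, chainID, ave(seq_len(n), chainID, FUN = seq_along),
        xyz[, 1], xyz[, 2], xyz[, 3])
    path <- tempfile(fileext = ".pdb")
    writeLines(c(lines, "END"), path)
    readPDB(path)
}

## All four geometries with representative parameters, for property loops.
allGeometries <- function() {
    list(
        slab = slabGeometry(),
        micelle = ellipsoidGeometry(0),
        bicelle = ellipsoidGeometry(20),
        vesicle = vesicleGeometry(120),
        double_vesicle = doubleVesicleGeometry(1000, 40)
    )
}

## Composed hydration field as a plain function of positions, for oracles.
fieldFunction <- function(geometry, pore = NULL,
                          params = TransitionParams()) {
    function(pos) {
        fg <- transitionValue(geometry, pos, params)
        if (is.null(pore)) return(fg)
        composePore(fg, poreTransition(pore, pos))
    }
}
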