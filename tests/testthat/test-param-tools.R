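test_that("default bicelle radius is 1.5x the max CA-CA cross-section", {
    ## two CAs at (+-10, 0, 0): max distance 20, halved = 10, x3 = 30
    st <- caStructure(rbind(c(10, 0, 0), c(-10, 0, 0)))
    expect_equal(defaultBicelleRadius(st), 30)
    ## CAs outside the 3 A slice are ignored
    st2 <- caStructure(rbind(c(10, 0, 0), c(-10, 0, 0), c(40, 0, 8)))
    expect_equal(defaultBicelleRadius(st2), 30)
    ## all CAs away from the membrane center: instructive error
    far <- caStructure(rbind(c(0, 0, 5), c(0, 0, 9)))
    expect_error(defaultBicelleRadius(far), "explicitly")
    ## invariant under rotation about z
    set.seed(5)
    xyz <- cbind(runif(20, -30, 30), runif(20, -30, 30), runif(20, -2, 2))
    th <- 0.83
    rot <- xyz %*% rbind(c(cos(th), sin(th), 0),
                         c(-sin(th), cos(th), 0),
                         c(0, 0, 1))
    ## (tolerance covers the %8.3f coordinate quantization of the PDB writer)
    expect_equal(defaultBicelleRadius(caStructure(rot)),
                 defaultBicelleRadius(caStructure(xyz)), tolerance = 1e-3)
})

test_that("bicelle size check warns exactly when the rule says so", {
    ## construct a 40 A cross-section at the membrane center
    st <- caStructure(rbind(c(20, 0, 1), c(-20, 0, -1), c(0, 0, 30)))
    expect_warning(res <- checkBicelleSize(st, ellipsoidGeometry(19)),
                   "larger than the bicelle")
    expect_false(res$ok)
    expect_silent(res2 <- checkBicelleSize(st, ellipsoidGeometry(21)))
    expect_true(res2$ok)
    expect_equal(res$maxDistance, sqrt(40^2 + 2^2))
    ## agrees with an independent O(N^2) scan on a random cloud
    set.seed(8)
    st8 <- caStructure(cbind(runif(40, -50, 50), runif(40, -50, 50),
                             runif(40, -10, 10)))
    xyz <- coords(st8)
    sel <- abs(xyz[, 3]) <= 3
    bf <- 0
    pts <- xyz[sel, , drop = FALSE]
    for (i in seq_len(nrow(pts))) {
        for (j in seq_len(nrow(pts))) {
            bf <- max(bf, sqrt(sum((pts[i, ] - pts[j, ])^2)))
        }
    }
    res3 <- suppressWarnings(checkBicelleSize(st8, ellipsoidGeometry(10)))
    expect_equal(res3$maxDistance, bf)
    ## no atoms near z = 0: vacuously ok
    high <- caStructure(rbind(c(0, 0, 20), c(5, 0, 25)))
    expect_silent(resV <- checkBicelleSize(high, ellipsoidGeometry(1)))
    expect_true(resV$ok)
})

## A flat bundle: straight vertical CA traces spread laterally, all residues
## membrane-spanning, so the flattest vesicle candidate matches best.
flatBundle <- function(nHelices = 5, nRes = 19, extent = 160) {
    offs <- seq(-extent / 2, extent / 2, length.out = nHelices)
    z <- (seq_len(nRes) - (nRes + 1) / 2) * 1.5
    xyz <- do.call(rbind, lapply(offs, function(o) cbind(o, 0, z)))
    st <- caStructure(xyz, chainID = rep(LETTERS[seq_len(nHelices)],
                                         each = nRes))
    span <- spanFile(cbind((seq_len(nHelices) - 1) * nRes + 1,
                           seq_len(nHelices) * nRes), nRes = nHelices * nRes)
    list(structure = st, span = span)
}

test_that("optimizer prefers the flattest vesicle for a flat bundle", {
    fb <- flatBundle()
    rep <- optimizeGeometryParams(fb$structure, fb$span, "vesicle")
    expect_equal(rep$best$radius, 1e6)
    expect_equal(rep$objective, 1)
})

test_that("vesicle grid search recovers the curvature radius of the bundle", {
    cb <- makeCurvedBundle(120, nHelices = 7)
    rep <- optimizeGeometryParams(cb$structure, cb$span, "vesicle")
    expect_lte(abs(rep$best$radius - 120), 20) # within one grid step
    expect_identical(rep$best$curvature, "down")
    ## curvature is real: the flat membrane fits these spans worse
    slabScore <- optimizeGeometryParams(cb$structure, cb$span,
                                        "slab")$objective
    expect_gt(rep$objective, slabScore)
})

test_that("objective equals a brute-force recomputation on a small grid", {
    cb <- makeCurvedBundle(120, nHelices = 5)
    grid <- data.frame(radius = c(80, 100, 120, 140, 1e6),
                       curvature = "down", stringsAsFactors = FALSE)
    rep <- optimizeGeometryParams(cb$structure, cb$span, "vesicle",
                                  grid = grid)
    ## independent oracle: direct field evaluation + set arithmetic
    a <- atoms(cb$structure)
    ca <- which(a$atomName == "CA")
    spanSet <- spanResidues(cb$span)
    bruteScores <- vapply(seq_len(nrow(grid)), function(i) {
        g <- vesicleGeometry(grid$radius[i], grid$curvature[i])
        f <- transitionValue(g, coords(cb$structure)[ca, ])
        hydro <- a$poseResNo[ca][f < 0.5]
        length(intersect(hydro, spanSet)) / length(union(hydro, spanSet))
    }, numeric(1))
    expect_equal(rep$grid$score, bruteScores)
    expect_equal(rep$best$radius, grid$radius[which.max(bruteScores)])
})

test_that("spanfile-marked-everything slab objective is the hydrophobic fraction", {
    helix <- makeTMHelix(31)
    allSpan <- spanFile(c(1, 31), nRes = 31)
    rep <- optimizeGeometryParams(helix$structure, allSpan, "slab")
    f <- transitionValue(slabGeometry(), coords(helix$structure))
    expect_equal(rep$objective, sum(f < 0.5) / 31)
})

test_that("optimizer tolerates small span-boundary perturbations", {
    cb <- makeCurvedBundle(120, nHelices = 4, nRes = 20)
    s <- spans(cb$span)
    perturbed <- spanFile(cbind(pmax(1, s[, 1] + 2), s[, 2] - 2),
                          nRes = cb$span@nRes)
    expect_no_error(
        rep <- optimizeGeometryParams(cb$structure, perturbed, "vesicle"))
    expect_true(is.finite(rep$objective))
    expect_error(optimizeGeometryParams(cb$structure, cb$span, "vesicle",
                                        grid = data.frame(radius = numeric(),
                                                          curvature = character())),
                 "empty")
})
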