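## Burial energy uses a custom atom-level table so expected values are exact
## hand sums; the default residue-level table is exercised separately.

test_that("burial energy is the hydration-weighted transfer sum", {
    ## two atoms with f_hyd = (0.25, 0.75) and dG = (-2, +4):
    ## (1-0.25)*(-2) + (1-0.75)*4 = -1.5 + 1.0 = -0.5
    st <- caStructure(rbind(c(0, 0, 5), c(0, 0, 10)))
    fake <- new("HydrationResult", fThk = c(0.25, 0.75),
                fCavity = c(0, 0), fHyd = c(0.25, 0.75),
                geometry = slabGeometry(), pore = NULL,
                params = TransitionParams())
    score <- burialEnergy(st, fake,
                          energyTable(data.frame(resName = "ALA",
                                                 atomName = "CA", dG = -2)))
    expect_equal(score@total, (1 - 0.25) * -2 + (1 - 0.75) * -2)
    ## mixed-sign hand sum via residue-level table on two residues
    stMix <- caStructure(rbind(c(0, 0, 5), c(0, 0, 10)),
                         resName = c("LEU", "ARG"))
    tbMix <- energyTable(data.frame(resName = c("LEU", "ARG"),
                                    atomName = NA, dG = c(-2, 4)))
    sMix <- burialEnergy(stMix, fake, tbMix)
    expect_equal(sMix@total, -0.5)
    expect_equal(sum(sMix@perResidue$dG), sMix@total)
})

test_that("fully aqueous atoms contribute exactly zero", {
    st <- makeTMHelix(21)$structure
    n <- nAtoms(st)
    aq <- new("HydrationResult", fThk = rep(1, n), fCavity = rep(0, n),
              fHyd = rep(1, n), geometry = slabGeometry(), pore = NULL,
              params = TransitionParams())
    expect_identical(burialEnergy(st, aq)@total, 0)
    buried <- new("HydrationResult", fThk = rep(0, n), fCavity = rep(0, n),
                  fHyd = rep(0, n), geometry = slabGeometry(), pore = NULL,
                  params = TransitionParams())
    ## full burial: total equals the plain sum of the table values (ALA trace)
    expect_equal(burialEnergy(st, buried)@total,
                 n * defaultEnergyTable()@table$dG[
                     defaultEnergyTable()@table$resName == "ALA"])
})

test_that("burial energy is linear in the table and monotone in burial", {
    st <- makeTMHelix(21)$structure
    hyd <- hydration(st, slabGeometry())
    tb <- defaultEnergyTable()
    s1 <- burialEnergy(st, hyd, tb)
    tb3 <- energyTable(transform(tb@table, dG = dG * 3))
    expect_equal(burialEnergy(st, hyd, tb3)@total, 3 * s1@total)
    ## moving a hydrophobic atom from aqueous to buried lowers the energy
    stL <- caStructure(c(0, 0, 0), resName = "LEU")
    tbL <- energyTable(data.frame(resName = "LEU", atomName = NA, dG = -1.8))
    mk <- function(f) new("HydrationResult", fThk = f, fCavity = 0, fHyd = f,
                          geometry = slabGeometry(), pore = NULL,
                          params = TransitionParams())
    expect_lt(burialEnergy(stL, mk(0), tbL)@total,
              burialEnergy(stL, mk(1), tbL)@total)
    expect_error(burialEnergy(st, hyd,
                              energyTable(data.frame(resName = character(),
                                                     atomName = character(),
                                                     dG = numeric()))),
                 "empty")
})

test_that("unknown atom classes fall back to element rows or zero", {
    st <- caStructure(c(0, 0, 0), resName = "XXX")
    hyd <- hydration(st, slabGeometry())
    expect_warning(s0 <- burialEnergy(st, hyd, defaultEnergyTable()),
                   "scored as 0")
    expect_identical(s0@total, 0)
    withElem <- energyTable(data.frame(resName = c("LEU", "*"),
                                       atomName = c(NA, "C"),
                                       dG = c(-1.8, -0.25)))
    expect_silent(sE <- burialEnergy(st, hyd, withElem))
    expect_equal(sE@total, -0.25)
})

test_that("pore-facing classification follows the fcavity/fthk thresholds", {
    mkHyd <- function(fc, ft) {
        new("HydrationResult", fThk = ft, fCavity = fc,
            fHyd = composePore(ft, fc), geometry = slabGeometry(),
            pore = poreSpec(radius = 5), params = TransitionParams())
    }
    st <- caStructure(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)))
    ## constructed values straddling the two §-rule thresholds
    hyd <- mkHyd(fc = c(0.2, 0.05, 0.2), ft = c(0.5, 0.5, 0.9))
    lab <- classifyResidues(st, hyd)$label
    expect_identical(as.character(lab[1]), "pore_facing")
    expect_false(lab[2] == "pore_facing") # cavity below 0.1
    expect_false(lab[3] == "pore_facing") # thk above 0.75
    ## boundary values are exclusive
    labB <- classifyResidues(st, mkHyd(fc = c(0.1, 0.100001, 0.2),
                                       ft = c(0.5, 0.5, 0.75)))$label
    expect_false(labB[1] == "pore_facing")
    expect_identical(as.character(labB[2]), "pore_facing")
    expect_false(labB[3] == "pore_facing")
})

test_that("lipid/aqueous/interface labels partition the remainder", {
    ## atoms well off the pore axis so f_cavity is negligible
    st <- caStructure(rbind(c(8, 0, 0), c(8, 0, 15), c(8, 0, 60)))
    hyd <- hydration(st, slabGeometry(), pore = poreSpec(radius = 1))
    lab <- classifyResidues(st, hyd)$label
    expect_identical(as.character(lab), c("lipid_facing", "interface",
                                          "aqueous"))
})

test_that("classification is invariant to atom order and chain relabeling", {
    pb <- makePoreBundle(4, poreRadius = 5)
    hyd <- hydration(pb$structure, slabGeometry(), pore = pb$pore)
    lab1 <- classifyResidues(pb$structure, hyd)
    ## same atoms, chains renamed and helix blocks written in reverse order
    a <- atoms(pb$structure)
    perm <- order(-as.integer(factor(a$chainID)), a$resNo)
    st2 <- caStructure(coords(pb$structure)[perm, ],
                       chainID = chartr("ABCD", "WXYZ", a$chainID[perm]))
    hyd2 <- hydration(st2, slabGeometry(), pore = pb$pore)
    lab2 <- classifyResidues(st2, hyd2)
    ## compare by atom identity: map pose residues through the permutation
    expect_identical(as.character(lab2$label),
                     as.character(lab1$label[a$poseResNo[perm]][
                         !duplicated(a$poseResNo[perm])]))
})
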