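test_that("slab transition has the right fixed points and shape", {
    p <- TransitionParams(halfThickness = 15, steepness = 10)
    expect_identical(fThkSlab(0, p), 0)
    expect_equal(fThkSlab(15, p), 0.5)
    expect_equal(fThkSlab(-15, p), 0.5)
    expect_lt(abs(fThkSlab(1e4 * 15, p) - 1), 1e-6)
    ## symmetric and monotone in |z|
    z <- seq(0, 60, by = 0.5)
    f <- fThkSlab(z, p)
    expect_equal(fThkSlab(-z, p), f)
    expect_true(all(diff(f) >= 0))
    expect_error(fThkSlab(NaN, p), "finite")
    expect_error(TransitionParams(halfThickness = -1), "positive")
})

test_that("ellipsoid field composes slab depth with the radial factor", {
    p <- TransitionParams()
    mic <- ellipsoidGeometry(0)
    expect_identical(transitionValue(mic, c(0, 0, 0), p), 0)
    ## outer-radius surface in the z = 0 plane: h = 0.5, f_thk = 0
    expect_equal(transitionValue(mic, c(15, 0, 0), p), 0.5)
    ## deep water above the membrane: f_thk ~ 1 is an absorbing fixed point
    expect_lt(abs(transitionValue(mic, c(0, 0, 5000), p) - 1), 1e-6)
    expect_lt(abs(transitionValue(ellipsoidGeometry(30), c(0, 0, 5000), p) - 1),
              1e-6)
    ## hand-evaluated composition at a generic point for a bicelle:
    ## r = a + sqrt((rho - a)^2 + z^2), h = g(r / (a + t)), f = soft union
    a <- 20
    pos <- c(30, 0, 8)
    r <- a + sqrt((30 - a)^2 + 8^2)
    h <- (r / (a + 15))^10 / (1 + (r / (a + 15))^10)
    fz <- (8 / 15)^10 / (1 + (8 / 15)^10)
    expect_equal(transitionValue(ellipsoidGeometry(a), pos, p),
                 fz + h - fz * h)
    expect_error(ellipsoidGeometry(-5), "innerRadius")
})

test_that("micelle is bit-for-bit the ellipsoid with inner radius zero", {
    set.seed(7)
    pos <- matrix(runif(300, -40, 40), ncol = 3)
    expect_identical(transitionValue(ellipsoidGeometry(0), pos),
                     transitionValue(ellipsoidGeometry(innerRadius = 0), pos))
    ## and inside the planar disc a bicelle looks exactly like the slab
    b <- ellipsoidGeometry(50)
    inner <- cbind(runif(50, -20, 20), runif(50, -20, 20), runif(50, -60, 60))
    inner <- inner[sqrt(inner[, 1]^2 + inner[, 2]^2) <= 50, , drop = FALSE]
    zOnly <- fThkSlab(inner[, 3])
    h <- transitionValue(b, inner) # f = fz + h - fz h with r = a + |z|
    r <- 50 + abs(inner[, 3])
    hExp <- (r / 65)^10 / (1 + (r / 65)^10)
    expect_equal(h, zOnly + hExp - zOnly * hExp)
})

test_that("vesicle field is the slab field in signed radial depth", {
    p <- TransitionParams()
    v <- vesicleGeometry(100)
    expect_identical(transitionValue(v, c(0, 0, 0), p), 0)
    ## curvature sign: down puts the center at (0, 0, -R), so a point below
    ## the origin is inside the sphere (toward water on the other side)
    down <- vesicleGeometry(100, "down")
    up <- vesicleGeometry(100, "up")
    expect_equal(transitionValue(down, c(0, 0, 30), p),
                 transitionValue(up, c(0, 0, -30), p))
    ## radial depth oracle at a generic point
    pos <- c(40, -20, 10)
    d <- sqrt(sum((pos - c(0, 0, -100))^2)) - 100
    expect_equal(transitionValue(down, pos, p), fThkSlab(d, p))
    expect_error(vesicleGeometry(-10), "radius")
})

test_that("vesicle at huge radius converges to the slab (sup over 50 A box)", {
    set.seed(11)
    pos <- matrix(runif(3000, -25, 25), ncol = 3)
    v <- transitionValue(vesicleGeometry(1e6), pos)
    s <- transitionValue(slabGeometry(), pos)
    expect_lt(max(abs(v - s)), 1e-4)
})

test_that("double vesicle is the product of two concentric sphere fields", {
    p <- TransitionParams()
    dv <- doubleVesicleGeometry(innerRadius = 1000, distance = 40)
    ## §-style config accepted: d = 40, inner radius 1000
    expect_s4_class(dv, "DoubleVesicleGeometry")
    ## on the inner mid-surface the field is 0
    expect_equal(transitionValue(dv, c(0, 0, 1000), p), 0)
    expect_equal(transitionValue(dv, c(1000, 0, 0), p), 0)
    ## on the outer mid-surface (radius 1000 + 30 + 40) too
    expect_equal(transitionValue(dv, c(0, 0, 1070), p), 0)
    ## midway between widely separated membranes both factors are ~ 1
    far <- doubleVesicleGeometry(1000, 200 * 15)
    mid <- c(0, 0, 1000 + 15 + 100 * 15)
    expect_lt(abs(transitionValue(far, mid, p) - 1), 1e-3)
    ## product oracle against two explicit vesicle-style fields
    set.seed(3)
    pos <- sweep(matrix(runif(300, -40, 40), ncol = 3), 2, c(0, 0, 1035), "+")
    r <- sqrt(rowSums(pos^2))
    expect_equal(transitionValue(dv, pos, p),
                 fThkSlab(r - 1000, p) * fThkSlab(r - 1070, p))
    expect_error(doubleVesicleGeometry(-1, 40), "innerRadius")
    expect_error(doubleVesicleGeometry(1000, -4), "distance")
})

test_that("double vesicle at huge radius converges to a two-slab product", {
    set.seed(13)
    base <- 1e6
    d <- 40
    pos <- matrix(runif(3000, -25, 25), ncol = 3)
    pos[, 3] <- pos[, 3] + base + 35 # box straddling the inter-membrane gap
    dv <- transitionValue(doubleVesicleGeometry(base, d), pos)
    twoSlab <- fThkSlab(pos[, 3] - base) * fThkSlab(pos[, 3] - (base + 30 + d))
    expect_lt(max(abs(dv - twoSlab)), 1e-4)
})

test_that("pore field: 1 on the axis, 0.5 at rho0, vanishing far away", {
    pore <- poreSpec(radius = 5, steepness = 10)
    expect_identical(poreTransition(pore, c(0, 0, 7)), 1)
    expect_equal(poreTransition(pore, c(5, 0, 0)), 0.5)
    expect_lt(poreTransition(pore, c(5000, 0, 0)), 1e-6)
    ## monotone non-increasing in rho, off-axis pores respected
    rho <- seq(0, 30, by = 0.25)
    f <- poreTransition(pore, cbind(rho, 0, 0))
    expect_true(all(diff(f) <= 0))
    shifted <- poreSpec(radius = 5, x0 = 3, y0 = -2)
    expect_identical(poreTransition(shifted, c(3, -2, 10)), 1)
    expect_identical(poreTransition(poreSpec(radius = 5, enabled = FALSE),
                                    c(0, 0, 0)), 0)
    expect_error(poreSpec(radius = 0), "radius")
})

test_that("pore composition is a bounded soft union", {
    expect_identical(composePore(0, 0), 0)
    expect_identical(composePore(1, 0.37), 1)
    expect_identical(composePore(0.37, 1), 1)
    expect_equal(composePore(0.5, 0.5), 0.75)
    set.seed(21)
    a <- runif(1e5)
    b <- runif(1e5)
    f <- composePore(a, b)
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(f >= pmax(a, b) - 1e-15))
    expect_equal(composePore(a, b), composePore(b, a))
    expect_identical(composePore(a, numeric(length(a)) ), a)
    expect_error(composePore(1.2, 0), "\\[0, 1\\]")
    expect_error(composePore(0.3, -0.1), "\\[0, 1\\]")
})

test_that("every geometry stays in [0, 1] under random params and positions", {
    set.seed(31)
    nPos <- 1e5
    pos <- matrix(runif(3 * nPos, -200, 200), ncol = 3)
    for (rep in 1:3) {
        p <- TransitionParams(halfThickness = runif(1, 5, 30),
                              steepness = runif(1, 2, 16))
        geoms <- list(
            slabGeometry(),
            ellipsoidGeometry(runif(1, 0, 60)),
            vesicleGeometry(runif(1, 60, 500),
                            sample(c("down", "up"), 1)),
            doubleVesicleGeometry(runif(1, 100, 2000), runif(1, 0, 300))
        )
        for (g in geoms) {
            f <- transitionValue(g, pos, p)
            expect_true(all(is.finite(f) & f >= 0 & f <= 1))
        }
    }
})

test_that("analytic gradients match central finite differences", {
    set.seed(41)
    p <- TransitionParams()
    pore <- poreSpec(radius = 6, x0 = 2, y0 = -1)
    for (nm in names(allGeometries())) {
        geom <- allGeometries()[[nm]]
        n <- 250
        pos <- matrix(runif(3 * n, -45, 45), ncol = 3)
        if (is(geom, "DoubleVesicleGeometry")) {
            pos[, 3] <- pos[, 3] + 1035
        }
        analytic <- gradientFHyd(pos, geom, pore, p)
        fd <- fdGradientField(fieldFunction(geom, pore, p), pos)
        expect_lt(max(abs(analytic - fd) / pmax(1, abs(fd))), 1e-6,
                  label = paste("gradient error for", nm))
    }
})

test_that("slab gradient is purely axial and zero at the midplane", {
    g <- transitionGradient(slabGeometry(), rbind(c(3, -9, 12), c(0, 0, 0)))
    expect_identical(g[, 1:2], matrix(0, 2, 2))
    expect_identical(g[2, 3], 0)
})

test_that("gradients at removable singularities are defined zero + warning", {
    v <- vesicleGeometry(100)
    expect_warning(g <- transitionGradient(v, c(0, 0, -100)), "center")
    expect_identical(g, matrix(0, 1, 3))
    ## pore axis: smooth maximum, zero without complaint
    g2 <- gradientFHyd(c(0, 0, 3), slabGeometry(), poreSpec(radius = 5))
    expect_identical(g2[1, 1:2], c(0, 0))
})

test_that("non-finite positions are rejected", {
    expect_error(transitionValue(slabGeometry(), c(0, 0, Inf)), "finite")
    expect_error(transitionValue(vesicleGeometry(100), c(NA, 0, 0)), "finite")
})
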