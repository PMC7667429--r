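# Microscopy features: basal-plane selection, nuclear morphometry, interface
# extraction and the triangulated contour.

test_that("basal plane selection: spacing arithmetic and contracts", {
    st <- new("NLOMStack", mpm = array(0, c(8, 8, 40)),
              shg = array(0, c(8, 8, 40)), pixelSize = 0.625, zStep = 1,
              bitDepth = 8)
    expect_equal(selectBasalPlanes(st, basalHint = 19, spacing = 5),
                 c(15L, 20L, 25L))
    expect_error(selectBasalPlanes(st, 19, spacing = 12), "\\[5, 10\\]")
    shallow <- new("NLOMStack", mpm = array(0, c(8, 8, 8)),
                   shg = array(0, c(8, 8, 8)), pixelSize = 0.625, zStep = 1,
                   bitDepth = 8)
    expect_error(selectBasalPlanes(shallow, 4, spacing = 5), "too shallow")
})

test_that("ellipse area uses axis lengths: closed forms and contracts", {
    expect_equal(ellipseArea(2, 2), pi)
    expect_equal(ellipseArea(10, 5), pi * 10 * 5 / 4)
    expect_equal(ellipseArea(10, 5), 39.2699, tolerance = 1e-5)
    expect_error(ellipseArea(10, 0), "> 0")
    expect_error(ellipseArea(5, 10), "exceeds")
})

test_that("polygon moments: a square's moment-equivalent ellipse", {
    s <- 10
    sq <- cbind(c(0, s, s, 0), c(0, 0, s, s))
    pm <- polygonMoments(sq)
    expect_equal(pm$area, s^2)
    expect_equal(pm$centroid, c(s / 2, s / 2))
    ## axis of the moment-matched ellipse: 4 * sqrt(s^2 / 12)
    expect_equal(pm$major, 4 * s / sqrt(12))
    expect_equal(pm$minor, 4 * s / sqrt(12))
    expect_error(polygonMoments(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")

    out <- delineateNuclei(matrix(1, 4, 4), "manual", outlines = list(sq),
                           pixelSize = 2)
    expect_equal(out$major, 4 * s / sqrt(12) * 2)
})

test_that("automatic delineation recovers planted circular nuclei within a pixel", {
    px <- 0.625
    plane <- matrix(120, 128, 128)
    d_um <- 7                                  # diameter, um
    centers <- rbind(c(30, 30), c(30, 90), c(90, 30), c(90, 90), c(64, 64))
    r <- d_um / 2 / px
    for (i in seq_len(nrow(centers))) {
        rr <- outer((1:128 - centers[i, 1])^2, rep(1, 128))
        cc <- outer(rep(1, 128), (1:128 - centers[i, 2])^2)
        plane[rr + cc <= r^2] <- 20
    }
    out <- delineateNuclei(plane, "automatic", pixelSize = px)
    expect_equal(nrow(out), 5)
    expect_true(all(abs(out$major - d_um) < px))
    expect_true(all(abs(out$minor - d_um) < px))

    expect_error(delineateNuclei(matrix(120, 64, 64), "automatic"), "blank")
    expect_error(delineateNuclei(plane, "manual"), "requires outlines")
})

test_that("site CoVa: hand arithmetic, pooling and scale invariance", {
    eq <- data.frame(major = rep(4, 5), minor = rep(4, 5))
    expect_equal(cova(suppressWarnings(siteCova(eq))), 0)

    ## areas {8, 12}: mean 10, sample sd 2.8284, CoVa 0.2828
    d1 <- sqrt(4 * 8 / pi); d2 <- sqrt(4 * 12 / pi)
    two <- data.frame(major = c(d1, d2), minor = c(d1, d2))
    m <- suppressWarnings(siteCova(two))
    expect_equal(m@meanArea, 10)
    expect_equal(m@sdArea, sqrt(8), tolerance = 1e-12)
    expect_equal(cova(m), sqrt(8) / 10, tolerance = 1e-12)

    ## scaling all areas by k > 0 leaves CoVa unchanged; order irrelevant
    set.seed(2)
    o <- data.frame(major = runif(70, 5, 9))
    o$minor <- o$major * runif(70, 0.6, 1)
    base <- cova(siteCova(o))
    expect_equal(cova(siteCova(transform(o, major = major * sqrt(3),
                                         minor = minor * sqrt(3)))), base)
    expect_equal(cova(siteCova(o[sample(70), ])), base)
    expect_warning(siteCova(two), "fewer than 60")
    expect_error(siteCova(o[1, , drop = FALSE]), "at least 2")
})

test_that("Heron triangle area: closed forms and cross-product oracle", {
    expect_equal(heronArea(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)), 6)
    expect_equal(heronArea(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 0)
    set.seed(7)
    for (i in 1:200) {
        p <- matrix(rnorm(9, sd = 10), 3, 3)
        crossArea <- 0.5 * sqrt(sum((pracma_cross(p[2, ] - p[1, ],
                                                  p[3, ] - p[1, ]))^2))
        expect_equal(heronArea(p[1, ], p[2, ], p[3, ]), crossArea,
                     tolerance = 1e-9)
    }
})

test_that("contour closed forms: flat map, tilted plane, sinusoid vs quadrature", {
    expect_equal(ectiContour(matrix(5, 20, 20), pixelSize = 1)$contour, 1.0)

    for (s in c(0.2, 1, 3)) {
        h <- matrix(rep(s * (0:39), each = 40), 40, 40)   # rises along cols
        expect_equal(ectiContour(h, pixelSize = 1)$contour, sqrt(1 + s^2),
                     tolerance = 1e-10)
    }

    A <- 2; P <- 32; px <- P / 32
    x <- (0:255) * px
    h <- matrix(rep(A * sin(2 * pi * x / P), each = 64), 64, 256)
    expect_equal(ectiContour(h, pixelSize = px)$contour,
                 sinusoidSurfaceRatio(A, P), tolerance = 0.01)
})

test_that("contour invariances: offset, rotations, diagonal split", {
    set.seed(3)
    base <- matrix(cumsum(rnorm(30)), 30, 30) +
        outer(sin((1:30) / 4), cos((1:30) / 5)) * 3
    c0 <- ectiContour(base, pixelSize = 1)$contour
    expect_gte(c0, 1)
    expect_equal(ectiContour(base + 17.3, pixelSize = 1)$contour, c0)
    rot90 <- t(base)[, nrow(base):1]
    expect_equal(ectiContour(rot90, pixelSize = 1)$contour, c0,
                 tolerance = 1e-6)
    flip <- base[nrow(base):1, ]
    expect_equal(ectiContour(flip, pixelSize = 1)$contour, c0,
                 tolerance = 1e-6)

    ## the two quad diagonals agree to < 0.5% on smooth sinusoids
    for (A in c(1, 3)) {
        P <- 20; px <- 0.625
        x <- (0:127) * px
        h <- matrix(rep(A * sin(2 * pi * x / P), each = 64), 64, 128)
        a <- ectiContour(h, pixelSize = px, diagonal = "nw-se")$contour
        b <- ectiContour(h, pixelSize = px, diagonal = "ne-sw")$contour
        expect_lt(abs(a - b) / a, 0.005)
    }

    ## equals 1 only for constant maps
    expect_gt(ectiContour(matrix(c(0, 0.5), 8, 8), pixelSize = 1)$contour, 1)
    expect_error(ectiContour(matrix(1, 1, 5), pixelSize = 1), "2 x 2")
})

test_that("interface extraction: flat and corrugated scenes, validity contracts", {
    flat <- genNLOMStack(smallNLOMSpec(amplitude = 0, noiseSd = 0))
    s <- extractECTI(flat$stack, sigmaLateral = 0, sigmaAxial = 0)
    expect_true(all(validMask(s)))
    expect_lt(max(abs(heightMap(s) - 26)), 0.5)

    corr <- genNLOMStack(smallNLOMSpec(amplitude = 3, noiseSd = 4, seed = 5))
    sc <- extractECTI(corr$stack)              # default smoothing
    err <- heightMap(sc)[validMask(sc)] - corr$heightMap[validMask(sc)]
    expect_lt(sqrt(mean(err^2)), 1)

    empty <- new("NLOMStack", mpm = array(1, c(16, 16, 5)),
                 shg = array(0, c(16, 16, 5)), pixelSize = 0.625, zStep = 1,
                 bitDepth = 8)
    expect_error(extractECTI(empty), "no signal")
})

test_that("pipeline recovers planted contour to 2% on noise-free stacks", {
    for (A in c(0, 2, 4)) {
        sc <- genNLOMStack(smallNLOMSpec(amplitude = A, period = 40,
                                         noiseSd = 0, seed = 6 + A))
        surf <- extractECTI(sc$stack)
        got <- ectiContour(surf)$contour
        expect_equal(got, sc$trueContour, tolerance = 0.02)
    }
})
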