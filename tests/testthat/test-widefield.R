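# Widefield module: channel splitting, ROI statistics, internal-control
# normalization, heat map, threshold overlay.

test_that("channel splitting isolates the R and G planes", {
    img <- array(0, c(4, 5, 3))
    img[, , 2] <- 50
    ch <- splitChannels(img)
    expect_equal(ch$red, matrix(0, 4, 5))
    expect_equal(ch$green, matrix(50, 4, 5))
    img[, , 1] <- 100
    ch <- splitChannels(img)
    expect_equal(unique(as.vector(ch$red)), 100)
    expect_error(splitChannels(matrix(1, 4, 5)), "RGB")

    sc <- genWFImage(smallWFSpec(noiseSd = 0))
    ch <- splitChannels(sc$image)
    expect_identical(ch$red, imageData(sc$image)[, , 1])
})

test_that("roiMean is the plain ROI average and rejects out-of-bounds ROIs", {
    expect_equal(roiMean(matrix(7, 10, 10), roiRect(2, 2, 4, 4)), 7)
    expect_equal(roiMean(matrix(1:4, 2, 2), roiRect(1, 1, 2, 2)), 2.5)
    expect_error(roiMean(matrix(1, 10, 10), roiRect(8, 8, 4, 4)), "outside")
})

test_that("control factor is the mean of five per-ROI ratios", {
    ## build a map whose five ROI ratios are 1.0, 1.5, 2.0, 2.5, 3.0
    red <- matrix(0, 10, 60); green <- matrix(10, 10, 60)
    rois <- lapply(0:4, function(i) roiRect(1, 1 + i * 12, 10, 10))
    for (i in 1:5) red[, (1:10) + (i - 1) * 12] <- 10 * c(1, 1.5, 2, 2.5, 3)[i]
    ch <- list(red = red, green = green)
    expect_equal(controlFactor(ch, rois), 2.0)
    expect_equal(controlFactor(list(red = green, green = green), rois), 1.0)
    expect_error(controlFactor(ch, rois[1:4]), "exactly 5")
    expect_error(controlFactor(list(red = red, green = red * 0), rois),
                 "green mean")
})

test_that("normalized RG: hand arithmetic, self-normalization and contracts", {
    mk <- function(ratios) {
        red <- matrix(0, 20, 70); green <- matrix(10, 20, 70)
        rois <- lapply(0:2, function(i) roiRect(1, 1 + i * 22, 20, 20))
        for (i in 1:3) red[, (1:20) + (i - 1) * 22] <- 10 * ratios[i]
        list(ch = list(red = red, green = green), rois = rois)
    }
    x <- mk(c(1.2, 1.5, 1.8))
    expect_equal(normalizedRG(x$ch, x$rois, ic = 1.5), 1.0)
    y <- mk(c(2, 2, 2))
    expect_equal(normalizedRG(y$ch, y$rois, ic = 2), 1.0)
    expect_error(normalizedRG(x$ch, x$rois[1:2], 1), "exactly 3")
    expect_error(normalizedRG(x$ch, x$rois, ic = 0), "> 0")

    ## permutation invariance over site ROI order
    expect_equal(normalizedRG(x$ch, x$rois[c(3, 1, 2)], 1.5),
                 normalizedRG(x$ch, x$rois, 1.5))
})

test_that("end-to-end recovery on noise-free scenes is exact; illumination cancels", {
    for (k in c(1, 0.5, 2.7)) {
        sc <- genWFImage(smallWFSpec(noiseSd = 0, illuminationScale = k))
        ch <- splitChannels(sc$image)
        ic <- controlFactor(ch, tileControlROIs(controlRect(sc$image)))
        v <- normalizedRG(ch, siteROIsAt(120, 130), ic)
        ## planted: (3/0.7) * (60/80) relative to a ratio-1 control
        expect_equal(v, 3 / 0.7 * 60 / 80, tolerance = 1e-12)
    }
    ## control ROI permutation invariance
    sc <- genWFImage(smallWFSpec(noiseSd = 0))
    ch <- splitChannels(sc$image)
    rois <- tileControlROIs(controlRect(sc$image))
    expect_equal(controlFactor(ch, rois[5:1]), controlFactor(ch, rois))
})

test_that("with noise, recovery is unbiased within 3 SE over 100 seeded replicates", {
    planted <- 3 / 0.7 * 60 / 80
    vals <- vapply(1:100, function(i) {
        sc <- genWFImage(smallWFSpec(noiseSd = 2, seed = 2000 + i))
        ch <- splitChannels(sc$image)
        ic <- controlFactor(ch, tileControlROIs(controlRect(sc$image)))
        normalizedRG(ch, siteROIsAt(120, 130), ic)
    }, numeric(1))
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(mean(vals) - planted), 3 * se)
})

test_that("heat map flags invalid pixels and the focus reads its multiplier", {
    sc <- genWFImage(smallWFSpec(noiseSd = 0, redMult = 3, greenMult = 1))
    ch <- splitChannels(sc$image)
    ic <- controlFactor(ch, tileControlROIs(controlRect(sc$image)))
    ## uniform region matching the control ratio reads 1.0 after scaling
    heat <- rgHeatmap(ch, ic, window = NULL)
    expect_equal(heat[30, 200], 60 / 80, tolerance = 1e-12)
    expect_equal(heat[120, 130], 3 * 60 / 80, tolerance = 1e-12)

    ## excluded pixels become NA and stay out of downstream statistics
    ex <- matrix(FALSE, 200, 260); ex[1:50, ] <- TRUE
    heatx <- rgHeatmap(ch, ic, exclusionMask = ex, window = NULL)
    expect_true(all(is.na(heatx[1:50, ])))
    ## zero-green pixels are invalid, not infinite
    ch0 <- ch; ch0$green[100, 100] <- 0
    expect_true(is.na(rgHeatmap(ch0, ic, window = NULL)[100, 100]))
    ## display window clamps
    expect_lte(max(rgHeatmap(ch, ic, window = c(0, 2)), na.rm = TRUE), 2)
})

test_that("threshold overlay: masks above threshold, boundary cases", {
    m <- matrix(c(1.0, 2.0, NA, 0.5), 2, 2)
    res <- thresholdOverlay(m, threshold = 1.46)
    expect_equal(res$mask, matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2))
    expect_false(any(thresholdOverlay(m, threshold = 10)$mask))
    ## threshold 0 flags exactly the valid pixel set
    expect_equal(thresholdOverlay(m, threshold = 0)$mask, !is.na(m))
    ## overlay paints masked pixels in the highlight color
    wl <- matrix(100, 2, 2)
    ov <- thresholdOverlay(m, 1.46, wl, highlight = c(1, 0, 0))$overlay
    expect_equal(ov[2, 1, ], c(1, 0, 0))
    expect_equal(ov[1, 1, ], c(1, 1, 1))
    expect_error(thresholdOverlay(m, 1.46, matrix(1, 3, 3)), "mismatch")
})

test_that("illumination invariance holds for arbitrary positive scalings of the maps", {
    sc <- genWFImage(smallWFSpec(noiseSd = 1, seed = 42))
    ch <- splitChannels(sc$image)
    rois <- tileControlROIs(controlRect(sc$image))
    site <- siteROIsAt(120, 130)
    ic <- controlFactor(ch, rois)
    v <- normalizedRG(ch, site, ic)
    h <- rgHeatmap(ch, ic, window = NULL)
    for (k in c(0.3, 1.7, 12)) {
        chk <- list(red = ch$red * k, green = ch$green * k)
        ick <- controlFactor(chk, rois)
        expect_equal(normalizedRG(chk, site, ick), v, tolerance = 1e-12)
        expect_equal(rgHeatmap(chk, ick, window = NULL), h, tolerance = 1e-12)
    }
})
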