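## Epithelium-stroma interface (ECTI) extraction and the triangulated
## surface-area contour metric.

## Separable Gaussian smoothing with replicate-edge padding. sigma in the
## units of the corresponding axis sample spacing; sigma = 0 disables.
.gaussKernel <- function(sigma) {
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-r, r), sd = sigma)
    k / sum(k)
}

.convolve1 <- function(x, k) {
    ## x: vector; replicate padding
    r <- (length(k) - 1L) / 2L
    xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
    stats::filter(xp, k, sides = 2)[(r + 1L):(r + length(x))]
}

.smoothVolume <- function(vol, sigmaLateral, sigmaAxial) {
    d <- dim(vol)
    if (sigmaLateral > 0) {
        k <- .gaussKernel(sigmaLateral)
        for (z in seq_len(d[3])) {
            pl <- vol[, , z]
            pl <- apply(pl, 2, .convolve1, k = k)          # along rows
            pl <- t(apply(pl, 1, .convolve1, k = k))       # along cols
            vol[, , z] <- pl
        }
    }
    if (sigmaAxial > 0) {
        k <- .gaussKernel(sigmaAxial)
        flat <- matrix(vol, d[1] * d[2], d[3])
        flat <- t(apply(flat, 1, .convolve1, k = k))
        vol <- array(flat, d)
    }
    vol
}

#' Extract the epithelium-stroma interface surface from a z-stack
#'
#' A lateral position carries an interface when the Gaussian-smoothed
#' second-harmonic signal along its z-column exceeds a detection threshold,
#' a fraction (default 0.2) of the channel's robust maximum (99th
#' percentile); positions never crossing it are masked invalid. The height
#' itself is localized at the first crossing of the *half*-plateau level
#' (0.5 of the robust maximum), with sub-plane precision by linear
#' interpolation between the bracketing z samples: for a symmetric
#' rising edge the half-height crossing is an unbiased estimate of the edge
#' position, whereas the low detection threshold itself would sit
#' systematically above the interface. Columns that reach the detection
#' level but never the localization level fall back to the detection
#' crossing.
#'
#' @param stack A \code{\linkS4class{NLOMStack}}.
#' @param thresholdFrac threshold as a fraction of the robust SHG maximum.
#' @param sigmaLateral,sigmaAxial Gaussian pre-smoothing scales (lateral in
#'   pixels, axial in planes); defaults 2 and 1; 0 disables.
#' @return An \code{\linkS4class{ECTISurface}} (heights in micrometers from
#'   the first acquired plane).
#' @export
extractECTI <- function(stack, thresholdFrac = 0.2, sigmaLateral = 2,
                        sigmaAxial = 1) {
    stopifnot(is(stack, "NLOMStack"))
    if (thresholdFrac <= 0 || thresholdFrac >= 1)
        stop("extractECTI: thresholdFrac must lie in (0, 1)")
    shg <- shgChannel(stack)
    robustMax <- stats::quantile(shg, 0.99, names = FALSE)
    if (robustMax <= 0)
        stop("extractECTI: SHG channel carries no signal")
    shg <- .smoothVolume(shg, sigmaLateral, sigmaAxial)
    thrDetect <- thresholdFrac * robustMax
    thrLocal  <- max(thresholdFrac, 0.5) * robustMax

    d <- dim(shg)
    detected <- matrix(FALSE, d[1], d[2])
    first <- matrix(NA_integer_, d[1], d[2])
    for (k in rev(seq_len(d[3]))) {             # keep the *first* crossing
        pl <- shg[, , k]
        detected <- detected | pl >= thrDetect
        first[pl >= thrLocal] <- k
    }
    ## detected columns that never reach the localization level fall back
    ## to the detection crossing
    fallback <- detected & is.na(first)
    if (any(fallback)) {
        for (k in rev(seq_len(d[3]))) {
            hit <- fallback & shg[, , k] >= thrDetect
            first[hit] <- k
        }
    }
    thrCol <- matrix(thrLocal, d[1], d[2])
    thrCol[fallback] <- thrDetect
    valid <- detected
    if (!any(valid))
        stop("extractECTI: SHG signal never crosses the threshold")
    height <- matrix(NA_real_, d[1], d[2])
    idx <- which(valid)
    kk <- first[idx]
    surfaceHit <- kk == 1L
    height[idx[surfaceHit]] <- 0
    deep <- !surfaceHit
    if (any(deep)) {
        ij <- arrayInd(idx[deep], d[1:2])
        thr <- thrCol[idx[deep]]
        vk  <- shg[cbind(ij, kk[deep])]
        vk1 <- shg[cbind(ij, kk[deep] - 1L)]
        frac <- (thr - vk1) / (vk - vk1)
        height[idx[deep]] <- ((kk[deep] - 2L) + frac) * zStep(stack)
    }
    height[!valid] <- 0                         # placeholder under the mask
    new("ECTISurface", height = height, valid = valid,
        pixelSize = pixelSize(stack))
}

#' Triangle area from three 3-D points (Heron's formula)
#'
#' Side lengths feed Heron's formula with Kahan's numerically stabilized
#' ordering, so thin triangles do not lose precision; degenerate (collinear)
#' inputs return 0.
#'
#' @param p1,p2,p3 numeric length-3 points (micrometers), or n x 3 matrices
#'   for a vectorized call.
#' @return Triangle area(s) in square micrometers.
#' @examples
#' heronArea(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0))   # 6
#' @export
heronArea <- function(p1, p2, p3) {
    if (is.null(dim(p1))) { p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3) }
    a <- sqrt(rowSums((p2 - p3)^2))
    b <- sqrt(rowSums((p1 - p3)^2))
    c_ <- sqrt(rowSums((p1 - p2)^2))
    .heronFromSides(a, b, c_)
}

## Kahan's stable form; requires a >= b >= c, enforced by sorting.
.heronFromSides <- function(a, b, c_) {
    s <- cbind(a, b, c_)
    s <- t(apply(s, 1, sort, decreasing = TRUE))
    a <- s[, 1]; b <- s[, 2]; c_ <- s[, 3]
    t1 <- a + (b + c_); t2 <- c_ - (a - b); t3 <- c_ + (a - b); t4 <- a + (b - c_)
    0.25 * sqrt(pmax(t1 * t2 * t3 * t4, 0))
}

#' Interface contour: triangulated surface area relative to a flat surface
#'
#' Each valid quad of the height-map grid (lateral spacing from the pixel
#' size, z from the height in micrometers) is split into two triangles whose
#' areas are computed with \code{\link{heronArea}}; the contour is the total
#' triangulated area divided by the flat projected area of the same valid
#' region. A flat interface gives exactly 1; neoplastic deformation of the
#' interface raises it.
#'
#' @param surface An \code{\linkS4class{ECTISurface}}, or a plain height
#'   matrix (micrometers) taken as fully valid.
#' @param pixelSize lateral spacing (micrometers); ignored when
#'   \code{surface} is an \code{ECTISurface}.
#' @param diagonal quad split direction; the two choices differ by < 0.5\%
#'   on smooth surfaces at the native resolution.
#' @param siteId identifier carried into the result.
#' @return list with \code{contour} (dimensionless ratio >= 1),
#'   \code{triangulatedArea}, \code{flatArea} (square micrometers),
#'   \code{nQuads} and \code{site_id}.
#' @examples
#' ectiContour(matrix(5, 16, 16), pixelSize = 1)$contour    # flat: 1
#' @export
ectiContour <- function(surface, pixelSize = NULL,
                        diagonal = c("nw-se", "ne-sw"), siteId = "site") {
    diagonal <- match.arg(diagonal)
    if (is(surface, "ECTISurface")) {
        h <- heightMap(surface); valid <- validMask(surface)
        p <- MucosalScope::pixelSize(surface)
    } else {
        h <- surface; valid <- matrix(TRUE, nrow(h), ncol(h))
        p <- if (is.null(pixelSize)) 1 else pixelSize
    }
    ny <- nrow(h); nx <- ncol(h)
    if (ny < 2 || nx < 2) stop("ectiContour: need at least a 2 x 2 grid")
    q <- valid[-ny, -nx] & valid[-1, -nx] & valid[-ny, -1] & valid[-1, -1]
    nQuads <- sum(q)
    if (nQuads < 1) stop("ectiContour: too few valid cells to triangulate")

    h00 <- h[-ny, -nx][q]; h10 <- h[-1, -nx][q]
    h01 <- h[-ny, -1][q];  h11 <- h[-1, -1][q]
    z <- function(v) v
    ## corner coordinates within a quad: (0,0), (p,0), (0,p), (p,p) laterally
    P00 <- cbind(0, 0, z(h00)); P10 <- cbind(0, p, z(h10))
    P01 <- cbind(p, 0, z(h01)); P11 <- cbind(p, p, z(h11))
    ## note: lateral offsets are relative per quad; absolute position is
    ## irrelevant for edge lengths
    if (diagonal == "nw-se") {
        area <- sum(heronArea(P00, P10, P11)) + sum(heronArea(P00, P01, P11))
    } else {
        area <- sum(heronArea(P00, P10, P01)) + sum(heronArea(P10, P11, P01))
    }
    flat <- nQuads * p^2
    list(contour = area / flat, triangulatedArea = area, flatArea = flat,
         nQuads = nQuads, site_id = siteId)
}

#' NLOM feature extraction for one site
#'
#' Runs the two microscopy features on one stack: interface contour from the
#' SHG channel and basal nuclear CoVa from three basal planes of the
#' multiphoton channel.
#'
#' @param stack A \code{\linkS4class{NLOMStack}}.
#' @param basalHint basal-layer center depth (micrometers).
#' @param spacing basal plane separation (micrometers, 5-10).
#' @param siteId site identifier.
#' @param thresholdFrac,sigmaLateral,sigmaAxial passed to
#'   \code{\link{extractECTI}}.
#' @param areaRange admissible nuclear areas for
#'   \code{\link{delineateNuclei}}.
#' @return data.frame with site_id, n_nuclei, mean_area, sd_area, cova and
#'   ecti_contour.
#' @export
nlomSiteFeatures <- function(stack, basalHint, spacing = 5, siteId = "site",
                             thresholdFrac = 0.2, sigmaLateral = 2,
                             sigmaAxial = 1, areaRange = c(8, 200)) {
    planes <- selectBasalPlanes(stack, basalHint, spacing)
    mpm <- mpmChannel(stack)
    outs <- do.call(rbind, lapply(planes, function(k)
        delineateNuclei(mpm[, , k], "automatic", pixelSize = pixelSize(stack),
                        areaRange = areaRange)))
    morph <- suppressWarnings(siteCova(outs, siteId))
    surf <- extractECTI(stack, thresholdFrac, sigmaLateral, sigmaAxial)
    ct <- ectiContour(surf, siteId = siteId)
    data.frame(site_id = siteId, n_nuclei = length(morph@areas),
               mean_area = morph@meanArea, sd_area = morph@sdArea,
               cova = morph@cova, ecti_contour = ct$contour,
               stringsAsFactors = FALSE)
}
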