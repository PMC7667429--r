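#' Specification of a synthetic nonlinear-microscopy z-stack
#'
#' Describes a two-channel (multiphoton autofluorescence + second-harmonic)
#' volumetric scene of buccal mucosa: a bright keratinized layer, a basal
#' epithelial layer carrying dark ellipsoidal nuclear lumina on brighter
#' cytoplasm (NADH/FAD contrast is cytoplasmic), and an SHG-bright stroma
#' below a corrugated interface. The interface height follows a sinusoid
#' along x, \code{depth + amplitude * sin(2*pi*x/period)}, so its true
#' surface-area ratio has a closed quadrature form
#' (\code{\link{sinusoidSurfaceRatio}}).
#'
#' @slot dim lateral (ny, nx) in pixels (nominal 512 x 512).
#' @slot pixelSize lateral pixel size, micrometers (default 0.625).
#' @slot zStep axial step, micrometers (default 1).
#' @slot nz number of z planes.
#' @slot keratinRange,basalRange depth ranges (micrometers, from the first
#'   plane) of the keratin and basal layers; must be ordered
#'   keratin < basal < interface.
#' @slot interfaceDepth mean interface depth (micrometers).
#' @slot corrugationAmplitude,corrugationPeriod interface corrugation
#'   (micrometers); amplitude 0 gives a flat interface.
#' @slot nNucleiPerPlane planted nuclei per basal plane.
#' @slot meanNuclearArea mean nuclear area (square micrometers).
#' @slot targetCova target coefficient of variance of nuclear area.
#' @slot noiseSd additive Gaussian channel noise sd (8-bit counts).
#' @slot seed integer random seed.
#' @export
setClass("SyntheticNLOMSpec", representation(
    dim = "numeric", pixelSize = "numeric", zStep = "numeric", nz = "numeric",
    keratinRange = "numeric", basalRange = "numeric",
    interfaceDepth = "numeric", corrugationAmplitude = "numeric",
    corrugationPeriod = "numeric", nNucleiPerPlane = "numeric",
    meanNuclearArea = "numeric", targetCova = "numeric",
    noiseSd = "numeric", seed = "numeric"))

setValidity("SyntheticNLOMSpec", function(object) {
    zmax <- (object@nz - 1) * object@zStep
    A <- object@corrugationAmplitude
    if (length(object@dim) != 2L || any(object@dim < 8))
        return("lateral dim must be at least 8 x 8")
    if (object@pixelSize <= 0 || object@zStep <= 0 || object@nz < 3)
        return("pixelSize, zStep must be > 0 and nz >= 3")
    if (A < 0) return("corrugation amplitude must be >= 0")
    if (A > 0 && object@corrugationPeriod <= 0)
        return("corrugation period must be > 0")
    if (object@keratinRange[2] >= object@basalRange[1])
        return("layers must be ordered: keratin below-depth basal")
    if (object@basalRange[2] >= object@interfaceDepth - A)
        return("basal layer must lie fully above the interface corrugation")
    if (object@interfaceDepth + A >= zmax)
        return("corrugation pushes the interface outside the z range")
    if (object@nNucleiPerPlane < 1) return("nucleus count must be >= 1")
    if (object@meanNuclearArea <= 0 || object@targetCova < 0)
        return("meanNuclearArea must be > 0 and targetCova >= 0")
    TRUE
})

#' @describeIn syntheticNLOMSpec Constructor with study-scale defaults
#'   (512 x 512 at 0.625 um/px, 1 um z-steps).
#' @param dim,pixelSize,zStep,nz,keratinRange,basalRange,interfaceDepth
#'   geometry; see slots.
#' @param corrugationAmplitude,corrugationPeriod interface corrugation (um).
#' @param nNucleiPerPlane,meanNuclearArea,targetCova nuclear ground truth.
#' @param noiseSd,seed noise level and seed.
#' @export
syntheticNLOMSpec <- function(dim = c(512, 512), pixelSize = 0.625, zStep = 1,
                              nz = 40, keratinRange = c(0, 8),
                              basalRange = c(12, 22), interfaceDepth = 30,
                              corrugationAmplitude = 3,
                              corrugationPeriod = 40, nNucleiPerPlane = 20,
                              meanNuclearArea = 38, targetCova = 0.21,
                              noiseSd = 4, seed = 1L) {
    new("SyntheticNLOMSpec", dim = dim, pixelSize = pixelSize, zStep = zStep,
        nz = nz, keratinRange = keratinRange, basalRange = basalRange,
        interfaceDepth = interfaceDepth,
        corrugationAmplitude = corrugationAmplitude,
        corrugationPeriod = corrugationPeriod,
        nNucleiPerPlane = nNucleiPerPlane, meanNuclearArea = meanNuclearArea,
        targetCova = targetCova, noiseSd = noiseSd, seed = as.numeric(seed))
}

#' Surface-area ratio of a 1-D sinusoidal height map
#'
#' Area ratio (relative to the flat projection) of the surface
#' \code{z = A * sin(2*pi*x / P)}, i.e. the mean over one period of
#' \code{sqrt(1 + (2*pi*A/P)^2 * cos(2*pi*x/P)^2)}, by adaptive quadrature.
#'
#' @param amplitude,period sinusoid amplitude and lateral period (same units).
#' @return Dimensionless area ratio >= 1.
#' @examples
#' sinusoidSurfaceRatio(0, 40)       # flat: exactly 1
#' sinusoidSurfaceRatio(3, 40)
#' @export
sinusoidSurfaceRatio <- function(amplitude, period) {
    if (amplitude == 0) return(1)
    k <- 2 * pi / period
    f <- function(x) sqrt(1 + (amplitude * k * cos(k * x))^2)
    stats::integrate(f, 0, period, rel.tol = 1e-10)$value / period
}

## Nuclear areas with target mean and CoVa (post-truncation moments).
.drawNuclearAreas <- function(n, meanArea, cova) {
    if (cova < .Machine$double.eps^0.5) return(rep(meanArea, n))
    p <- truncnormParams(meanArea, cova * meanArea, 0)
    .rtruncnorm(n, p$mu, p$sigma, 0)
}

## Place n non-overlapping ellipses; returns data.frame of centers/axes (px
## for centers, um for axes). Errors if the field cannot host them.
.placeNuclei <- function(n, meanArea, cova, dim, pixelSize) {
    areas <- .drawNuclearAreas(n, meanArea, cova)
    aspect <- stats::runif(n, 1.05, 1.8)
    major <- sqrt(4 * areas * aspect / pi)     # axis lengths, um
    minor <- major / aspect
    theta <- stats::runif(n, 0, pi)
    rpx <- major / 2 / pixelSize               # semi-major in px
    margin <- rpx + 3
    row <- col <- numeric(n)
    for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(400)) {
            r <- stats::runif(1, 1 + margin[i], dim[1] - margin[i])
            c <- stats::runif(1, 1 + margin[i], dim[2] - margin[i])
            if (i == 1L ||
                all((row[seq_len(i - 1)] - r)^2 + (col[seq_len(i - 1)] - c)^2 >
                    (rpx[seq_len(i - 1)] + rpx[i] + 2)^2)) {
                row[i] <- r; col[i] <- c; ok <- TRUE; break
            }
        }
        if (!ok) stop("field too small to place ", n, " non-overlapping nuclei")
    }
    data.frame(row = row, col = col, major = major, minor = minor,
               theta = theta, area = areas)
}

## Stamp dark elliptical lumina into a plane matrix (in place semantics).
.stampNuclei <- function(plane, nuc, pixelSize, lumen) {
    ny <- nrow(plane); nx <- ncol(plane)
    for (i in seq_len(nrow(nuc))) {
        a <- nuc$major[i] / 2 / pixelSize
        b <- nuc$minor[i] / 2 / pixelSize
        th <- nuc$theta[i]
        rr <- max(1L, floor(nuc$row[i] - a)):min(ny, ceiling(nuc$row[i] + a))
        cc <- max(1L, floor(nuc$col[i] - a)):min(nx, ceiling(nuc$col[i] + a))
        dr <- outer(rr - nuc$row[i], rep(1, length(cc)))
        dc <- outer(rep(1, length(rr)), cc - nuc$col[i])
        u <- (dc * cos(th) + dr * sin(th)) / a
        v <- (-dc * sin(th) + dr * cos(th)) / b
        inside <- u * u + v * v <= 1
        block <- plane[rr, cc, drop = FALSE]
        block[inside] <- lumen
        plane[rr, cc] <- block
    }
    plane
}

#' Render a synthetic two-channel z-stack with planted ground truth
#'
#' @name syntheticNLOMSpec
#' @aliases genNLOMStack
#' @param spec A \code{\linkS4class{SyntheticNLOMSpec}}.
#' @return \code{genNLOMStack} returns a list with:
#'   \describe{
#'     \item{stack}{the \code{\linkS4class{NLOMStack}};}
#'     \item{nuclei}{data.frame of planted nuclei (plane, row, col, major,
#'       minor, theta, area) for every basal plane;}
#'     \item{heightMap}{true interface depth (um) at every lateral pixel;}
#'     \item{trueContour}{analytic surface-area ratio of the planted
#'       interface (\code{\link{sinusoidSurfaceRatio}});}
#'     \item{basalPlanes}{indices of the rendered basal planes.}
#'   }
#' @examples
#' sc <- genNLOMStack(syntheticNLOMSpec(dim = c(64, 64), nz = 24,
#'                    basalRange = c(6, 10), keratinRange = c(0, 4),
#'                    interfaceDepth = 16, corrugationAmplitude = 0,
#'                    nNucleiPerPlane = 4, pixelSize = 1.25, noiseSd = 0))
#' sc$stack
#' sc$trueContour
#' @export
genNLOMStack <- function(spec) {
    stopifnot(is(spec, "SyntheticNLOMSpec"))
    validObject(spec)
    set.seed(as.integer(spec@seed))
    ny <- spec@dim[1]; nx <- spec@dim[2]; nz <- spec@nz
    depth <- (seq_len(nz) - 1) * spec@zStep

    xum <- (seq_len(nx) - 1) * spec@pixelSize
    hrow <- spec@interfaceDepth + if (spec@corrugationAmplitude > 0)
        spec@corrugationAmplitude * sin(2 * pi * xum / spec@corrugationPeriod)
    else rep(0, nx)
    height <- matrix(hrow, ny, nx, byrow = TRUE)

    keratin <- depth >= spec@keratinRange[1] & depth <= spec@keratinRange[2]
    basal   <- depth >= spec@basalRange[1]   & depth <= spec@basalRange[2]

    mpm <- array(8, c(ny, nx, nz))
    shg <- array(0, c(ny, nx, nz))
    nucleiAll <- list()
    for (k in seq_len(nz)) {
        if (keratin[k]) {
            mpm[, , k] <- 150 + matrix(stats::runif(ny * nx, -25, 25), ny, nx)
        } else if (basal[k]) {
            plane <- matrix(120, ny, nx)
            nuc <- .placeNuclei(spec@nNucleiPerPlane, spec@meanNuclearArea,
                                spec@targetCova, spec@dim, spec@pixelSize)
            plane <- .stampNuclei(plane, nuc, spec@pixelSize, lumen = 20)
            mpm[, , k] <- plane
            nuc$plane <- k
            nucleiAll[[length(nucleiAll) + 1L]] <- nuc
        } else {
            mpm[, , k] <- 35
        }
        ## SHG rises across the interface as an erf edge (~1 um width,
        ## emulating the axial point spread), centered on the true height
        frac <- stats::pnorm((depth[k] - height) / 1.0)
        shg[, , k] <- 180 * frac *
            (1 + 0.08 * sin(2 * pi * (seq_len(ny) - 1) * spec@pixelSize / 9))
    }
    if (spec@noiseSd > 0) {
        mpm <- mpm + array(stats::rnorm(length(mpm), 0, spec@noiseSd), dim(mpm))
        shg <- shg + array(stats::rnorm(length(shg), 0, spec@noiseSd), dim(shg))
    }
    mpm <- pmin(pmax(mpm, 0), 255)
    shg <- pmin(pmax(shg, 0), 255)

    nuclei <- if (length(nucleiAll)) do.call(rbind, nucleiAll)
              else data.frame()
    list(stack = new("NLOMStack", mpm = mpm, shg = shg,
                     pixelSize = spec@pixelSize, zStep = spec@zStep,
                     bitDepth = 8),
         nuclei = nuclei, heightMap = height,
         trueContour = sinusoidSurfaceRatio(spec@corrugationAmplitude,
                                            spec@corrugationPeriod),
         basalPlanes = which(basal))
}
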