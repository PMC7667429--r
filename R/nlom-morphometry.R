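#' Basal nuclear morphometry of one imaged site
#'
#' @slot siteId site identifier.
#' @slot areas pooled nuclear areas (square micrometers) from the sampled
#'   basal planes.
#' @slot meanArea,sdArea sample moments of the areas (sd uses n - 1).
#' @slot cova coefficient of variance of nuclear area, sd/mean; the
#'   quantitative proxy for anisonucleosis / nuclear pleomorphism.
#' @export
setClass("NuclearMorphometry", representation(
    siteId = "character", areas = "numeric", meanArea = "numeric",
    sdArea = "numeric", cova = "numeric"))

setValidity("NuclearMorphometry", function(object) {
    if (length(object@areas) < 2) return("at least 2 nuclear areas required")
    if (object@cova < 0) return("CoVa must be >= 0")
    TRUE
})

setMethod("show", "NuclearMorphometry", function(object) {
    cat(sprintf("NuclearMorphometry [%s]: %d nuclei, area %.2f +/- %.2f um^2, CoVa %.4f\n",
                object@siteId, length(object@areas), object@meanArea,
                object@sdArea, object@cova))
})

#' @rdname accessors
#' @export
setGeneric("cova", function(object) standardGeneric("cova"))
#' @rdname accessors
#' @export
setMethod("cova", "NuclearMorphometry", function(object) object@cova)

#' Select three basal-layer planes from a z-stack
#'
#' Returns three plane indices centered on the basal-layer depth hint and
#' separated by the requested spacing; the spacing must lie between 5 and
#' 10 micrometers, matching how cytology planes are sampled within the basal
#' layer.
#'
#' @param stack A \code{\linkS4class{NLOMStack}}.
#' @param basalHint center depth of the basal layer, micrometers.
#' @param spacing plane separation in micrometers (default 5; allowed 5-10).
#' @return Integer vector of three plane indices.
#' @examples
#' st <- new("NLOMStack", mpm = array(0, c(8, 8, 40)),
#'           shg = array(0, c(8, 8, 40)), pixelSize = 0.625, zStep = 1,
#'           bitDepth = 8)
#' selectBasalPlanes(st, basalHint = 19)   # planes 15, 20, 25
#' @export
selectBasalPlanes <- function(stack, basalHint, spacing = 5) {
    stopifnot(is(stack, "NLOMStack"))
    if (spacing < 5 || spacing > 10)
        stop("selectBasalPlanes: spacing must lie in [5, 10] micrometers")
    nz <- dim(mpmChannel(stack))[3]
    sIdx <- round(spacing / zStep(stack))
    center <- round(basalHint / zStep(stack)) + 1L
    planes <- center + c(-sIdx, 0L, sIdx)
    if (planes[1] < 1 || planes[3] > nz)
        stop("selectBasalPlanes: stack too shallow for 3 planes at ",
             spacing, " um spacing around the hint")
    as.integer(planes)
}

#' Area of an ellipse from its axis lengths
#'
#' Nuclei are treated as ellipsoidal; the area uses the axis *lengths*
#' (diameters), i.e. \code{pi * major * minor / 4}.
#'
#' @param major,minor axis lengths (micrometers), \code{major >= minor > 0}.
#' @return Area in square micrometers.
#' @examples
#' ellipseArea(2, 2)      # pi
#' ellipseArea(10, 5)     # 39.27
#' @export
ellipseArea <- function(major, minor) {
    if (any(minor <= 0)) stop("ellipseArea: axes must be > 0")
    if (any(minor > major)) stop("ellipseArea: minor axis exceeds major axis")
    pi * major * minor / 4
}

#' Moment-equivalent ellipse of a polygon
#'
#' Analytic (Green's theorem) area, centroid and central second moments of a
#' simple polygon, and the axis lengths of the ellipse with the same second
#' moments (axis = 4 * sqrt(eigenvalue of the covariance)).
#'
#' @param vertices 2-column matrix of (x, y) vertices, any orientation.
#' @return list with \code{area}, \code{centroid}, \code{cov} (2 x 2
#'   covariance), \code{major}, \code{minor}, \code{theta} (major-axis angle,
#'   radians).
#' @export
polygonMoments <- function(vertices) {
    v <- rbind(vertices, vertices[1, , drop = FALSE])
    x <- v[, 1]; y <- v[, 2]
    n <- nrow(vertices)
    i <- seq_len(n); j <- i + 1L
    cr <- x[i] * y[j] - x[j] * y[i]
    A <- sum(cr) / 2
    if (abs(A) < 1e-12) stop("polygonMoments: degenerate polygon")
    cx <- sum((x[i] + x[j]) * cr) / (6 * A)
    cy <- sum((y[i] + y[j]) * cr) / (6 * A)
    Ixx <- sum((y[i]^2 + y[i] * y[j] + y[j]^2) * cr) / 12       # int y^2 dA
    Iyy <- sum((x[i]^2 + x[i] * x[j] + x[j]^2) * cr) / 12       # int x^2 dA
    Ixy <- sum((x[i] * y[j] + 2 * x[i] * y[i] + 2 * x[j] * y[j] +
                x[j] * y[i]) * cr) / 24
    covm <- matrix(c(Iyy / A - cx^2, Ixy / A - cx * cy,
                     Ixy / A - cx * cy, Ixx / A - cy^2), 2, 2)
    e <- eigen(covm, symmetric = TRUE)
    list(area = abs(A), centroid = c(cx, cy), cov = covm,
         major = 4 * sqrt(max(e$values[1], 0)),
         minor = 4 * sqrt(max(e$values[2], 0)),
         theta = atan2(e$vectors[2, 1], e$vectors[1, 1]))
}

#' Delineate basal nuclei in one image plane
#'
#' Automatic mode detects dark elliptical nuclear lumina on the brighter
#' cytoplasm (two-photon contrast is cytoplasmic): the plane is thresholded
#' (Otsu), connected components are labelled, components in the admissible
#' area range not touching the border are kept, and an ellipse is fitted to
#' each via second moments (axis = 4 sqrt(eigenvalue)). Manual mode accepts
#' either fitted axes directly or polygon outlines, from which the
#' moment-equivalent ellipse is computed analytically.
#'
#' @param plane intensity matrix (one basal z-plane).
#' @param mode \code{"automatic"} or \code{"manual"}.
#' @param outlines manual input: a data.frame with columns \code{major} and
#'   \code{minor} (micrometers; optionally row, col, theta), or a list of
#'   polygon vertex matrices in pixel coordinates.
#' @param pixelSize lateral pixel size (micrometers) for converting fitted
#'   pixel axes to micrometers.
#' @param areaRange admissible nuclear area (square micrometers),
#'   default c(8, 200).
#' @return data.frame with row, col (pixel center), major, minor
#'   (micrometers) and theta for each detected nucleus.
#' @export
delineateNuclei <- function(plane, mode = c("automatic", "manual"),
                            outlines = NULL, pixelSize = 0.625,
                            areaRange = c(8, 200)) {
    mode <- match.arg(mode)
    if (mode == "manual") {
        if (is.null(outlines))
            stop("delineateNuclei: manual mode requires outlines")
        if (is.data.frame(outlines)) {
            stopifnot(all(c("major", "minor") %in% names(outlines)))
            out <- outlines
            if (is.null(out$row)) out$row <- NA_real_
            if (is.null(out$col)) out$col <- NA_real_
            if (is.null(out$theta)) out$theta <- NA_real_
            return(out[, c("row", "col", "major", "minor", "theta")])
        }
        fits <- lapply(outlines, polygonMoments)
        return(data.frame(
            row = vapply(fits, function(f) f$centroid[2], numeric(1)),
            col = vapply(fits, function(f) f$centroid[1], numeric(1)),
            major = vapply(fits, `[[`, numeric(1), "major") * pixelSize,
            minor = vapply(fits, `[[`, numeric(1), "minor") * pixelSize,
            theta = vapply(fits, `[[`, numeric(1), "theta")))
    }

    rng <- range(plane)
    if (diff(rng) < 1e-9)
        stop("delineateNuclei: blank plane, no candidate nuclei found")
    norm <- (plane - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm))
    mask <- norm < thr
    lab <- EBImage::bwlabel(EBImage::Image(mask))
    labm <- EBImage::imageData(lab)
    nlabs <- max(labm)
    if (nlabs < 1)
        stop("delineateNuclei: no candidate nuclei found")

    minPx <- areaRange[1] / pixelSize^2
    maxPx <- areaRange[2] / pixelSize^2
    res <- vector("list", nlabs)
    ny <- nrow(plane); nx <- ncol(plane)
    idx <- which(labm > 0)
    rows <- ((idx - 1) %% ny) + 1
    cols <- ((idx - 1) %/% ny) + 1
    labs <- labm[idx]
    for (l in seq_len(nlabs)) {
        sel <- labs == l
        npx <- sum(sel)
        if (npx < minPx || npx > maxPx) next
        r <- rows[sel]; c <- cols[sel]
        if (min(r) <= 1 || max(r) >= ny || min(c) <= 1 || max(c) >= nx)
            next                               # clipped at the border
        covm <- stats::cov(cbind(c, r)) * (npx - 1) / npx
        e <- eigen(covm, symmetric = TRUE)
        res[[l]] <- data.frame(
            row = mean(r), col = mean(c),
            major = 4 * sqrt(max(e$values[1], 0)) * pixelSize,
            minor = 4 * sqrt(max(e$values[2], 0)) * pixelSize,
            theta = atan2(e$vectors[2, 1], e$vectors[1, 1]))
    }
    res <- do.call(rbind, res)
    if (is.null(res) || !nrow(res))
        stop("delineateNuclei: no candidate nuclei in the admissible area range")
    rownames(res) <- NULL
    res
}

#' Pooled nuclear-area coefficient of variance of a site
#'
#' Pools the ellipse areas of the nuclei delineated on (typically three)
#' basal planes of one stack and computes CoVa = sample sd / mean. Roughly
#' 20 nuclei per plane, 60 per stack, is the intended sampling density; a
#' warning is raised below 60.
#'
#' @param outlines data.frame with \code{major}/\code{minor} axis lengths in
#'   micrometers (rows pooled across planes), as returned by
#'   \code{\link{delineateNuclei}}.
#' @param siteId site identifier.
#' @return A \code{\linkS4class{NuclearMorphometry}}.
#' @examples
#' o <- data.frame(major = c(4, 5), minor = c(3, 4))
#' cova(siteCova(o))
#' @export
siteCova <- function(outlines, siteId = "site") {
    if (nrow(outlines) < 2)
        stop("siteCova: at least 2 nuclei are required")
    if (nrow(outlines) < 60)
        warning("siteCova: fewer than 60 pooled nuclei (", nrow(outlines), ")")
    areas <- ellipseArea(outlines$major, outlines$minor)
    m <- mean(areas); s <- stats::sd(areas)
    new("NuclearMorphometry", siteId = siteId, areas = areas,
        meanArea = m, sdArea = s, cova = s / m)
}
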