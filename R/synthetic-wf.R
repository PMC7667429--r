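#' Specification of a synthetic widefield scene
#'
#' Describes a synthetic buccal-pouch widefield autofluorescence frame: a
#' uniform red/green background, a uniform internal-control strip on the
#' sample holder, and circular lesion foci whose red and green emissions are
#' scaled by per-focus multipliers (elevated red / reduced green emulates
#' neoplasia). An illumination scale factor multiplies the whole frame
#' (tissue and control together), which the internal-control normalization
#' must cancel.
#'
#' @slot dim image height and width in pixels.
#' @slot backgroundRed,backgroundGreen base tissue intensities (counts).
#' @slot controlRect internal-control strip (\code{\link{roiRect}} geometry).
#' @slot controlRed,controlGreen fixed control-strip intensities.
#' @slot foci data.frame with columns row, col, radius, redMult, greenMult.
#' @slot illuminationScale global intensity scale factor.
#' @slot noiseSd additive Gaussian noise sd (counts).
#' @slot seed integer random seed.
#' @export
setClass("SyntheticWFSpec", representation(
    dim = "numeric", backgroundRed = "numeric", backgroundGreen = "numeric",
    controlRect = "numeric", controlRed = "numeric", controlGreen = "numeric",
    foci = "data.frame", illuminationScale = "numeric", noiseSd = "numeric",
    seed = "numeric"))

## TRUE when a circle intersects a rectangle (clamp center into rect).
.circleHitsRect <- function(row, col, radius, rect) {
    r0 <- rect[["row"]]; r1 <- rect[["row"]] + rect[["height"]] - 1
    c0 <- rect[["col"]]; c1 <- rect[["col"]] + rect[["width"]] - 1
    dr <- row - min(max(row, r0), r1)
    dc <- col - min(max(col, c0), c1)
    dr * dr + dc * dc <= radius * radius
}

setValidity("SyntheticWFSpec", function(object) {
    if (length(object@dim) != 2L || any(object@dim < 1))
        return("dim must be positive (height, width)")
    if (!.rectInside(object@controlRect, object@dim))
        return("control strip outside image bounds")
    f <- object@foci
    need <- c("row", "col", "radius", "redMult", "greenMult")
    if (nrow(f)) {
        if (!all(need %in% names(f)))
            return(paste("foci must have columns:", paste(need, collapse = ", ")))
        if (any(f$redMult <= 0 | f$greenMult <= 0))
            return("focus multipliers must be > 0")
        hit <- mapply(.circleHitsRect, f$row, f$col, f$radius,
                      MoreArgs = list(rect = object@controlRect))
        if (any(hit))
            return("control strip must be disjoint from all lesion foci")
    }
    if (object@illuminationScale <= 0) return("illuminationScale must be > 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
})

#' @describeIn syntheticWFSpec Constructor with realistic defaults.
#' @param dim image (height, width) in pixels.
#' @param backgroundRed,backgroundGreen base tissue intensities.
#' @param controlRect internal-control strip, a \code{\link{roiRect}}.
#' @param controlRed,controlGreen control-strip intensities.
#' @param foci data.frame of lesion foci (row, col, radius, redMult,
#'   greenMult).
#' @param illuminationScale global intensity scale.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed integer seed.
#' @export
syntheticWFSpec <- function(dim = c(240, 320),
                            backgroundRed = 60, backgroundGreen = 80,
                            controlRect = roiRect(6, 6, 20, dim[2] - 10),
                            controlRed = 70, controlGreen = 70,
                            foci = data.frame(row = 150, col = 160, radius = 25,
                                              redMult = 3, greenMult = 0.7),
                            illuminationScale = 1, noiseSd = 2, seed = 1L) {
    new("SyntheticWFSpec", dim = dim, backgroundRed = backgroundRed,
        backgroundGreen = backgroundGreen, controlRect = .asRect(controlRect),
        controlRed = controlRed, controlGreen = controlGreen, foci = foci,
        illuminationScale = illuminationScale, noiseSd = noiseSd,
        seed = as.numeric(seed))
}

#' Render a synthetic widefield frame with planted lesion ground truth
#'
#' @name syntheticWFSpec
#' @aliases genWFImage
#' @param spec A \code{\linkS4class{SyntheticWFSpec}}.
#' @return \code{genWFImage} returns a list with \code{image} (a
#'   \code{\linkS4class{WFImage}} whose control rectangle is carried over from
#'   the spec and whose white-light companion is a grayscale rendition) and
#'   \code{lesionMask} (logical matrix of planted lesion pixels; every planted
#'   pixel lies inside a focus, none inside the control strip).
#' @examples
#' sc <- genWFImage(syntheticWFSpec(noiseSd = 0))
#' sc$image
#' sum(sc$lesionMask)
#' @export
genWFImage <- function(spec) {
    stopifnot(is(spec, "SyntheticWFSpec"))
    validObject(spec)
    set.seed(as.integer(spec@seed))
    h <- spec@dim[1]; w <- spec@dim[2]
    R <- matrix(spec@backgroundRed, h, w)
    G <- matrix(spec@backgroundGreen, h, w)
    lesion <- matrix(FALSE, h, w)

    if (nrow(spec@foci)) {
        rowIdx <- matrix(seq_len(h), h, w)
        colIdx <- matrix(seq_len(w), h, w, byrow = TRUE)
        for (i in seq_len(nrow(spec@foci))) {
            f <- spec@foci[i, ]
            inside <- (rowIdx - f$row)^2 + (colIdx - f$col)^2 <= f$radius^2
            R[inside] <- R[inside] * f$redMult
            G[inside] <- G[inside] * f$greenMult
            lesion <- lesion | inside
        }
    }
    rows <- .rectRows(spec@controlRect); cols <- .rectCols(spec@controlRect)
    R[rows, cols] <- spec@controlRed
    G[rows, cols] <- spec@controlGreen

    k <- spec@illuminationScale
    R <- R * k; G <- G * k
    B <- matrix(0, h, w)
    if (spec@noiseSd > 0) {
        R <- R + stats::rnorm(h * w, 0, spec@noiseSd)
        G <- G + stats::rnorm(h * w, 0, spec@noiseSd)
        B <- B + abs(stats::rnorm(h * w, 0, spec@noiseSd / 2))
    }
    img <- array(0, c(h, w, 3))
    img[, , 1] <- pmax(R, 0); img[, , 2] <- pmax(G, 0); img[, , 3] <- pmax(B, 0)

    wl <- 0.5 * (img[, , 1] + img[, , 2])
    list(image = new("WFImage", image = img, whiteLight = wl,
                     controlRect = spec@controlRect, exclusionMask = NULL),
         lesionMask = lesion)
}
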