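#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

## Canonical histology classes and feature names used throughout.
.CLASSES  <- c("normal", "inflammation", "OED", "OSCC")
.FEATURES <- c("normalized_rg", "ecti_contour", "basal_cova")

#' Rectangular region of interest
#'
#' Rectangles are 1-based, inclusive, in (row, col) order: \code{row}/\code{col}
#' is the top-left pixel and \code{height}/\code{width} the extent in pixels.
#'
#' @param row,col Top-left pixel (1-based).
#' @param height,width Extent in pixels (>= 1).
#' @return A named numeric vector of length 4 with class \code{"roiRect"}.
#' @examples
#' roiRect(10, 10, 20, 20)
#' @export
roiRect <- function(row, col, height, width) {
    r <- c(row = as.numeric(row), col = as.numeric(col),
           height = as.numeric(height), width = as.numeric(width))
    if (any(!is.finite(r)) || r["height"] < 1 || r["width"] < 1 ||
        r["row"] < 1 || r["col"] < 1)
        stop("roiRect: row/col must be >= 1 and height/width >= 1")
    structure(r, class = "roiRect")
}

.asRect <- function(x)
    stats::setNames(as.numeric(x), c("row", "col", "height", "width"))

.rectRows <- function(r) seq.int(r[["row"]], r[["row"]] + r[["height"]] - 1L)
.rectCols <- function(r) seq.int(r[["col"]], r[["col"]] + r[["width"]]  - 1L)

.rectInside <- function(r, dim) {
    r[["row"]] >= 1 && r[["col"]] >= 1 &&
        r[["row"]] + r[["height"]] - 1 <= dim[1] &&
        r[["col"]] + r[["width"]]  - 1 <= dim[2]
}

#' Class-conditional feature calibration
#'
#' Holds per-class mean and standard deviation for each image-derived feature
#' (normalized red-to-green ratio, interface contour, basal nuclear area CoVa),
#' the distribution family used to emulate each feature, and per-class cohort
#' sizes. \code{NA} moments mark feature/class combinations that are not
#' defined (carcinoma sites are excluded from the microscopy features because
#' exophytic tumors cannot be imaged by the depth-resolved modality).
#'
#' @slot means,sds numeric matrices, classes x features.
#' @slot families named character, one of \code{"lognormal"} or
#'   \code{"truncnorm"} per feature.
#' @slot lowerBounds named numeric lower support bound per feature (used by the
#'   truncated-Gaussian family).
#' @slot cohortSizes named numeric, sites per class in the emulated cohort.
#' @export
setClass("FeatureCalibration", representation(
    means = "matrix", sds = "matrix", families = "character",
    lowerBounds = "numeric", cohortSizes = "numeric"))

setValidity("FeatureCalibration", function(object) {
    msg <- character()
    m <- object@means; s <- object@sds
    if (!identical(dim(m), dim(s)))
        msg <- c(msg, "means and sds must have identical dimensions")
    if (!all(.FEATURES %in% colnames(m)))
        msg <- c(msg, "means must have one column per feature")
    ok <- !is.na(m)
    if (any(m[ok] <= 0)) msg <- c(msg, "all means must be > 0")
    ok <- !is.na(s)
    if (any(s[ok] <= 0)) msg <- c(msg, "all sds must be > 0")
    if ("ecti_contour" %in% colnames(m)) {
        e <- m[, "ecti_contour"]
        if (any(e[!is.na(e)] < 1))
            msg <- c(msg, "ecti_contour means must be >= 1")
    }
    if (!all(object@families %in% c("lognormal", "truncnorm")))
        msg <- c(msg, "families must be 'lognormal' or 'truncnorm'")
    if (length(msg)) msg else TRUE
})

#' Widefield autofluorescence frame
#'
#' An RGB widefield fluorescence image together with the geometry needed for
#' internal-control normalization: the control strip on the sample holder and
#' an optional exclusion mask for folds, pins and pouch edges.
#'
#' @slot image numeric array \code{h x w x 3} (R, G, B intensity counts).
#' @slot whiteLight optional grayscale companion image (matrix) or NULL.
#' @slot controlRect \code{\link{roiRect}} of the internal-control strip.
#' @slot exclusionMask optional logical matrix, TRUE = excluded pixel.
#' @export
setClass("WFImage", representation(
    image = "array", whiteLight = "matrixOrNULL",
    controlRect = "numeric", exclusionMask = "matrixOrNULL"))

setValidity("WFImage", function(object) {
    d <- dim(object@image)
    if (length(d) != 3L || d[3] != 3L)
        return("image must be an h x w x 3 RGB array")
    if (!.rectInside(object@controlRect, d))
        return("control rectangle outside image bounds")
    if (!is.null(object@exclusionMask) &&
        !identical(dim(object@exclusionMask), d[1:2]))
        return("exclusion mask shape must match the image")
    TRUE
})

#' Two-channel nonlinear-microscopy z-stack
#'
#' Volumetric in vivo microscopy of mucosa: a multiphoton autofluorescence
#' channel (keratin, cytoplasmic NADH/FAD) and a second-harmonic channel
#' (fibrillar collagen of the stroma), on a common voxel grid. z increases
#' from the tissue surface downward; plane \code{k} sits at depth
#' \code{(k - 1) * zStep} micrometers.
#'
#' @slot mpm,shg numeric arrays \code{ny x nx x nz}.
#' @slot pixelSize lateral pixel size in micrometers (default 0.625).
#' @slot zStep axial step in micrometers (default 1).
#' @slot bitDepth nominal acquisition bit depth (8 or 16).
#' @export
setClass("NLOMStack", representation(
    mpm = "array", shg = "array", pixelSize = "numeric",
    zStep = "numeric", bitDepth = "numeric"))

setValidity("NLOMStack", function(object) {
    if (!identical(dim(object@mpm), dim(object@shg)))
        return("mpm and shg channels must have identical dimensions")
    if (length(dim(object@mpm)) != 3L)
        return("channels must be 3-dimensional (ny x nx x nz)")
    if (object@pixelSize <= 0 || object@zStep <= 0)
        return("pixelSize and zStep must be > 0")
    if (!object@bitDepth %in% c(8, 16))
        return("bitDepth must be 8 or 16")
    TRUE
})

#' Epithelium-stroma interface surface
#'
#' Lateral height map of the epithelial-connective-tissue interface (ECTI),
#' in micrometers of depth from the first acquired plane, with a validity
#' mask for lateral positions where no interface was found.
#'
#' @slot height numeric matrix of depths (micrometers).
#' @slot valid logical matrix, same shape.
#' @slot pixelSize lateral pixel size in micrometers.
#' @export
setClass("ECTISurface", representation(
    height = "matrix", valid = "matrix", pixelSize = "numeric"))

setValidity("ECTISurface", function(object) {
    if (!identical(dim(object@height), dim(object@valid)))
        return("height and valid mask must have identical shape")
    if (object@pixelSize <= 0) return("pixelSize must be > 0")
    h <- object@height[object@valid]
    if (length(h) && any(!is.finite(h))) return("valid heights must be finite")
    TRUE
})

#' Empirical ROC curve
#'
#' @slot thresholds candidate decision thresholds (ascending), including the
#'   -Inf/+Inf endpoints.
#' @slot sensitivity,specificity operating characteristics aligned with
#'   \code{thresholds} (classify positive when score >= threshold).
#' @slot auc area under the curve (trapezoid; equals the Mann-Whitney
#'   statistic with tie correction).
#' @slot operatingPoint named numeric (threshold, sensitivity, specificity) at
#'   the maximum of Youden's J; threshold ties break toward the lower
#'   threshold (higher sensitivity).
#' @slot direction \code{">"} if larger scores indicate the positive class.
#' @export
setClass("ROCResult", representation(
    thresholds = "numeric", sensitivity = "numeric", specificity = "numeric",
    auc = "numeric", operatingPoint = "numeric", direction = "character"))

setValidity("ROCResult", function(object) {
    n <- length(object@thresholds)
    if (length(object@sensitivity) != n || length(object@specificity) != n)
        return("sensitivity/specificity must align with thresholds")
    if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
    if (any(object@sensitivity < 0 | object@sensitivity > 1) ||
        any(object@specificity < 0 | object@specificity > 1))
        return("sensitivity and specificity must lie in [0, 1]")
    TRUE
})

#' Binomial GLM fit (logit link)
#'
#' @slot coefficients named coefficient vector (intercept first).
#' @slot se,zValues standard errors and Wald z statistics, aligned.
#' @slot deviance,nullDeviance residual and null deviance.
#' @slot iterations IRLS iterations used.
#' @slot converged FALSE when stopped at the iteration cap (e.g. under
#'   quasi-separation); the boundary is still usable.
#' @slot features predictor names included in the model.
#' @slot boundary human-readable description of the probability-0.5 linear
#'   decision boundary.
#' @slot trace per-cycle record for forward selection (empty otherwise).
#' @export
setClass("GLMFit", representation(
    coefficients = "numeric", se = "numeric", zValues = "numeric",
    deviance = "numeric", nullDeviance = "numeric", iterations = "numeric",
    converged = "logical", features = "character", boundary = "character",
    trace = "data.frame"))

setValidity("GLMFit", function(object) {
    if (length(object@coefficients) != length(object@features) + 1L)
        return("coefficient count must equal included-feature count + 1")
    if (object@iterations < 1) return("iterations must be >= 1")
    TRUE
})

#' Per-site classification report
#'
#' @slot predictions data.frame with site_id, truth, prob, predicted,
#'   misclassified.
#' @slot nMisclassified count of misclassified sites.
#' @slot sensitivity,specificity,percentCorrect summary statistics (percent
#'   correct on the 0-100 scale).
#' @slot roc ROC of model probabilities against truth.
#' @export
setClass("ClassificationReport", representation(
    predictions = "data.frame", nMisclassified = "numeric",
    sensitivity = "numeric", specificity = "numeric",
    percentCorrect = "numeric", roc = "ROCResult"))

setValidity("ClassificationReport", function(object) {
    p <- object@predictions
    need <- c("site_id", "truth", "prob", "predicted", "misclassified")
    if (!all(need %in% names(p)))
        return(paste("predictions must contain:", paste(need, collapse = ", ")))
    if (object@nMisclassified != sum(p$misclassified))
        return("nMisclassified inconsistent with per-site flags")
    TRUE
})
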