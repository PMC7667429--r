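#' Accessors for MucosalScope classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mpmChannel", function(object) standardGeneric("mpmChannel"))
#' @rdname accessors
#' @export
setGeneric("shgChannel", function(object) standardGeneric("shgChannel"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("zStep", function(object) standardGeneric("zStep"))
#' @rdname accessors
#' @export
setGeneric("heightMap", function(object) standardGeneric("heightMap"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))
#' @rdname accessors
#' @export
setGeneric("controlRect", function(object) standardGeneric("controlRect"))
#' @rdname accessors
#' @export
setGeneric("exclusionMask", function(object) standardGeneric("exclusionMask"))
#' @rdname accessors
#' @export
setGeneric("rocAUC", function(object) standardGeneric("rocAUC"))
#' @rdname accessors
#' @export
setGeneric("operatingPoint", function(object) standardGeneric("operatingPoint"))
#' @rdname accessors
#' @export
setGeneric("selectionTrace", function(object) standardGeneric("selectionTrace"))

#' @rdname accessors
#' @export
setMethod("mpmChannel", "NLOMStack", function(object) object@mpm)
#' @rdname accessors
#' @export
setMethod("shgChannel", "NLOMStack", function(object) object@shg)
#' @rdname accessors
#' @export
setMethod("pixelSize", "NLOMStack", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ECTISurface", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("zStep", "NLOMStack", function(object) object@zStep)
#' @rdname accessors
#' @export
setMethod("heightMap", "ECTISurface", function(object) object@height)
#' @rdname accessors
#' @export
setMethod("validMask", "ECTISurface", function(object) object@valid)
#' @rdname accessors
#' @export
setMethod("imageData", "WFImage", function(object) object@image)
#' @rdname accessors
#' @export
setMethod("controlRect", "WFImage", function(object) object@controlRect)
#' @rdname accessors
#' @export
setMethod("exclusionMask", "WFImage", function(object) object@exclusionMask)
#' @rdname accessors
#' @export
setMethod("rocAUC", "ROCResult", function(object) object@auc)
#' @rdname accessors
#' @export
setMethod("operatingPoint", "ROCResult", function(object) object@operatingPoint)
#' @rdname accessors
#' @export
setMethod("rocAUC", "ClassificationReport", function(object) object@roc@auc)
#' @rdname accessors
#' @export
setMethod("selectionTrace", "GLMFit", function(object) object@trace)

#' @describeIn accessors coefficients of a fitted logistic model
#' @export
setMethod("coef", "GLMFit", function(object) object@coefficients)

setMethod("show", "WFImage", function(object) {
    d <- dim(object@image)
    cat("WFImage:", d[1], "x", d[2], "RGB\n")
    cat("  control strip:", paste(round(object@controlRect), collapse = " "),
        "(row col height width)\n")
    cat("  white light:", if (is.null(object@whiteLight)) "none" else "present",
        "| exclusion mask:",
        if (is.null(object@exclusionMask)) "none"
        else paste0(sum(object@exclusionMask), " px"), "\n")
})

setMethod("show", "NLOMStack", function(object) {
    d <- dim(object@mpm)
    cat("NLOMStack:", d[1], "x", d[2], "x", d[3],
        sprintf("(%.4g um lateral, %.4g um z-step, %d-bit)\n",
                object@pixelSize, object@zStep, as.integer(object@bitDepth)))
})

setMethod("show", "ECTISurface", function(object) {
    d <- dim(object@height)
    h <- object@height[object@valid]
    cat("ECTISurface:", d[1], "x", d[2],
        sprintf("(%.4g um/px), %.1f%% valid", object@pixelSize,
                100 * mean(object@valid)))
    if (length(h))
        cat(sprintf(", depth %.2f-%.2f um", min(h), max(h)))
    cat("\n")
})

setMethod("show", "ROCResult", function(object) {
    op <- object@operatingPoint
    cat(sprintf("ROCResult: AUC = %.4f (direction %s)\n", object@auc,
                object@direction))
    cat(sprintf("  Youden point: threshold %.4g, sensitivity %.3f, specificity %.3f\n",
                op["threshold"], op["sensitivity"], op["specificity"]))
})

setMethod("show", "GLMFit", function(object) {
    cat("GLMFit (binomial, logit):",
        if (length(object@features)) paste(object@features, collapse = " + ")
        else "intercept only", "\n")
    print(round(object@coefficients, 4))
    cat(sprintf("  deviance %.3f (null %.3f), %d IRLS iterations, converged: %s\n",
                object@deviance, object@nullDeviance,
                as.integer(object@iterations), object@converged))
    if (nchar(object@boundary)) cat("  boundary:", object@boundary, "\n")
    if (nrow(object@trace)) {
        cat("  forward-selection trace:\n")
        print(object@trace)
    }
})

setMethod("show", "ClassificationReport", function(object) {
    cat(sprintf("ClassificationReport: %d/%d misclassified (%.1f%% correct)\n",
                as.integer(object@nMisclassified), nrow(object@predictions),
                object@percentCorrect))
    cat(sprintf("  sensitivity %.3f, specificity %.3f, AUC %.4f\n",
                object@sensitivity, object@specificity, object@roc@auc))
})

setMethod("show", "FeatureCalibration", function(object) {
    cat("FeatureCalibration (mean +/- sd):\n")
    m <- object@means; s <- object@sds
    for (cl in rownames(m)) {
        vals <- vapply(colnames(m), function(f) {
            if (is.na(m[cl, f])) "--"
            else sprintf("%.3g+/-%.3g", m[cl, f], s[cl, f])
        }, character(1))
        cat(sprintf("  %-12s %s\n", cl,
                    paste(sprintf("%s=%s", colnames(m), vals), collapse = "  ")))
    }
    cat("  families:", paste(names(object@families), object@families,
                             sep = ":", collapse = "  "), "\n")
    cat("  cohort sizes:", paste(names(object@cohortSizes),
                                 object@cohortSizes, sep = "=", collapse = "  "), "\n")
})
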