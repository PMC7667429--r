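#' Simulate a per-site feature table from a class-conditional calibration
#'
#' Draws one row per site with histology class label and the three image
#' features sampled independently from the calibrated class-conditional
#' distributions (lognormal for normalized RG; lower-truncated Gaussians,
#' moment-matched after truncation, for ECTI contour and CoVa). Features that
#' are undefined for a class (microscopy features for OSCC by default) are
#' \code{NA}. Identical (calibration, counts, seed) give an identical table.
#'
#' Features are drawn independently within a site; the emulated cohort carries
#' no within-site cross-modality correlation (see the methods vignette).
#'
#' @param calibration A \code{\linkS4class{FeatureCalibration}}.
#' @param nPerClass named integer vector of sites per class; defaults to the
#'   calibration's cohort sizes.
#' @param seed integer random seed.
#' @return data.frame with columns \code{site_id}, \code{class},
#'   \code{normalized_rg}, \code{ecti_contour}, \code{basal_cova}.
#' @examples
#' tab <- genFeatureTable(defaultFeatureCalibration(),
#'                        c(normal = 5, OED = 5), seed = 1)
#' tab
#' @export
genFeatureTable <- function(calibration, nPerClass = NULL, seed = 1L) {
    stopifnot(is(calibration, "FeatureCalibration"))
    validObject(calibration)
    if (is.null(nPerClass)) nPerClass <- calibration@cohortSizes
    if (is.null(names(nPerClass)) || any(!nzchar(names(nPerClass))))
        stop("nPerClass must be a named vector of class counts")
    unknown <- setdiff(names(nPerClass), rownames(calibration@means))
    if (length(unknown))
        stop("unknown class label(s): ", paste(unknown, collapse = ", "))
    if (any(nPerClass < 1 | nPerClass != round(nPerClass)))
        stop("all class counts must be positive integers")

    set.seed(as.integer(seed))
    feats <- colnames(calibration@means)
    rows <- lapply(names(nPerClass), function(cl) {
        n <- as.integer(nPerClass[[cl]])
        draws <- lapply(feats, function(f)
            .drawFeature(n, cl, f, calibration))
        names(draws) <- feats
        data.frame(site_id = sprintf("%s_%04d", cl, seq_len(n)),
                   class = cl, draws, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

## One class/feature sample of size n; NA moments give NA draws.
.drawFeature <- function(n, cl, feature, calibration) {
    m <- calibration@means[cl, feature]
    s <- calibration@sds[cl, feature]
    if (is.na(m) || is.na(s)) return(rep(NA_real_, n))
    lower <- calibration@lowerBounds[[feature]]
    fam <- calibration@families[[feature]]
    if (s < .Machine$double.eps^0.5)          # degenerate dispersion
        return(rep(m, n))
    if (fam == "lognormal") {
        p <- .lognormParams(m, s)
        stats::rlnorm(n, p$meanlog, p$sdlog)
    } else {
        p <- truncnormParams(m, s, lower)
        .rtruncnorm(n, p$mu, p$sigma, lower)
    }
}
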