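## Moment-matched positive-support distributions for feature emulation.
##
## Features are emulated from families with the correct support: a lognormal
## for the right-skewed normalized RG ratio, and lower-truncated Gaussians for
## the interface contour (support > 1: a triangulated surface can never have
## less area than its projection) and the nuclear-area CoVa (support > 0).
## The parameters are solved so that the *post-truncation* mean and sd equal
## the requested moments; a naive truncation of N(mean, sd) would bias the
## mean upward whenever the bound is within a few sd of it.

## Inverse Mills ratio, stable for large |a|.
.millsLambda <- function(a)
    exp(stats::dnorm(a, log = TRUE) -
        stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))

## sd/(mean - lower) of a lower-truncated standard normal as a function of
## the standardized bound alpha; strictly increasing from 0 toward 1.
.truncRatio <- function(alpha) {
    lam <- .millsLambda(alpha)
    sqrt(pmax(1 - lam * (lam - alpha), 0)) / (lam - alpha)
}

#' Solve pre-truncation Gaussian parameters for target truncated moments
#'
#' Finds \code{(mu, sigma)} such that a Gaussian truncated below at
#' \code{lower} has the requested mean and standard deviation.
#'
#' @param mean,sd target moments of the truncated distribution.
#' @param lower lower support bound.
#' @return list with \code{mu}, \code{sigma}, \code{alpha} (standardized
#'   bound \code{(lower - mu)/sigma}).
#' @keywords internal
truncnormParams <- function(mean, sd, lower) {
    if (mean <= lower) stop("target mean must exceed the lower bound")
    if (sd <= 0) stop("target sd must be > 0")
    target <- sd / (mean - lower)
    if (target >= 1)
        stop("sd/(mean - lower) >= 1 is not attainable by a truncated Gaussian")
    f <- function(a) .truncRatio(a) - target
    alpha <- stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
    lam <- .millsLambda(alpha)
    sigma <- sd / sqrt(1 - lam * (lam - alpha))
    list(mu = lower - alpha * sigma, sigma = sigma, alpha = alpha)
}

## Exact inverse-CDF sampler for the lower-truncated Gaussian.
.rtruncnorm <- function(n, mu, sigma, lower) {
    plo <- stats::pnorm((lower - mu) / sigma)
    mu + sigma * stats::qnorm(stats::runif(n, plo, 1))
}

## Lognormal moment matching (closed form).
.lognormParams <- function(mean, sd) {
    sdlog2 <- log(1 + (sd / mean)^2)
    list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Construct a feature calibration
#'
#' @param means,sds classes x features numeric matrices (rownames = classes,
#'   colnames = features); \code{NA} marks undefined combinations.
#' @param families named character: distribution family per feature,
#'   \code{"lognormal"} or \code{"truncnorm"}.
#' @param lowerBounds named numeric: lower support bound per feature.
#' @param cohortSizes named numeric: emulated sites per class.
#' @return A \code{\linkS4class{FeatureCalibration}}.
#' @export
featureCalibration <- function(means, sds, families, lowerBounds, cohortSizes) {
    new("FeatureCalibration", means = means, sds = sds, families = families,
        lowerBounds = lowerBounds, cohortSizes = cohortSizes)
}

#' Default class-conditional feature calibration
#'
#' The default calibration encodes the class-conditional moments of the three
#' image features in the hamster buccal-pouch cohort: normalized RG
#' 1.23 +/- 0.55 (normal), 2.48 +/- 0.96 (inflammation), 3.13 +/- 3.23 (OED),
#' 8.15 +/- 4.9 (OSCC); ECTI contour 1.55 +/- 0.37, 2.43 +/- 1.03,
#' 4.28 +/- 1.88 (no OSCC value: protruding tumors are excluded from
#' depth-resolved microscopy); basal nuclear-area CoVa 0.21 +/- 0.04,
#' 0.2 +/- 0.05, 0.4 +/- 0.09 (likewise no OSCC).
#'
#' @return A \code{\linkS4class{FeatureCalibration}}.
#' @examples
#' defaultFeatureCalibration()
#' @export
defaultFeatureCalibration <- function() {
    means <- rbind(
        normal       = c(1.23, 1.55, 0.21),
        inflammation = c(2.48, 2.43, 0.20),
        OED          = c(3.13, 4.28, 0.40),
        OSCC         = c(8.15, NA,   NA))
    sds <- rbind(
        normal       = c(0.55, 0.37, 0.04),
        inflammation = c(0.96, 1.03, 0.05),
        OED          = c(3.23, 1.88, 0.09),
        OSCC         = c(4.90, NA,   NA))
    colnames(means) <- colnames(sds) <- .FEATURES
    featureCalibration(
        means, sds,
        families = c(normalized_rg = "lognormal", ecti_contour = "truncnorm",
                     basal_cova = "truncnorm"),
        lowerBounds = c(normalized_rg = 0, ecti_contour = 1, basal_cova = 0),
        cohortSizes = c(normal = 37, inflammation = 16, OED = 28, OSCC = 31))
}

#' Emulated cohort sizes per modality
#'
#' Site counts per histology class in the emulated study: 37/16/28/31
#' (normal/inflammation/OED/OSCC) for widefield analysis and 33/11/19
#' (normal/inflammation/OED) for the microscopy substudy, from which tumors
#' were excluded.
#'
#' @param modality \code{"widefield"} or \code{"nlom"}.
#' @return Named integer vector of sites per class.
#' @export
defaultCohortSizes <- function(modality = c("widefield", "nlom")) {
    modality <- match.arg(modality)
    if (modality == "widefield")
        c(normal = 37L, inflammation = 16L, OED = 28L, OSCC = 31L)
    else
        c(normal = 33L, inflammation = 11L, OED = 19L)
}

#' @rdname accessors
#' @export
setGeneric("featureMeans", function(object) standardGeneric("featureMeans"))
#' @rdname accessors
#' @export
setGeneric("featureSds", function(object) standardGeneric("featureSds"))
#' @rdname accessors
#' @export
setMethod("featureMeans", "FeatureCalibration", function(object) object@means)
#' @rdname accessors
#' @export
setMethod("featureSds", "FeatureCalibration", function(object) object@sds)
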