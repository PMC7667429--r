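#' Pipeline configuration
#'
#' Assembles and validates the configuration of the end-to-end run:
#' simulation, widefield extraction, microscopy feature extraction and
#' classification. All tunables carry the defaults used throughout the
#' package; the paths are created on demand.
#'
#' @param outputDir output directory (created if missing).
#' @param seed integer seed governing every random stage.
#' @param simulate generate the cohort synthetically (the only mode that
#'   needs no input files).
#' @param featuresPath input feature CSV when \code{simulate = FALSE}.
#' @param calibration \code{\linkS4class{FeatureCalibration}} for simulation.
#' @param cohort named per-class site counts (default: the microscopy
#'   substudy cohort, 33/11/19).
#' @param neoplasticDef \code{"oed"} or \code{"oed_oscc"}
#'   (\code{\link{neoplasticLabels}}).
#' @param rgThreshold widefield decision threshold for the suspicion map
#'   (default 1.46).
#' @param epsilon invalid-green intensity floor (counts).
#' @param displayWindow heat-map clamp range.
#' @param shgThresholdFrac,sigmaLateral,sigmaAxial interface-extraction
#'   parameters (\code{\link{extractECTI}}).
#' @param basalSpacing basal plane separation, micrometers.
#' @param renderWFSites,renderNLOMSites how many sites are pushed through
#'   full image rendering + extraction (the rest keep their simulated
#'   feature values); rendering every site is supported but slow.
#' @param renderDim lateral size of rendered stacks.
#' @param nNucleiPerPlane planted nuclei per basal plane in rendered stacks.
#' @return A validated config (list with class \code{"PipelineConfig"}).
#' @export
pipelineConfig <- function(outputDir = tempfile("mucosalscope_run_"),
                           seed = 1L, simulate = TRUE, featuresPath = NULL,
                           calibration = defaultFeatureCalibration(),
                           cohort = defaultCohortSizes("nlom"),
                           neoplasticDef = c("oed", "oed_oscc"),
                           rgThreshold = 1.46, epsilon = 1,
                           displayWindow = c(0, 7), shgThresholdFrac = 0.2,
                           sigmaLateral = 2, sigmaAxial = 1, basalSpacing = 5,
                           renderWFSites = 3L, renderNLOMSites = 2L,
                           renderDim = c(128, 128), nNucleiPerPlane = 12L) {
    neoplasticDef <- match.arg(neoplasticDef)
    stopifnot(rgThreshold > 0, epsilon >= 0,
              shgThresholdFrac > 0, shgThresholdFrac < 1,
              basalSpacing >= 5, basalSpacing <= 10,
              renderWFSites >= 0, renderNLOMSites >= 0)
    if (!simulate && is.null(featuresPath))
        stop("pipelineConfig: featuresPath is required when simulate = FALSE")
    structure(list(
        outputDir = outputDir, seed = as.integer(seed), simulate = simulate,
        featuresPath = featuresPath, calibration = calibration,
        cohort = cohort, neoplasticDef = neoplasticDef,
        rgThreshold = rgThreshold, epsilon = epsilon,
        displayWindow = displayWindow, shgThresholdFrac = shgThresholdFrac,
        sigmaLateral = sigmaLateral, sigmaAxial = sigmaAxial,
        basalSpacing = basalSpacing, renderWFSites = as.integer(renderWFSites),
        renderNLOMSites = as.integer(renderNLOMSites), renderDim = renderDim,
        nNucleiPerPlane = as.integer(nNucleiPerPlane)),
        class = "PipelineConfig")
}

## Corrugation amplitude whose sinusoidal interface has the target contour.
.amplitudeForContour <- function(contour, period) {
    if (contour <= 1 + 1e-9) return(0)
    stats::uniroot(function(A) sinusoidSurfaceRatio(A, period) - contour,
                   c(0, 3 * period), tol = 1e-8)$root
}

## Render a widefield scene for the given sites (planted normalized RG =
## feature value), extract normalized RG, return measured values + artifacts.
.renderWFStage <- function(values, config) {
    n <- length(values)
    ncols <- ceiling(sqrt(n))
    nrows <- ceiling(n / ncols)
    spacing <- 60; margin <- 70
    h <- margin + nrows * spacing + 20
    w <- max(margin + ncols * spacing + 20, 200)
    centers <- cbind(
        row = margin + spacing * ((seq_len(n) - 1) %/% ncols),
        col = margin + spacing * ((seq_len(n) - 1) %% ncols))
    ## background red = green so the background ratio equals the control
    ## ratio and a focus red-multiplier of v plants normalized RG = v
    foci <- data.frame(row = centers[, "row"], col = centers[, "col"],
                       radius = 22, redMult = values, greenMult = 1)
    spec <- syntheticWFSpec(
        dim = c(h, w), backgroundRed = 80, backgroundGreen = 80,
        controlRect = roiRect(6, 6, 24, w - 10), controlRed = 90,
        controlGreen = 90, foci = foci, noiseSd = 1, seed = config$seed + 101)
    scene <- genWFImage(spec)
    sites <- lapply(seq_len(n), function(i)
        lapply(c(-3, 0, 3), function(o)
            roiRect(centers[i, "row"] - 10 + o, centers[i, "col"] - 10, 20, 20)))
    names(sites) <- sprintf("wf_%02d", seq_len(n))
    feats <- wfSiteFeatures(scene$image, sites, epsilon = config$epsilon)
    ch <- splitChannels(scene$image)
    ic <- controlFactor(ch, tileControlROIs(controlRect(scene$image)),
                        config$epsilon)
    heat <- rgHeatmap(ch, ic, epsilon = config$epsilon,
                      window = config$displayWindow)
    ov <- thresholdOverlay(heat, config$rgThreshold,
                           scene$image@whiteLight)
    list(measured = feats$normalized_rg, scene = scene, heatmap = heat,
         overlay = ov)
}

## Render one z-stack per site with planted contour/CoVa, re-extract both.
.renderNLOMStage <- function(contours, covas, config) {
    px <- 0.625
    vapplyRows <- function(i) {
        A <- .amplitudeForContour(contours[i], period = 40)
        depth <- 26 + A
        nz <- ceiling(depth + A + 4)
        s <- config$basalSpacing
        spec <- syntheticNLOMSpec(
            dim = config$renderDim, pixelSize = px, nz = nz,
            keratinRange = c(0, 14 - s - 2), basalRange = c(14 - s, 14 + s),
            interfaceDepth = depth, corrugationAmplitude = A,
            corrugationPeriod = 40,
            nNucleiPerPlane = config$nNucleiPerPlane,
            targetCova = covas[i], noiseSd = 2, seed = config$seed + 500 + i)
        sc <- genNLOMStack(spec)
        nlomSiteFeatures(sc$stack, basalHint = 14,
                         spacing = config$basalSpacing,
                         siteId = sprintf("nlom_%02d", i),
                         thresholdFrac = config$shgThresholdFrac,
                         sigmaLateral = config$sigmaLateral,
                         sigmaAxial = config$sigmaAxial)
    }
    do.call(rbind, lapply(seq_along(contours), vapplyRows))
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the study sequence: cohort simulation (or feature-CSV input),
#' widefield normalized-RG extraction on a rendered scene, microscopy
#' feature extraction on rendered z-stacks, then group statistics, ROC
#' analysis per feature, the two-feature logistic models and the
#' three-feature forward-selection model, and a per-site classification
#' report. Every artifact is written under \code{config$outputDir} along
#' with a manifest (config, seed, versions, feature-file checksum).
#' Identical config + seed give byte-identical feature CSVs.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return Invisible list with the feature table, per-feature ROC results,
#'   the fitted models, the classification report and the artifact paths.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)

    ## 1. cohort features
    feats <- if (config$simulate)
        genFeatureTable(config$calibration, config$cohort, seed = config$seed)
    else readFeatureTable(config$featuresPath)

    ## 2. widefield stage on rendered scene for the first sites
    nWF <- min(config$renderWFSites, nrow(feats))
    if (nWF > 0) {
        wf <- .renderWFStage(feats$normalized_rg[seq_len(nWF)], config)
        feats$normalized_rg[seq_len(nWF)] <- wf$measured
        writeWFImage(wf$scene$image,
                     file.path(config$outputDir, "wf_scene.tif"))
        heat <- wf$heatmap; heat[is.na(heat)] <- 0
        tiff::writeTIFF(heat / max(heat, 1),
                        file.path(config$outputDir, "wf_rg_heatmap.tif"),
                        bits.per.sample = 16)
        if (!is.null(wf$overlay$overlay))
            tiff::writeTIFF(wf$overlay$overlay,
                            file.path(config$outputDir, "wf_overlay.tif"),
                            bits.per.sample = 8)
    }

    ## 3. microscopy stage on rendered stacks (non-OSCC sites only)
    eligible <- which(!is.na(feats$ecti_contour) & !is.na(feats$basal_cova))
    nNL <- min(config$renderNLOMSites, length(eligible))
    if (nNL > 0) {
        pick <- eligible[seq_len(nNL)]
        nl <- .renderNLOMStage(feats$ecti_contour[pick],
                               feats$basal_cova[pick], config)
        feats$ecti_contour[pick] <- nl$ecti_contour
        feats$basal_cova[pick] <- nl$cova
        writeFeatureTable(nl, file.path(config$outputDir,
                                        "nlom_site_features.csv"))
    }

    featPath <- file.path(config$outputDir, "features.csv")
    writeFeatureTable(feats, featPath)

    ## 4. statistics and classification on sites with complete features
    complete <- stats::complete.cases(
        feats[, c("normalized_rg", "ecti_contour", "basal_cova")])
    tab <- feats[complete, ]
    y <- neoplasticLabels(tab$class, config$neoplasticDef)

    groups <- lapply(.FEATURES, function(f)
        groupCompare(tab[[f]], tab$class))
    names(groups) <- .FEATURES
    rocs <- lapply(.FEATURES, function(f) rocCurve(tab[[f]], y))
    names(rocs) <- .FEATURES
    for (f in .FEATURES) {
        r <- rocs[[f]]
        utils::write.csv(data.frame(threshold = r@thresholds,
                                    sensitivity = r@sensitivity,
                                    specificity = r@specificity),
                         file.path(config$outputDir,
                                   paste0("roc_", f, ".csv")),
                         row.names = FALSE)
    }
    pairs <- list(rg_ecti = c("normalized_rg", "ecti_contour"),
                  rg_cova = c("normalized_rg", "basal_cova"))
    glms <- lapply(pairs, function(p) fitGLM(tab, p, y))
    fwd <- forwardSelect(tab, y)
    report <- classifySites(fwd, tab, y)

    jsonlite::write_json(list(
        pair_models = lapply(glms, function(g) as.list(coef(g))),
        forward_model = list(coefficients = as.list(coef(fwd)),
                             trace = fwd@trace,
                             converged = fwd@converged,
                             iterations = fwd@iterations),
        auc = lapply(rocs, function(r) r@auc),
        forward_auc = report@roc@auc),
        file.path(config$outputDir, "model.json"),
        auto_unbox = TRUE, digits = NA)
    utils::write.csv(report@predictions,
                     file.path(config$outputDir, "report.csv"),
                     row.names = FALSE)

    manifest <- list(
        package = "MucosalScope",
        version = as.character(utils::packageVersion("MucosalScope")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = config$seed,
        neoplastic_definition = config$neoplasticDef,
        cohort = as.list(config$cohort),
        rg_threshold = config$rgThreshold,
        features_md5 = unname(tools::md5sum(featPath)))
    jsonlite::write_json(manifest,
                         file.path(config$outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)

    invisible(list(features = feats, groupStats = groups, roc = rocs,
                   pairModels = glms, forwardModel = fwd, report = report,
                   outputDir = config$outputDir))
}
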