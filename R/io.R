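## File formats: 8/16-bit TIFF images and stacks, CSV feature tables and ROI
## geometry, JSON ground-truth sidecars. Stacks are stored as multi-page
## TIFF with channels interleaved per plane (MPM_1, SHG_1, MPM_2, SHG_2, ...)
## and intensities quantized to the stated bit depth; a quantized file
## round-trips bit-identically.

.bitMax <- function(bitDepth) {
    if (!bitDepth %in% c(8, 16))
        stop("unsupported bit depth: ", bitDepth, " (only 8 and 16 supported)")
    2^bitDepth - 1
}

#' Write / read a two-channel z-stack as multi-page TIFF
#'
#' @param stack An \code{\linkS4class{NLOMStack}}.
#' @param path TIFF file path.
#' @return \code{readNLOMStack} returns an \code{\linkS4class{NLOMStack}}.
#' @rdname stackIO
#' @export
writeNLOMStack <- function(stack, path) {
    stopifnot(is(stack, "NLOMStack"))
    mx <- .bitMax(stack@bitDepth)
    nz <- dim(mpmChannel(stack))[3]
    pages <- vector("list", 2L * nz)
    for (k in seq_len(nz)) {
        pages[[2L * k - 1L]] <- pmin(pmax(mpmChannel(stack)[, , k], 0), mx) / mx
        pages[[2L * k]]      <- pmin(pmax(shgChannel(stack)[, , k], 0), mx) / mx
    }
    tiff::writeTIFF(pages, path, bits.per.sample = stack@bitDepth)
    invisible(path)
}

#' @param pixelSize,zStep,bitDepth voxel geometry of the file (not stored in
#'   the TIFF itself).
#' @rdname stackIO
#' @export
readNLOMStack <- function(path, pixelSize = 0.625, zStep = 1, bitDepth = 8) {
    mx <- .bitMax(bitDepth)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) %% 2L != 0L)
        stop("readNLOMStack: expected an even number of pages (two channels)")
    nz <- length(pages) / 2L
    d <- dim(pages[[1]])
    if (length(d) != 2L)
        stop("readNLOMStack: pages must be single-channel grayscale")
    mpm <- array(0, c(d, nz)); shg <- array(0, c(d, nz))
    for (k in seq_len(nz)) {
        mpm[, , k] <- round(pages[[2L * k - 1L]] * mx)
        shg[, , k] <- round(pages[[2L * k]] * mx)
    }
    new("NLOMStack", mpm = mpm, shg = shg, pixelSize = pixelSize,
        zStep = zStep, bitDepth = bitDepth)
}

#' Write / read a widefield RGB frame as TIFF
#'
#' @param image A \code{\linkS4class{WFImage}}.
#' @param path TIFF file path.
#' @param bitDepth 8 or 16.
#' @rdname wfIO
#' @export
writeWFImage <- function(image, path, bitDepth = 8) {
    stopifnot(is(image, "WFImage"))
    mx <- .bitMax(bitDepth)
    tiff::writeTIFF(pmin(pmax(imageData(image), 0), mx) / mx, path,
                    bits.per.sample = bitDepth)
    invisible(path)
}

#' @param controlRect control-strip \code{\link{roiRect}} of the frame.
#' @param whiteLightPath,exclusionMaskPath optional companion TIFFs
#'   (grayscale; the mask is nonzero = excluded).
#' @rdname wfIO
#' @export
readWFImage <- function(path, controlRect, bitDepth = 8,
                        whiteLightPath = NULL, exclusionMaskPath = NULL) {
    mx <- .bitMax(bitDepth)
    arr <- tiff::readTIFF(path)
    if (length(dim(arr)) != 3L || dim(arr)[3] < 3L)
        stop("readWFImage: expected an RGB TIFF")
    arr <- round(arr[, , 1:3] * mx)
    wl <- if (!is.null(whiteLightPath))
        round(tiff::readTIFF(whiteLightPath) * mx) else NULL
    ex <- if (!is.null(exclusionMaskPath))
        tiff::readTIFF(exclusionMaskPath) > 0 else NULL
    new("WFImage", image = arr, whiteLight = wl,
        controlRect = .asRect(controlRect), exclusionMask = ex)
}

#' Write an interface height map as TIFF plus JSON scale sidecar
#'
#' Heights are stored as a 16-bit TIFF scaled to the depth extent; the
#' sidecar records the scale so the map re-reads in micrometers.
#'
#' @param surface An \code{\linkS4class{ECTISurface}}.
#' @param path TIFF path; the sidecar is \code{<path>.json}.
#' @export
writeECTISurface <- function(surface, path) {
    stopifnot(is(surface, "ECTISurface"))
    h <- heightMap(surface)
    zmax <- max(h[validMask(surface)], 1e-9)
    tiff::writeTIFF(pmin(pmax(h / zmax, 0), 1), path, bits.per.sample = 16)
    tiff::writeTIFF(validMask(surface) * 1, paste0(tools::file_path_sans_ext(path),
                                                   "_valid.tif"),
                    bits.per.sample = 8)
    jsonlite::write_json(list(scale_um = zmax,
                              pixel_size_um = pixelSize(surface)),
                         paste0(path, ".json"), auto_unbox = TRUE)
    invisible(path)
}

#' Feature-table CSV with schema validation
#'
#' Columns: site_id, class, normalized_rg, ecti_contour, basal_cova (the
#' microscopy columns may be NA, e.g. for carcinoma sites).
#'
#' @param table feature data.frame.
#' @param path CSV path.
#' @rdname featureIO
#' @export
writeFeatureTable <- function(table, path) {
    utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname featureIO
#' @export
readFeatureTable <- function(path) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("site_id", "class", "normalized_rg", "ecti_contour", "basal_cova")
    missingCols <- setdiff(need, names(tab))
    if (length(missingCols))
        stop("readFeatureTable: missing required column(s): ",
             paste(missingCols, collapse = ", "))
    for (col in c("normalized_rg", "ecti_contour", "basal_cova")) {
        bad <- which(!is.na(tab[[col]]) & !is.finite(suppressWarnings(
            as.numeric(tab[[col]]))))
        if (length(bad))
            stop("readFeatureTable: non-numeric ", col, " at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", "))
        tab[[col]] <- as.numeric(tab[[col]])
    }
    badClass <- which(!tab$class %in% .CLASSES)
    if (length(badClass))
        stop("readFeatureTable: unknown class at row(s) ",
             paste(utils::head(badClass, 5), collapse = ", "))
    tab
}

#' Site-ROI geometry CSV
#'
#' Columns: site_id, roi (1-3), row, col; each site needs exactly three
#' 20 x 20 ROIs given by their top-left pixel.
#'
#' @param path CSV path.
#' @param size ROI side in pixels (default 20).
#' @return Named list (per site) of lists of three \code{\link{roiRect}}s.
#' @export
readSiteROIs <- function(path, size = 20L) {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("site_id", "roi", "row", "col")
    missingCols <- setdiff(need, names(tab))
    if (length(missingCols))
        stop("readSiteROIs: missing required column(s): ",
             paste(missingCols, collapse = ", "))
    sites <- split(tab, tab$site_id)
    lapply(sites, function(s) {
        if (nrow(s) != 3L)
            stop("readSiteROIs: site ", s$site_id[1], " has ", nrow(s),
                 " ROIs (need exactly 3)")
        lapply(seq_len(3), function(i)
            roiRect(s$row[i], s$col[i], size, size))
    })
}
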