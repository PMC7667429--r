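#' Split a widefield RGB frame into red and green channel maps
#'
#' The red and green autofluorescence channels (nominal 580-700 nm and
#' 500-580 nm emission) are taken directly from the R and G planes of the
#' demosaiced RGB frame; the blue plane is discarded.
#'
#' @param image A \code{\linkS4class{WFImage}} or an h x w x 3 array.
#' @return list with \code{red} and \code{green} intensity matrices.
#' @examples
#' sc <- genWFImage(syntheticWFSpec(noiseSd = 0))
#' ch <- splitChannels(sc$image)
#' dim(ch$red)
#' @export
splitChannels <- function(image) {
    arr <- if (is(image, "WFImage")) imageData(image) else image
    if (length(dim(arr)) != 3L || dim(arr)[3] < 3L)
        stop("splitChannels: input must be an RGB (h x w x 3) image")
    if (any(arr < 0)) stop("splitChannels: negative intensities")
    list(red = arr[, , 1], green = arr[, , 2])
}

#' Mean intensity over a rectangular ROI
#'
#' @param map intensity matrix.
#' @param roi a \code{\link{roiRect}}.
#' @return Arithmetic mean over the ROI pixels.
#' @examples
#' roiMean(matrix(1:4, 2, 2), roiRect(1, 1, 2, 2))  # 2.5
#' @export
roiMean <- function(map, roi) {
    if (!.rectInside(roi, dim(map)))
        stop("roiMean: ROI extends outside the intensity map")
    mean(map[.rectRows(roi), .rectCols(roi)])
}

#' Internal-control normalization factor (IC-RG)
#'
#' Mean of the five per-ROI red/green intensity ratios measured on the
#' internal-control strip of the sample holder; used to normalize site
#' ratios against illumination and acquisition variation.
#'
#' @param channels list with \code{red}/\code{green} matrices
#'   (\code{\link{splitChannels}}).
#' @param controlROIs list of exactly five \code{\link{roiRect}}s on the
#'   control strip.
#' @param epsilon smallest admissible green mean (counts); a control ROI at
#'   or below it is an error.
#' @return The IC-RG scalar.
#' @export
controlFactor <- function(channels, controlROIs, epsilon = 1) {
    if (length(controlROIs) != 5L)
        stop("controlFactor: exactly 5 control ROIs are required, got ",
             length(controlROIs))
    ratios <- vapply(controlROIs, function(roi) {
        g <- roiMean(channels$green, roi)
        if (g <= epsilon)
            stop("controlFactor: control ROI with green mean <= ", epsilon)
        roiMean(channels$red, roi) / g
    }, numeric(1))
    mean(ratios)
}

#' Normalized red-to-green ratio of one site
#'
#' Each of the three 20 x 20 site ROIs yields a red/green mean-intensity
#' ratio; each is divided by the internal-control factor and the three
#' normalized ratios are averaged to give the site's normalized RG value.
#' Multiplying every pixel of both channels (sites and control alike) by any
#' positive constant leaves the value unchanged.
#'
#' @param channels list with \code{red}/\code{green} matrices.
#' @param siteROIs list of exactly three \code{\link{roiRect}}s.
#' @param ic the IC-RG control factor (> 0), from \code{\link{controlFactor}}.
#' @param epsilon smallest admissible green mean.
#' @return The dimensionless normalized RG value (> 0).
#' @export
normalizedRG <- function(channels, siteROIs, ic, epsilon = 1) {
    if (length(siteROIs) != 3L)
        stop("normalizedRG: exactly 3 site ROIs are required, got ",
             length(siteROIs))
    if (!is.finite(ic) || ic <= 0)
        stop("normalizedRG: control factor must be > 0")
    ratios <- vapply(siteROIs, function(roi) {
        g <- roiMean(channels$green, roi)
        if (g <= epsilon)
            stop("normalizedRG: site ROI with green mean <= ", epsilon)
        roiMean(channels$red, roi) / g
    }, numeric(1))
    mean(ratios / ic)
}

#' Per-pixel normalized RG map
#'
#' Per-pixel (red/green)/IC-RG with invalid pixels (excluded by mask or with
#' green at or below \code{epsilon}) set to \code{NA}. Values are clamped to
#' \code{window} for display; statistics downstream should use the
#' unclamped = FALSE default only for rendering.
#'
#' @param channels list with \code{red}/\code{green} matrices.
#' @param ic control factor (> 0).
#' @param exclusionMask optional logical matrix, TRUE = exclude.
#' @param epsilon invalid-green threshold (counts).
#' @param window display clamp range, default \code{c(0, 7)}; \code{NULL}
#'   for no clamping.
#' @return Matrix of normalized RG values with \code{NA} at invalid pixels.
#' @export
rgHeatmap <- function(channels, ic, exclusionMask = NULL, epsilon = 1,
                      window = c(0, 7)) {
    if (!is.finite(ic) || ic <= 0) stop("rgHeatmap: control factor must be > 0")
    red <- channels$red; green <- channels$green
    map <- red / green / ic
    map[green <= epsilon] <- NA
    if (!is.null(exclusionMask)) {
        if (!identical(dim(exclusionMask), dim(map)))
            stop("rgHeatmap: exclusion mask shape mismatch")
        map[exclusionMask] <- NA
    }
    if (!is.null(window))
        map <- pmin(pmax(map, window[1]), window[2])
    map
}

#' Threshold mask and white-light overlay of a normalized RG map
#'
#' Pixels whose normalized RG exceeds the threshold (default 1.46, the ROC
#' operating threshold separating normal from neoplastic mucosa) are flagged
#' suspicious and rendered in a highlight color over the grayscale
#' white-light image.
#'
#' @param rgMap normalized RG matrix (\code{NA} = invalid).
#' @param threshold decision threshold (> 0), default 1.46.
#' @param whiteLight optional grayscale matrix, same shape.
#' @param highlight RGB triplet (0-1) for flagged pixels.
#' @return list with \code{mask} (logical; NA-invalid pixels are FALSE) and
#'   \code{overlay} (h x w x 3 array in [0, 1], or NULL when no white-light
#'   image is supplied).
#' @export
thresholdOverlay <- function(rgMap, threshold = 1.46, whiteLight = NULL,
                             highlight = c(1, 0, 0)) {
    if (!is.finite(threshold) || threshold < 0)
        stop("thresholdOverlay: threshold must be >= 0")
    mask <- !is.na(rgMap) & rgMap > threshold
    overlay <- NULL
    if (!is.null(whiteLight)) {
        if (!identical(dim(whiteLight), dim(rgMap)))
            stop("thresholdOverlay: white-light image shape mismatch")
        g <- whiteLight / max(whiteLight, 1e-12)
        overlay <- array(rep(g, 3), c(dim(g), 3))
        for (ch in 1:3) {
            plane <- overlay[, , ch]
            plane[mask] <- highlight[ch]
            overlay[, , ch] <- plane
        }
    }
    list(mask = mask, overlay = overlay)
}

#' Per-site widefield feature extraction
#'
#' Convenience wrapper: splits channels, measures the control factor and the
#' normalized RG of each site of a frame.
#'
#' @param image A \code{\linkS4class{WFImage}}.
#' @param sites named list; each element a list of three site
#'   \code{\link{roiRect}}s.
#' @param controlROIs list of five control \code{\link{roiRect}}s; by default
#'   five ROIs tiled along the image's control strip.
#' @param epsilon invalid-green threshold.
#' @return data.frame with site_id, ic_rg and normalized_rg.
#' @export
wfSiteFeatures <- function(image, sites, controlROIs = NULL, epsilon = 1) {
    stopifnot(is(image, "WFImage"))
    ch <- splitChannels(image)
    if (is.null(controlROIs))
        controlROIs <- tileControlROIs(controlRect(image))
    ic <- controlFactor(ch, controlROIs, epsilon)
    vals <- vapply(sites, function(r) normalizedRG(ch, r, ic, epsilon),
                   numeric(1))
    data.frame(site_id = names(sites), ic_rg = ic, normalized_rg = vals,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Tile five control ROIs along the internal-control strip
#'
#' @param rect control-strip \code{\link{roiRect}}.
#' @param n number of ROIs (default 5).
#' @param size ROI side (default 20 px, shrunk to fit thin strips).
#' @return list of \code{n} \code{\link{roiRect}}s inside the strip.
#' @export
tileControlROIs <- function(rect, n = 5L, size = 20L) {
    size <- min(size, rect[["height"]], floor(rect[["width"]] / n))
    if (size < 1) stop("control strip too small to tile ", n, " ROIs")
    step <- (rect[["width"]] - size) / max(n - 1, 1)
    lapply(seq_len(n) - 1L, function(i)
        roiRect(rect[["row"]], rect[["col"]] + round(i * step), size, size))
}
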