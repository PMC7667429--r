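# Shared fixture builders: small, fast synthetic scenes.

smallNLOMSpec <- function(noiseSd = 0, seed = 1, amplitude = 3, period = 20,
                          dim = c(96, 96), nNuclei = 8, targetCova = 0.21,
                          pixelSize = 0.625) {
    syntheticNLOMSpec(dim = dim, pixelSize = pixelSize, nz = 36,
                      keratinRange = c(0, 6), basalRange = c(9, 19),
                      interfaceDepth = 26, corrugationAmplitude = amplitude,
                      corrugationPeriod = period, nNucleiPerPlane = nNuclei,
                      meanNuclearArea = 38, targetCova = targetCova,
                      noiseSd = noiseSd, seed = seed)
}

smallWFSpec <- function(noiseSd = 0, seed = 1, redMult = 3, greenMult = 0.7,
                        illuminationScale = 1) {
    syntheticWFSpec(dim = c(200, 260),
                    controlRect = roiRect(6, 6, 20, 250),
                    foci = data.frame(row = 120, col = 130, radius = 25,
                                      redMult = redMult,
                                      greenMult = greenMult),
                    illuminationScale = illuminationScale,
                    noiseSd = noiseSd, seed = seed)
}

siteROIsAt <- function(row, col, offsets = c(-3, 0, 3)) {
    lapply(offsets, function(o) roiRect(row + o - 10, col - 10, 20, 20))
}

pracma_cross <- function(a, b)
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])

# Independent Mann-Whitney pair-counting AUC oracle (ties count 1/2).
aucByPairCounting <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}
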