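#' Binary neoplastic outcome from histology classes
#'
#' Neoplastic is OED + OSCC for the widefield analyses; OED only for the
#' microscopy / multimodal analyses (protruding tumors are excluded from
#' depth-resolved imaging). Both groupings are explicit options.
#'
#' @param class character/factor of histology classes (normal, inflammation,
#'   OED, OSCC).
#' @param definition \code{"oed_oscc"} or \code{"oed"}.
#' @return Integer vector, 1 = neoplastic, 0 = non-neoplastic.
#' @export
neoplasticLabels <- function(class, definition = c("oed_oscc", "oed")) {
    definition <- match.arg(definition)
    class <- as.character(class)
    bad <- setdiff(unique(class), .CLASSES)
    if (length(bad)) stop("unknown histology class: ", paste(bad, collapse = ", "))
    pos <- if (definition == "oed_oscc") c("OED", "OSCC") else "OED"
    as.integer(class %in% pos)
}

#' Group comparison: one-way ANOVA with Tukey's post hoc test
#'
#' @param values numeric feature values.
#' @param groups group labels (factor or character), >= 2 groups with >= 2
#'   values each.
#' @return list with \code{F}, \code{p}, and \code{tukey} (data.frame of
#'   pairwise comparisons with adjusted p values and significance flags at
#'   0.05 / 0.01).
#' @examples
#' groupCompare(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))$F  # 150
#' @export
groupCompare <- function(values, groups) {
    groups <- factor(groups)
    if (nlevels(groups) < 2)
        stop("groupCompare: at least 2 groups required")
    if (any(table(groups) < 2))
        stop("groupCompare: every group needs at least 2 values")
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$groups
    tukey <- data.frame(
        comparison = rownames(tk), diff = tk[, "diff"],
        lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
        sig05 = tk[, "p adj"] < 0.05, sig01 = tk[, "p adj"] < 0.01,
        row.names = NULL)
    list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], tukey = tukey)
}

#' Empirical ROC curve
#'
#' ROC over every achievable threshold (classify positive when
#' score >= threshold, after orienting scores so that larger means positive).
#' AUC is the trapezoid area, identical to the Mann-Whitney pair-counting
#' statistic with ties counted 1/2. The operating point maximizes Youden's
#' J = sensitivity + specificity - 1; ties break toward the lower threshold
#' (higher sensitivity).
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical), both classes present.
#' @param direction \code{">"} when larger scores indicate the positive
#'   class (default), \code{"<"} for the reverse (scores are negated
#'   internally and thresholds reported on the original scale).
#' @return A \code{\linkS4class{ROCResult}}.
#' @examples
#' rocAUC(rocCurve(c(1, 3, 2, 4), c(0, 0, 1, 1)))   # 0.75
#' @export
rocCurve <- function(scores, labels, direction = c(">", "<")) {
    direction <- match.arg(direction)
    labels <- as.integer(labels)
    if (length(scores) != length(labels))
        stop("rocCurve: scores and labels must align")
    if (length(unique(labels)) < 2)
        stop("rocCurve: both classes must be present")
    s <- if (direction == "<") -scores else scores

    cuts <- sort(unique(s))
    thr <- c(-Inf, cuts, Inf)
    nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
    sens <- vapply(thr, function(t) sum(s >= t & labels == 1) / nPos,
                   numeric(1))
    spec <- vapply(thr, function(t) sum(s < t & labels == 0) / nNeg,
                   numeric(1))

    ## trapezoid AUC over (FPR, TPR), points ordered by threshold
    fpr <- 1 - spec
    o <- order(fpr, sens)
    auc <- sum(diff(fpr[o]) * (utils::head(sens[o], -1) +
                               utils::tail(sens[o], -1)) / 2)

    j <- sens + spec - 1
    best <- which(j == max(j))
    best <- best[which.min(thr[best])]          # ties: lower threshold
    opThr <- thr[best]
    if (direction == "<") { thr <- -thr; opThr <- -opThr }
    new("ROCResult", thresholds = thr, sensitivity = sens,
        specificity = spec, auc = auc,
        operatingPoint = c(threshold = opThr, sensitivity = sens[best],
                           specificity = spec[best]),
        direction = direction)
}

## IRLS for the binomial GLM with logit link. Weights are floored so that
## quasi-separated fits stop gracefully at the iteration cap.
.irlsLogit <- function(X, y, maxIter = 25, tol = 1e-10) {
    beta <- rep(0, ncol(X))
    devOld <- Inf
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(maxIter)) {
        eta <- drop(X %*% beta)
        mu <- stats::plogis(eta)
        w <- pmax(mu * (1 - mu), 1e-10)
        z <- eta + (y - mu) / w
        XtW <- t(X * w)
        beta <- drop(solve(XtW %*% X, XtW %*% z))
        mu <- stats::plogis(drop(X %*% beta))
        mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
        dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
        if (abs(dev - devOld) < tol * (abs(dev) + 0.1)) {
            converged <- TRUE
            break
        }
        devOld <- dev
    }
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    cov <- tryCatch(solve(t(X * w) %*% X), error = function(e)
        matrix(NA_real_, ncol(X), ncol(X)))
    list(beta = beta, se = sqrt(diag(cov)), deviance = dev,
         iterations = iter, converged = converged)
}

#' Fit a two-class logistic GLM on site features
#'
#' Binomial GLM with logit link, fit by iteratively reweighted least squares.
#' Under quasi-separation the fit stops at the iteration cap with
#' \code{converged = FALSE} but still reports a usable decision boundary
#' (the probability-0.5 hyperplane).
#'
#' @param features data.frame of per-site features.
#' @param include character vector of feature columns to include.
#' @param outcome binary outcome vector (0/1), or the name of a column in
#'   \code{features}.
#' @param maxIter IRLS iteration cap.
#' @return A \code{\linkS4class{GLMFit}}.
#' @export
fitGLM <- function(features, include, outcome, maxIter = 25) {
    if (is.character(outcome) && length(outcome) == 1L)
        outcome <- features[[outcome]]
    y <- as.integer(outcome)
    if (length(unique(y)) < 2)
        stop("fitGLM: both outcome classes must be present")
    if (any(table(y) < 2))
        stop("fitGLM: at least 2 sites per outcome class are required")
    missingCols <- setdiff(include, names(features))
    if (length(missingCols))
        stop("fitGLM: missing feature column(s): ",
             paste(missingCols, collapse = ", "))
    X <- as.matrix(features[, include, drop = FALSE])
    if (anyNA(X)) stop("fitGLM: missing values among included features")
    if (ncol(X) && any(apply(X, 2, function(v) diff(range(v)) == 0)))
        stop("fitGLM: a feature is constant across all sites")
    X <- cbind(`(Intercept)` = 1, X)

    fit <- .irlsLogit(X, y, maxIter = maxIter)
    names(fit$beta) <- names(fit$se) <- colnames(X)
    p0 <- mean(y)
    nullDev <- -2 * sum(y * log(p0) + (1 - y) * log(1 - p0))
    boundary <- if (length(include))
        paste0("0 = ", paste(sprintf("%.6g*%s", fit$beta,
                                     c("1", include)), collapse = " + "))
    else ""
    new("GLMFit", coefficients = fit$beta, se = fit$se,
        zValues = fit$beta / fit$se, deviance = fit$deviance,
        nullDeviance = nullDev, iterations = fit$iterations,
        converged = fit$converged, features = include, boundary = boundary,
        trace = data.frame())
}

#' Multivariable model by forward selection
#'
#' Starts from the widefield-only model (normalized RG) and in each cycle
#' adds the single microscopy feature whose inclusion most reduces the
#' residual deviance, stopping when the best candidate's reduction does not
#' clear \code{minImprovement}. The default threshold is the 0.05-level
#' likelihood-ratio cutoff \code{qchisq(0.95, 1)}: a nested fit always
#' lowers the deviance a little, so the improvement must exceed what pure
#' noise yields before a feature earns its place. Returns the final fit
#' with the per-cycle trace.
#'
#' @param features data.frame with normalized_rg, ecti_contour, basal_cova.
#' @param outcome binary outcome (vector or column name).
#' @param start feature(s) forced into the initial model.
#' @param candidates features available for addition.
#' @param minImprovement deviance reduction required to accept an addition
#'   (default \code{qchisq(0.95, 1)}, about 3.84).
#' @param maxIter IRLS iteration cap per fit.
#' @return A \code{\linkS4class{GLMFit}} whose \code{trace} records each
#'   cycle (feature added, deviance before/after).
#' @export
forwardSelect <- function(features, outcome, start = "normalized_rg",
                          candidates = c("ecti_contour", "basal_cova"),
                          minImprovement = stats::qchisq(0.95, 1),
                          maxIter = 25) {
    need <- union(start, candidates)
    missingCols <- setdiff(need, names(features))
    if (length(missingCols))
        stop("forwardSelect: missing feature column(s): ",
             paste(missingCols, collapse = ", "))
    included <- start
    fit <- fitGLM(features, included, outcome, maxIter)
    trace <- data.frame(cycle = 0L, added = paste(start, collapse = "+"),
                        deviance = fit@deviance)
    pool <- setdiff(candidates, included)
    cycle <- 0L
    while (length(pool)) {
        cycle <- cycle + 1L
        trial <- lapply(pool, function(f)
            fitGLM(features, c(included, f), outcome, maxIter))
        dev <- vapply(trial, function(t) t@deviance, numeric(1))
        best <- which.min(dev)
        if (fit@deviance - dev[best] <= minImprovement) break
        included <- c(included, pool[best])
        fit <- trial[[best]]
        trace <- rbind(trace, data.frame(cycle = cycle, added = pool[best],
                                         deviance = dev[best]))
        pool <- pool[-best]
    }
    initialize(fit, trace = trace)
}

#' Predicted probabilities from a fitted GLM
#'
#' @param object A \code{\linkS4class{GLMFit}}.
#' @param features data.frame containing the model's features.
#' @return Numeric vector of neoplastic probabilities.
#' @export
predictProb <- function(object, features) {
    stopifnot(is(object, "GLMFit"))
    missingCols <- setdiff(object@features, names(features))
    if (length(missingCols))
        stop("predictProb: missing feature column(s): ",
             paste(missingCols, collapse = ", "))
    X <- cbind(1, as.matrix(features[, object@features, drop = FALSE]))
    stats::plogis(drop(X %*% object@coefficients))
}

#' Classify sites with a fitted model and report misclassifications
#'
#' Sites with model probability above 0.5 are called neoplastic; the report
#' lists misclassified sites and the usual operating characteristics, plus
#' the ROC of the model probabilities against truth.
#'
#' @param model A \code{\linkS4class{GLMFit}}.
#' @param features data.frame with the model's features and a
#'   \code{site_id} column (generated if absent).
#' @param truth binary true labels (0/1), aligned with rows.
#' @param cutoff probability cutoff (default 0.5).
#' @return A \code{\linkS4class{ClassificationReport}}.
#' @export
classifySites <- function(model, features, truth, cutoff = 0.5) {
    if (!nrow(features)) stop("classifySites: empty feature table")
    truth <- as.integer(truth)
    prob <- predictProb(model, features)
    pred <- as.integer(prob > cutoff)
    ids <- if ("site_id" %in% names(features)) features$site_id
           else sprintf("site_%03d", seq_len(nrow(features)))
    mis <- pred != truth
    tp <- sum(pred == 1 & truth == 1); fn <- sum(pred == 0 & truth == 1)
    tn <- sum(pred == 0 & truth == 0); fp <- sum(pred == 1 & truth == 0)
    new("ClassificationReport",
        predictions = data.frame(site_id = ids, truth = truth, prob = prob,
                                 predicted = pred, misclassified = mis,
                                 stringsAsFactors = FALSE),
        nMisclassified = sum(mis),
        sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
        specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
        percentCorrect = 100 * mean(!mis),
        roc = rocCurve(prob, truth))
}
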