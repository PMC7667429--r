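# Classification module: group statistics, ROC, logistic models, forward
# selection, per-site reports.

test_that("group comparison matches hand-computed one-way ANOVA", {
    ## groups {1,2,3} vs {11,12,13}: SSB = 150 on 1 df, MSW = 1 -> F = 150
    g <- groupCompare(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
    expect_equal(g$F, 150)
    expect_lt(g$p, 0.01)
    expect_true(g$tukey$sig01)

    ## three identical groups -> F = 0
    g0 <- groupCompare(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
    expect_equal(g0$F, 0)

    expect_error(groupCompare(1:3, c("a", "a", "b")), "at least 2")
})

test_that("group comparison holds its type-I error at alpha = 0.05", {
    set.seed(31)
    rej <- vapply(1:1000, function(i) {
        x <- rnorm(60)
        groupCompare(x, rep(c("a", "b"), each = 30))$p < 0.05
    }, logical(1))
    ## binomial 3 sd band around 5%
    expect_lt(abs(mean(rej) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("ROC: frozen examples, symmetry, operating point", {
    r <- rocCurve(c(1, 3, 2, 4), c(0, 0, 1, 1))
    expect_equal(rocAUC(r), 0.75)

    sep <- rocCurve(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
    expect_equal(rocAUC(sep), 1.0)
    expect_equal(unname(operatingPoint(sep)[c("sensitivity", "specificity")]),
                 c(1, 1))

    ## label inversion: AUC' = 1 - AUC (ties included)
    set.seed(13)
    s <- sample(1:6, 30, replace = TRUE)
    l <- rbinom(30, 1, 0.5); l[1:2] <- 0:1
    expect_equal(rocAUC(rocCurve(s, 1 - l)), 1 - rocAUC(rocCurve(s, l)))

    expect_error(rocCurve(1:5, rep(1, 5)), "both classes")
})

test_that("ROC AUC is invariant under strictly monotone score transforms", {
    set.seed(17)
    s <- rnorm(40); l <- rbinom(40, 1, 0.5); l[1:2] <- 0:1
    a <- rocAUC(rocCurve(s, l))
    expect_equal(rocAUC(rocCurve(exp(s), l)), a)
    expect_equal(rocAUC(rocCurve(2 * s - 7, l)), a)
    expect_equal(rocAUC(rocCurve(atan(s), l)), a)
})

test_that("ROC AUC equals the exhaustive pair-counting oracle (n <= 12, ties)", {
    ## exhaustive: all score vectors over {1,2,3} of length 5, all labelings
    scoreGrid <- expand.grid(rep(list(1:3), 5))
    labelGrid <- expand.grid(rep(list(0:1), 5))
    labelGrid <- labelGrid[rowSums(labelGrid) %in% 1:4, ]
    set.seed(23)
    pickS <- sample(nrow(scoreGrid), 60)
    for (i in pickS) {
        s <- as.numeric(scoreGrid[i, ])
        for (j in seq_len(nrow(labelGrid))) {
            l <- as.numeric(labelGrid[j, ])
            expect_equal(rocAUC(rocCurve(s, l)), aucByPairCounting(s, l))
        }
    }
    ## random tied inputs up to n = 12
    for (i in 1:150) {
        n <- sample(4:12, 1)
        s <- sample(1:4, n, replace = TRUE)
        l <- c(0, 1, rbinom(n - 2, 1, 0.5))
        expect_equal(rocAUC(rocCurve(s, l)), aucByPairCounting(s, l))
    }
})

test_that("logistic fit matches the reference IRLS (stats::glm) to 1e-6", {
    set.seed(41)
    tables <- list(
        data.frame(x1 = rnorm(30)),
        data.frame(x1 = rnorm(50), x2 = runif(50)),
        data.frame(x1 = rnorm(80), x2 = rnorm(80), x3 = rexp(80)))
    for (tab in tables) {
        eta <- -0.3 + as.matrix(tab) %*% seq_len(ncol(tab))
        y <- rbinom(nrow(tab), 1, plogis(eta))
        if (length(unique(y)) < 2) y[1:2] <- 0:1
        mine <- fitGLM(tab, names(tab), y)
        ref <- glm(y ~ ., data = tab, family = binomial())
        expect_lt(max(abs(coef(mine) - coef(ref))), 1e-6)
        expect_lt(abs(mine@deviance - ref$deviance), 1e-6)
        expect_true(mine@converged)
        expect_gte(mine@iterations, 1)
    }
})

test_that("separated 1-D feature puts the decision boundary inside the margin", {
    tab <- data.frame(x = c(1, 2, 3, 4, 6, 7, 8, 9))
    y <- c(0, 0, 0, 0, 1, 1, 1, 1)
    f <- fitGLM(tab, "x", y)
    expect_false(f@converged)              # quasi-separation
    boundary <- -coef(f)[1] / coef(f)[2]
    expect_gt(boundary, 4); expect_lt(boundary, 6)
    ## the boundary is usable: it classifies the training data perfectly
    expect_equal(as.integer(predictProb(f, tab) > 0.5), y)
})

test_that("logistic fit contracts: single class, constant feature, NA", {
    tab <- data.frame(x = rnorm(10))
    expect_error(fitGLM(tab, "x", rep(1, 10)), "both outcome classes")
    expect_error(fitGLM(data.frame(x = rep(2, 10)), "x",
                        rep(0:1, 5)), "constant")
    tab$x[3] <- NA
    expect_error(fitGLM(tab, "x", rep(0:1, 5)), "missing")
})

test_that("null labels give well-calibrated Wald statistics", {
    set.seed(53)
    ok <- vapply(1:200, function(i) {
        tab <- data.frame(x1 = rnorm(120), x2 = rnorm(120))
        y <- sample(rep(0:1, 60))
        f <- fitGLM(tab, c("x1", "x2"), y)
        all(abs(f@zValues[2:3]) < 3)
    }, logical(1))
    expect_gte(mean(ok), 0.95)
})

test_that("forward selection recovers planted signal and resists pure noise", {
    set.seed(61)
    n <- 120
    ## RG uninformative, CoVa perfectly separating
    tab <- data.frame(normalized_rg = rnorm(n, 2, 0.5),
                      ecti_contour = rnorm(n, 2, 0.5),
                      basal_cova = c(rnorm(n / 2, 0.2, 0.02),
                                     rnorm(n / 2, 0.5, 0.02)))
    y <- rep(0:1, each = n / 2)
    fw <- forwardSelect(tab, y)
    expect_true("basal_cova" %in% fw@features)
    expect_true("basal_cova" %in% fw@trace$added)

    ## both microscopy features pure noise (large n): RG-only model in
    ## >= 90% of runs
    keep <- vapply(1:100, function(i) {
        set.seed(700 + i)
        t2 <- data.frame(normalized_rg = c(rnorm(400, 1.3, 0.4),
                                           rnorm(400, 3.2, 1.2)),
                         ecti_contour = rnorm(800, 2, 0.7),
                         basal_cova = rnorm(800, 0.3, 0.08))
        f <- forwardSelect(t2, rep(0:1, each = 400))
        identical(f@features, "normalized_rg")
    }, logical(1))
    expect_gte(mean(keep), 0.90)
})

test_that("adding features never increases deviance (nesting monotonicity)", {
    set.seed(71)
    n <- 80
    tab <- data.frame(normalized_rg = rnorm(n), ecti_contour = rnorm(n),
                      basal_cova = rnorm(n))
    y <- rbinom(n, 1, plogis(tab$normalized_rg + 0.5 * tab$ecti_contour +
                             0.8 * tab$basal_cova))
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    full <- fitGLM(tab, names(tab), y)
    for (drop in names(tab)) {
        two <- fitGLM(tab, setdiff(names(tab), drop), y)
        expect_lte(full@deviance, two@deviance + 1e-8)
    }
})

test_that("classification report agrees with direct confusion-matrix arithmetic", {
    set.seed(83)
    tab <- data.frame(x = c(rnorm(25, 0), rnorm(25, 2)))
    y <- rep(0:1, each = 25)
    f <- fitGLM(tab, "x", y)
    rep_ <- classifySites(f, tab, y)
    pred <- as.integer(predictProb(f, tab) > 0.5)
    tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
    tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
    expect_equal(rep_@sensitivity, tp / (tp + fn))
    expect_equal(rep_@specificity, tn / (tn + fp))
    expect_equal(rep_@nMisclassified, fp + fn)
    expect_equal(rep_@percentCorrect, 100 * (tp + tn) / 50)
    ## a perfect model misclassifies nothing
    perfect <- classifySites(fitGLM(data.frame(x = c(0, 0, 1, 1) * 10),
                                    "x", c(0, 0, 1, 1)),
                             data.frame(x = c(0, 0, 1, 1) * 10), c(0, 0, 1, 1))
    expect_equal(perfect@nMisclassified, 0)
    expect_equal(perfect@percentCorrect, 100)
    expect_error(classifySites(f, tab[0, , drop = FALSE], integer(0)), "empty")
})

test_that("neoplastic label definitions follow the modality groupings", {
    cls <- c("normal", "inflammation", "OED", "OSCC")
    expect_equal(neoplasticLabels(cls, "oed_oscc"), c(0L, 0L, 1L, 1L))
    expect_equal(neoplasticLabels(cls, "oed"), c(0L, 0L, 1L, 0L))
    expect_error(neoplasticLabels("tumor"), "unknown")
})
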