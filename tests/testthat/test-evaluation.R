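# A feature matrix shaped like the default cohort (49 AD / 37 MCI / 23 HC)
# with a handful of features that separate the classes.
cohortLikeMatrix <- function(seed = 1, informative = TRUE) {
    set.seed(seed)
    labels <- rep(c("AD", "MCI", "HC"), times = c(49, 37, 23))
    n <- length(labels)
    shift <- c(AD = 2, MCI = 1, HC = 0)[labels]
    values <- cbind(if (informative) shift + rnorm(n, sd = 0.5)
                    else rnorm(n),
                    matrix(rnorm(n * 4), n, 4))
    colnames(values) <- paste0("f", 1:5)
    rownames(values) <- paste0("s", seq_len(n))
    FeatureMatrixFromValues(values, labels)
}

test_that("binary problems filter and relabel the cohort correctly", {
    fm <- cohortLikeMatrix()
    sizes <- c(HCvsAD = 72, HCvsMCI = 60, MCIvsAD = 86, HCvsCASE = 109)
    for (pb in names(sizes)) {
        bin <- makeProblem(fm, pb)
        expect_equal(length(sampleLabels(bin)), unname(sizes[pb]))
    }
    case <- makeProblem(fm, "HCvsCASE")
    expect_equal(sum(sampleLabels(case) == "HC"), 23)
    expect_equal(sum(sampleLabels(case) == "CASE"), 86)
    expect_error(makeProblem(fm, "ADvsEverything"), "unknown problem")

    hcOnly <- subsetFeatureMatrix(fm, samples = sampleLabels(fm) == "HC")
    expect_error(makeProblem(hcOnly, "HCvsAD"), "absent")
})

test_that("confusion-matrix metrics match hand arithmetic", {
    m <- metricsFromConfusion(matrix(c(8, 3, 2, 7), 2,
                                     dimnames = list(c("HC", "AD"),
                                                     c("HC", "AD"))))
    expect_equal(m$accuracy, 75)
    expect_equal(m$per_class$precision[1], 100 * 8 / 11, tolerance = 1e-12)
    expect_equal(m$per_class$sensitivity[1], 80)
    expect_equal(m$per_class$specificity[1], 70)
    # weighted sensitivity equals accuracy by construction
    expect_equal(m$sensitivity, m$accuracy)
    f_hc <- 2 * (8 / 11) * 0.8 / (8 / 11 + 0.8)
    expect_equal(m$per_class$f_measure[1], 100 * f_hc, tolerance = 1e-12)
})

test_that("LOOCV runs one fold per sample and pools the confusion", {
    fm <- cohortLikeMatrix()
    bin <- makeProblem(fm, "HCvsAD")
    rep <- crossValidate(bin, "loocv", problem = "HCvsAD")
    expect_equal(rep@nFolds, 72)
    expect_equal(sum(rep@confusion), 72)
    expect_gt(rep@metrics$accuracy, 85)    # classes are well separated

    sep <- separableFeatureMatrix(n_per_class = 8)
    expect_equal(crossValidate(sep, "loocv")@metrics$accuracy, 100)
})

test_that("k-fold and holdout are stratified, seeded and reproducible", {
    fm <- makeProblem(cohortLikeMatrix(), "HCvsAD")
    k1 <- crossValidate(fm, "kfold10", seed = 5)
    k2 <- crossValidate(fm, "kfold10", seed = 5)
    expect_identical(k1@confusion, k2@confusion)
    expect_equal(k1@nFolds, 10)
    expect_equal(sum(k1@confusion), 72)

    h1 <- crossValidate(fm, "holdout90", seed = 5)
    expect_equal(h1@nFolds, 1)
    # ~10% held out, both classes represented
    expect_equal(sum(h1@confusion), 8)
    expect_equal(unname(rowSums(h1@confusion)), c(3, 5))

    tiny <- separableFeatureMatrix(n_per_class = 1)
    expect_error(crossValidate(tiny, "kfold10"), "at least 2")
})

test_that("nested feature selection never sees the held-out sample", {
    sep <- separableFeatureMatrix(n_per_class = 8, p_noise = 50, seed = 31)
    all_feats <- ncol(featureValues(sep))
    a <- crossValidate(sep, "loocv")
    b <- selectThenValidate(sep, "loocv", top_k = all_feats)
    expect_equal(b@metrics, a@metrics)

    # the informative feature tops the ranking in every training fold
    v <- featureValues(sep); lab <- sampleLabels(sep)
    for (i in seq_len(nrow(v))) {
        rank <- infoGainRank(FeatureMatrixFromValues(v[-i, ], lab[-i]))
        expect_true("inf" %in% rank$feature[1:5])
    }
    sel <- selectThenValidate(sep, "loocv", top_k = 5)
    expect_equal(sel@metrics$accuracy, 100)

    expect_error(selectThenValidate(sep, "loocv", top_k = 0), ">= 1")
    expect_warning(selectThenValidate(sep, "loocv", top_k = 1000), "capped")
})

test_that("label permutations preserve class sizes and are seeded", {
    fm <- separableFeatureMatrix(n_per_class = 6, seed = 32)
    p1 <- permutationTest(fm, n_perm = 5, seed = 7)
    p2 <- permutationTest(fm, n_perm = 5, seed = 7)
    expect_identical(p1$accuracies, p2$accuracies)
    expect_length(p1$accuracies, 5)
    expect_equal(p1$mean_accuracy, mean(p1$accuracies))
    p3 <- permutationTest(fm, n_perm = 5, seed = 8)
    expect_false(identical(p1$accuracies, p3$accuracies))
    expect_error(permutationTest(fm, n_perm = 0), "n_perm")
})

test_that("report rendering exposes the five metrics", {
    rep <- crossValidate(separableFeatureMatrix(6), "loocv",
                         problem = "HCvsAD")
    lines <- renderReportTable(rep)
    expect_length(lines, 6)
    expect_match(lines[1], "HCvsAD")
    expect_match(lines[2], "accuracy")
    lst <- reportAsList(rep)
    expect_equal(lst$n_folds, 12)
    expect_named(lst$metrics, c("accuracy", "precision", "sensitivity",
                                "specificity", "f_measure"))
})
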