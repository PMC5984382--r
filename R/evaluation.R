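.problems <- list(
    HCvsAD   = list(keep = c("HC", "AD"),  relabel = NULL),
    HCvsMCI  = list(keep = c("HC", "MCI"), relabel = NULL),
    MCIvsAD  = list(keep = c("MCI", "AD"), relabel = NULL),
    HCvsCASE = list(keep = c("HC", "MCI", "AD"),
                    relabel = c(MCI = "CASE", AD = "CASE")))

#' Build one of the four binary classification problems
#'
#' Filters a three-class feature matrix down to a binary problem: HC vs AD,
#' HC vs MCI, MCI vs AD, or HC vs CASE, where CASE pools the MCI and AD
#' samples to test recognition of diseased versus healthy subjects. Feature
#' columns are untouched.
#'
#' @param matrix a [FeatureMatrix-class] with labels among HC, MCI, AD.
#' @param problem `"HCvsAD"`, `"HCvsMCI"`, `"MCIvsAD"` or `"HCvsCASE"`.
#' @return A binary [FeatureMatrix-class].
#' @export
makeProblem <- function(matrix, problem) {
    if (!problem %in% names(.problems))
        stop("unknown problem: ", problem, " (expected one of ",
             paste(names(.problems), collapse = ", "), ")")
    spec <- .problems[[problem]]
    labels <- sampleLabels(matrix)
    missing <- setdiff(spec$keep, unique(labels))
    if (length(missing) > 0)
        stop("classes absent from the matrix: ",
             paste(missing, collapse = ", "))
    keep <- labels %in% spec$keep
    out <- subsetFeatureMatrix(matrix, samples = keep)
    if (!is.null(spec$relabel)) {
        lab <- sampleLabels(out)
        hit <- lab %in% names(spec$relabel)
        lab[hit] <- spec$relabel[lab[hit]]
        out <- FeatureMatrixFromValues(featureValues(out), lab)
    }
    out
}

#' Metrics from a 2x2 confusion matrix
#'
#' Computes the five evaluation metrics from a pooled confusion matrix
#' (rows = actual, columns = predicted). Accuracy is the diagonal fraction;
#' precision, sensitivity (recall), specificity and F-measure are computed
#' per class and summarized as support-weighted averages across the two
#' classes, so weighted sensitivity equals accuracy. A class never
#' predicted receives precision 0. All values are percentages.
#'
#' @param confusion 2x2 numeric matrix with identical row/column order.
#' @return Named list: `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `f_measure` (weighted) and `per_class` (data.frame).
#' @examples
#' metricsFromConfusion(matrix(c(8, 3, 2, 7), 2,
#'                             dimnames = list(c("HC", "AD"), c("HC", "AD"))))
#' @export
metricsFromConfusion <- function(confusion) {
    stopifnot(all(dim(confusion) == c(2, 2)))
    n <- sum(confusion)
    support <- rowSums(confusion)
    per <- data.frame(class = rownames(confusion) %||% c("c1", "c2"),
                      support = as.numeric(support))
    per$precision <- vapply(1:2, function(i) {
        pred <- sum(confusion[, i])
        if (pred == 0) 0 else confusion[i, i] / pred
    }, numeric(1))
    per$sensitivity <- vapply(1:2, function(i) {
        if (support[i] == 0) 0 else confusion[i, i] / support[i]
    }, numeric(1))
    per$specificity <- per$sensitivity[2:1]   # binary: recall of the other class
    per$f_measure <- ifelse(per$precision + per$sensitivity == 0, 0,
                            2 * per$precision * per$sensitivity /
                                (per$precision + per$sensitivity))
    w <- support / n
    pct <- function(x) 100 * x
    list(accuracy = pct(sum(diag(confusion)) / n),
         precision = pct(sum(w * per$precision)),
         sensitivity = pct(sum(w * per$sensitivity)),
         specificity = pct(sum(w * per$specificity)),
         f_measure = pct(sum(w * per$f_measure)),
         per_class = transform(per,
                               precision = pct(precision),
                               sensitivity = pct(sensitivity),
                               specificity = pct(specificity),
                               f_measure = pct(f_measure)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stratified fold assignment: samples of each class are shuffled and dealt
# round-robin over k folds.
.stratifiedFolds <- function(labels, k, seed) {
    fold <- integer(length(labels))
    .withSeed(seed, {
        for (cl in unique(labels)) {
            idx <- which(labels == cl)
            idx <- idx[sample.int(length(idx))]
            fold[idx] <- rep_len(seq_len(k), length(idx))
        }
    })
    fold
}

#' Cross-validate a decision tree on a binary problem
#'
#' Evaluates [trainC45()] under one of three sampling schemes: `"loocv"`
#' (leave-one-out: n folds of one held-out sample), `"kfold10"` (stratified
#' 10-fold, seeded) or `"holdout90"` (one stratified 90/10 split, seeded).
#' Per-fold predictions on the held-out samples are pooled into a single
#' confusion matrix from which the metrics are computed.
#'
#' @param matrix a binary [FeatureMatrix-class] with at least 2 samples per
#'   class.
#' @param scheme sampling scheme.
#' @param seed seed for fold assignment (ignored by LOOCV).
#' @param problem problem name recorded in the report.
#' @param min_leaf,cf passed to [trainC45()].
#' @param select_top_k optional: within each training fold rank features
#'   with [infoGainRank()] and keep only the top k before training (nested
#'   selection, no test-fold leakage).
#' @return An [EvaluationReport-class].
#' @export
crossValidate <- function(matrix, scheme = c("loocv", "kfold10", "holdout90"),
                          seed = 1, problem = "binary",
                          min_leaf = 2, cf = 0.25, select_top_k = NULL) {
    scheme <- match.arg(scheme)
    labels <- sampleLabels(matrix)
    classes <- unique(labels)
    if (length(classes) != 2) stop("a binary problem is required")
    n <- length(labels)
    counts <- table(labels)
    if (scheme != "loocv" && any(counts < 2))
        stop("each class needs at least 2 samples for ", scheme)
    if (any(counts < 2)) stop("each class needs at least 2 samples")
    if (!is.null(select_top_k)) {
        if (select_top_k < 1) stop("select_top_k must be >= 1")
        p <- ncol(featureValues(matrix))
        if (select_top_k > p) {
            warning("select_top_k exceeds feature count; capped at ", p)
            select_top_k <- p
        }
    }
    fold <- switch(scheme,
        loocv = seq_len(n),
        kfold10 = .stratifiedFolds(labels, 10L, seed),
        holdout90 = ifelse(.stratifiedFolds(labels, 10L, seed) == 1L, 1L, 0L))
    testFolds <- if (scheme == "holdout90") 1L else sort(unique(fold))
    # class order fixed by first appearance in canonical class order
    lev <- intersect(c("HC", "MCI", "AD", "CASE", sort(classes)), classes)
    confusion <- matrix(0, 2, 2, dimnames = list(lev, lev))
    for (f in testFolds) {
        testIdx <- which(fold == f)
        trainFm <- subsetFeatureMatrix(matrix, samples = -testIdx)
        testFm <- subsetFeatureMatrix(matrix, samples = testIdx)
        if (!is.null(select_top_k)) {
            top <- infoGainRank(trainFm)$feature[seq_len(select_top_k)]
            trainFm <- subsetFeatureMatrix(trainFm, features = top)
            testFm <- subsetFeatureMatrix(testFm, features = top)
        }
        tree <- trainC45(trainFm, min_leaf = min_leaf, cf = cf)
        pred <- predict(tree, testFm)
        for (i in seq_along(testIdx))
            confusion[labels[testIdx[i]], pred[i]] <-
                confusion[labels[testIdx[i]], pred[i]] + 1
    }
    new("EvaluationReport", problem = problem, scheme = scheme,
        nFolds = length(testFolds), confusion = confusion,
        metrics = metricsFromConfusion(confusion))
}

#' Feature selection nested inside cross-validation
#'
#' Convenience wrapper for [crossValidate()] with `select_top_k` set:
#' within every training fold the features are ranked by information gain
#' and only the `top_k` best are used, so the held-out samples never
#' influence the ranking.
#'
#' @inheritParams crossValidate
#' @param top_k number of features kept per fold.
#' @return An [EvaluationReport-class].
#' @export
selectThenValidate <- function(matrix, scheme = "loocv", seed = 1,
                               top_k, problem = "binary",
                               min_leaf = 2, cf = 0.25) {
    crossValidate(matrix, scheme = scheme, seed = seed, problem = problem,
                  min_leaf = min_leaf, cf = cf, select_top_k = top_k)
}

#' Label-permutation control
#'
#' Re-runs the full cross-validation with randomly permuted class labels
#' (the label multiset, and hence the class sizes, are preserved) `n_perm`
#' times. The resulting accuracy distribution estimates chance-level
#' performance: a real-label accuracy well above its upper quantiles
#' indicates signal rather than overfitting.
#'
#' @param matrix a binary [FeatureMatrix-class].
#' @param n_perm number of permutations (default 100).
#' @param scheme sampling scheme for each permutation (default `"loocv"`).
#' @param seed master seed; permutations and fold seeds derive from it.
#' @param min_leaf,cf passed to [trainC45()].
#' @return List with `accuracies` (length `n_perm`) and `mean_accuracy`.
#' @export
permutationTest <- function(matrix, n_perm = 100, scheme = "loocv",
                            seed = 1, min_leaf = 2, cf = 0.25) {
    if (n_perm < 1) stop("n_perm must be >= 1")
    labels <- sampleLabels(matrix)
    values <- featureValues(matrix)
    perms <- .withSeed(seed, lapply(seq_len(n_perm), function(i)
        sample.int(length(labels))))
    acc <- vapply(seq_len(n_perm), function(i) {
        permFm <- FeatureMatrixFromValues(values, labels[perms[[i]]])
        rep <- crossValidate(permFm, scheme = scheme, seed = seed + i,
                             problem = "permuted",
                             min_leaf = min_leaf, cf = cf)
        rep@metrics$accuracy
    }, numeric(1))
    list(accuracies = acc, mean_accuracy = mean(acc))
}

#' Render a report as a text table
#'
#' @param reports list of [EvaluationReport-class] objects (e.g. one per
#'   problem).
#' @return Character vector of table lines, printed invisibly.
#' @export
renderReportTable <- function(reports) {
    if (is(reports, "EvaluationReport")) reports <- list(reports)
    header <- sprintf("%-12s", "Metric")
    for (r in reports) header <- paste0(header, sprintf("%10s", r@problem))
    lines <- header
    for (m in c("accuracy", "precision", "sensitivity", "specificity",
                "f_measure")) {
        row <- sprintf("%-12s", m)
        for (r in reports)
            row <- paste0(row, sprintf("%10.1f", r@metrics[[m]]))
        lines <- c(lines, row)
    }
    lines
}

#' Convert a report to a plain list (for JSON serialization)
#'
#' @param report an [EvaluationReport-class].
#' @return Nested list of the report's fields.
#' @export
reportAsList <- function(report) {
    list(problem = report@problem, scheme = report@scheme,
         n_folds = report@nFolds,
         confusion = list(labels = rownames(report@confusion),
                          counts = unname(report@confusion)),
         metrics = report@metrics[c("accuracy", "precision", "sensitivity",
                                    "specificity", "f_measure")],
         per_class = report@metrics$per_class)
}
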