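#' Train a C4.5-style gain-ratio decision tree
#'
#' Grows a binary decision tree over numeric features: at each node every
#' (feature, threshold) candidate is scored, where candidate thresholds are
#' the midpoints between consecutive distinct sorted values of a feature,
#' and the split maximizing the gain ratio (information gain divided by the
#' split's intrinsic information) is taken, subject to both children
#' receiving at least `min_leaf` samples. Ties resolve to the lower feature
#' index, then the lower threshold, so training is deterministic and
#' invariant to row order. Growth is followed by pessimistic-error pruning:
#' a subtree is replaced by a leaf when the leaf's pessimistic error
#' estimate (normal-approximation upper confidence bound at confidence
#' `cf`) does not exceed the subtree's.
#'
#' @param matrix a [FeatureMatrix-class].
#' @param min_leaf minimum samples per child (default 2, the J48 default).
#' @param cf pruning confidence factor (default 0.25, the J48 default).
#' @param prune set `FALSE` to keep the unpruned tree.
#' @return A [DecisionTree-class].
#' @examples
#' fm <- FeatureMatrixFromValues(
#'     matrix(c(1, 2, 3, 10, 11, 12), ncol = 1,
#'            dimnames = list(paste0("s", 1:6), "f1")),
#'     rep(c("HC", "AD"), each = 3))
#' tree <- trainC45(fm)
#' treeSize(tree)
#' @export
trainC45 <- function(matrix, min_leaf = 2, cf = 0.25, prune = TRUE) {
    stopifnot(is(matrix, "FeatureMatrix"))
    X <- featureValues(matrix)
    if (nrow(X) < 1 || ncol(X) < 1) stop("empty feature matrix")
    y <- factor(sampleLabels(matrix))
    classes <- levels(y)
    yi <- as.integer(y) - 1L
    root <- .growNode(X, yi, length(classes), as.integer(min_leaf))
    if (prune) root <- .pruneNode(root, cf)
    new("DecisionTree", root = root, classes = classes,
        featureNames = colnames(X), nTrain = nrow(X))
}

.makeLeaf <- function(yi, nClasses) {
    cnt <- tabulate(yi + 1L, nClasses)
    lab <- which.max(cnt)                      # ties -> first class level
    list(leaf = TRUE, class = lab,
         n_total = length(yi), n_mis = length(yi) - cnt[lab],
         counts = cnt)
}

.growNode <- function(X, yi, nClasses, minLeaf) {
    n <- length(yi)
    if (n < 2L * minLeaf || length(unique(yi)) == 1L)
        return(.makeLeaf(yi, nClasses))
    sp <- .bestSplitCpp(X, yi, nClasses, minLeaf)
    if (sp$feature < 0) return(.makeLeaf(yi, nClasses))
    goLeft <- X[, sp$feature] <= sp$threshold
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         gain_ratio = sp$gain_ratio,
         counts = tabulate(yi + 1L, nClasses),
         left = .growNode(X[goLeft, , drop = FALSE], yi[goLeft],
                          nClasses, minLeaf),
         right = .growNode(X[!goLeft, , drop = FALSE], yi[!goLeft],
                           nClasses, minLeaf))
}

# Pessimistic error count of a would-be leaf: N times the upper confidence
# bound (normal approximation) of the observed error rate f = E/N.
.pessimisticError <- function(E, N, cf) {
    if (N == 0) return(0)
    z <- stats::qnorm(1 - cf)
    f <- E / N
    N * (f + z^2 / (2 * N) + z * sqrt(f * (1 - f) / N + z^2 / (4 * N^2))) /
        (1 + z^2 / N)
}

.subtreeError <- function(node, cf) {
    if (node$leaf) .pessimisticError(node$n_mis, node$n_total, cf)
    else .subtreeError(node$left, cf) + .subtreeError(node$right, cf)
}

.pruneNode <- function(node, cf) {
    if (node$leaf) return(node)
    node$left <- .pruneNode(node$left, cf)
    node$right <- .pruneNode(node$right, cf)
    cnt <- node$counts
    n <- sum(cnt)
    leafErr <- .pessimisticError(n - max(cnt), n, cf)
    if (leafErr <= .subtreeError(node, cf) + 1e-9) {
        lab <- which.max(cnt)
        return(list(leaf = TRUE, class = lab, n_total = n,
                    n_mis = n - cnt[lab], counts = cnt))
    }
    node
}

#' Predict classes with a decision tree
#'
#' Routes each sample from the root to a leaf: at an internal node the
#' sample goes left when its tested feature value is less than or equal to
#' the node threshold (values exactly equal to a threshold take the `<=`
#' branch), right otherwise.
#'
#' @param object a [DecisionTree-class].
#' @param newdata named numeric vector, samples-by-features matrix or
#'   data.frame providing every feature the tree tests.
#' @param ... ignored.
#' @return Character vector of predicted class labels.
#' @export
setMethod("predict", "DecisionTree", function(object, newdata, ...) {
    if (is(newdata, "FeatureMatrix")) newdata <- featureValues(newdata)
    if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
    if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
    used <- .usedFeatures(object@root)
    feats <- object@featureNames[used]
    if (!is.null(colnames(newdata))) {
        missing <- setdiff(feats, colnames(newdata))
        if (length(missing) > 0)
            stop("missing tested features: ", paste(missing, collapse = ", "))
    } else if (ncol(newdata) < max(c(used, 0L))) {
        stop("sample provides fewer features than the tree tests")
    }
    byName <- !is.null(colnames(newdata))
    vapply(seq_len(nrow(newdata)), function(i) {
        node <- object@root
        while (!node$leaf) {
            v <- if (byName)
                newdata[i, object@featureNames[node$feature]]
            else newdata[i, node$feature]
            if (is.na(v)) stop("missing value for tested feature")
            node <- if (v <= node$threshold) node$left else node$right
        }
        object@classes[node$class]
    }, character(1))
})

.usedFeatures <- function(node) {
    if (node$leaf) return(integer(0))
    unique(c(node$feature, .usedFeatures(node$left),
             .usedFeatures(node$right)))
}

#' Export a decision tree as human-readable rules
#'
#' One rule per leaf: the conjunction of the threshold predicates on the
#' path from the root, the predicted class, and the leaf annotation
#' `(n)` or `(n/m)` giving the number of training instances recognized by
#' the rule and, when nonzero, how many of them are misclassified. The text
#' round-trips through [parseRules()].
#'
#' @param tree a [DecisionTree-class].
#' @return Character vector, one rule per element.
#' @export
exportRules <- function(tree) {
    stopifnot(is(tree, "DecisionTree"))
    walk <- function(node, conds) {
        if (node$leaf) {
            ann <- if (node$n_mis > 0)
                sprintf("(%d/%d)", node$n_total, node$n_mis)
            else sprintf("(%d)", node$n_total)
            head <- if (length(conds) == 0) "IF TRUE"
                    else paste("IF", paste(conds, collapse = " AND "))
            return(sprintf("%s THEN %s %s", head,
                           tree@classes[node$class], ann))
        }
        f <- tree@featureNames[node$feature]
        thr <- sprintf("%.17g", node$threshold)
        c(walk(node$left, c(conds, sprintf("%s <= %s", f, thr))),
          walk(node$right, c(conds, sprintf("%s > %s", f, thr))))
    }
    walk(tree@root, character(0))
}

#' Parse exported rules back into a rule list
#'
#' @param text character vector of rules written by [exportRules()].
#' @return A list of class `RuleSet`; each rule holds `conditions`
#'   (data.frame of feature, op, value), `class`, `n_total`, `n_mis`.
#'   Apply with [predictRules()].
#' @export
parseRules <- function(text) {
    rules <- lapply(text, function(line) {
        m <- regmatches(line,
            regexec("^IF (.*) THEN (\\S+) \\((\\d+)(?:/(\\d+))?\\)$", line))[[1]]
        if (length(m) == 0) stop("unparseable rule: ", line)
        condstr <- m[2]
        conds <- if (identical(condstr, "TRUE")) {
            data.frame(feature = character(0), op = character(0),
                       value = numeric(0))
        } else {
            parts <- strsplit(condstr, " AND ", fixed = TRUE)[[1]]
            do.call(rbind, lapply(parts, function(p) {
                cm <- regmatches(p, regexec("^(\\S+) (<=|>) (\\S+)$", p))[[1]]
                if (length(cm) == 0) stop("unparseable condition: ", p)
                data.frame(feature = cm[2], op = cm[3],
                           value = as.numeric(cm[4]))
            }))
        }
        list(conditions = conds, class = m[3],
             n_total = as.integer(m[4]),
             n_mis = if (m[5] == "") 0L else as.integer(m[5]))
    })
    structure(rules, class = "RuleSet")
}

#' Apply a parsed rule set to samples
#'
#' @param rules a `RuleSet` from [parseRules()].
#' @param newdata named numeric vector or samples-by-features matrix.
#' @return Character vector of predicted class labels.
#' @export
predictRules <- function(rules, newdata) {
    if (is(newdata, "FeatureMatrix")) newdata <- featureValues(newdata)
    if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
    vapply(seq_len(nrow(newdata)), function(i) {
        for (r in rules) {
            ok <- TRUE
            for (k in seq_len(nrow(r$conditions))) {
                v <- newdata[i, r$conditions$feature[k]]
                ok <- if (r$conditions$op[k] == "<=") v <= r$conditions$value[k]
                      else v > r$conditions$value[k]
                if (!ok) break
            }
            if (ok) return(r$class)
        }
        stop("no rule matched sample ", i)
    }, character(1))
}

#' Serialize a decision tree to JSON
#'
#' @param tree a [DecisionTree-class].
#' @param path optional file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
treeToJSON <- function(tree, path = NULL) {
    payload <- list(classes = tree@classes,
                    feature_names = tree@featureNames,
                    n_train = tree@nTrain, root = tree@root)
    js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    if (is.null(path)) return(js)
    writeLines(js, path)
    invisible(js)
}

#' Deserialize a decision tree from JSON
#'
#' @param source JSON string or path to a file written by [treeToJSON()].
#' @return A [DecisionTree-class].
#' @export
treeFromJSON <- function(source) {
    payload <- jsonlite::fromJSON(source, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
    fix <- function(node) {
        node$leaf <- isTRUE(node$leaf)
        if (node$leaf) {
            node$class <- as.integer(node$class)
            node$n_total <- as.integer(node$n_total)
            node$n_mis <- as.integer(node$n_mis)
        } else {
            node$feature <- as.integer(node$feature)
            node$left <- fix(node$left)
            node$right <- fix(node$right)
        }
        node$counts <- as.numeric(node$counts)
        node
    }
    new("DecisionTree", root = fix(payload$root),
        classes = as.character(payload$classes),
        featureNames = as.character(payload$feature_names),
        nTrain = as.integer(payload$n_train))
}

#' Rank features by information gain
#'
#' Each feature is discretized into `n_bins` equal-width bins over its
#' observed range and scored by the information gain
#' `IG = H(class) - H(class | binned feature)`. Features are returned in
#' descending gain order with ties broken by ascending feature index (the
#' Ranker convention). Constant features score zero.
#'
#' @param matrix a [FeatureMatrix-class].
#' @param n_bins number of discretization bins (default 10).
#' @return data.frame with columns `feature`, `gain`, sorted by decreasing
#'   gain.
#' @export
infoGainRank <- function(matrix, n_bins = 10) {
    stopifnot(is(matrix, "FeatureMatrix"), n_bins >= 1)
    X <- featureValues(matrix)
    y <- factor(sampleLabels(matrix))
    hClass <- .entropy(table(y))
    gains <- vapply(seq_len(ncol(X)), function(j) {
        x <- X[, j]
        rng <- range(x)
        if (rng[2] - rng[1] <= 0) return(0)
        bin <- findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1),
                            rightmost.closed = TRUE)
        hCond <- 0
        for (b in unique(bin)) {
            sel <- bin == b
            hCond <- hCond + mean(sel) * .entropy(table(y[sel]))
        }
        hClass - hCond
    }, numeric(1))
    ord <- order(-gains, seq_along(gains))
    data.frame(feature = colnames(X)[ord], gain = gains[ord],
               row.names = NULL)
}

.entropy <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log2(p))
}
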