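test_that("a separable feature yields one split with zero training error", {
    fm <- separableFeatureMatrix(n_per_class = 10)
    tree <- trainC45(fm)
    expect_equal(treeSize(tree), 3)
    expect_equal(nLeaves(tree), 2)
    expect_equal(predict(tree, fm), sampleLabels(fm))

    # single-class data collapses to one leaf
    uni <- FeatureMatrixFromValues(
        matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6),
                                                c("a", "b"))),
        rep("HC", 6))
    t1 <- trainC45(uni)
    expect_equal(treeSize(t1), 1)
    expect_equal(predict(t1, uni), rep("HC", 6))

    expect_error(trainC45(FeatureMatrixFromValues(
        matrix(numeric(0), 0, 0), character(0))), "empty|samples|dim")
})

test_that("split choice matches exhaustive gain-ratio enumeration", {
    # XOR: no admissible split (every candidate has zero gain), so the
    # grower and the oracle must both refuse to split
    X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2,
                dimnames = list(paste0("s", 1:4), c("a", "b")))
    y <- c("A", "B", "B", "A")
    oracle <- bruteBestSplit(X, y)
    expect_equal(oracle$feature, -1L)
    xor_tree <- trainC45(FeatureMatrixFromValues(X, y), prune = FALSE)
    expect_equal(treeSize(xor_tree), 1)

    # random matrices: chosen root split equals the enumerated optimum
    set.seed(20)
    for (i in 1:20) {
        n <- sample(10:50, 1); p <- sample(2:10, 1)
        X <- matrix(round(rnorm(n * p), 2), n, p,
                    dimnames = list(paste0("s", 1:n), paste0("f", 1:p)))
        y <- sample(c("A", "B"), n, replace = TRUE)
        if (length(unique(y)) < 2) next
        oracle <- bruteBestSplit(X, y)
        tree <- trainC45(FeatureMatrixFromValues(X, y), prune = FALSE)
        if (oracle$feature < 0) {
            expect_equal(treeSize(tree), 1)
        } else {
            root <- tree@root
            expect_false(root$leaf)
            expect_equal(root$feature, oracle$feature)
            expect_equal(root$threshold, oracle$threshold, tolerance = 1e-12)
            expect_equal(root$gain_ratio, oracle$gain_ratio,
                         tolerance = 1e-10)
        }
    }
})

test_that("prediction routes by thresholds with <= going left", {
    fm <- separableFeatureMatrix(n_per_class = 5)
    tree <- trainC45(fm)
    thr <- tree@root$threshold
    left_label <- tree@classes[tree@root$left$class]
    expect_equal(predict(tree, c(inf = thr)), left_label)       # boundary
    expect_equal(predict(tree, c(inf = thr - 1e-9)), left_label)
    right_label <- tree@classes[tree@root$right$class]
    expect_equal(predict(tree, c(inf = thr + 1e-9)), right_label)
    expect_error(predict(tree, c(other = 1)), "missing tested features")
})

test_that("training is invariant to row order", {
    fm <- randomFeatureMatrix(30, 5, seed = 21)
    v <- featureValues(fm); l <- sampleLabels(fm)
    set.seed(22); perm <- sample(nrow(v))
    t1 <- trainC45(fm)
    t2 <- trainC45(FeatureMatrixFromValues(v[perm, ], l[perm]))
    expect_equal(exportRules(t1), exportRules(t2))
})

test_that("rules mirror leaves, annotate counts, and round-trip", {
    # four well-separated clusters with alternating classes force a tree
    # of size 7 with 4 leaves
    vals <- c(1, 2, 3, 11, 12, 13, 21, 22, 23, 31, 32, 33)
    fm <- FeatureMatrixFromValues(
        matrix(vals, ncol = 1, dimnames = list(paste0("s", 1:12), "f1")),
        rep(c("A", "B", "A", "B"), each = 3))
    tree <- trainC45(fm, prune = FALSE)
    expect_equal(treeSize(tree), 7)
    expect_equal(nLeaves(tree), 4)
    rules <- exportRules(tree)
    expect_length(rules, 4)
    expect_true(all(grepl("\\(3\\)$", rules)))   # each leaf holds 3 instances

    parsed <- parseRules(rules)
    expect_equal(predictRules(parsed, fm), predict(tree, fm))

    # single-leaf tree exports one unconditional rule
    t1 <- trainC45(FeatureMatrixFromValues(
        matrix(1:4, ncol = 1, dimnames = list(paste0("s", 1:4), "f1")),
        rep("A", 4)))
    r1 <- exportRules(t1)
    expect_length(r1, 1)
    expect_match(r1, "^IF TRUE THEN A \\(4\\)$")

    # noisy leaves carry the misclassified count and sum to the training size
    fm2 <- randomFeatureMatrix(40, 3, seed = 23)
    t2 <- trainC45(fm2)
    parsed2 <- parseRules(exportRules(t2))
    expect_equal(sum(vapply(parsed2, `[[`, integer(1), "n_total")), 40)
    expect_equal(predictRules(parsed2, fm2), predict(t2, fm2))
})

test_that("JSON serialization round-trips trained trees", {
    fm <- separableFeatureMatrix(n_per_class = 6, p_noise = 3)
    tree <- trainC45(fm)
    path <- tempfile(fileext = ".json")
    treeToJSON(tree, path)
    back <- treeFromJSON(path)
    expect_equal(predict(back, fm), predict(tree, fm))
    expect_equal(treeSize(back), treeSize(tree))
})

test_that("pruning never grows the tree or its pessimistic error", {
    for (seed in 24:29) {
        fm <- randomFeatureMatrix(40, 4, seed = seed)
        full <- trainC45(fm, prune = FALSE)
        pruned <- trainC45(fm, prune = TRUE)
        expect_lte(treeSize(pruned), treeSize(full))
        err <- function(tree) eegdem:::.subtreeError(tree@root, 0.25)
        expect_lte(err(pruned), err(full) + 1e-9)
    }
})

test_that("information gain ranking matches direct entropy computation", {
    # a feature identical to the class indicator attains H(class)
    y <- rep(c("A", "B"), each = 10)
    X <- cbind(ind = as.numeric(factor(y)), const = rep(1, 20),
               noise = rnorm(20))
    rownames(X) <- paste0("s", 1:20)
    fm <- FeatureMatrixFromValues(X, y)
    rank <- infoGainRank(fm)
    expect_equal(rank$feature[1], "ind")
    expect_equal(rank$gain[1], 1)                      # H(class) = 1 bit
    expect_equal(rank$gain[rank$feature == "const"], 0)

    # random matrices against the oracle, exact to 1e-12
    set.seed(30)
    for (i in 1:5) {
        fm <- randomFeatureMatrix(20, 5, seed = 30 + i)
        rank <- infoGainRank(fm)
        v <- featureValues(fm); lab <- sampleLabels(fm)
        for (j in seq_len(ncol(v))) {
            expect_equal(rank$gain[rank$feature == colnames(v)[j]],
                         bruteInfoGain(v[, j], lab),
                         tolerance = 1e-12)
        }
    }
})
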