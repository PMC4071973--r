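test_that("upgma reproduces hand computations on tiny matrices", {
    d2 <- matrix(c(0, 0.2, 0.2, 0), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
    t2 <- upgma(d2)
    expect_equal(t2@height, 0.2)
    expect_equal(asNewick(t2), "(A:0.1,B:0.1);")

    # d(A,B) = 0.1, d(A,C) = d(B,C) = 0.4 -> merges at 0.1 then 0.4
    d3 <- matrix(c(0, 0.1, 0.4,
                   0.1, 0, 0.4,
                   0.4, 0.4, 0), 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    t3 <- upgma(d3)
    expect_equal(t3@height, c(0.1, 0.4))
    expect_equal(copheneticDistances(t3)["A", "C"], 0.4)

    expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
    expect_error(upgma(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("upgma recovers ultrametric inputs exactly", {
    set.seed(71)
    for (i in 1:30) {
        d <- randomUltrametricMatrix(sample(4:8, 1))
        tr <- upgma(d)
        expect_equal(copheneticDistances(tr), d, tolerance = 1e-12)
        expect_equal(copheneticCorrelation(tr, d), 1, tolerance = 1e-9)
    }
})

test_that("upgma matches the naive leaf-set reference on random matrices", {
    set.seed(81)
    for (i in 1:50) {
        d <- randomDistanceMatrix(6)
        expect_equal(copheneticDistances(upgma(d)),
                     refUpgmaCophenetic(d), tolerance = 1e-9)
    }
})

test_that("upgma agrees with stats::hclust average linkage", {
    set.seed(91)
    for (i in 1:20) {
        d <- randomDistanceMatrix(sample(5:12, 1))
        tr <- upgma(d)
        h <- stats::hclust(stats::as.dist(d), method = "average")
        expect_equal(sort(tr@height), sort(h$height), tolerance = 1e-12)
        expect_equal(copheneticDistances(tr)[h$labels, h$labels],
                     as.matrix(stats::cophenetic(h)), tolerance = 1e-12)
    }
})

test_that("merge heights never decrease (no inversions)", {
    set.seed(101)
    for (i in 1:30) {
        tr <- upgma(randomDistanceMatrix(sample(4:15, 1)))
        expect_false(is.unsorted(tr@height))
    }
})

test_that("relabelling strains permutes but never changes the tree", {
    set.seed(111)
    d <- randomDistanceMatrix(8)
    tr <- upgma(d)
    perm <- sample(8)
    dp <- d[perm, perm]
    trp <- upgma(dp)
    cd <- copheneticDistances(tr)
    cdp <- copheneticDistances(trp)[rownames(cd), colnames(cd)]
    expect_equal(cdp, cd, tolerance = 1e-12)
    expect_equal(sort(trp@height), sort(tr@height))
    dd <- randomDistanceMatrix(6)
    expect_equal(copheneticCorrelation(upgma(dd), dd),
                 copheneticCorrelation(upgma(dd[6:1, 6:1]), dd[6:1, 6:1]))
})

test_that("ties are broken toward the smallest leaf indices", {
    # equilateral triangle: every pair at 0.3; (L1, L2) must merge first
    d <- matrix(0.3, 3, 3); diag(d) <- 0
    dimnames(d) <- list(c("L1", "L2", "L3"), c("L1", "L2", "L3"))
    tr <- upgma(d)
    expect_equal(tr@merge[1, ], c(-1L, -2L))
})

test_that("cophenetic correlation matches brute-force Pearson", {
    set.seed(121)
    d <- randomDistanceMatrix(6)
    tr <- upgma(d)
    cd <- copheneticDistances(tr)
    xs <- c(); ys <- c()
    for (a in 1:5) for (b in (a + 1):6) { xs <- c(xs, d[a, b]); ys <- c(ys, cd[a, b]) }
    expect_equal(copheneticCorrelation(tr, d), cor(xs, ys))
    expect_error(copheneticCorrelation(upgma(d[1:2, 1:2]), d[1:2, 1:2]),
                 "fewer than 3")
})

test_that("similarity-threshold cuts behave at the extremes and in between", {
    set.seed(131)
    d <- randomDistanceMatrix(7)
    tr <- upgma(d)
    expect_equal(cutAtSimilarity(tr, 1)$k, 7L)      # singletons
    expect_equal(cutAtSimilarity(tr, 0)$k, 1L)      # one cluster
    # cluster count is non-increasing as the threshold decreases
    ks <- vapply(seq(1, 0, by = -0.05),
                 function(s) cutAtSimilarity(tr, s)$k, integer(1))
    expect_false(is.unsorted(rev(ks)))
    expect_error(cutAtSimilarity(tr, 1.5), "\\[0, 1\\]")
    # labels partition the strain set
    ct <- cutAtSimilarity(tr, 0.5)
    expect_setequal(names(ct$labels), rownames(d))
    expect_equal(sort(unique(unname(ct$labels))), seq_len(ct$k))
})

test_that("cutting just below the planted separation recovers both clusters", {
    sim <- simulateMarkerMatrix(referencePanelConfig(seed = 5))
    tr <- upgma(toDistance(similarityMatrix(sim$matrix)))
    h <- tr@height
    sRoot <- 1 - h[length(h)]       # similarity of the final merge
    ct <- cutAtSimilarity(tr, sRoot + 1e-9)
    expect_equal(ct$k, 2L)
    tab <- table(ct$labels, sim$truth$clusterLabels)
    expect_equal(sort(unname(rowSums(tab > 0))), c(1, 1))  # one-to-one
})

test_that("newick export round-trips through an independent parser", {
    skip_if_not_installed("ape")
    set.seed(141)
    for (i in 1:10) {
        d <- randomDistanceMatrix(sample(4:10, 1))
        tr <- upgma(d)
        ph <- ape::read.tree(text = asNewick(tr))
        expect_setequal(ph$tip.label, tr@labels)
        # cophenetic through ape = 2 x node depth = our merge heights
        cdApe <- ape::cophenetic.phylo(ph)[tr@labels, tr@labels]
        expect_equal(cdApe, copheneticDistances(tr), tolerance = 1e-9)
    }
    # labels with spaces and metacharacters are quoted
    d <- matrix(c(0, .4, .4, 0), 2,
                dimnames = list(c("strain one", "B(2)"),
                                c("strain one", "B(2)")))
    nw <- asNewick(upgma(d))
    expect_match(nw, "'strain one'", fixed = TRUE)
    expect_match(nw, "'B(2)'", fixed = TRUE)
})

test_that("as.hclust coercion preserves heights and supports cutree", {
    set.seed(151)
    d <- randomDistanceMatrix(9)
    tr <- upgma(d)
    h <- stats::as.hclust(tr)
    expect_s3_class(h, "hclust")
    expect_equal(h$height, tr@height)
    expect_equal(sort(unique(stats::cutree(h, k = 3))), 1:3)
})
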