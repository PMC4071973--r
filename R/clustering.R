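#' UpgmaTree: a rooted ultrametric UPGMA dendrogram
#'
#' Stores an agglomerative average-linkage (UPGMA) dendrogram in the
#' `stats::hclust` merge convention: `merge` is an `(n-1) x 2` integer matrix
#' whose negative entries index leaves and positive entries earlier merges;
#' `height` gives each merge's height on the distance scale. UPGMA heights
#' are non-decreasing in merge order (the tree is ultrametric), which the
#' validity method enforces.
#'
#' @slot labels Character vector of leaf (strain) labels.
#' @slot merge Integer matrix of merges, `hclust` convention.
#' @slot height Numeric vector of merge heights (distance scale).
#'
#' @seealso [upgma()], [cutAtSimilarity()], [copheneticDistances()],
#'   [asNewick()]
#' @aliases UpgmaTree-class
#' @exportClass UpgmaTree
setClass("UpgmaTree",
         representation(labels = "character", merge = "matrix",
                        height = "numeric"))

setValidity("UpgmaTree", function(object) {
    n <- length(object@labels)
    msg <- character()
    if (nrow(object@merge) != n - 1L || length(object@height) != n - 1L)
        msg <- c(msg, "a tree on n leaves must record exactly n-1 merges")
    if (is.unsorted(object@height))
        msg <- c(msg, "merge heights must be non-decreasing (ultrametricity)")
    if (anyDuplicated(object@labels))
        msg <- c(msg, "leaf labels must be unique")
    if (length(msg)) msg else TRUE
})

#' @describeIn UpgmaTree-class Compact display.
#' @param object An `UpgmaTree`.
#' @export
setMethod("show", "UpgmaTree", function(object) {
    n <- length(object@labels)
    cat("UpgmaTree with", n, "leaves\n")
    cat(sprintf("  merge heights: %.4g .. %.4g (root)\n",
                object@height[1L], object@height[n - 1L]))
    cat("  leaves:", paste(utils::head(object@labels, 5), collapse = ", "),
        if (n > 5) "...", "\n")
})

.checkDistanceMatrix <- function(d) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-12))
        stop("distance matrix must be square and symmetric")
    if (any(d < 0))
        stop("distance matrix must be non-negative")
    if (is.null(rownames(d)))
        rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
    d
}

#' UPGMA hierarchical clustering
#'
#' Unweighted pair-group method with arithmetic mean: repeatedly merge the
#' two closest clusters, defining the distance between clusters as the
#' arithmetic mean of all cross-pair leaf distances. After merging `A` and
#' `B`, the distance to any other cluster `X` is updated proportionally as
#' `(n_A d(A,X) + n_B d(B,X)) / (n_A + n_B)`, which keeps the unweighted
#' leaf-pair average exact. The merge height is the merged pair's distance,
#' and heights are guaranteed non-decreasing (UPGMA admits no inversions).
#'
#' Ties: when several cluster pairs attain the minimum distance, the pair
#' whose (row, column) index pair is lexicographically smallest — clusters
#' ordered by their smallest original leaf index — is merged, making the
#' result deterministic.
#'
#' @param d A symmetric non-negative distance matrix (zero diagonal) with
#'   leaf labels as dimnames, e.g. from [toDistance()].
#' @return An [`UpgmaTree`].
#' @examples
#' d <- toDistance(similarityMatrix(exampleBandMatrix()))
#' upgma(d)
#' @export
upgma <- function(d) {
    d <- .checkDistanceMatrix(d)
    n <- nrow(d)
    if (n < 2L) stop("need >= 2 leaves")
    labels <- rownames(d)
    # active cluster bookkeeping; id: -leaf or +merge index (hclust style)
    active <- seq_len(n)          # positions into D
    id <- -seq_len(n)
    size <- rep(1L, n)
    minLeaf <- seq_len(n)         # smallest original leaf index per cluster
    D <- d
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        k <- length(active)
        # order active clusters by smallest member leaf for the tie rule
        ord <- order(minLeaf[active])
        best <- NULL
        bestD <- Inf
        for (ii in seq_len(k - 1L)) {
            for (jj in (ii + 1L):k) {
                i <- active[ord[ii]]; j <- active[ord[jj]]
                if (D[i, j] < bestD - 1e-15) {  # strictly better; first hit wins ties
                    bestD <- D[i, j]
                    best <- c(i, j)
                }
            }
        }
        i <- best[1L]; j <- best[2L]
        merge[step, ] <- c(id[i], id[j])  # left = cluster with smaller leaf
        height[step] <- D[i, j]
        # proportional (unweighted leaf-pair) average update into slot i
        others <- setdiff(active, c(i, j))
        D[i, others] <- (size[i] * D[i, others] + size[j] * D[j, others]) /
            (size[i] + size[j])
        D[others, i] <- D[i, others]
        size[i] <- size[i] + size[j]
        id[i] <- step
        minLeaf[i] <- min(minLeaf[i], minLeaf[j])
        active <- setdiff(active, j)
    }
    methods::new("UpgmaTree", labels = labels, merge = merge,
                 height = height)
}

# leaf index sets of each internal node, in merge order
.mergeMembers <- function(tree) {
    members <- vector("list", nrow(tree@merge))
    for (s in seq_along(members)) {
        get1 <- function(v) if (v < 0) -v else members[[v]]
        members[[s]] <- c(get1(tree@merge[s, 1L]), get1(tree@merge[s, 2L]))
    }
    members
}

#' Cophenetic distances of a dendrogram
#'
#' The cophenetic distance of two leaves is the height of the merge at which
#' they first join. On an ultrametric input, UPGMA reproduces the input
#' distances exactly.
#'
#' @param tree An [`UpgmaTree`].
#' @return A symmetric matrix of cophenetic distances with leaf labels.
#' @export
copheneticDistances <- function(tree) {
    stopifnot(methods::is(tree, "UpgmaTree"))
    n <- length(tree@labels)
    cd <- matrix(0, n, n, dimnames = list(tree@labels, tree@labels))
    members <- .mergeMembers(tree)
    for (s in seq_len(n - 1L)) {
        left <- if (tree@merge[s, 1L] < 0) -tree@merge[s, 1L] else
            members[[tree@merge[s, 1L]]]
        right <- if (tree@merge[s, 2L] < 0) -tree@merge[s, 2L] else
            members[[tree@merge[s, 2L]]]
        cd[left, right] <- tree@height[s]
        cd[right, left] <- tree@height[s]
    }
    cd
}

#' Cophenetic correlation between a dendrogram and its input distances
#'
#' Pearson correlation between the `n(n-1)/2` input distances and the
#' dendrogram's cophenetic distances — the standard diagnostic of how
#' faithfully an UPGMA tree represents a distance matrix. Equals 1 exactly
#' when the input is ultrametric.
#'
#' @param tree An [`UpgmaTree`].
#' @param d The distance matrix the tree was built from (same leaf set).
#' @return Pearson `r` in `[-1, 1]`.
#' @export
copheneticCorrelation <- function(tree, d) {
    d <- .checkDistanceMatrix(d)
    if (nrow(d) < 3L)
        stop("cophenetic correlation is undefined for fewer than 3 leaves")
    if (!setequal(rownames(d), tree@labels))
        stop("tree and distance matrix must share the same leaf set")
    d <- d[tree@labels, tree@labels]
    cd <- copheneticDistances(tree)
    low <- lower.tri(d)
    stats::cor(d[low], cd[low])
}

#' Cut a dendrogram at a similarity threshold
#'
#' Clusters are the maximal subtrees all of whose internal merge heights lie
#' strictly below `1 - s` on the distance scale — i.e. groups of strains
#' that have all joined at similarity above `s`. A threshold of 1 yields
#' singletons; a threshold of 0 yields a single cluster (provided no merge
#' sits exactly at distance 1). Cluster ids are numbered 1..k in order of
#' first appearance along the leaf order.
#'
#' @param tree An [`UpgmaTree`].
#' @param s Similarity threshold in `[0, 1]`.
#' @return A list with `threshold` (`s`), `k` (number of clusters) and
#'   `labels` (named integer vector, strain -> cluster id).
#' @export
cutAtSimilarity <- function(tree, s) {
    stopifnot(methods::is(tree, "UpgmaTree"))
    if (is.na(s) || s < 0 || s > 1)
        stop("similarity threshold must lie in [0, 1]")
    hmax <- 1 - s
    n <- length(tree@labels)
    members <- .mergeMembers(tree)
    parent <- seq_len(n)
    findRoot <- function(parent, i) { while (parent[i] != i) i <- parent[i]; i }
    for (step in seq_len(n - 1L)) {
        if (tree@height[step] < hmax) {
            mem <- members[[step]]
            r0 <- findRoot(parent, mem[1L])
            for (m in mem[-1L]) parent[findRoot(parent, m)] <- r0
        }
    }
    roots <- vapply(seq_len(n), function(i) findRoot(parent, i), integer(1))
    ids <- match(roots, unique(roots))
    names(ids) <- tree@labels
    list(threshold = s, k = length(unique(ids)), labels = ids)
}

.quoteNewick <- function(lab) {
    needs <- grepl("[][ ():;,']", lab)
    lab[needs] <- paste0("'", gsub("'", "''", lab[needs]), "'")
    lab
}

#' Serialise a dendrogram as a Newick string
#'
#' Branch lengths follow the ultrametric convention in which a node merging
#' at height `h` is drawn at depth `h/2`, so every root-to-leaf path length
#' equals half the root height (each merge height is a distance between two
#' groups; the tree splits it evenly between the two lineages). Labels
#' containing Newick metacharacters (spaces, parentheses, colons, ...) are
#' single-quoted.
#'
#' @param tree An [`UpgmaTree`].
#' @return A Newick string terminated by `";"`.
#' @examples
#' d <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' asNewick(upgma(d))  # "(A:0.1,B:0.1);"
#' @export
asNewick <- function(tree) {
    stopifnot(methods::is(tree, "UpgmaTree"))
    labels <- .quoteNewick(tree@labels)
    build <- function(node) {
        if (node < 0)
            return(list(str = labels[-node], h = 0))
        left <- build(tree@merge[node, 1L])
        right <- build(tree@merge[node, 2L])
        h <- tree@height[node]
        list(str = sprintf("(%s:%s,%s:%s)",
                           left$str, format((h - left$h) / 2, digits = 15),
                           right$str, format((h - right$h) / 2, digits = 15)),
             h = h)
    }
    paste0(build(nrow(tree@merge))$str, ";")
}

#' Write a dendrogram to a Newick file
#'
#' @param tree An [`UpgmaTree`].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
    writeLines(asNewick(tree), path)
    invisible(path)
}

#' Coerce an UpgmaTree to stats::hclust
#'
#' Enables plotting and interoperation with base R dendrogram tooling.
#'
#' @param x An [`UpgmaTree`].
#' @param ... Ignored.
#' @return An object of class `hclust`.
#' @exportS3Method stats::as.hclust
as.hclust.UpgmaTree <- function(x, ...) {
    # leaf order: left-to-right traversal of the final merge
    ord <- integer(0)
    walk <- function(node) {
        if (node < 0) ord <<- c(ord, -node)
        else { walk(x@merge[node, 1L]); walk(x@merge[node, 2L]) }
    }
    walk(nrow(x@merge))
    structure(list(merge = x@merge, height = x@height, order = ord,
                   labels = x@labels, method = "average",
                   call = match.call(), dist.method = "user"),
              class = "hclust")
}
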