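# Independent reference implementations and fixture builders used as
# oracles. These deliberately take the slow, literal route so they share no
# code path with the package.

# Jaccard by explicit per-band enumeration
refJaccard <- function(x, y) {
    a <- 0L; b <- 0L; cc <- 0L
    for (i in seq_along(x)) {
        if (x[i] == 1 && y[i] == 1) a <- a + 1L
        else if (x[i] == 1 && y[i] == 0) b <- b + 1L
        else if (x[i] == 0 && y[i] == 1) cc <- cc + 1L
    }
    if (a + b + cc == 0L) 0 else a / (a + b + cc)
}

# Naive UPGMA: clusters kept as explicit leaf sets; every inter-cluster
# distance recomputed from the ORIGINAL leaf matrix at every step (O(n^3)),
# never via the proportional update. Returns the cophenetic matrix.
refUpgmaCophenetic <- function(d) {
    n <- nrow(d)
    clusters <- lapply(seq_len(n), identity)
    cd <- matrix(0, n, n)
    while (length(clusters) > 1L) {
        k <- length(clusters)
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_len(k - 1L)) {
            for (j in (i + 1L):k) {
                dd <- mean(d[clusters[[i]], clusters[[j]]])
                if (dd < bestD) { bestD <- dd; best <- c(i, j) }
            }
        }
        A <- clusters[[best[1]]]; B <- clusters[[best[2]]]
        cd[A, B] <- bestD; cd[B, A] <- bestD
        clusters[[best[1]]] <- c(A, B)
        clusters[[best[2]]] <- NULL
    }
    dimnames(cd) <- dimnames(d)
    cd
}

# random symmetric distance matrix with zero diagonal
randomDistanceMatrix <- function(n, labels = paste0("L", seq_len(n))) {
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
    d <- d + t(d)
    dimnames(d) <- list(labels, labels)
    d
}

# random ultrametric matrix built from a random recursive bifurcation with
# heights shrinking toward the leaves
randomUltrametricMatrix <- function(n) {
    labels <- paste0("L", seq_len(n))
    d <- matrix(0, n, n, dimnames = list(labels, labels))
    split <- function(idx, h) {
        if (length(idx) < 2L) return()
        pick <- sample(seq_along(idx), sample(1:(length(idx) - 1L), 1))
        A <- idx[pick]; B <- idx[-pick]
        d[A, B] <<- h; d[B, A] <<- h
        split(A, h * runif(1, 0.3, 0.9))
        split(B, h * runif(1, 0.3, 0.9))
    }
    split(seq_len(n), runif(1, 0.5, 1))
    d
}

# random binary band matrix wrapped as a MarkerMatrix
randomBandMatrix <- function(nStrains = 6, nBands = 30, nPrimers = 3,
                             p = 0.5) {
    v <- matrix(rbinom(nStrains * nBands, 1L, p), nStrains, nBands,
                dimnames = list(sprintf("S%02d", seq_len(nStrains)), NULL))
    sizes <- sample(c(NA_integer_, 100:2000), nBands, replace = TRUE)
    MarkerMatrix(v,
                 primerCombination = sort(rep_len(sprintf("P%02d",
                                                          seq_len(nPrimers)),
                                                  nBands)),
                 sizeBp = sizes)
}
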