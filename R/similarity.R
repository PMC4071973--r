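#' Jaccard similarity of two binary band profiles
#'
#' `a / (a + b + c)` where `a` counts bands present in both profiles and `b`,
#' `c` count bands unique to each — joint absences carry no information about
#' relatedness under a dominant marker system and are excluded, the standard
#' Jaccard convention. If both profiles are all-zero (`a + b + c = 0`) the
#' coefficient is undefined; the function returns 0 with a warning rather
#' than failing, since an all-absent strain is degenerate but representable.
#'
#' @param x,y Binary (0/1) vectors of equal length >= 1.
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
jaccard <- function(x, y) {
    if (length(x) != length(y))
        stop("profiles differ in length (", length(x), " vs ", length(y), ")")
    if (length(x) < 1L) stop("profiles must have length >= 1")
    if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
        stop("profiles must be binary 0/1 vectors")
    a <- sum(x == 1 & y == 1)
    u <- sum(x == 1 | y == 1)  # a + b + c
    if (u == 0L) {
        warning("both profiles are all-zero; Jaccard undefined, returning 0")
        return(0)
    }
    a / u
}

#' Pairwise Jaccard similarity matrix among strains
#'
#' Computes all `n(n-1)/2` pairwise Jaccard coefficients between strain band
#' profiles. The diagonal is 1 for any strain with at least one band present
#' (and 0, with a warning, for an all-zero strain, where self-similarity is
#' undefined).
#'
#' @param m A [`MarkerMatrix`].
#' @return A symmetric `n x n` numeric matrix with strain identifiers as
#'   dimnames and entries in `[0, 1]`.
#' @export
similarityMatrix <- function(m) {
    stopifnot(methods::is(m, "MarkerMatrix"))
    v <- bandMatrix(m)                  # strains x bands
    inter <- tcrossprod(v)              # shared presences a
    rs <- rowSums(v)
    union <- outer(rs, rs, "+") - inter # a + b + c
    if (any(union == 0))
        warning("all-zero strain profile(s); affected Jaccard entries set to 0")
    s <- ifelse(union == 0, 0, inter / union)
    dimnames(s) <- list(rownames(v), rownames(v))
    s
}

#' Convert a similarity matrix to a distance matrix
#'
#' Elementwise `d = 1 - s`; the complement of Jaccard similarity is the
#' (metric) Jaccard distance consumed by the UPGMA and PCoA stages. Cluster
#' cut thresholds quoted on the similarity scale convert the same way.
#'
#' @param s A symmetric similarity matrix with entries in `[0, 1]`.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
toDistance <- function(s) {
    s <- as.matrix(s)
    if (nrow(s) != ncol(s) || any(abs(s - t(s)) > 1e-12))
        stop("similarity matrix must be square and symmetric")
    if (any(s < -1e-12 | s > 1 + 1e-12))
        stop("similarity entries must lie in [0, 1]")
    d <- 1 - s
    diag(d) <- 0
    d
}

#' Write a square labelled matrix as CSV
#'
#' Full-precision writer for similarity or distance matrices: strain labels
#' appear as both header and first column.
#'
#' @param x A square matrix with dimnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeSquareMatrix <- function(x, path) {
    stopifnot(nrow(x) == ncol(x), !is.null(rownames(x)))
    df <- data.frame(strain = rownames(x),
                     format(x, digits = 17, trim = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
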