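#' PCoAResult: principal coordinates of a distance matrix
#'
#' Holds the full eigenvalue spectrum of the Gower-centered matrix (sorted
#' descending), the retained coordinate axes, the per-axis percentage of
#' variance (computed over positive eigenvalues only), and a flag recording
#' whether negative eigenvalues occurred — expected for Jaccard distances,
#' which are not always Euclidean-embeddable.
#'
#' @slot eigenvalues Numeric, all `n` eigenvalues, descending.
#' @slot coordinates Numeric matrix, strains x retained axes; axes whose
#'   eigenvalue is not positive carry zero coordinates.
#' @slot pctVariance Numeric, per retained axis, `100 * lambda_i / sum(lambda+)`
#'   (0 for non-positive axes).
#' @slot negativeEigenvalues Logical flag.
#'
#' @seealso [runPCoA()], [varianceCaptured()]
#' @aliases PCoAResult-class
#' @exportClass PCoAResult
setClass("PCoAResult",
         representation(eigenvalues = "numeric", coordinates = "matrix",
                        pctVariance = "numeric",
                        negativeEigenvalues = "logical"))

setValidity("PCoAResult", function(object) {
    msg <- character()
    if (is.unsorted(rev(object@eigenvalues)))
        msg <- c(msg, "eigenvalues must be sorted descending")
    if (ncol(object@coordinates) != length(object@pctVariance))
        msg <- c(msg, "one pctVariance entry per retained axis")
    if (sum(object@pctVariance) > 100 + 1e-8)
        msg <- c(msg, "pctVariance must sum to <= 100 over retained axes")
    if (length(msg)) msg else TRUE
})

#' @describeIn PCoAResult-class Compact display.
#' @param object A `PCoAResult`.
#' @export
setMethod("show", "PCoAResult", function(object) {
    k <- ncol(object@coordinates)
    cat("PCoAResult:", nrow(object@coordinates), "points,", k,
        "retained axes\n")
    cat("  % variance per axis:",
        paste(sprintf("%.2f", object@pctVariance), collapse = " "), "\n")
    if (object@negativeEigenvalues)
        cat("  note: negative eigenvalues present",
            "(non-Euclidean distances)\n")
})

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower's method: the squared distance matrix is double-centered,
#' `B = -C (d^2 / 2) C` with `C = I - 11'/n`, and eigendecomposed. Retained
#' coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; axes with non-positive eigenvalues carry zero coordinates.
#' Per-axis variance percentages are taken over the positive eigenvalues
#' only; negative eigenvalues (possible for non-Euclidean dissimilarities
#' such as Jaccard) are reported via the `negativeEigenvalues` flag and are
#' not corrected.
#'
#' Eigenvector signs are fixed deterministically: the largest-magnitude
#' entry of each axis is made positive.
#'
#' @param d A symmetric non-negative distance matrix with zero diagonal.
#' @param nAxes Number of axes to retain, `1 <= nAxes <= n - 1` (default 3,
#'   the usual number inspected for a 3-D ordination plot).
#' @return A [`PCoAResult`].
#' @examples
#' d <- toDistance(similarityMatrix(exampleBandMatrix()))
#' runPCoA(d, nAxes = 3)
#' @export
runPCoA <- function(d, nAxes = 3L) {
    d <- .checkDistanceMatrix(d)
    n <- nrow(d)
    if (nAxes < 1L || nAxes > n - 1L)
        stop("'nAxes' must lie in [1, n-1]")
    A <- -0.5 * d^2
    B <- sweep(A, 1L, rowMeans(A))
    B <- sweep(B, 2L, colMeans(B))   # row-centered then column-centered
    B <- (B + t(B)) / 2              # symmetrise against round-off
    e <- eigen(B, symmetric = TRUE)
    lambda <- e$values               # descending
    tol <- max(abs(lambda), 0) * 1e-12
    pos <- lambda > tol
    totPos <- sum(lambda[pos])
    keep <- seq_len(nAxes)
    coords <- matrix(0, n, nAxes,
                     dimnames = list(rownames(d),
                                     paste0("Axis", seq_len(nAxes))))
    pct <- numeric(nAxes)
    for (j in keep) {
        if (pos[j]) {
            v <- e$vectors[, j]
            if (v[which.max(abs(v))] < 0) v <- -v
            coords[, j] <- v * sqrt(lambda[j])
            pct[j] <- 100 * lambda[j] / totPos
        }
    }
    methods::new("PCoAResult", eigenvalues = lambda, coordinates = coords,
                 pctVariance = pct,
                 negativeEigenvalues = any(lambda < -tol))
}

#' Accessors for PCoAResult objects
#'
#' @param r A [`PCoAResult`].
#' @return `pcoaEigenvalues()`: all eigenvalues, descending;
#'   `pcoaCoordinates()`: the strains-by-axes coordinate matrix;
#'   `pcoaPctVariance()`: per-axis percentage of (positive-eigenvalue)
#'   variance.
#' @name PCoAResult-accessors
NULL

#' @rdname PCoAResult-accessors
#' @export
pcoaEigenvalues <- function(r) r@eigenvalues

#' @rdname PCoAResult-accessors
#' @export
pcoaCoordinates <- function(r) r@coordinates

#' @rdname PCoAResult-accessors
#' @export
pcoaPctVariance <- function(r) r@pctVariance

#' Cumulative variance captured by the leading axes
#'
#' Sum of the first `k` per-axis variance percentages — e.g. how much of the
#' (positive-eigenvalue) variation the three axes of a 3-D ordination plot
#' account for.
#'
#' @param r A [`PCoAResult`].
#' @param k Number of leading axes, `0 <= k <=` number of retained axes.
#' @return A percentage in `[0, 100]`.
#' @export
varianceCaptured <- function(r, k) {
    stopifnot(methods::is(r, "PCoAResult"))
    if (k < 0 || k > length(r@pctVariance))
        stop("'k' must lie in [0, ", length(r@pctVariance), "]")
    if (k == 0) return(0)
    sum(r@pctVariance[seq_len(k)])
}
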