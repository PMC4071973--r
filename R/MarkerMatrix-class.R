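#' MarkerMatrix: a binary band-presence matrix grouped by primer combination
#'
#' `MarkerMatrix` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' a dominant-marker fingerprint panel: each row is one scored band (an
#' electrophoretic fragment position), each column is one strain, and the
#' single assay `"bands"` holds presence (1) / absence (0) calls. Per-band
#' metadata lives in `rowData`: the primer combination the band belongs to,
#' the band label within that combination, and an optional fragment size in
#' base pairs.
#'
#' Validity requires: every assay value exactly 0 or 1 (no missing codes —
#' absence of a score is a data error, not a value to impute); at least two
#' strains with unique identifiers; globally unique band identifiers of the
#' form `<primer>:<label>`; every band assigned to exactly one non-empty
#' primer combination; fragment sizes, when given, strictly positive.
#'
#' @slot Inherits all slots from `SummarizedExperiment`.
#'
#' @seealso [MarkerMatrix()] the constructor, [readMarkerMatrix()],
#'   [bandMatrix()], [primerCombinations()]
#' @aliases MarkerMatrix-class
#' @importFrom methods setClass setValidity new validObject is
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass MarkerMatrix
setClass("MarkerMatrix", contains = "SummarizedExperiment")

.validMarkerMatrix <- function(object) {
    msg <- character()
    if (!"bands" %in% SummarizedExperiment::assayNames(object))
        return("assay 'bands' is required")
    v <- SummarizedExperiment::assay(object, "bands")
    if (anyNA(v) || !all(v %in% c(0L, 1L)))
        msg <- c(msg, "assay values must all be exactly 0 or 1 (no missing codes)")
    if (ncol(object) < 2L)
        msg <- c(msg, "need >= 2 strains")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)) ||
        any(!nzchar(colnames(object))))
        msg <- c(msg, "strain identifiers must be unique and non-empty")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("primerCombination", "bandLabel") %in% colnames(rd))) {
        msg <- c(msg, "rowData must contain 'primerCombination' and 'bandLabel'")
    } else {
        pc <- as.character(rd$primerCombination)
        bl <- as.character(rd$bandLabel)
        if (any(is.na(pc)) || any(!nzchar(pc)))
            msg <- c(msg, "every band must belong to exactly one non-empty primer combination")
        if (anyDuplicated(paste(pc, bl, sep = ":")))
            msg <- c(msg, "(primer combination, band label) pairs must be unique")
        if ("sizeBp" %in% colnames(rd)) {
            sz <- rd$sizeBp
            if (any(!is.na(sz) & sz <= 0))
                msg <- c(msg, "sizeBp, when present, must be > 0")
        }
    }
    if (length(msg)) msg else TRUE
}

setValidity("MarkerMatrix", .validMarkerMatrix)

#' Construct a MarkerMatrix from a strains-by-bands binary table
#'
#' @param values Integer or numeric matrix of 0/1 calls, strains in rows and
#'   bands in columns, with strain identifiers as row names. This is the
#'   orientation band matrices are scored and exchanged in; internally the
#'   object stores bands as rows (features) and strains as columns (samples),
#'   following the `SummarizedExperiment` convention.
#' @param primerCombination Character vector, one entry per band, naming the
#'   primer combination each band was amplified by (e.g. `"GQ76R1-ME9"`).
#' @param bandLabel Character vector of band labels, unique within each primer
#'   combination. Defaults to the column names of `values`, or `b1, b2, ...`
#'   numbered within each primer combination.
#' @param sizeBp Optional integer vector of fragment sizes in base pairs
#'   (`NA` where unknown).
#'
#' @return A validated [`MarkerMatrix`] object.
#'
#' @examples
#' m <- MarkerMatrix(
#'     values = matrix(c(1, 0, 1, 1, 0, 1), nrow = 2,
#'                     dimnames = list(c("S1", "S2"), NULL)),
#'     primerCombination = c("P1", "P1", "P2"))
#' m
#' bandFrequency(m, bandIds(m)[1])
#'
#' @export
MarkerMatrix <- function(values, primerCombination, bandLabel = NULL,
                         sizeBp = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("'values' must carry strain identifiers as row names")
    nb <- ncol(values)
    primerCombination <- as.character(primerCombination)
    if (length(primerCombination) != nb)
        stop("'primerCombination' must name one primer combination per band")
    if (is.null(bandLabel)) {
        bandLabel <- colnames(values)
        if (is.null(bandLabel))  # numbered within each primer combination
            bandLabel <- stats::ave(primerCombination, primerCombination,
                                    FUN = function(x) paste0("b", seq_along(x)))
    }
    bandLabel <- as.character(bandLabel)
    if (is.null(sizeBp)) sizeBp <- rep(NA_integer_, nb)
    sizeBp <- as.integer(sizeBp)
    storage.mode(values) <- "integer"
    ids <- paste(primerCombination, bandLabel, sep = ":")
    rd <- S4Vectors::DataFrame(primerCombination = primerCombination,
                               bandLabel = bandLabel,
                               sizeBp = sizeBp,
                               row.names = ids)
    assayM <- t(values)
    dimnames(assayM) <- list(ids, rownames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(bands = assayM), rowData = rd)
    methods::new("MarkerMatrix", se)
}

#' Accessors for MarkerMatrix objects
#'
#' `strainIds()` returns the strain identifiers; `bandIds()` the global band
#' identifiers (`<primer>:<label>`); `primerCombinations()` the distinct
#' primer combinations in band order; `bandInfo()` the per-band metadata;
#' `bandMatrix()` the strains-by-bands 0/1 integer matrix (the orientation
#' the similarity stage consumes); `nStrains()`/`nBands()` the panel
#' dimensions.
#'
#' @param x A [`MarkerMatrix`].
#' @return See the individual descriptions.
#' @name MarkerMatrix-accessors
#' @examples
#' m <- exampleBandMatrix()
#' nStrains(m); nBands(m)
#' head(primerCombinations(m))
NULL

#' @rdname MarkerMatrix-accessors
#' @export
strainIds <- function(x) colnames(x)

#' @rdname MarkerMatrix-accessors
#' @export
bandIds <- function(x) rownames(x)

#' @rdname MarkerMatrix-accessors
#' @export
primerCombinations <- function(x)
    unique(as.character(SummarizedExperiment::rowData(x)$primerCombination))

#' @rdname MarkerMatrix-accessors
#' @export
bandInfo <- function(x) SummarizedExperiment::rowData(x)

#' @rdname MarkerMatrix-accessors
#' @export
bandMatrix <- function(x) t(SummarizedExperiment::assay(x, "bands"))

#' @rdname MarkerMatrix-accessors
#' @export
nStrains <- function(x) ncol(x)

#' @rdname MarkerMatrix-accessors
#' @export
nBands <- function(x) nrow(x)

#' @describeIn MarkerMatrix-class Compact display of panel dimensions and
#'   primer grouping.
#' @param object A `MarkerMatrix`.
#' @importFrom methods show
#' @export
setMethod("show", "MarkerMatrix", function(object) {
    cat("MarkerMatrix:", ncol(object), "strains x", nrow(object),
        "bands in", length(primerCombinations(object)),
        "primer combinations\n")
    p <- vapply(seq_len(nrow(object)), function(i)
        bandFrequencyFromCounts(sum(SummarizedExperiment::assay(object)[i, ]),
                                ncol(object)), numeric(1))
    cat(sprintf("polymorphic bands: %d (%.1f%%)\n",
                sum(p > 0 & p < 1), 100 * mean(p > 0 & p < 1)))
    cat("strains:", paste(utils::head(colnames(object), 4), collapse = ", "),
        if (ncol(object) > 4) "...", "\n")
})

# internal: presence frequency from a presence count
bandFrequencyFromCounts <- function(k, n) k / n

#' A tiny example band matrix
#'
#' Six strains scored over two primer combinations (5 bands); used in
#' documentation examples.
#'
#' @return A [`MarkerMatrix`] with 6 strains and 5 bands.
#' @export
exampleBandMatrix <- function() {
    v <- rbind(
        S1 = c(1L, 1L, 0L, 1L, 1L),
        S2 = c(1L, 1L, 0L, 1L, 1L),
        S3 = c(1L, 0L, 1L, 1L, 1L),
        S4 = c(0L, 0L, 1L, 1L, 1L),
        S5 = c(0L, 1L, 1L, 1L, 0L),
        S6 = c(0L, 1L, 1L, 1L, 0L))
    MarkerMatrix(v, primerCombination = c("P1", "P1", "P1", "P2", "P2"),
                 bandLabel = c("b1", "b2", "b3", "b1", "b2"),
                 sizeBp = c(300L, 450L, 700L, 150L, 900L))
}
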