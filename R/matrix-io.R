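#' Read a binary band matrix from delimited text
#'
#' The file dialect is a flat UTF-8 CSV holding both the 0/1 calls and the
#' primer grouping: a header row `strain,<token>,<token>,...` where each band
#' token is `<primer_combination>:<band_label>` or
#' `<primer_combination>:<band_label>:<size_bp>`, then one row per strain with
#' the strain identifier in the first column and 0/1 in the body.
#'
#' Validation is strict: any cell other than `0` or `1` is rejected with the
#' offending strain and band named; duplicate strain or band identifiers and
#' files with fewer than two strains are rejected. Band and strain order are
#' preserved from the file.
#'
#' @param path Path to a CSV file in the dialect above.
#' @param sep Field separator, `","` by default.
#' @return A validated [`MarkerMatrix`].
#' @seealso [writeMarkerMatrix()] for the inverse; the pair round-trips
#'   exactly (labels, order, values).
#' @export
readMarkerMatrix <- function(path, sep = ",") {
    if (!file.exists(path))
        stop("cannot read band matrix: no such file: ", path)
    df <- utils::read.table(path, sep = sep, header = TRUE,
                            check.names = FALSE, colClasses = "character",
                            quote = "\"", comment.char = "",
                            fileEncoding = "UTF-8")
    if (ncol(df) < 2L)
        stop("band-matrix file needs a strain column and at least one band column")
    strains <- df[[1L]]
    if (length(strains) < 2L)
        stop("need >= 2 strains, found ", length(strains))
    if (anyDuplicated(strains))
        stop("duplicate strain identifier(s): ",
             paste(unique(strains[duplicated(strains)]), collapse = ", "))
    tokens <- colnames(df)[-1L]
    parts <- strsplit(tokens, ":", fixed = TRUE)
    nfield <- lengths(parts)
    if (any(nfield < 2L | nfield > 3L))
        stop("malformed band token(s): ",
             paste(tokens[nfield < 2L | nfield > 3L], collapse = ", "),
             " (expected <primer>:<label>[:<size_bp>])")
    primer <- vapply(parts, `[[`, character(1), 1L)
    label <- vapply(parts, `[[`, character(1), 2L)
    size <- vapply(parts, function(p)
        if (length(p) == 3L) as.integer(p[[3L]]) else NA_integer_, integer(1))
    id <- paste(primer, label, sep = ":")
    if (anyDuplicated(id))
        stop("duplicate band identifier(s): ",
             paste(unique(id[duplicated(id)]), collapse = ", "))
    body <- as.matrix(df[, -1L, drop = FALSE])
    bad <- which(!(body %in% c("0", "1")), arr.ind = FALSE)
    if (length(bad)) {
        i <- ((bad[1L] - 1L) %% nrow(body)) + 1L
        j <- ((bad[1L] - 1L) %/% nrow(body)) + 1L
        stop(sprintf("non-binary cell '%s' for strain '%s', band '%s'",
                     body[bad[1L]], strains[i], id[j]))
    }
    values <- matrix(as.integer(body), nrow = nrow(body),
                     dimnames = list(strains, NULL))
    MarkerMatrix(values, primerCombination = primer, bandLabel = label,
                 sizeBp = size)
}

#' Write a band matrix as delimited text
#'
#' Serialises a [`MarkerMatrix`] in the flat CSV dialect read by
#' [readMarkerMatrix()]. The output is byte-stable for a given object, and
#' `readMarkerMatrix(writeMarkerMatrix(m, f))` reproduces `m` exactly.
#'
#' @param m A valid [`MarkerMatrix`].
#' @param path Output file path.
#' @param sep Field separator, `","` by default.
#' @return `path`, invisibly.
#' @export
writeMarkerMatrix <- function(m, path, sep = ",") {
    stopifnot(methods::is(m, "MarkerMatrix"))
    methods::validObject(m)
    rd <- bandInfo(m)
    if (any(grepl(":", rd$primerCombination, fixed = TRUE)) ||
        any(grepl(":", rd$bandLabel, fixed = TRUE)))
        stop("primer combinations and band labels must not contain ':'")
    tok <- ifelse(is.na(rd$sizeBp),
                  paste(rd$primerCombination, rd$bandLabel, sep = ":"),
                  paste(rd$primerCombination, rd$bandLabel, rd$sizeBp,
                        sep = ":"))
    v <- bandMatrix(m)
    lines <- c(paste(c("strain", tok), collapse = sep),
               vapply(seq_len(nrow(v)), function(i)
                   paste(c(rownames(v)[i], v[i, ]), collapse = sep),
                   character(1)))
    con <- tryCatch(file(path, open = "wb"),
                    error = function(e) stop("cannot write to ", path,
                                             ": ", conditionMessage(e)))
    on.exit(close(con))
    writeLines(lines, con, useBytes = TRUE)
    invisible(path)
}

#' Published per-primer summary table of the reference TRAP panel
#'
#' Loads the packaged transcription of the published per-primer-combination
#' summary of a 20-strain *Hypsizygus marmoreus* TRAP panel: 28 primer
#' combinations with total and polymorphic band counts, percentage
#' polymorphism, mean polymorphism information content (PIC), marker index
#' (MI) and fragment size range, exactly as printed. The raw band matrix
#' behind the table was never published, so this table is the panel-level
#' regression surface: feeding it to [summarizePanel()] reproduces the
#' published column means.
#'
#' The printed grand total of scorable fragments (287) disagrees with the
#' column sum of the printed rows (288); the rows are stored verbatim and the
#' grand total is attached as attribute `printedTotalBands` rather than
#' asserted.
#'
#' @return A 28-row `data.frame` with columns `primer_combination`,
#'   `total_bands`, `polymorphic_bands`, `pct_polymorphism`, `pic`, `mi`,
#'   `size_range`.
#' @examples
#' t1 <- loadTable1Fixture()
#' sum(t1$polymorphic_bands)  # 202
#' @export
loadTable1Fixture <- function() {
    path <- system.file("extdata", "trap_table1.csv", package = "TRAPdiv",
                        mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    df$total_bands <- as.integer(df$total_bands)
    df$polymorphic_bands <- as.integer(df$polymorphic_bands)
    stopifnot(nrow(df) == 28L,
              all(df$total_bands >= df$polymorphic_bands),
              all(df$polymorphic_bands >= 0L))
    attr(df, "printedTotalBands") <- 287L
    df
}
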