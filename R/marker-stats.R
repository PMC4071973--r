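#' Band presence frequency
#'
#' Fraction of strains in which a band is present.
#'
#' @param m A [`MarkerMatrix`].
#' @param band A band identifier (`<primer>:<label>`, see [bandIds()]).
#' @return A fraction in `[0, 1]`.
#' @export
bandFrequency <- function(m, band) {
    i <- match(band, bandIds(m))
    if (is.na(i)) stop("unknown band: ", band)
    sum(SummarizedExperiment::assay(m, "bands")[i, ]) / nStrains(m)
}

#' Polymorphism information content of a dominant (two-state) band
#'
#' For a dominant marker scored present/absent, the pattern frequencies are
#' `p` and `1 - p`, so PIC = 1 - p^2 - (1-p)^2 = 2p(1-p): zero for a
#' monomorphic band and at most 0.5, attained at p = 0.5. Heterozygotes are
#' invisible to dominant markers, which is why the two-state ceiling of 0.5
#' (rather than the codominant 1 - sum p_i^2 form) applies.
#'
#' @param p Presence frequency (vectorised), each in `[0, 1]`.
#' @return PIC value(s) in `[0, 0.5]`.
#' @examples
#' bandPIC(c(0, 0.25, 0.5, 1))
#' @export
bandPIC <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("presence frequency must lie in [0, 1]")
    2 * p * (1 - p)
}

#' Is a band polymorphic?
#'
#' A band is polymorphic when both states are observed in the panel:
#' `0 < bandFrequency < 1`. No minor-frequency threshold is applied.
#'
#' @inheritParams bandFrequency
#' @return `TRUE` or `FALSE`.
#' @export
isPolymorphic <- function(m, band) {
    p <- bandFrequency(m, band)
    p > 0 && p < 1
}

#' Mean PIC of a primer combination
#'
#' Arithmetic mean of [bandPIC()] over the polymorphic bands of one primer
#' combination. Monomorphic bands are excluded from the average: published
#' dominant-marker tables report per-primer PIC values that reach the 0.5
#' ceiling even when only a minority of the primer's bands are polymorphic,
#' which is only consistent with averaging over the polymorphic bands.
#' If the primer combination has no polymorphic band the mean is 0 and a
#' warning is raised.
#'
#' @param m A [`MarkerMatrix`].
#' @param primer A primer combination present in `m`.
#' @return Mean PIC in `[0, 0.5]`.
#' @export
primerPIC <- function(m, primer) {
    idx <- which(bandInfo(m)$primerCombination == primer)
    if (!length(idx)) stop("unknown primer combination: ", primer)
    p <- rowSums(SummarizedExperiment::assay(m, "bands")[idx, , drop = FALSE]) /
        nStrains(m)
    poly <- p > 0 & p < 1
    if (!any(poly)) {
        warning("no polymorphic band for primer combination '", primer,
                "'; PIC set to 0")
        return(0)
    }
    mean(bandPIC(p[poly]))
}

#' Marker index of a primer combination
#'
#' The marker index (MI) summarises the informativeness of a whole primer
#' combination by combining its mean PIC with its band yield. Two published
#' conventions circulate and both are exposed:
#'
#' * `mode = "table"` (default): `MI = PIC * eta`, mean PIC times the total
#'   number of bands `eta`. This is the definition that published
#'   dominant-marker summary tables actually follow.
#' * `mode = "formula"`: `MI = PIC * eta * beta`, additionally multiplying by
#'   the proportion of polymorphic bands `beta`, the form usually printed in
#'   methods sections.
#'
#' The two disagree whenever `beta < 1`; for the packaged reference table the
#' `"table"` mode reproduces the printed MI column within the rounding of the
#' 2-decimal PIC for 27 of its 28 rows (see the methods vignette).
#'
#' @param picMean Mean PIC of the primer combination, in `[0, 0.5]`.
#' @param nTotal Total number of bands `eta` (>= 0).
#' @param pctPoly Percentage of polymorphic bands (`beta * 100`); only used
#'   by `mode = "formula"`.
#' @param mode `"table"` or `"formula"`.
#' @return A non-negative marker index.
#' @examples
#' markerIndex(0.32, 6)                        # 1.92
#' markerIndex(0.50, 12, 75, mode = "formula") # 4.5
#' @export
markerIndex <- function(picMean, nTotal, pctPoly = NULL,
                        mode = c("table", "formula")) {
    mode <- match.arg(mode)
    if (picMean < 0 || nTotal < 0)
        stop("marker-index inputs must be non-negative")
    if (mode == "table")
        return(picMean * nTotal)
    if (is.null(pctPoly) || pctPoly < 0)
        stop("mode 'formula' needs a non-negative 'pctPoly'")
    picMean * nTotal * pctPoly / 100
}

#' Per-primer polymorphism statistics
#'
#' One summary row for a primer combination: band counts, percentage
#' polymorphism, mean PIC over polymorphic bands, marker index, and the
#' fragment size range when band sizes are recorded. Statistics are computed
#' at full precision; rounding to two decimals happens only at report time.
#'
#' @param m A [`MarkerMatrix`].
#' @param primer A primer combination present in `m`.
#' @param miMode Marker-index convention, see [markerIndex()].
#' @return A one-row `data.frame` with columns `primer_combination`,
#'   `total_bands`, `polymorphic_bands`, `pct_polymorphism`, `pic`, `mi`,
#'   `size_min`, `size_max`.
#' @export
primerStats <- function(m, primer, miMode = c("table", "formula")) {
    miMode <- match.arg(miMode)
    idx <- which(bandInfo(m)$primerCombination == primer)
    if (!length(idx)) stop("unknown primer combination: ", primer)
    p <- rowSums(SummarizedExperiment::assay(m, "bands")[idx, , drop = FALSE]) /
        nStrains(m)
    poly <- p > 0 & p < 1
    nTotal <- length(idx)
    nPoly <- sum(poly)
    if (nPoly == 0L)
        warning("no polymorphic band for primer combination '", primer,
                "'; PIC set to 0")
    picMean <- if (nPoly) mean(bandPIC(p[poly])) else 0
    pctPoly <- 100 * nPoly / nTotal
    sz <- bandInfo(m)$sizeBp[idx]
    data.frame(primer_combination = primer,
               total_bands = nTotal,
               polymorphic_bands = nPoly,
               pct_polymorphism = pctPoly,
               pic = picMean,
               mi = markerIndex(picMean, nTotal, pctPoly, mode = miMode),
               size_min = if (all(is.na(sz))) NA_integer_ else
                   min(sz, na.rm = TRUE),
               size_max = if (all(is.na(sz))) NA_integer_ else
                   max(sz, na.rm = TRUE),
               stringsAsFactors = FALSE)
}

#' Panel-level summary of per-primer statistics
#'
#' `summarizePanel()` assembles one [primerStats()] row per primer
#' combination plus unweighted column means, band-count totals and column
#' ranges — the panel-level quantities a dominant-marker survey reports. It
#' accepts either a [`MarkerMatrix`] (rows computed from the band calls) or a
#' per-primer `data.frame` that already carries the columns `total_bands`,
#' `polymorphic_bands`, `pct_polymorphism`, `pic` and `mi` — the latter lets
#' a published summary table (see [loadTable1Fixture()]) flow through the
#' same totals/means path when the raw band matrix is unavailable.
#'
#' @param x A [`MarkerMatrix`] or a per-primer statistics `data.frame`.
#' @param miMode Marker-index convention (matrix input only).
#' @return A `PanelSummary`: a list with elements `rows` (per-primer
#'   `data.frame`), `totals` (named: `total_bands`, `polymorphic_bands`),
#'   `means` (named, unweighted over rows) and `ranges` (min/max per column).
#' @examples
#' summarizePanel(loadTable1Fixture())$means
#' @export
setGeneric("summarizePanel", function(x, ...) standardGeneric("summarizePanel"))

.panelSummary <- function(rows) {
    num <- c("total_bands", "polymorphic_bands", "pct_polymorphism",
             "pic", "mi")
    out <- list(
        rows = rows,
        totals = c(total_bands = sum(rows$total_bands),
                   polymorphic_bands = sum(rows$polymorphic_bands)),
        means = vapply(rows[num], mean, numeric(1)),
        ranges = rbind(min = vapply(rows[num], min, numeric(1)),
                       max = vapply(rows[num], max, numeric(1))))
    class(out) <- "PanelSummary"
    out
}

#' @rdname summarizePanel
#' @export
setMethod("summarizePanel", "MarkerMatrix", function(x, miMode = "table") {
    rows <- do.call(rbind, lapply(primerCombinations(x), function(pc)
        primerStats(x, pc, miMode = miMode)))
    .panelSummary(rows)
})

#' @rdname summarizePanel
#' @export
setMethod("summarizePanel", "data.frame", function(x, ...) {
    need <- c("primer_combination", "total_bands", "polymorphic_bands",
              "pct_polymorphism", "pic", "mi")
    if (!all(need %in% colnames(x)))
        stop("per-primer table must have columns: ",
             paste(need, collapse = ", "))
    .panelSummary(x)
})

#' @export
print.PanelSummary <- function(x, ...) {
    cat("Panel summary over", nrow(x$rows), "primer combinations\n")
    cat(sprintf("  bands: %d total, %d polymorphic\n",
                x$totals["total_bands"], x$totals["polymorphic_bands"]))
    cat(sprintf("  means: %%poly %.2f  PIC %.2f  MI %.2f\n",
                x$means["pct_polymorphism"], x$means["pic"], x$means["mi"]))
    invisible(x)
}

#' Write a panel summary as CSV
#'
#' Serialises the per-primer rows (values rounded to two decimals, matching
#' how such tables are reported) followed by `Total`, `Mean`, `Minimum` and
#' `Maximum` footer rows.
#'
#' @param s A `PanelSummary` from [summarizePanel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writePanelSummary <- function(s, path) {
    stopifnot(inherits(s, "PanelSummary"))
    r <- s$rows
    sizeTxt <- if (all(c("size_min", "size_max") %in% colnames(r))) {
        ifelse(is.na(r$size_min), "",
               paste0(r$size_min, "-", r$size_max))
    } else if ("size_range" %in% colnames(r)) r$size_range else ""
    fmt <- function(x) formatC(x, format = "f", digits = 2)
    body <- data.frame(
        primer_combination = r$primer_combination,
        total_bands = r$total_bands,
        polymorphic_bands = r$polymorphic_bands,
        pct_polymorphism = fmt(r$pct_polymorphism),
        pic = fmt(r$pic),
        mi = fmt(r$mi),
        size_range = sizeTxt,
        stringsAsFactors = FALSE)
    foot <- data.frame(
        primer_combination = c("Total", "Mean", "Minimum", "Maximum"),
        total_bands = c(s$totals["total_bands"], fmt(s$means["total_bands"]),
                        s$ranges["min", "total_bands"],
                        s$ranges["max", "total_bands"]),
        polymorphic_bands = c(s$totals["polymorphic_bands"],
                              fmt(s$means["polymorphic_bands"]),
                              s$ranges["min", "polymorphic_bands"],
                              s$ranges["max", "polymorphic_bands"]),
        pct_polymorphism = c("", fmt(s$means["pct_polymorphism"]),
                             fmt(s$ranges["min", "pct_polymorphism"]),
                             fmt(s$ranges["max", "pct_polymorphism"])),
        pic = c("", fmt(s$means["pic"]), fmt(s$ranges["min", "pic"]),
                fmt(s$ranges["max", "pic"])),
        mi = c("", fmt(s$means["mi"]), fmt(s$ranges["min", "mi"]),
               fmt(s$ranges["max", "mi"])),
        size_range = "",
        stringsAsFactors = FALSE)
    utils::write.csv(rbind(body, foot), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
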