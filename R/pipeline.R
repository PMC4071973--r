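#' Pipeline stage: simulate a panel and write it to files
#'
#' Writes the simulated band matrix (`matrix.csv`, the [readMarkerMatrix()]
#' dialect) and the planted truth labels (`truth.csv`: strain, cluster,
#' subgroup) into `dir`. Identical config + seed produces byte-identical
#' files.
#'
#' @param config A [`SimulationConfig`].
#' @param dir Output directory (created if absent).
#' @param verbose Print summary counts.
#' @return Invisibly, a named character vector of the written paths.
#' @export
simulateToFiles <- function(config, dir, verbose = FALSE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateMarkerMatrix(config)
    matrixPath <- file.path(dir, "matrix.csv")
    truthPath <- file.path(dir, "truth.csv")
    writeMarkerMatrix(sim$matrix, matrixPath)
    truth <- data.frame(strain = strainIds(sim$matrix),
                        cluster = unname(sim$truth$clusterLabels),
                        subgroup = unname(sim$truth$subgroupLabels),
                        stringsAsFactors = FALSE)
    utils::write.csv(truth, truthPath, row.names = FALSE, quote = FALSE)
    if (verbose)
        message(sprintf("simulated %d strains x %d bands (%d clusters)",
                        nStrains(sim$matrix), nBands(sim$matrix),
                        length(unique(sim$truth$clusterLabels))))
    invisible(c(matrix = matrixPath, truth = truthPath))
}

#' Pipeline stage: per-primer summary report
#'
#' Runs [summarizePanel()] and writes the per-primer table with
#' totals/means/min/max footer rows via [writePanelSummary()]. `x` may be a
#' [`MarkerMatrix`], a path to a band-matrix CSV, or a per-primer statistics
#' `data.frame` such as [loadTable1Fixture()] — the last feeds a published
#' summary table through the identical totals/means path.
#'
#' @param x Input (see above).
#' @param path Output CSV path.
#' @param miMode Marker-index convention, see [markerIndex()].
#' @param verbose Print the panel means.
#' @return The `PanelSummary`, invisibly.
#' @export
statsToFile <- function(x, path, miMode = "table", verbose = FALSE) {
    if (is.character(x)) x <- readMarkerMatrix(x)
    s <- if (is.data.frame(x)) summarizePanel(x)
         else summarizePanel(x, miMode = miMode)
    writePanelSummary(s, path)
    if (verbose) print(s)
    invisible(s)
}

#' Pipeline stage: Jaccard/UPGMA clustering to files
#'
#' Computes the Jaccard similarity matrix, builds the UPGMA dendrogram,
#' writes it as Newick (`upgma.nwk`), and writes one cluster-assignment CSV
#' (`clusters_s<threshold>.csv`: strain, cluster, threshold) per similarity
#' threshold.
#'
#' @param x A [`MarkerMatrix`] or a band-matrix CSV path.
#' @param dir Output directory (created if absent).
#' @param thresholds Similarity thresholds at which to cut the tree.
#' @param verbose Print cluster counts per threshold.
#' @return Invisibly, a list with the `tree` and per-threshold assignments.
#' @export
clusterToFiles <- function(x, dir, thresholds = c(0.718, 0.575, 0.435),
                           verbose = FALSE) {
    if (is.character(x)) x <- readMarkerMatrix(x)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tree <- upgma(toDistance(similarityMatrix(x)))
    writeNewick(tree, file.path(dir, "upgma.nwk"))
    cuts <- lapply(thresholds, function(s) {
        ct <- cutAtSimilarity(tree, s)
        df <- data.frame(strain = names(ct$labels),
                         cluster = unname(ct$labels),
                         threshold = s, stringsAsFactors = FALSE)
        utils::write.csv(df, file.path(dir, sprintf("clusters_s%.3f.csv", s)),
                         row.names = FALSE, quote = FALSE)
        if (verbose)
            message(sprintf("similarity %.3f -> %d clusters", s, ct$k))
        ct
    })
    invisible(list(tree = tree, cuts = cuts))
}

#' Pipeline stage: PCoA to files
#'
#' Runs [runPCoA()] on the Jaccard distance matrix and writes the strain
#' coordinates (`pcoa_coordinates.csv`) and the eigenvalue/variance table
#' (`pcoa_eigenvalues.csv`).
#'
#' @param x A [`MarkerMatrix`] or a band-matrix CSV path.
#' @param dir Output directory (created if absent).
#' @param nAxes Number of axes to retain.
#' @param verbose Print the cumulative variance of the first `min(3, nAxes)`
#'   axes.
#' @return The [`PCoAResult`], invisibly.
#' @export
pcoaToFiles <- function(x, dir, nAxes = 3L, verbose = FALSE) {
    if (is.character(x)) x <- readMarkerMatrix(x)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    r <- runPCoA(toDistance(similarityMatrix(x)), nAxes = nAxes)
    co <- data.frame(strain = rownames(pcoaCoordinates(r)),
                     format(pcoaCoordinates(r), digits = 17, trim = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(co, file.path(dir, "pcoa_coordinates.csv"),
                     row.names = FALSE, quote = FALSE)
    ev <- data.frame(axis = seq_along(pcoaEigenvalues(r)),
                     eigenvalue = pcoaEigenvalues(r),
                     pct_variance = c(pcoaPctVariance(r),
                                      rep(NA, length(pcoaEigenvalues(r)) -
                                              length(pcoaPctVariance(r)))))
    utils::write.csv(ev, file.path(dir, "pcoa_eigenvalues.csv"),
                     row.names = FALSE, quote = FALSE)
    if (verbose)
        message(sprintf("first %d axes capture %.2f%% of the variance",
                        min(3L, nAxes),
                        varianceCaptured(r, min(3L, nAxes))))
    invisible(r)
}

#' End-to-end diversity report
#'
#' Runs the whole pipeline — per-primer statistics, Jaccard/UPGMA clustering
#' with threshold cuts, and PCoA — on a band matrix (read from CSV, given
#' directly, or simulated from a [`SimulationConfig`]), writing every stage's
#' artifacts plus a human-readable `report.txt` summarising counts, means,
#' cluster tables, the cophenetic correlation and the variance captured.
#' The report records the package version, the marker-index mode and the
#' configuration used; re-running with the same inputs and seed reproduces
#' it byte for byte.
#'
#' @param x A [`MarkerMatrix`], a band-matrix CSV path, or a
#'   [`SimulationConfig`] (simulated first, matrix and truth written too).
#' @param dir Output directory (created if absent).
#' @param thresholds Similarity thresholds for the cluster cuts.
#' @param nAxes PCoA axes to retain.
#' @param miMode Marker-index convention.
#' @return Invisibly, a list with the panel summary, tree, cuts and PCoA
#'   result.
#' @export
diversityReport <- function(x, dir, thresholds = c(0.718, 0.575, 0.435),
                            nAxes = 3L, miMode = "table") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cfgEcho <- NULL
    if (methods::is(x, "SimulationConfig")) {
        cfgEcho <- sprintf(
            "simulated input: %d strains, %d bands, %d ancestors, flip %.3g, seed %d",
            x@nStrains, sum(x@primerBandCounts),
            length(x@ancestorWeights), x@flipProbability, x@seed)
        simulateToFiles(x, dir)
        x <- readMarkerMatrix(file.path(dir, "matrix.csv"))
    } else if (is.character(x)) {
        cfgEcho <- paste("input file:", x)
        x <- readMarkerMatrix(x)
    }
    s <- statsToFile(x, file.path(dir, "panel_summary.csv"), miMode = miMode)
    cl <- clusterToFiles(x, dir, thresholds = thresholds)
    r <- pcoaToFiles(x, dir, nAxes = nAxes)
    cc <- if (nStrains(x) >= 3)
        copheneticCorrelation(cl$tree, toDistance(similarityMatrix(x)))
    else NA_real_

    lines <- c(
        sprintf("TRAPdiv diversity report (package version %s)",
                as.character(utils::packageVersion("TRAPdiv"))),
        if (!is.null(cfgEcho)) cfgEcho,
        sprintf("marker-index mode: %s", miMode),
        "",
        sprintf("panel: %d strains, %d bands, %d primer combinations",
                nStrains(x), nBands(x), length(primerCombinations(x))),
        sprintf("bands: %d total, %d polymorphic (%.2f%% mean per primer)",
                s$totals["total_bands"], s$totals["polymorphic_bands"],
                s$means["pct_polymorphism"]),
        sprintf("mean PIC %.2f, mean MI %.2f", s$means["pic"], s$means["mi"]),
        sprintf("cophenetic correlation: %.4f", cc),
        "",
        "cluster cuts (similarity threshold -> clusters):",
        vapply(cl$cuts, function(ct)
            sprintf("  s = %.3f -> k = %d  [%s]", ct$threshold, ct$k,
                    paste(tapply(names(ct$labels), ct$labels, paste,
                                 collapse = ","), collapse = " | ")),
            character(1)),
        "",
        sprintf("PCoA: first %d axes capture %.2f%% of the variance%s",
                nAxes, varianceCaptured(r, nAxes),
                if (r@negativeEigenvalues)
                    " (negative eigenvalues present)" else ""))
    writeLines(lines, file.path(dir, "report.txt"))
    invisible(list(summary = s, tree = cl$tree, cuts = cl$cuts, pcoa = r))
}
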