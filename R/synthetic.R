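#' SimulationConfig: parameters for the synthetic band-matrix generator
#'
#' The generator plants known population structure into a dominant-marker
#' panel so every pipeline stage can be validated against ground truth.
#' Each ancestor (cluster) gets an ancestral binary band profile; strains
#' copy their ancestor's (or sub-group's) profile with independent per-band
#' Bernoulli flips. Monomorphic bands are fixed present in every profile and
#' exempt from flip noise — they model species-diagnostic fragments shared
#' by the whole panel.
#'
#' @slot nStrains Number of strains (>= 2).
#' @slot ancestorWeights Cluster-size fractions, summing to 1.
#' @slot subgroupWeights List (one element per ancestor) of nested sub-group
#'   weight vectors, or `NULL` entries for unstructured ancestors.
#' @slot primerBandCounts Integer vector, bands per primer combination
#'   (names become primer labels).
#' @slot monomorphicFraction Fraction of bands fixed present in all strains.
#' @slot flipProbability Per-band, per-strain flip rate applied to
#'   polymorphic bands.
#' @slot ancestralPresenceProb Probability a polymorphic band is present in
#'   an ancestral profile (drawn independently per ancestor).
#' @slot subgroupFlips Number of polymorphic-band positions toggled to make
#'   each sub-group profile from its ancestor profile.
#' @slot seed Integer RNG seed; identical config + seed gives bit-identical
#'   output.
#'
#' @seealso [simulationConfig()], [referencePanelConfig()],
#'   [simulateMarkerMatrix()]
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(nStrains = "integer", ancestorWeights = "numeric",
                        subgroupWeights = "list",
                        primerBandCounts = "integer",
                        monomorphicFraction = "numeric",
                        flipProbability = "numeric",
                        ancestralPresenceProb = "numeric",
                        subgroupFlips = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nStrains < 2L)
        msg <- c(msg, "nStrains must be >= 2")
    if (abs(sum(object@ancestorWeights) - 1) > 1e-8 ||
        any(object@ancestorWeights <= 0))
        msg <- c(msg, "ancestorWeights must be positive and sum to 1")
    if (length(object@subgroupWeights) != length(object@ancestorWeights))
        msg <- c(msg, "one subgroupWeights entry (possibly NULL) per ancestor")
    for (w in object@subgroupWeights)
        if (!is.null(w) && (abs(sum(w) - 1) > 1e-8 || any(w <= 0)))
            msg <- c(msg, "sub-group weights must be positive and sum to 1")
    if (any(object@primerBandCounts < 1L))
        msg <- c(msg, "every primer combination needs >= 1 band")
    probs <- c(object@monomorphicFraction, object@flipProbability,
               object@ancestralPresenceProb)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (object@subgroupFlips < 0L)
        msg <- c(msg, "subgroupFlips must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig-class Compact display.
#' @param object A `SimulationConfig`.
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nStrains, "strains,",
        sum(object@primerBandCounts), "bands in",
        length(object@primerBandCounts), "primer combinations\n")
    cat(sprintf("  %d ancestors (weights %s), flip prob %.3g, monomorphic %.2f, seed %d\n",
                length(object@ancestorWeights),
                paste(signif(object@ancestorWeights, 3), collapse = "/"),
                object@flipProbability, object@monomorphicFraction,
                object@seed))
})

#' Construct a simulation configuration
#'
#' @param nStrains Number of strains.
#' @param ancestorWeights Cluster-size fractions (sum 1).
#' @param subgroupWeights Optional list of nested weight vectors per ancestor
#'   (`NULL` entries for unstructured ancestors).
#' @param primerBandCounts Bands per primer combination; unnamed vectors get
#'   primer labels `PC01, PC02, ...`.
#' @param monomorphicFraction Fraction of bands fixed present everywhere.
#' @param flipProbability Per-band per-strain flip rate on polymorphic bands.
#' @param ancestralPresenceProb Bernoulli presence probability for
#'   polymorphic bands in ancestral profiles.
#' @param subgroupFlips Band toggles distinguishing each sub-group profile
#'   from its ancestor.
#' @param seed Integer RNG seed.
#' @return A validated [`SimulationConfig`].
#' @export
simulationConfig <- function(nStrains = 20L,
                             ancestorWeights = c(0.9, 0.1),
                             subgroupWeights = NULL,
                             primerBandCounts = rep(10L, 28L),
                             monomorphicFraction = 0.15,
                             flipProbability = 0.05,
                             ancestralPresenceProb = 0.5,
                             subgroupFlips = 12L,
                             seed = 101L) {
    if (is.null(subgroupWeights))
        subgroupWeights <- vector("list", length(ancestorWeights))
    if (is.null(names(primerBandCounts)))
        names(primerBandCounts) <- sprintf("PC%02d",
                                           seq_along(primerBandCounts))
    methods::new("SimulationConfig",
                 nStrains = as.integer(nStrains),
                 ancestorWeights = as.numeric(ancestorWeights),
                 subgroupWeights = subgroupWeights,
                 primerBandCounts = stats::setNames(
                     as.integer(primerBandCounts), names(primerBandCounts)),
                 monomorphicFraction = monomorphicFraction,
                 flipProbability = flipProbability,
                 ancestralPresenceProb = ancestralPresenceProb,
                 subgroupFlips = as.integer(subgroupFlips),
                 seed = as.integer(seed))
}

#' Default configuration emulating the reference TRAP panel
#'
#' Reproduces the architecture of the published 20-strain *H. marmoreus*
#' TRAP panel: 20 strains; two ancestors weighted 18/20 and 2/20 (the
#' published dendrogram splits 18 strains against a 2-strain cluster); the
#' larger ancestor nested into three sub-groups of 2, 14 and 2 strains; 28
#' primer combinations carrying the published per-primer band counts (288
#' bands in total); flip probability 0.05. The designated-monomorphic
#' fraction is 0.15, chosen so that the *observed* polymorphic fraction
#' lands near the published 70%: a designated-polymorphic band is observed
#' polymorphic with probability about 0.82 under these settings (see the
#' methods vignette for the calculation), giving an expected observed
#' polymorphism of roughly 0.85 x 0.82 = 70%.
#'
#' @param seed Integer RNG seed (default 101).
#' @return A [`SimulationConfig`].
#' @export
referencePanelConfig <- function(seed = 101L) {
    t1 <- loadTable1Fixture()
    counts <- stats::setNames(t1$total_bands, t1$primer_combination)
    simulationConfig(nStrains = 20L,
                     ancestorWeights = c(18, 2) / 20,
                     subgroupWeights = list(c(2, 14, 2) / 18, NULL),
                     primerBandCounts = counts,
                     monomorphicFraction = 0.15,
                     flipProbability = 0.05,
                     ancestralPresenceProb = 0.5,
                     subgroupFlips = 12L,
                     seed = seed)
}

# largest-remainder apportionment of n into length(w) positive counts
.apportion <- function(n, w) {
    raw <- n * w / sum(w)
    k <- floor(raw)
    rem <- n - sum(k)
    if (rem > 0) {
        extra <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
        k[extra] <- k[extra] + 1
    }
    as.integer(k)
}

#' Simulate a band matrix with planted population structure
#'
#' For each ancestor an ancestral profile is drawn: designated-monomorphic
#' bands are fixed present; polymorphic bands are Bernoulli
#' (`ancestralPresenceProb`), independently per ancestor. Ancestors with
#' declared sub-groups get one sub-group profile each, equal to the ancestral
#' profile with `subgroupFlips` random polymorphic positions toggled. Every
#' strain then copies its (sub-)group profile with independent per-band
#' flips at `flipProbability`, applied to polymorphic bands only. The result
#' is deterministic given the config (which carries the seed); the caller's
#' RNG state is left untouched.
#'
#' @param config A [`SimulationConfig`].
#' @param seed Optional override of `config@seed`.
#' @return A list with elements `matrix` (a [`MarkerMatrix`]) and `truth`
#'   (list: `clusterLabels`, `subgroupLabels` — named integer/character
#'   vectors per strain — and `ancestralProfiles`, an ancestors-by-bands 0/1
#'   matrix).
#' @examples
#' sim <- simulateMarkerMatrix(simulationConfig(nStrains = 8, seed = 7))
#' table(sim$truth$clusterLabels)
#' @export
simulateMarkerMatrix <- function(config, seed = NULL) {
    stopifnot(methods::is(config, "SimulationConfig"))
    methods::validObject(config)
    if (is.null(seed)) seed <- config@seed
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)

    nb <- sum(config@primerBandCounts)
    n <- config@nStrains
    nA <- length(config@ancestorWeights)
    primer <- rep(names(config@primerBandCounts), config@primerBandCounts)

    nMono <- round(config@monomorphicFraction * nb)
    monoIdx <- sort(sample.int(nb, nMono))
    polyIdx <- setdiff(seq_len(nb), monoIdx)

    profiles <- matrix(1L, nA, nb)
    for (a in seq_len(nA))
        profiles[a, polyIdx] <- stats::rbinom(length(polyIdx), 1L,
                                              config@ancestralPresenceProb)
    rownames(profiles) <- paste0("ancestor", seq_len(nA))

    clusterSizes <- .apportion(n, config@ancestorWeights)
    clusterLabels <- rep(seq_len(nA), clusterSizes)

    # per-strain source profile: sub-group perturbation of the ancestor
    subgroupLabels <- character(n)
    source <- matrix(0L, n, nb)
    pos <- 0L
    for (a in seq_len(nA)) {
        sw <- config@subgroupWeights[[a]]
        if (is.null(sw)) sw <- 1
        sgSizes <- .apportion(clusterSizes[a], sw)
        sgProfiles <- lapply(seq_along(sgSizes), function(g) {
            pr <- profiles[a, ]
            if (length(sgSizes) > 1L && config@subgroupFlips > 0L &&
                length(polyIdx)) {
                fl <- polyIdx[sample.int(
                    length(polyIdx),
                    min(config@subgroupFlips, length(polyIdx)))]
                pr[fl] <- 1L - pr[fl]
            }
            pr
        })
        for (g in seq_along(sgSizes)) {
            for (i in seq_len(sgSizes[g])) {
                pos <- pos + 1L
                source[pos, ] <- sgProfiles[[g]]
                subgroupLabels[pos] <- paste0(a, ".", g)
            }
        }
    }

    values <- source
    if (config@flipProbability > 0 && length(polyIdx)) {
        flips <- matrix(stats::rbinom(n * length(polyIdx), 1L,
                                      config@flipProbability),
                        n, length(polyIdx))
        values[, polyIdx] <- abs(source[, polyIdx] - flips)
    }
    strains <- sprintf("S%02d", seq_len(n))
    rownames(values) <- strains
    names(clusterLabels) <- names(subgroupLabels) <- strains

    m <- MarkerMatrix(values, primerCombination = primer)
    list(matrix = m,
         truth = list(clusterLabels = clusterLabels,
                      subgroupLabels = subgroupLabels,
                      ancestralProfiles = profiles))
}

#' Read a simulation configuration from a YAML/JSON key-value file
#'
#' Accepts any file `yaml::read_yaml` understands (YAML or plain JSON) with
#' keys matching the [simulationConfig()] arguments; absent keys keep their
#' defaults.
#'
#' @param path Path to the config file.
#' @return A [`SimulationConfig`].
#' @export
readSimulationConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(simulationConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown simulation config key(s): ", paste(bad, collapse = ", "))
    do.call(simulationConfig, vals)
}
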