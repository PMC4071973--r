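---
title: "Diversity analysis of dominant marker panels: models and methods"
author: "TRAPdiv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity analysis of dominant marker panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TRAPdiv)
```

## The problem

Dominant molecular markers — TRAP, SRAP, ISSR, RAPD — fingerprint a panel of
strains as multi-band electrophoretic profiles. Each band is scored only as
present (1) or absent (0) per strain; a heterozygote is indistinguishable from
a homozygous presence. The standard analysis of such a panel has four stages,
and `TRAPdiv` implements each of them against a single validated container,
the `MarkerMatrix` (a `SummarizedExperiment` with bands as features, strains
as samples, and per-band primer-combination metadata):

1. **Per-primer polymorphism statistics** — band counts, percentage of
   polymorphic bands, polymorphism information content (PIC), marker index
   (MI).
2. **Pairwise Jaccard similarity** among strains and its complement, the
   Jaccard distance.
3. **UPGMA clustering** of the distance matrix, with clusters read off at
   similarity thresholds and the tree exported as Newick.
4. **Principal coordinates analysis** (PCoA) of the same distances.

A synthetic generator with planted population structure provides ground truth
for every stage, since real band matrices of this kind are frequently not
deposited alongside the published summary tables.

## Polymorphism statistics

For a dominant band with presence frequency $p$ there are two observable
pattern states, so

$$\mathrm{PIC} = 1 - p^2 - (1-p)^2 = 2p(1-p),$$

which is 0 for a monomorphic band and peaks at 0.5 when $p = 0.5$. The
per-primer PIC is the arithmetic mean over the **polymorphic** bands of that
primer combination. This is a deliberate reading of an ambiguous convention:
published per-primer PIC columns for dominant markers routinely print 0.50
for primer combinations in which only a minority of bands are polymorphic,
which is arithmetically impossible if monomorphic bands (PIC 0) entered the
average and impossible under a multilocus-pattern reading (whose ceiling
grows with the number of patterns, not 0.5). A primer combination with no
polymorphic band gets PIC 0 with a warning. A band counts as polymorphic
whenever both states are observed; no minor-frequency threshold is applied,
because none is standard for these panels.

The marker index combines the mean PIC with the band yield of a primer
combination. Two conventions circulate and `markerIndex()` exposes both:

* `mode = "table"` (default): $\mathrm{MI} = \mathrm{PIC} \cdot \eta$, with
  $\eta$ the total band count;
* `mode = "formula"`: $\mathrm{MI} = \mathrm{PIC} \cdot \eta \beta$, with
  $\beta$ the proportion of polymorphic bands.

The two disagree whenever $\beta < 1$. The packaged reference table
(`loadTable1Fixture()`, a 28-row published per-primer summary of a 20-strain
*Hypsizygus marmoreus* TRAP panel) settles the default: its printed MI column
matches $\mathrm{PIC} \cdot \eta$ within the half-ulp rounding of the
2-decimal PIC for 27 of 28 rows (e.g. $0.32 \times 6 = 1.92$ exactly),
while the $\mathrm{PIC}\,\eta\beta$ form fits almost none of them. The one
row that fits neither definition (JN00L1-EM16: 10 bands, PIC 0.50, MI 4.48,
and a printed percentage that is not `100 * 8/10` either) is treated as a
typographical anomaly and excluded from the consistency invariant. The same
table's printed grand total of bands (287) disagrees with its own column sum
(288); the rows are stored verbatim and the grand total is kept out of all
assertions. An "effective MI" is sometimes mentioned alongside these
statistics without a definition; it is not implemented.

All statistics are computed at full precision; rounding to two decimals
happens only in report serialisation, matching how such tables are printed.

## Similarity and distance

Between two band profiles, `jaccard()` computes $a/(a+b+c)$ over shared
presences $a$ and one-sided presences $b, c$. Joint absences are excluded —
the absence of a dominant band is not evidence of shared ancestry — which is
the standard Jaccard convention for band data. Two all-zero profiles have an
undefined coefficient; the package returns 0 with a warning rather than
failing, since an all-absent strain is degenerate but representable.
Clustering and ordination operate on the complement $d = 1 - s$; thresholds
quoted on the similarity scale convert the same way.

## UPGMA and threshold cuts

`upgma()` is the unweighted pair-group method: the distance between two
clusters is the arithmetic mean of all cross-pair leaf distances, maintained
exactly through the proportional update
$d(A \cup B, X) = (n_A d(A,X) + n_B d(B,X))/(n_A + n_B)$. Merge heights are
the merged pair's distance and can never decrease (UPGMA admits no
inversions), so the tree is ultrametric; on an ultrametric input the
cophenetic distances reproduce the input exactly. Ties — several pairs at
the minimal distance — are broken deterministically toward the pair whose
member leaf indices are lexicographically smallest; average-linkage software
is typically silent on this point, and a fixed rule is what makes the output
testable. Equivalently one could run UPGMA on similarities directly, merging
at maxima; the topology is identical and the heights mirror, so the package
standardises on the distance scale and converts thresholds.

`cutAtSimilarity(tree, s)` returns the maximal subtrees all of whose internal
merges sit **strictly below** $1 - s$ on the distance scale: $s = 1$ yields
singletons even in the presence of duplicate strains (zero-height merges),
and $s = 0$ yields one cluster provided no merge sits exactly at distance 1.
Cluster counts are non-increasing as the threshold decreases. The companion
diagnostic `copheneticCorrelation()` is the Pearson correlation between input
and cophenetic distances over the $n(n-1)/2$ pairs.

Newick export uses the ultrametric plotting convention: a node merging at
height $h$ sits at depth $h/2$, so each merge height — a distance between two
groups — is split evenly between the two lineages and every root-to-leaf path
has length half the root height. Labels containing Newick metacharacters are
single-quoted.

## Principal coordinates

`runPCoA()` follows Gower: double-center $-d^2/2$ with $C = I - \mathbf{1}
\mathbf{1}^\top/n$, eigendecompose the symmetric result, and scale
eigenvectors by the square roots of their positive eigenvalues. Jaccard
distances are metric but not always Euclidean-embeddable, so negative
eigenvalues are expected; they are flagged (`negativeEigenvalues`) and
reported, never corrected — Lingoes/Cailliez adjustments are deliberately out
of scope, as they change the variance decomposition and are not standard in
these panel analyses. Per-axis variance percentages are computed over the
positive eigenvalues only, so `varianceCaptured(r, k)` reaches 100 at the
last positive axis. Axes with non-positive eigenvalues carry zero
coordinates. Numerical policy: eigenvalues within `1e-12 * max|lambda|` of
zero are treated as zero, and each eigenvector's sign is fixed by making its
largest-magnitude entry positive, so results are deterministic.

## The synthetic generator

`simulateMarkerMatrix()` plants known structure into a panel:

* a designated **monomorphic fraction** of bands is fixed present in every
  profile (species-diagnostic fragments) and exempt from noise;
* each **ancestor** (cluster) draws an ancestral profile over the remaining
  bands, Bernoulli(`ancestralPresenceProb` = 0.5) independently per ancestor;
* each declared **sub-group** perturbs its ancestor's profile at
  `subgroupFlips` (default 12) random polymorphic positions — a second-level
  profile shift that mirrors nested dendrogram subgroups without asserting
  any evolutionary model;
* each **strain** copies its (sub-)group profile with independent per-band
  flips at `flipProbability`.

A symmetric flip model, not a coalescent, is used on purpose: the analyses
under test make no evolutionary-model claims, and band flips are the minimal
mechanism that makes cluster recovery, polymorphism levels and PIC all
tunable. Output is bit-identical for identical config + seed, and the
caller's RNG state is untouched.

`referencePanelConfig()` emulates the reference panel's architecture: 20
strains; two ancestors weighted 18/20 and 2/20 (the published dendrogram
splits 18 strains against a 2-strain cluster); the larger ancestor nested
2/14/2 into three sub-groups; 28 primer combinations with the published
per-primer band counts (288 bands); flip probability 0.05. The designated
monomorphic fraction is **0.15**, not the ~0.30 one might read off the
published 70% polymorphism directly, and the distinction matters: a
designated-polymorphic band is *observed* polymorphic only with probability
$\approx 0.5 + 0.5\,(1 - 0.95^{20}) \approx 0.82$ (the two ancestors agree on
it half the time, and then at least one of 20 strains must flip it). The
expected observed fractions under 0.15 are therefore $\approx 0.85 \times
0.82 \approx 70\%$ polymorphic and $\approx 30\%$ monomorphic — matching the
reference panel on the observable scale, which is the scale the package's
statistics measure. This calculation fixed the default before any simulation
was run.

What the generator does **not** emulate: gel artifacts, co-migrating
fragments scored as one band, band-intensity ambiguity, linkage between
bands of one primer combination, and real marker ascertainment ("only
well-separated bands selected"). Passing tests on synthetic panels therefore
demonstrate the correctness of the computations and the recoverability of
planted structure at realistic noise levels — not that any particular real
panel will separate at a given similarity threshold.

## Validation design and problem sizes

Every stage is checked against an independent oracle implemented in the test
suite by a different route: Jaccard against an explicit per-band enumeration
loop and against `vegan::vegdist`; UPGMA cophenetic distances against a naive
reference that re-averages leaf-set distances from the original matrix at
every step (200 random 6-leaf matrices, tolerance 1e-9) and against
`stats::hclust`; PCoA against closed forms ($n = 2$: coordinates $\pm d/2$,
eigenvalue $d^2/2$), distance reconstruction of random 3-D point clouds to
1e-9, and `stats::cmdscale`; Newick against `ape::read.tree`. Structure
recovery uses 100 seeded default panels and requires the 2-cluster cut to
reach an adjusted Rand index of at least 0.9 against planted truth in at
least 95 of them. These sizes (6–20 leaves, 288 bands, 100–200 replicates)
keep the whole suite under a minute while leaving each property's failure
modes plenty of room to surface.

## Known limitations

* Dataset-specific published results (particular strain memberships at
  similarity cuts 0.718/0.575/0.435, a 35.48% three-axis PCoA variance)
  depend on an unpublished band matrix and are not reproduction targets;
  the package reproduces the published panel-level statistics from the
  packaged per-primer table and validates the pipeline by property.
* Codominant PIC, heterozygosity-based diversity indices (Nei's H, Shannon),
  other association coefficients (Dice/Nei–Li, simple matching), bootstrap
  support, and eigenvalue corrections are out of scope.
* `cutAtSimilarity(tree, 0)` returns one cluster only when no merge sits
  exactly at distance 1 (strains with entirely disjoint band sets).
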