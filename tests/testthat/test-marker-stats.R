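mkPanel <- function(cols, primer = rep("P1", ncol(cols))) {
    # cols: strains x bands 0/1
    rownames(cols) <- sprintf("S%02d", seq_len(nrow(cols)))
    MarkerMatrix(cols, primerCombination = primer)
}

test_that("band frequency and polymorphism classification count presences", {
    v <- cbind(c(rep(1L, 10), rep(0L, 10)),  # p = 0.5
               rep(1L, 20),                  # p = 1
               c(rep(1L, 5), rep(0L, 15)),   # p = 0.25
               c(1L, rep(0L, 19)),           # p = 0.05
               rep(0L, 20))                  # p = 0
    m <- mkPanel(v)
    ids <- bandIds(m)
    expect_equal(bandFrequency(m, ids[1]), 0.5)
    expect_equal(bandFrequency(m, ids[2]), 1.0)
    expect_equal(bandFrequency(m, ids[3]), 0.25)
    expect_error(bandFrequency(m, "nope:b1"), "unknown band")
    expect_false(isPolymorphic(m, ids[2]))
    expect_true(isPolymorphic(m, ids[4]))
    expect_false(isPolymorphic(m, ids[5]))
})

test_that("two-state PIC follows 2p(1-p) with its 0.5 ceiling and symmetry", {
    expect_equal(bandPIC(0.5), 0.5)
    expect_equal(bandPIC(0), 0)
    expect_equal(bandPIC(1), 0)
    expect_equal(bandPIC(0.25), 0.375)  # 1 - 0.0625 - 0.5625
    expect_error(bandPIC(1.2), "\\[0, 1\\]")
    expect_error(bandPIC(-0.1), "\\[0, 1\\]")
    p <- seq(0, 1, by = 0.01)
    expect_true(all(bandPIC(p) >= 0 & bandPIC(p) <= 0.5))
    expect_equal(bandPIC(p), bandPIC(1 - p))  # dominant-marker symmetry
    expect_equal(which.max(bandPIC(p)), which(p == 0.5))
})

test_that("primer PIC averages over polymorphic bands only", {
    # two bands at p = 0.5 plus monomorphic padding -> mean PIC 0.5
    v <- cbind(c(rep(1L, 3), rep(0L, 3)), c(rep(0L, 3), rep(1L, 3)),
               rep(1L, 6), rep(1L, 6))
    expect_equal(primerPIC(mkPanel(v), "P1"), 0.5)
    # p = 0.5 and p = 0.25 (n = 8) -> mean of 0.5 and 0.375
    v2 <- cbind(c(rep(1L, 4), rep(0L, 4)), c(rep(1L, 2), rep(0L, 6)))
    expect_equal(primerPIC(mkPanel(v2), "P1"), 0.4375)
    # all monomorphic -> 0 with a warning
    v3 <- cbind(rep(1L, 4), rep(0L, 4))
    expect_warning(pic <- primerPIC(mkPanel(v3), "P1"), "no polymorphic")
    expect_equal(pic, 0)
    expect_error(primerPIC(mkPanel(v3), "P9"), "unknown primer")
})

test_that("marker index supports the table and formula conventions", {
    expect_equal(markerIndex(0.32, 6), 1.92)
    expect_equal(markerIndex(0.50, 4, 75.00), 2.00)
    expect_equal(markerIndex(0.50, 12, 75.00, mode = "formula"), 4.50)
    expect_error(markerIndex(-0.1, 6), "non-negative")
    expect_error(markerIndex(0.5, 6, mode = "formula"), "pctPoly")
})

test_that("per-primer stats assemble counts, PIC, MI and size range", {
    # 7 bands, 6 polymorphic: pct = 600/7
    v <- cbind(rep(1L, 20),
               sapply(1:6, function(k) c(rep(1L, 2 * k), rep(0L, 20 - 2 * k))))
    m <- MarkerMatrix(
        matrix(v, 20, dimnames = list(sprintf("S%02d", 1:20), NULL)),
        primerCombination = rep("P1", 7),
        sizeBp = c(100L, 300L, NA, 500L, 1200L, NA, 900L))
    st <- primerStats(m, "P1")
    expect_equal(st$total_bands, 7L)
    expect_equal(st$polymorphic_bands, 6L)
    expect_equal(round(st$pct_polymorphism, 2), 85.71)
    expect_equal(st$size_min, 100L)
    expect_equal(st$size_max, 1200L)
    expect_equal(st$mi, st$pic * 7)
    # single monomorphic band
    v3 <- cbind(rep(1L, 4))
    expect_warning(st3 <- primerStats(mkPanel(v3), "P1"))
    expect_equal(unlist(st3[c("polymorphic_bands", "pct_polymorphism",
                              "pic", "mi")], use.names = FALSE),
                 c(0, 0, 0, 0))
})

test_that("percent polymorphism is invariant to strain and band reordering", {
    set.seed(11)
    m <- randomBandMatrix(nStrains = 8, nBands = 24, nPrimers = 2)
    base <- summarizePanel(m)$rows
    ps <- sample(nStrains(m)); pb <- sample(nBands(m))
    v <- bandMatrix(m)[ps, pb]
    m2 <- MarkerMatrix(v,
                       primerCombination = bandInfo(m)$primerCombination[pb],
                       bandLabel = bandInfo(m)$bandLabel[pb],
                       sizeBp = bandInfo(m)$sizeBp[pb])
    perm <- summarizePanel(m2)$rows
    perm <- perm[match(base$primer_combination, perm$primer_combination), ]
    expect_equal(perm$pct_polymorphism, base$pct_polymorphism)
    expect_equal(perm$pic, base$pic)
})

test_that("adding a monomorphic band raises the band count and nothing else", {
    set.seed(5)
    m <- randomBandMatrix(nStrains = 10, nBands = 12, nPrimers = 1)
    before <- primerStats(m, "P01")
    v <- cbind(bandMatrix(m), extra = rep(1L, 10))
    m2 <- MarkerMatrix(v, primerCombination = rep("P01", 13),
                       bandLabel = c(bandInfo(m)$bandLabel, "extra"))
    after <- primerStats(m2, "P01")
    expect_equal(after$total_bands, before$total_bands + 1L)
    expect_equal(after$polymorphic_bands, before$polymorphic_bands)
    expect_equal(after$pic, before$pic)
})

test_that("panel summary over a single primer equals that primer's row", {
    set.seed(9)
    m <- randomBandMatrix(nStrains = 8, nBands = 10, nPrimers = 1)
    s <- summarizePanel(m)
    expect_equal(nrow(s$rows), 1L)
    expect_equal(s$means[["pic"]], s$rows$pic)
    expect_equal(s$means[["pct_polymorphism"]], s$rows$pct_polymorphism)
    expect_equal(unname(s$totals["total_bands"]), s$rows$total_bands)
})

test_that("panel summary CSV has the seven columns plus footer rows", {
    f <- withr::local_tempfile(fileext = ".csv")
    s <- statsToFile(loadTable1Fixture(), f)
    out <- read.csv(f, stringsAsFactors = FALSE)
    expect_equal(ncol(out), 7L)
    expect_equal(nrow(out), 28L + 4L)
    expect_equal(tail(out$primer_combination, 4),
                 c("Total", "Mean", "Minimum", "Maximum"))
    expect_equal(out$pct_polymorphism[out$primer_combination == "Mean"],
                 69.73)
})
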