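test_that("peak weight is a half-life decay in TSS distance", {
    expect_equal(peakWeight(0, 1000), 1)
    expect_equal(peakWeight(1000, 1000), 0.5)
    expect_equal(peakWeight(2000, 1000), 0.25)
    expect_equal(peakWeight(500, 500), 0.5)
    expect_error(peakWeight(-1, 1000), "negative")
    d <- sort(runif(50, 0, 1e5))
    expect_true(all(diff(peakWeight(d, 3000)) < 0))  # strictly decreasing
})

test_that("raw RP sums windowed peak weights with a closed boundary", {
    ann <- toyAnnotation("gA", "chr1", 100000)
    # no peaks within 15 d0
    far <- toyPeaks("chr1", 100000 + 16000)
    expect_equal(unname(rawRP(ann, far, d0 = 1000)), 0)
    # peaks at distances 0 and d0: weights 1 + 0.5
    two <- toyPeaks("chr1", c(100000, 101000))
    expect_equal(unname(rawRP(ann, two, d0 = 1000)), 1.5)
    # a peak exactly at 15 d0 is included with weight 2^-15
    edge <- toyPeaks("chr1", 100000 + 15000)
    expect_equal(unname(rawRP(ann, edge, d0 = 1000)), 2^-15)
    # other chromosomes never contribute
    other <- toyPeaks("chr2", 100000)
    expect_equal(unname(rawRP(ann, other, d0 = 1000)), 0)
})

test_that("multi-TSS genes take the maximum over their TSS scores", {
    ann <- toyAnnotation(c("gA", "gA"), "chr1", c(10000, 50000))
    pk <- toyPeaks("chr1", c(10000, 50000, 50500))
    # TSS1 scores 1; TSS2 scores 1 + 2^(-0.5)
    expect_equal(unname(rawRP(ann, pk, d0 = 1000)), 1 + 2^-0.5)
})

test_that("interval-indexed RP equals the brute-force oracle", {
    for (seed in 1:5) {
        set.seed(seed)
        n_genes <- 30; n_peaks <- 120
        ann <- toyAnnotation(sprintf("g%02d", seq_len(n_genes)),
                             sample(c("c1", "c2"), n_genes, TRUE),
                             sample.int(2e6, n_genes))
        pk <- toyPeaks(sample(c("c1", "c2", "c3"), n_peaks, TRUE),
                       sample.int(2e6, n_peaks))
        a <- rawRP(ann, pk, d0 = 5000)
        b <- rawRPBruteForce(ann, pk, d0 = 5000)
        expect_equal(a, b, tolerance = 1e-12)
    }
})

test_that("RP is translation invariant and monotone under peak approach", {
    set.seed(9)
    ann <- toyAnnotation(sprintf("g%02d", 1:10), "c1",
                         sort(sample.int(1e6, 10)) + 5e5)
    pk <- toyPeaks("c1", sample.int(2e6, 60))
    base <- rawRP(ann, pk, d0 = 2000)
    shift <- 12345
    annS <- toyAnnotation(mcols(ann)$gene_id, "c1",
                          mcols(ann)$tss + shift)
    pkS <- toyPeaks("c1", mcols(pk)$center + shift)
    expect_equal(rawRP(annS, pkS, d0 = 2000), base)
    # move one in-window peak strictly closer to gene 1's TSS
    tss1 <- mcols(ann)$tss[1]
    d <- abs(mcols(pk)$center - tss1)
    j <- which(d <= 15 * 2000 & d > 0)[1]
    stopifnot(!is.na(j))
    pk2 <- pk
    mcols(pk2)$center[j] <- tss1 + (mcols(pk)$center[j] - tss1) %/% 2
    expect_gte(rawRP(ann, pk2, d0 = 2000)[[1]], base[[1]])
})

test_that("min-max scaling handles range, degenerate and affine cases", {
    expect_equal(scaleRP(c(0, 1, 3)), c(0, 1/3, 1))
    expect_equal(scaleRP(c(2, 2, 2)), c(0, 0, 0))
    expect_equal(scaleRP(5), 0)
    set.seed(4)
    x <- rexp(40)
    s <- scaleRP(x)
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(scaleRP(3.7 * x + 11), s)  # affine invariance
})

test_that("baseline adjustment subtracts with a zero default", {
    scaled <- c(gA = 0.8, gB = 0.2, gC = 0.5)
    expect_equal(adjustRP(scaled, NULL), scaled)
    base <- c(gA = 0.3, gB = 0.6)
    expect_message(adj <- adjustRP(scaled, base), "absent from baseline")
    expect_equal(adj, c(gA = 0.5, gB = -0.4, gC = 0.5))
})

test_that("baseline is the median of per-dataset scaled RP", {
    # five genes on chr1; gX alone on chr2 so one dataset can miss it
    ann <- toyAnnotation(c("gMax", "gZero", "gX"),
                         c("chr1", "chr1", "chr2"),
                         c(100000, 400000, 100000))
    at <- function(gene, k) {  # k peaks on the TSS => raw RP k
        tss <- mcols(ann)$tss[match(gene, mcols(ann)$gene_id)]
        chrom <- as.character(seqnames(ann))[match(gene,
                                                   mcols(ann)$gene_id)]
        toyPeaks(rep(chrom, k), rep(tss, k))
    }
    # ds1: no chr2 peaks at all -> gX raw 0 -> scaled 0
    ds1 <- at("gMax", 5)
    # ds2: gX raw 2 of max 5 -> scaled 0.4; ds3: 3 of 5 -> 0.6
    ds2 <- suppressWarnings(c(at("gMax", 5), at("gX", 2)))
    ds3 <- suppressWarnings(c(at("gMax", 5), at("gX", 3)))
    one <- computeBaseline(list(ds2), ann, d0 = 1000)
    expect_equal(one[["gX"]], 0.4)  # median of one dataset
    three <- computeBaseline(list(ds1, ds2, ds3), ann, d0 = 1000)
    expect_equal(three[["gX"]], 0.4)  # median(0, 0.4, 0.6)
    expect_equal(three[["gMax"]], 1)
    expect_equal(three[["gZero"]], 0)
    expect_error(computeBaseline(list(), ann), "empty")
})

test_that("adjusted-RP ranking uses mid-ranks and deterministic order", {
    expect_equal(rankByAdjustedRP(c(gA = 0.9, gB = 0.1))$rank, c(1, 2))
    r <- rankByAdjustedRP(c(gB = 0.5, gA = 0.5, gC = 0.1))
    expect_equal(r$gene_id, c("gA", "gB", "gC"))  # ties by gene id
    expect_equal(r$rank, c(1.5, 1.5, 3))
    allTied <- rankByAdjustedRP(c(gA = 1, gB = 1, gC = 1, gD = 1))
    expect_equal(allTied$rank, rep(2.5, 4))
})

test_that("regPotential assembles a valid object and writes ranks", {
    spec <- fixtureSpec(n_genes = 100, n_background_peaks = 300, seed = 2)
    ann <- fixtureAnnotation(spec)
    pk <- fixturePeaks(spec, ann)
    rp <- regPotential(ann, pk, d0 = 1000)
    expect_s4_class(rp, "RegulatoryPotential")
    tab <- rpTable(rp)
    expect_equal(nrow(tab), 100L)
    expect_equal(sort(tab$rank_rp), sort(rank(-tab$rp_adjusted)))
    expect_true(validObject(rp))
    # baseline round-trip through the two-column table format
    d <- withr::local_tempdir()
    base <- fixtureBaseline(fixtureSpec(n_genes = 50, seed = 5,
                                        n_background_peaks = 200),
                            fixtureAnnotation(fixtureSpec(n_genes = 50,
                                                          seed = 5)))
    writeBaseline(base, file.path(d, "b.tsv"))
    expect_equal(readBaseline(file.path(d, "b.tsv")), base,
                 tolerance = 1e-5)
})
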