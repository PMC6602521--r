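test_that("toy annotation spaces genes evenly with alternating strand", {
    spec <- fixtureSpec(n_genes = 4, n_chromosomes = 1,
                        spacing = 100000, seed = 1)
    ann <- fixtureAnnotation(spec)
    expect_equal(mcols(ann)$tss, c(1e5, 2e5, 3e5, 4e5))
    expect_equal(as.character(strand(ann)), c("+", "-", "+", "-"))
    spec2 <- fixtureSpec(n_genes = 4, n_chromosomes = 2, seed = 1)
    expect_equal(as.character(seqnames(fixtureAnnotation(spec2))),
                 c("chr1", "chr1", "chr2", "chr2"))
})

test_that("identical spec and seed give byte-identical fixture files", {
    spec <- fixtureSpec(n_genes = 120, n_background_peaks = 300,
                        planted_term_size = 15, n_null_terms = 8,
                        n_baseline_sets = 2, seed = 77)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    p1 <- writeFixture(spec, d1)
    p2 <- writeFixture(spec, d2)
    expect_equal(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
    # a different seed changes the data
    p3 <- writeFixture(fixtureSpec(n_genes = 120,
                                   n_background_peaks = 300,
                                   planted_term_size = 15,
                                   n_null_terms = 8,
                                   n_baseline_sets = 2, seed = 78),
                       withr::local_tempdir())
    expect_false(all(tools::md5sum(unname(p1["peaks"])) ==
                         tools::md5sum(unname(p3["peaks"]))))
})

test_that("signal-rich fixtures are classified promoter-dominant", {
    # every gene is a bound target with near-TSS peaks and background is
    # sparse, so most peaks sit on promoters
    spec <- fixtureSpec(n_genes = 200, planted_term_size = 200,
                        peaks_per_target_lambda = 5, signal_scale = 200,
                        n_background_peaks = 200, seed = 11)
    ann <- fixtureAnnotation(spec)
    cls <- classifyTF(fixturePeaks(spec, ann), ann)
    expect_equal(tfLabel(cls), "promoter-dominant")
    expect_equal(chosenD0(cls), 1000)
})

test_that("background-only fixtures match the analytic promoter fraction", {
    spec <- fixtureSpec(n_genes = 500, n_chromosomes = 1, frac_bound = 0,
                        n_background_peaks = 20000, seed = 13)
    ann <- fixtureAnnotation(spec)
    pk <- fixturePeaks(spec, ann)
    frac <- fractionNearTss(pk, ann)
    len <- (ceiling(500 / 1) + 1) * spec$spacing - spec$peak_width
    expected <- 500 * 2001 / len
    se <- sqrt(expected * (1 - expected) / 20000)
    expect_lt(abs(frac - expected), 3 * se)
})

test_that("an all-null spec generates no peaks and an unreadable BED", {
    spec <- fixtureSpec(n_genes = 10, frac_bound = 0,
                        n_background_peaks = 0, seed = 1)
    ann <- fixtureAnnotation(spec)
    expect_error(fixturePeaks(spec, ann), "no peaks")
    f <- withr::local_tempfile(lines = character())
    expect_error(readPeaks(f), "no peak records")
})

test_that("null DGE p-values are uniform and planted targets lead the DE rank", {
    spec <- fixtureSpec(n_genes = 5000, dge_signal = FALSE, seed = 11)
    ann <- fixtureAnnotation(spec)
    dge <- fixtureDge(spec, ann)
    expect_gt(stats::ks.test(dge$pvalue, "punif")$p.value, 0.01)

    spec2 <- fixtureSpec(n_genes = 1000, planted_term_size = 30,
                         de_direction = "up", seed = 11)
    ann2 <- fixtureAnnotation(spec2)
    dge2 <- fixtureDge(spec2, ann2)
    tg <- fixtureTargets(spec2)
    ranked <- rankByDE(dge2)
    # all planted targets sit at the very top of the DE ranking (a few
    # uniform nulls may interleave below 1e-4)
    expect_true(all(match(tg$de, ranked$gene_id) <= 40))
    expect_true(all(dge2$log2fc[dge2$gene_id %in% tg$de] > 0))
    spec3 <- fixtureSpec(n_genes = 200, planted_term_size = 20,
                         de_direction = "down", seed = 11)
    dge3 <- fixtureDge(spec3, fixtureAnnotation(spec3))
    tg3 <- fixtureTargets(spec3)
    expect_true(all(dge3$log2fc[dge3$gene_id %in% tg3$de] < 0))
})

test_that("generated gene sets exercise both size filters and dedup", {
    spec <- fixtureSpec(n_genes = 3000, planted_term_size = 40,
                        n_null_terms = 200, seed = 17)
    ann <- fixtureAnnotation(spec)
    sets <- fixtureGmt(spec, ann)
    expect_equal(length(sets), 201L)
    expect_equal(sets$planted_1, fixtureTargets(spec)$targets)
    sizes <- lengths(sets)
    expect_gt(sum(sizes < 10), 0)    # some terms below the lower bound
    expect_gt(sum(sizes > 2000), 0)  # and above the upper bound
    kept <- filterTermSets(sets, sprintf("g%05d", 1:3000))
    expect_true(all(lengths(kept) >= 10 & lengths(kept) <= 2000))
    # a duplicated planted term under a second id collapses to one
    dup <- c(sets["planted_1"],
             list(planted_copy = sets$planted_1))
    expect_named(suppressMessages(dedupByJaccard(dup)), "planted_1")
})

test_that("partially overlapping binding and DE programs are seeded subsets", {
    spec <- fixtureSpec(n_genes = 500, planted_term_size = 40,
                        frac_bound = 0.5, frac_de = 0.5, seed = 19)
    tg <- fixtureTargets(spec)
    expect_length(tg$bound, 20L)
    expect_length(tg$de, 20L)
    expect_true(all(tg$bound %in% tg$targets))
    expect_true(all(tg$de %in% tg$targets))
    expect_identical(tg, fixtureTargets(spec))  # deterministic
})
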