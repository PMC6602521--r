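# Small in-code builders and independent oracles shared across tests.

library(GenomicRanges)

toyAnnotation <- function(gene_id, chrom, tss, strand = "+") {
    gr <- GRanges(chrom, IRanges(start = tss + 1, width = 1),
                  strand = rep_len(strand, length(gene_id)))
    mcols(gr)$gene_id <- gene_id
    mcols(gr)$tss <- as.numeric(tss)
    gr
}

toyPeaks <- function(chrom, center, score = NA_real_, width = 200) {
    half <- width / 2
    gr <- GRanges(rep_len(chrom, length(center)),
                  IRanges(start = center - half + 1,
                          end = center + half))
    mcols(gr)$center <- as.numeric(center)
    mcols(gr)$score <- rep_len(as.numeric(score), length(center))
    gr
}

# minimum hypergeometric tail of one arrangement, by direct phyper calls
minHgtOracle <- function(indicator) {
    N <- length(indicator); B <- sum(indicator)
    b <- cumsum(indicator)
    min(vapply(seq_len(N), function(n)
        stats::phyper(b[n] - 1, B, N - B, n, lower.tail = FALSE), 0))
}

# exact mHG p-value by exhaustive enumeration of all C(N, B) arrangements
enumMhgStats <- function(N, B) {
    if (B == 0 || B == N)
        return(1.0)
    pos <- utils::combn(N, B)
    apply(pos, 2L, function(p) {
        v <- integer(N); v[p] <- 1L
        minHgtOracle(v)
    })
}

# in-memory solo enrichment over a fixture spec
soloEnrichment <- function(spec, d0 = NULL) {
    ann <- fixtureAnnotation(spec)
    pk <- fixturePeaks(spec, ann)
    cls <- classifyTF(pk, ann, d0Override = d0)
    rp <- regPotential(ann, pk, d0 = chosenD0(cls))
    tab <- rpTable(rp)
    ranking <- rankByAdjustedRP(stats::setNames(tab$rp_adjusted,
                                                tab$gene_id))
    sets <- suppressMessages(dedupByJaccard(
        filterTermSets(fixtureGmt(spec, ann), ranking$gene_id)))
    suppressMessages(runEnrichment(ranking, sets))
}

# in-memory ensemble enrichment (returns both solo and ensemble tables)
ensembleEnrichment <- function(spec, direction = "all") {
    ann <- fixtureAnnotation(spec)
    pk <- fixturePeaks(spec, ann)
    cls <- classifyTF(pk, ann)
    rp <- regPotential(ann, pk, d0 = chosenD0(cls))
    tab <- rpTable(rp)
    adj <- stats::setNames(tab$rp_adjusted, tab$gene_id)
    rpRanking <- rankByAdjustedRP(adj)
    dge <- fixtureDge(spec, ann)
    ens <- suppressMessages(rankProduct(rpRanking,
                                        rankByDE(dge, direction)))
    sets <- suppressMessages(dedupByJaccard(
        filterTermSets(fixtureGmt(spec, ann), rpRanking$gene_id)))
    list(solo = suppressMessages(runEnrichment(rpRanking, sets)),
         ensemble = suppressMessages(
             runEnrichment(rankingFromEnsemble(ens), sets)),
         adjusted = adj, dge = dge)
}

termP <- function(res, id) {
    tab <- enrichmentTable(res)
    tab$pvalue[tab$set_id == id]
}
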