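#' Exponential peak weight
#'
#' Weight of a peak at `distance` bp from a TSS: `2^(-distance / d0)`.
#' The decay distance `d0` is a half-life: a peak exactly at `d0` carries
#' weight 0.5, a peak on the TSS weight 1.
#'
#' @param distance Non-negative distance(s) in bp.
#' @param d0 Decay distance in bp (> 0); default 1000 (promoter-dominant
#'   setting). Enhancer-dominant cistromes use 10000 by default.
#' @return Numeric weight(s) in (0, 1].
#' @examples
#' peakWeight(c(0, 1000, 2000), d0 = 1000)  # 1, 0.5, 0.25
#' @export
peakWeight <- function(distance, d0 = 1000) {
    stopifnot(length(d0) == 1L, d0 > 0)
    if (any(distance < 0))
        stop("peakWeight: negative distance")
    2^(-distance / d0)
}

#' Raw regulatory potential per gene
#'
#' For each gene, the sum of [peakWeight()] over all peaks whose center
#' lies within `windowMultiple * d0` bp of the gene's TSS (closed
#' interval, same chromosome). Genes annotated with several TSSs score
#' each TSS separately and take the maximum; genes with no peak in the
#' window (including genes on chromosomes absent from the peak file)
#' get 0.
#'
#' @param annotation TSS `GRanges` from [readTss()].
#' @param peaks Peak `GRanges` from [readPeaks()].
#' @param d0 Decay distance in bp.
#' @param windowMultiple Window half-width as a multiple of `d0`
#'   (default 15).
#' @return Named numeric vector of raw RP scores, one per distinct
#'   `gene_id`, in first-appearance order.
#' @export
rawRP <- function(annotation, peaks, d0 = 1000, windowMultiple = 15) {
    stopifnot(d0 > 0, windowMultiple > 0)
    w <- windowMultiple * d0
    tss <- mcols(annotation)$tss
    gene <- mcols(annotation)$gene_id
    genes <- unique(gene)
    centers <- GRanges(GenomicRanges::seqnames(peaks),
                       IRanges(start = mcols(peaks)$center + 1, width = 1))
    # closed window |center - tss| <= w in 0-based coordinates
    windows <- GRanges(GenomicRanges::seqnames(annotation),
                       IRanges(start = pmax(0, tss - w) + 1,
                               end = tss + w + 1))
    # genes on chromosomes absent from the peak file legitimately score
    # 0; silence the disjoint-seqlevels notice that case triggers
    hits <- suppressWarnings(
        GenomicRanges::findOverlaps(windows, centers,
                                    ignore.strand = TRUE))
    rp_tss <- numeric(length(annotation))
    if (length(hits)) {
        d <- abs(mcols(peaks)$center[subjectHits(hits)] -
                 tss[queryHits(hits)])
        keep <- d <= w  # guard the start-clamped edge near coordinate 0
        contrib <- peakWeight(d[keep], d0)
        agg <- rowsum(contrib, group = queryHits(hits)[keep])
        rp_tss[as.integer(rownames(agg))] <- agg[, 1L]
    }
    out <- vapply(split(rp_tss, factor(gene, levels = genes)), max, 0)
    names(out) <- genes
    out
}

#' Brute-force raw RP (reference implementation)
#'
#' All-pairs double loop over genes and peaks, used as an independent
#' oracle for [rawRP()] at small scale. Identical contract.
#'
#' @inheritParams rawRP
#' @return Named numeric vector of raw RP scores.
#' @export
rawRPBruteForce <- function(annotation, peaks, d0 = 1000,
                            windowMultiple = 15) {
    w <- windowMultiple * d0
    pchrom <- as.character(GenomicRanges::seqnames(peaks))
    pcenter <- mcols(peaks)$center
    gene <- mcols(annotation)$gene_id
    genes <- unique(gene)
    rp_tss <- numeric(length(annotation))
    for (i in seq_along(annotation)) {
        chrom_i <- as.character(GenomicRanges::seqnames(annotation)[i])
        tss_i <- mcols(annotation)$tss[i]
        acc <- 0
        for (j in seq_along(peaks)) {
            if (pchrom[j] != chrom_i) next
            d <- abs(pcenter[j] - tss_i)
            if (d <= w) acc <- acc + 2^(-d / d0)
        }
        rp_tss[i] <- acc
    }
    out <- vapply(split(rp_tss, factor(gene, levels = genes)), max, 0)
    names(out) <- genes
    out
}

#' Min-max scale RP scores to [0, 1]
#'
#' `(x - min) / (max - min)`; when all scores are equal (including a
#' single gene) every scaled value is 0.
#'
#' @param raw Numeric vector of raw RP scores.
#' @return Scaled scores in `[0, 1]`, names preserved.
#' @export
scaleRP <- function(raw) {
    stopifnot(length(raw) >= 1L)
    rng <- range(raw)
    if (rng[1] == rng[2]) return(raw * 0)
    (raw - rng[1]) / (rng[2] - rng[1])
}

#' Baseline-adjust scaled RP scores
#'
#' `adjusted(g) = scaled(g) - baseline(g)`. Genes missing from the
#' baseline table get baseline 0 (count reported); a `NULL` baseline
#' means no adjustment.
#'
#' @param scaled Named numeric vector of scaled RP scores.
#' @param baseline Named numeric vector mapping gene ids to baseline RP
#'   in `[0, 1]`, or `NULL`.
#' @return Named numeric vector of adjusted scores in `[-1, 1]`.
#' @export
adjustRP <- function(scaled, baseline = NULL) {
    if (is.null(baseline)) return(scaled)
    stopifnot(all(baseline >= 0 & baseline <= 1))
    b <- baseline[names(scaled)]
    n_missing <- sum(is.na(b))
    if (n_missing)
        message("adjustRP: ", n_missing,
                " gene(s) absent from baseline table, using baseline 0")
    b[is.na(b)] <- 0
    scaled - b
}

#' Baseline RP over a collection of cistromes
#'
#' For each peak set, raw RP scores are computed and min-max scaled over
#' all annotated genes; the baseline of a gene is the median of its
#' scaled scores across the datasets (a gene absent from a dataset's
#' chromosomes simply scores 0 there, so no special-casing is needed
#' beyond the shared annotation universe).
#'
#' @param peakSets List of peak `GRanges`.
#' @param annotation TSS `GRanges`.
#' @inheritParams rawRP
#' @return Named numeric vector: gene id to baseline RP in `[0, 1]`.
#' @export
computeBaseline <- function(peakSets, annotation, d0 = 1000,
                            windowMultiple = 15) {
    if (!length(peakSets))
        stop("computeBaseline: empty dataset list")
    scaled <- vapply(peakSets, function(p)
        scaleRP(rawRP(annotation, p, d0, windowMultiple)),
        numeric(length(unique(mcols(annotation)$gene_id))))
    if (is.null(dim(scaled)))
        scaled <- matrix(scaled, nrow = 1,
                         dimnames = list(unique(mcols(annotation)$gene_id)))
    apply(scaled, 1L, stats::median)
}

#' Read / write two-column baseline tables
#'
#' Format: TSV with header `gene_id`, `baseline`; values must lie in
#' `[0, 1]`.
#'
#' @param path File path.
#' @return `readBaseline`: named numeric vector.
#' @export
readBaseline <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t")
    stopifnot(all(c("gene_id", "baseline") %in% colnames(tab)))
    b <- as.numeric(tab$baseline)
    if (any(is.na(b) | b < 0 | b > 1))
        stop("baseline '", path, "': values must lie in [0, 1]")
    stats::setNames(b, as.character(tab$gene_id))
}

#' @rdname readBaseline
#' @param baseline Named numeric vector as returned by
#'   [computeBaseline()].
#' @export
writeBaseline <- function(baseline, path) {
    writeTsv(data.frame(gene_id = names(baseline),
                        baseline = unname(baseline)), path)
}

#' Rank genes by decreasing adjusted RP
#'
#' Ties receive the average (mid) rank, the convention required for the
#' rank-product arithmetic downstream; list output additionally orders
#' tied genes lexicographically by gene id for determinism.
#'
#' @param adjusted Named numeric vector of adjusted RP scores.
#' @return A `data.frame` with columns `gene_id`, `score`, `rank`
#'   (mid-ranks, 1 = highest score), ordered by increasing rank then
#'   gene id.
#' @export
rankByAdjustedRP <- function(adjusted) {
    r <- rank(-adjusted, ties.method = "average")
    out <- data.frame(gene_id = names(adjusted), score = unname(adjusted),
                      rank = unname(r), stringsAsFactors = FALSE)
    out[order(out$rank, out$gene_id), , drop = FALSE]
}

#' Full regulatory-potential pipeline for one cistrome
#'
#' Runs [rawRP()], [scaleRP()], [adjustRP()] and [rankByAdjustedRP()]
#' over all annotated genes and assembles a
#' [RegulatoryPotential-class] object.
#'
#' @inheritParams rawRP
#' @param baseline Optional named baseline vector (see
#'   [computeBaseline()]).
#' @return A [RegulatoryPotential-class] object.
#' @examples
#' ann <- fixtureAnnotation(fixtureSpec(n_genes = 20, seed = 1))
#' pk <- fixturePeaks(fixtureSpec(n_genes = 20, seed = 1), ann)
#' rp <- regPotential(ann, pk, d0 = 1000)
#' head(rpTable(rp))
#' @export
regPotential <- function(annotation, peaks, d0 = 1000, windowMultiple = 15,
                         baseline = NULL) {
    raw <- rawRP(annotation, peaks, d0, windowMultiple)
    scaled <- scaleRP(raw)
    adjusted <- adjustRP(scaled, baseline)
    b <- scaled - adjusted
    tab <- DataFrame(gene_id = names(raw), rp_raw = unname(raw),
                     rp_scaled = unname(scaled), baseline = unname(b),
                     rp_adjusted = unname(adjusted),
                     rank_rp = unname(rank(-adjusted,
                                           ties.method = "average")))
    new("RegulatoryPotential", table = tab, d0 = d0,
        windowMultiple = windowMultiple)
}
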