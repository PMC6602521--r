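#' Specification for a synthetic test dataset
#'
#' Describes a toy genome, a planted regulatory program, and noise
#' models, from which all five pipeline inputs (TSS annotation, peak
#' BED, DGE table, GMT gene sets, baseline table) can be generated
#' deterministically. All randomness flows from the single `seed`;
#' identical specs yield byte-identical files.
#'
#' The defaults emulate a mid-sized enhancer-binding TF experiment at
#' desk scale: 5000 genes on 5 toy chromosomes spaced 100 kb apart, one
#' planted 50-gene target program, 50 null gene sets whose sizes span
#' the term-size filters, ~3 promoter-proximal peaks per true target
#' (Poisson) at exponentially distributed distances (scale 200 bp), a
#' uniform background of 10000 peaks, and a DGE table in which planted
#' targets are strongly perturbed (`-log10 p = 4 + Exp(1)`) against a
#' uniform null.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of toy chromosomes (genes split evenly).
#' @param spacing Distance in bp between consecutive TSSs.
#' @param planted_term_size Genes in the planted target program
#'   (capped at `n_genes`).
#' @param n_null_terms Number of random null gene sets.
#' @param null_size_range Null-term sizes are drawn log-uniformly in
#'   this range; the default `[5, 2500]` straddles both size filters.
#' @param peaks_per_target_lambda Poisson mean of signal peaks per
#'   bound target.
#' @param signal_scale Exponential scale (bp) of signal peak-to-TSS
#'   distances.
#' @param n_background_peaks Peaks placed uniformly over the genome.
#' @param peak_width Width in bp of every generated peak (even).
#' @param frac_bound,frac_de Fraction of planted targets that receive
#'   binding / expression signal (1 = signals coincide; lower values
#'   make them partially overlap).
#' @param de_shift Minimum `-log10 p` of a perturbed target.
#' @param de_direction Sign of planted log2 fold changes: `"up"`,
#'   `"down"`, or `"both"` (random sign).
#' @param dge_signal If `FALSE` the DGE table is pure null (uniform
#'   p-values, standard-normal log2fc) — a signal-free fixture.
#' @param include_padj Whether the DGE table carries a BH-adjusted
#'   column.
#' @param n_baseline_sets Background-only cistromes used by
#'   [fixtureBaseline()].
#' @param seed Integer seed; the only source of randomness.
#' @return A list of class `fixtureSpec`.
#' @export
fixtureSpec <- function(n_genes = 5000, n_chromosomes = 5,
                        spacing = 100000,
                        planted_term_size = min(50, n_genes),
                        n_null_terms = 50, null_size_range = c(5, 2500),
                        peaks_per_target_lambda = 3, signal_scale = 200,
                        n_background_peaks = 10000, peak_width = 200,
                        frac_bound = 1, frac_de = 1, de_shift = 4,
                        de_direction = c("up", "down", "both"),
                        dge_signal = TRUE, include_padj = TRUE,
                        n_baseline_sets = 3, seed = 1) {
    de_direction <- match.arg(de_direction)
    stopifnot(n_genes >= 1, n_chromosomes >= 1, spacing > 0,
              planted_term_size <= n_genes, peak_width %% 2 == 0,
              frac_bound >= 0, frac_bound <= 1, frac_de >= 0, frac_de <= 1)
    structure(as.list(environment()), class = "fixtureSpec")
}

# distinct deterministic streams per generated artifact
.fixSeed <- function(spec, offset) set.seed(spec$seed * 101L + offset)

#' Generate the toy genome annotation
#'
#' Genes are evenly spaced along each chromosome (TSS at `spacing`,
#' `2 * spacing`, ...) with alternating strand; deterministic given the
#' spec.
#'
#' @param spec A [fixtureSpec()].
#' @return A TSS `GRanges` as produced by [readTss()].
#' @export
fixtureAnnotation <- function(spec) {
    per <- ceiling(spec$n_genes / spec$n_chromosomes)
    idx <- seq_len(spec$n_genes) - 1L
    chrom <- paste0("chr", idx %/% per + 1L)
    tss <- (idx %% per + 1L) * spec$spacing
    gr <- GRanges(chrom, IRanges(start = tss + 1, width = 1),
                  strand = rep_len(c("+", "-"), spec$n_genes))
    mcols(gr)$gene_id <- sprintf("g%05d", seq_len(spec$n_genes))
    mcols(gr)$tss <- as.numeric(tss)
    gr
}

#' Planted target program of a fixture
#'
#' The gene ids of the planted term, and the (seeded) subsets that carry
#' binding and expression signal.
#'
#' @param spec A [fixtureSpec()].
#' @return List with `targets`, `bound`, `de`.
#' @export
fixtureTargets <- function(spec) {
    .fixSeed(spec, 1L)
    ids <- sprintf("g%05d", seq_len(spec$n_genes))
    targets <- sort(sample(ids, spec$planted_term_size))
    bound <- sort(sample(targets, round(spec$frac_bound *
                                        length(targets))))
    de <- sort(sample(targets, round(spec$frac_de * length(targets))))
    list(targets = targets, bound = bound, de = de)
}

.chromLengths <- function(spec) {
    per <- ceiling(spec$n_genes / spec$n_chromosomes)
    stats::setNames(rep((per + 1) * spec$spacing, spec$n_chromosomes),
                    paste0("chr", seq_len(spec$n_chromosomes)))
}

#' Generate a synthetic peak set
#'
#' Bound targets receive `Poisson(lambda)` peaks centered at
#' `TSS +/- Exp(signal_scale)`; background peaks are uniform over each
#' chromosome. Signal peaks draw higher -log10 p-value scores than
#' background so that significance-ranked subsets are signal-first.
#'
#' @param spec A [fixtureSpec()].
#' @param annotation Output of [fixtureAnnotation()].
#' @return A peak `GRanges` as produced by [readPeaks()].
#' @export
fixturePeaks <- function(spec, annotation) {
    tg <- fixtureTargets(spec)
    .fixSeed(spec, 2L)
    half <- spec$peak_width / 2
    lens <- .chromLengths(spec)
    idx <- match(tg$bound, mcols(annotation)$gene_id)
    nsig <- stats::rpois(length(idx), spec$peaks_per_target_lambda)
    sig_tss <- rep(mcols(annotation)$tss[idx], nsig)
    sig_chrom <- rep(as.character(GenomicRanges::seqnames(annotation))[idx],
                     nsig)
    off <- round(stats::rexp(length(sig_tss), 1 / spec$signal_scale)) *
        sample(c(-1, 1), length(sig_tss), replace = TRUE)
    sig_center <- pmax(half, sig_tss + off)
    sig_score <- 10 + stats::rexp(length(sig_center), 1 / 5)
    nbg <- spec$n_background_peaks
    bg_chrom <- sample(names(lens), nbg, replace = TRUE)
    bg_center <- round(stats::runif(nbg, half, lens[bg_chrom] - half))
    bg_score <- stats::runif(nbg, 0.5, 8)
    chrom <- c(sig_chrom, bg_chrom)
    center <- c(sig_center, bg_center)
    score <- c(sig_score, bg_score)
    if (!length(center))
        stop("fixturePeaks: spec generates no peaks")
    gr <- GRanges(chrom, IRanges(start = center - half + 1,
                                 end = center + half))
    mcols(gr)$center <- as.numeric(center)
    mcols(gr)$score <- score
    gr
}

#' Generate a synthetic differential-expression table
#'
#' Planted DE targets get `-log10 p = de_shift + Exp(1)` and
#' direction-consistent log2 fold changes (`N(2, 0.5)` magnitude); all
#' other genes (and all genes when `dge_signal = FALSE`) get uniform
#' p-values and `N(0, 1)` fold changes. `padj` is BH over all genes.
#'
#' @inheritParams fixturePeaks
#' @return A DGE `data.frame` as produced by [readDge()].
#' @export
fixtureDge <- function(spec, annotation) {
    tg <- fixtureTargets(spec)
    .fixSeed(spec, 3L)
    ids <- unique(mcols(annotation)$gene_id)
    n <- length(ids)
    pvalue <- stats::runif(n)
    log2fc <- stats::rnorm(n)
    if (spec$dge_signal) {
        hit <- ids %in% tg$de
        pvalue[hit] <- 10^-(spec$de_shift + stats::rexp(sum(hit)))
        sign <- switch(spec$de_direction, up = 1, down = -1,
                       both = sample(c(-1, 1), sum(hit), replace = TRUE))
        log2fc[hit] <- sign * abs(stats::rnorm(sum(hit), 2, 0.5))
    }
    out <- data.frame(gene_id = ids, log2fc = log2fc, pvalue = pvalue,
                      padj = if (spec$include_padj)
                          stats::p.adjust(pvalue, "BH") else NA_real_,
                      stringsAsFactors = FALSE)
    out
}

#' Generate synthetic gene sets
#'
#' The planted term contains exactly the planted target program; null
#' terms are uniform random gene draws with log-uniform sizes spanning
#' `null_size_range`, so some fall below the minimum and above the
#' maximum term-size filter.
#'
#' @inheritParams fixturePeaks
#' @return A named list of gene sets (see [readGmt()]).
#' @export
fixtureGmt <- function(spec, annotation) {
    tg <- fixtureTargets(spec)
    .fixSeed(spec, 4L)
    ids <- unique(mcols(annotation)$gene_id)
    lo <- log(spec$null_size_range[1]); hi <- log(spec$null_size_range[2])
    sizes <- pmin(length(ids),
                  round(exp(stats::runif(spec$n_null_terms, lo, hi))))
    sets <- c(list(planted_1 = tg$targets),
              stats::setNames(lapply(sizes, sample, x = ids),
                              sprintf("null_%02d",
                                      seq_len(spec$n_null_terms))))
    attr(sets, "descriptions") <-
        stats::setNames(c("planted target program",
                          sprintf("random null set %02d",
                                  seq_len(spec$n_null_terms))),
                        names(sets))
    sets
}

#' Baseline table from background-only cistromes
#'
#' Generates `n_baseline_sets` signal-free peak sets (background only)
#' and runs [computeBaseline()] over them.
#'
#' @inheritParams fixturePeaks
#' @param d0 Decay distance passed to [computeBaseline()].
#' @return Named numeric baseline vector.
#' @export
fixtureBaseline <- function(spec, annotation, d0 = 10000) {
    stopifnot(spec$n_baseline_sets >= 1)
    null_spec <- spec
    null_spec$frac_bound <- 0
    sets <- lapply(seq_len(spec$n_baseline_sets), function(k) {
        s <- null_spec
        s$seed <- spec$seed * 1000L + k
        fixturePeaks(s, annotation)
    })
    computeBaseline(sets, annotation, d0 = d0)
}

#' Write a complete fixture dataset to disk
#'
#' Emits `annotation.tsv`, `peaks.bed`, `dge.tsv`, `sets.gmt` and (when
#' `n_baseline_sets > 0`) `baseline.tsv` in exactly the formats the
#' readers of this package consume.
#'
#' @param spec A [fixtureSpec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeFixture <- function(spec, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ann <- fixtureAnnotation(spec)
    paths <- c(annotation = file.path(dir, "annotation.tsv"),
               peaks = file.path(dir, "peaks.bed"),
               dge = file.path(dir, "dge.tsv"),
               gmt = file.path(dir, "sets.gmt"))
    writeTsv(data.frame(gene_id = mcols(ann)$gene_id,
                        chrom = as.character(GenomicRanges::seqnames(ann)),
                        tss = mcols(ann)$tss,
                        strand = as.character(GenomicRanges::strand(ann))),
             paths[["annotation"]])
    writeBed(fixturePeaks(spec, ann), paths[["peaks"]])
    dge <- fixtureDge(spec, ann)
    writeTsv(data.frame(gene_id = dge$gene_id,
                        log2FoldChange = dge$log2fc, pvalue = dge$pvalue,
                        padj = dge$padj), paths[["dge"]])
    sets <- fixtureGmt(spec, ann)
    desc <- attr(sets, "descriptions")
    writeLines(vapply(names(sets), function(id)
        paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), ""),
        paths[["gmt"]])
    if (spec$n_baseline_sets > 0) {
        paths[["baseline"]] <- file.path(dir, "baseline.tsv")
        writeBaseline(fixtureBaseline(spec, ann), paths[["baseline"]])
    }
    invisible(paths)
}
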