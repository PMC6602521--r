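#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom S4Vectors DataFrame
NULL

#' Promoter- vs enhancer-dominant classification of a cistrome
#'
#' Holds the per-subset fractions of peaks within a fixed radius of the
#' nearest TSS (for the top 2000 / 5000 / 10000 most significant peaks and
#' for all peaks), the resulting label, and the decay distance selected for
#' regulatory-potential scoring.
#'
#' @slot fractions Named numeric vector mapping subset labels
#'   (`"2000"`, `"5000"`, `"10000"`, `"all"`) to the fraction of peak
#'   centers within `radius` bp of the nearest TSS. Only applicable
#'   subsets are present.
#' @slot label Either `"promoter-dominant"` or `"enhancer-dominant"`.
#' @slot threshold Fraction above which any subset triggers the
#'   promoter-dominant label (default 0.20).
#' @slot radius Distance in bp defining "near the TSS" (default 1000).
#' @slot chosenD0 Decay distance in bp implied by the label (1000 for
#'   promoter-dominant, 10000 for enhancer-dominant) or a user override.
#'
#' @seealso [classifyTF()]
#' @export
setClass("TFClassification",
    representation(
        fractions = "numeric",
        label = "character",
        threshold = "numeric",
        radius = "numeric",
        chosenD0 = "numeric"
    )
)

setValidity("TFClassification", function(object) {
    msg <- character()
    if (length(object@label) != 1L ||
        !object@label %in% c("promoter-dominant", "enhancer-dominant"))
        msg <- c(msg, "label must be 'promoter-dominant' or 'enhancer-dominant'")
    if (any(object@fractions < 0 | object@fractions > 1))
        msg <- c(msg, "fractions must lie in [0, 1]")
    if (is.null(names(object@fractions)) || anyNA(names(object@fractions)))
        msg <- c(msg, "fractions must be named by subset")
    if (length(object@chosenD0) != 1L || object@chosenD0 <= 0)
        msg <- c(msg, "chosenD0 must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Per-gene regulatory potential scores
#'
#' Container for raw, min-max scaled, and baseline-adjusted regulatory
#' potential (RP) scores together with the binding-derived gene rank.
#' The raw RP of a gene is the sum of `2^(-d/d0)` over all peaks whose
#' center lies within `windowMultiple * d0` of the gene's TSS.
#'
#' @slot table A [S4Vectors::DataFrame] with one row per annotated gene and
#'   columns `gene_id`, `rp_raw`, `rp_scaled`, `baseline`, `rp_adjusted`,
#'   `rank_rp` (mid-ranks on ties; 1 = highest adjusted RP).
#' @slot d0 Decay distance in bp used for the weights.
#' @slot windowMultiple Peak inclusion window as a multiple of `d0`
#'   (default 15).
#'
#' @seealso [regPotential()], [rpTable()], [rankByAdjustedRP()]
#' @export
setClass("RegulatoryPotential",
    representation(
        table = "DataFrame",
        d0 = "numeric",
        windowMultiple = "numeric"
    )
)

setValidity("RegulatoryPotential", function(object) {
    msg <- character()
    need <- c("gene_id", "rp_raw", "rp_scaled", "baseline", "rp_adjusted",
              "rank_rp")
    missing <- setdiff(need, colnames(object@table))
    if (length(missing))
        msg <- c(msg, paste0("table lacks column(s): ",
                             paste(missing, collapse = ", ")))
    else {
        tab <- object@table
        if (anyDuplicated(tab$gene_id))
            msg <- c(msg, "gene_id must be unique")
        if (any(tab$rp_raw < 0))
            msg <- c(msg, "rp_raw must be >= 0")
        if (any(tab$rp_scaled < -1e-12 | tab$rp_scaled > 1 + 1e-12))
            msg <- c(msg, "rp_scaled must lie in [0, 1]")
        if (any(abs(tab$rp_adjusted - (tab$rp_scaled - tab$baseline)) > 1e-9))
            msg <- c(msg, "rp_adjusted must equal rp_scaled - baseline")
        if (nrow(tab) && !isTRUE(all.equal(sort(tab$rank_rp),
                                           sort(rank(-tab$rp_adjusted)))))
            msg <- c(msg, "rank_rp must be mid-ranks of decreasing rp_adjusted")
    }
    if (length(object@d0) != 1L || object@d0 <= 0)
        msg <- c(msg, "d0 must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' Minimum-hypergeometric enrichment results
#'
#' One row per tested gene set: the mHG statistic (minimum hypergeometric
#' tail over all ranking prefixes), the optimal cutoff attaining it, the
#' exact p-value under random gene ordering, the Benjamini-Hochberg FDR
#' across the tested collection, and a fold-enrichment score at the
#' optimal cutoff.
#'
#' @slot table A [S4Vectors::DataFrame] with columns `set_id`, `name`,
#'   `N` (universe size), `B` (term size within the universe), `n_opt`
#'   (smallest prefix length attaining the minimum), `b_at_cutoff`
#'   (term members within the prefix), `mhg_stat`, `enrichment_score`
#'   (`(b/n_opt)/(B/N)`), `pvalue`, `fdr`, `genes` (semicolon-separated
#'   `gene:rank` pairs), sorted by increasing p-value.
#' @slot universeSize Number of genes in the ranking the sets were tested
#'   against.
#' @slot fdrCutoff FDR threshold used by [reportedTerms()] (default 0.2).
#'
#' @seealso [runEnrichment()], [mhgTest()]
#' @export
setClass("MhgResults",
    representation(
        table = "DataFrame",
        universeSize = "integer",
        fdrCutoff = "numeric"
    )
)

setValidity("MhgResults", function(object) {
    msg <- character()
    need <- c("set_id", "name", "N", "B", "n_opt", "b_at_cutoff", "mhg_stat",
              "enrichment_score", "pvalue", "fdr", "genes")
    missing <- setdiff(need, colnames(object@table))
    if (length(missing))
        msg <- c(msg, paste0("table lacks column(s): ",
                             paste(missing, collapse = ", ")))
    else {
        tab <- object@table
        if (any(tab$pvalue <= 0 | tab$pvalue > 1))
            msg <- c(msg, "pvalue must lie in (0, 1]")
        if (any(tab$fdr <= 0 | tab$fdr > 1))
            msg <- c(msg, "fdr must lie in (0, 1]")
        if (is.unsorted(tab$pvalue))
            msg <- c(msg, "table must be sorted by increasing pvalue")
    }
    if (length(msg)) msg else TRUE
})
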