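#' Restrict gene sets to a universe and filter by size
#'
#' Each set is intersected with the ranking universe; sets with fewer
#' than `minSize` (default 10) or more than `maxSize` (default 2000)
#' remaining members are excluded. Very large terms are too generic to
#' be informative about a TF's regulatory program; very small ones are
#' too unreliable to test. Input order is preserved.
#'
#' @param sets Named list of member vectors (see [readGmt()]).
#' @param universe Character vector of ranked gene ids.
#' @param minSize,maxSize Inclusive bounds on post-intersection size.
#' @return Named list of filtered, universe-intersected sets.
#' @export
filterTermSets <- function(sets, universe, minSize = 10, maxSize = 2000) {
    desc <- attr(sets, "descriptions")
    out <- lapply(sets, function(m) m[m %in% universe])
    keep <- lengths(out) >= minSize & lengths(out) <= maxSize
    if (!any(keep))
        message("filterTermSets: no gene set within size bounds [",
                minSize, ", ", maxSize, "]")
    out <- out[keep]
    attr(out, "descriptions") <- desc[names(out)]
    out
}

#' Remove redundant gene sets by Jaccard similarity
#'
#' Greedy pass over sets sorted by decreasing size (ties broken by
#' lexicographic set id): a set is dropped when its Jaccard index
#' `|A n B| / |A u B|` with any already-kept set exceeds `threshold`
#' (default 0.85), so of two nearly identical terms only the larger is
#' reported. Sets must already be universe-intersected
#' ([filterTermSets()]); sizes are post-intersection sizes.
#'
#' @param sets Named list of universe-intersected member vectors.
#' @param threshold Jaccard index above which (strictly) the smaller set
#'   is dropped.
#' @return Named list of retained sets, in the size-sorted order of the
#'   greedy pass.
#' @export
dedupByJaccard <- function(sets, threshold = 0.85) {
    if (length(sets) <= 1L) return(sets)
    desc <- attr(sets, "descriptions")
    ord <- order(-lengths(sets), names(sets))
    sets <- sets[ord]
    kept <- logical(length(sets))
    for (i in seq_along(sets)) {
        a <- sets[[i]]
        drop <- FALSE
        for (j in which(kept)) {
            b <- sets[[j]]
            jac <- length(intersect(a, b)) / length(union(a, b))
            if (jac > threshold) { drop <- TRUE; break }
        }
        kept[i] <- !drop
    }
    n_drop <- sum(!kept)
    if (n_drop)
        message("dedupByJaccard: dropped ", n_drop,
                " redundant set(s) at Jaccard > ", threshold)
    out <- sets[kept]
    attr(out, "descriptions") <- desc[names(out)]
    out
}

#' Threshold-free gene-set enrichment on a gene ranking
#'
#' For each gene set, the ranking is translated into a 0/1 indicator of
#' term membership and the exact mHG test ([mhgTest()]) is applied;
#' FDRs are Benjamini-Hochberg across all tested sets of the collection.
#' The enrichment score is the fold enrichment at the mHG-optimal
#' cutoff, `(b / n_opt) / (B / N)`. Tied ranking scores are broken
#' deterministically (gene id order) before building the indicator; the
#' number of tied blocks is reported.
#'
#' @param ranking A ranked `data.frame` (`gene_id`, `score`, `rank`)
#'   from [rankByAdjustedRP()], [rankProduct()] (use `final_rank` via
#'   `rankingFromEnsemble()`) or [rankByDE()]. Lower rank = stronger
#'   candidate target.
#' @param sets Named list of gene sets, already passed through
#'   [filterTermSets()] and [dedupByJaccard()].
#' @param fdrCutoff FDR threshold used for the reported subset
#'   (default 0.2).
#' @return A [MhgResults-class] object (full table; use
#'   [reportedTerms()] for the FDR-filtered view).
#' @export
runEnrichment <- function(ranking, sets, fdrCutoff = 0.2) {
    stopifnot(nrow(ranking) > 0)
    ord <- order(ranking$rank, ranking$gene_id)
    genes <- ranking$gene_id[ord]
    if (anyDuplicated(genes))
        stop("runEnrichment: duplicated gene ids in the ranking")
    n_tied <- nrow(ranking) - length(unique(ranking$rank))
    if (n_tied)
        message("runEnrichment: ", n_tied,
                " tied rank(s) broken by gene id order")
    N <- length(genes)
    desc <- attr(sets, "descriptions")
    if (!length(sets)) {
        warning("runEnrichment: no gene sets to test")
        tab <- DataFrame(set_id = character(), name = character(),
                         N = integer(), B = integer(), n_opt = integer(),
                         b_at_cutoff = integer(), mhg_stat = numeric(),
                         enrichment_score = numeric(), pvalue = numeric(),
                         fdr = numeric(), genes = character())
        return(new("MhgResults", table = tab, universeSize = N,
                   fdrCutoff = fdrCutoff))
    }
    rows <- lapply(names(sets), function(id) {
        member <- genes %in% sets[[id]]
        res <- mhgTest(as.integer(member))
        hit <- which(member)
        list(set_id = id,
             name = if (!is.null(desc) && id %in% names(desc))
                 desc[[id]] else id,
             N = N, B = res$B, n_opt = res$n_opt,
             b_at_cutoff = res$b_at_cutoff,
             mhg_stat = res$mhg_stat,
             enrichment_score = if (res$B > 0)
                 (res$b_at_cutoff / res$n_opt) / (res$B / N) else 0,
             pvalue = res$pvalue,
             genes = paste0(genes[hit], ":", hit, collapse = ";"))
    })
    tab <- DataFrame(
        set_id = vapply(rows, `[[`, "", "set_id"),
        name = vapply(rows, `[[`, "", "name"),
        N = vapply(rows, `[[`, 0L, "N"),
        B = vapply(rows, `[[`, 0L, "B"),
        n_opt = vapply(rows, `[[`, 0L, "n_opt"),
        b_at_cutoff = vapply(rows, `[[`, 0L, "b_at_cutoff"),
        mhg_stat = vapply(rows, `[[`, 0, "mhg_stat"),
        enrichment_score = vapply(rows, `[[`, 0, "enrichment_score"),
        pvalue = vapply(rows, `[[`, 0, "pvalue"),
        genes = vapply(rows, `[[`, "", "genes"))
    tab$fdr <- stats::p.adjust(tab$pvalue, method = "BH")
    tab <- tab[order(tab$pvalue, tab$set_id),
               c("set_id", "name", "N", "B", "n_opt", "b_at_cutoff",
                 "mhg_stat", "enrichment_score", "pvalue", "fdr", "genes")]
    new("MhgResults", table = tab, universeSize = N, fdrCutoff = fdrCutoff)
}

#' Ranking view of an ensemble table
#'
#' Adapts the output of [rankProduct()] to the `gene_id`/`score`/`rank`
#' shape [runEnrichment()] expects, ordering by the final rank-product
#' rank.
#'
#' @param ensemble A `data.frame` from [rankProduct()].
#' @return A ranked `data.frame` with columns `gene_id`, `score`
#'   (the rank product; smaller = better), `rank`.
#' @export
rankingFromEnsemble <- function(ensemble) {
    data.frame(gene_id = ensemble$gene_id, score = ensemble$rank_product,
               rank = ensemble$final_rank, stringsAsFactors = FALSE)
}
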