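#' Rank genes by differential-expression significance
#'
#' Optionally filters to up- (`log2fc > 0`) or down-regulated
#' (`log2fc < 0`) genes, then ranks by increasing p-value; ties get
#' mid-ranks.
#'
#' @param dge A DGE `data.frame` from [readDge()].
#' @param direction `"all"` (default), `"up"` or `"down"`.
#' @return A `data.frame` with columns `gene_id`, `score` (the p-value),
#'   `rank` (1 = most significant), ordered by increasing rank then
#'   gene id.
#' @export
rankByDE <- function(dge, direction = c("all", "up", "down")) {
    direction <- match.arg(direction)
    keep <- switch(direction,
                   all = rep(TRUE, nrow(dge)),
                   up = dge$log2fc > 0,
                   down = dge$log2fc < 0)
    dge <- dge[keep, , drop = FALSE]
    if (!nrow(dge))
        stop("rankByDE: no genes left after '", direction,
             "' direction filter")
    r <- rank(dge$pvalue, ties.method = "average")
    out <- data.frame(gene_id = dge$gene_id, score = dge$pvalue,
                      rank = unname(r), stringsAsFactors = FALSE)
    out[order(out$rank, out$gene_id), , drop = FALSE]
}

#' Integrate binding and expression ranks by rank product
#'
#' The gene universe is the intersection of the two ranked lists; both
#' ranks are re-computed within the intersection (so the two scales
#' agree) before multiplying. Genes present in only one list are dropped
#' and counted via `message()`. The final ranking ascends in rank
#' product, with mid-ranks on ties and lexicographic gene id order for
#' output.
#'
#' @param rpRanks Binding ranking from [rankByAdjustedRP()].
#' @param deRanks Expression ranking from [rankByDE()].
#' @return A `data.frame` with columns `gene_id`, `rank_rp`, `rank_de`,
#'   `rank_product`, `final_rank`, ordered by increasing `final_rank`
#'   then gene id.
#' @export
rankProduct <- function(rpRanks, deRanks) {
    stopifnot(nrow(rpRanks) > 0, nrow(deRanks) > 0)
    common <- intersect(rpRanks$gene_id, deRanks$gene_id)
    if (!length(common))
        stop("rankProduct: empty intersection between the binding and ",
             "expression gene universes")
    dropRp <- nrow(rpRanks) - length(common)
    dropDe <- nrow(deRanks) - length(common)
    if (dropRp || dropDe)
        message("rankProduct: dropped ", dropRp, " binding-only and ",
                dropDe, " expression-only gene(s); universe = ",
                length(common), " genes")
    rp <- rpRanks[match(common, rpRanks$gene_id), ]
    de <- deRanks[match(common, deRanks$gene_id), ]
    # re-rank within the intersection from the input ranks, so both
    # scales are 1..|intersection| and the product is symmetric
    rank_rp <- rank(rp$rank, ties.method = "average")
    rank_de <- rank(de$rank, ties.method = "average")
    prod <- rank_rp * rank_de
    out <- data.frame(gene_id = common, rank_rp = rank_rp,
                      rank_de = rank_de, rank_product = prod,
                      final_rank = rank(prod, ties.method = "average"),
                      stringsAsFactors = FALSE)
    out[order(out$final_rank, out$gene_id), , drop = FALSE]
}

.sweepCurves <- function(scores, labels) {
    # threshold sweep over unique descending scores; labels logical
    ord <- order(-scores)
    labels <- labels[ord]
    scores <- scores[ord]
    P <- sum(labels); N <- sum(!labels)
    tp <- cumsum(labels); fp <- cumsum(!labels)
    # collapse tied scores to the last index of each tie block
    last <- !duplicated(scores, fromLast = TRUE)
    tp <- tp[last]; fp <- fp[last]
    tpr <- c(0, tp / P); fpr <- c(0, fp / N)
    auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    recall <- tp / P
    precision <- tp / (tp + fp)
    # precision at recall 0 pinned to that of the highest-scoring block
    recall <- c(0, recall); precision <- c(precision[1], precision)
    aupr <- sum(diff(recall) *
                (utils::head(precision, -1) + utils::tail(precision, -1)) / 2)
    list(roc = data.frame(fpr = fpr, tpr = tpr),
         pr = data.frame(recall = recall, precision = precision),
         auroc = auroc, aupr = aupr)
}

#' ROC and PR curves of binding scores against DE labels
#'
#' Diagnoses how well the adjusted RP score predicts differential
#' expression: positives are genes passing the DE label rule
#' (`padj < cutoff` when `padj` is available, else `pvalue < cutoff`;
#' restricted to the chosen direction), negatives the remaining genes of
#' the intersection universe, predictions the adjusted RP scores. Curves
#' come from a full threshold sweep; areas by the trapezoid rule, with
#' precision at recall 0 set by the highest-scoring prediction block.
#'
#' @param adjusted Named numeric vector of adjusted RP scores.
#' @param dge DGE `data.frame` from [readDge()].
#' @param cutoff Significance cutoff for the label rule (default 0.05).
#' @param direction `"all"`, `"up"` or `"down"`; a non-`"all"` direction
#'   also requires the matching `log2fc` sign for a positive label.
#' @return A list with `roc` and `pr` point tables, `auroc`, `aupr`,
#'   `n_pos`, `n_neg`.
#' @export
bindingExpressionCurves <- function(adjusted, dge, cutoff = 0.05,
                                    direction = c("all", "up", "down")) {
    direction <- match.arg(direction)
    common <- intersect(names(adjusted), dge$gene_id)
    if (!length(common))
        stop("bindingExpressionCurves: no genes shared between RP scores ",
             "and the DGE table")
    dge <- dge[match(common, dge$gene_id), ]
    sig <- if (all(is.na(dge$padj))) dge$pvalue < cutoff
           else !is.na(dge$padj) & dge$padj < cutoff
    dirok <- switch(direction, all = TRUE, up = dge$log2fc > 0,
                    down = dge$log2fc < 0)
    labels <- sig & dirok
    if (!any(labels) || all(labels))
        stop("bindingExpressionCurves: need at least one positive and one ",
             "negative label (got ", sum(labels), " positives of ",
             length(labels), ")")
    out <- .sweepCurves(unname(adjusted[common]), labels)
    out$n_pos <- sum(labels)
    out$n_neg <- sum(!labels)
    out
}
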