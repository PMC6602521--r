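#' Fraction of peaks near a TSS
#'
#' Fraction of peak centers lying within `radius` bp (closed) of the
#' nearest TSS of any gene on the same chromosome. Peaks on chromosomes
#' with no annotated TSS count as "not near".
#'
#' @param peaks Peak `GRanges` from [readPeaks()].
#' @param annotation TSS `GRanges` from [readTss()].
#' @param radius Distance in bp (default 1000).
#' @return A fraction in `[0, 1]`.
#' @export
fractionNearTss <- function(peaks, annotation, radius = 1000) {
    if (!length(peaks))
        stop("fractionNearTss: empty peak set")
    centers <- GRanges(GenomicRanges::seqnames(peaks),
                       IRanges(start = mcols(peaks)$center + 1, width = 1))
    tss <- GRanges(GenomicRanges::seqnames(annotation),
                   IRanges(start = mcols(annotation)$tss + 1, width = 1))
    hits <- suppressWarnings(
        GenomicRanges::distanceToNearest(centers, tss,
                                         ignore.strand = TRUE))
    near <- logical(length(peaks))
    if (length(hits)) {
        # base-pair distance |center - tss| (GRanges gap semantics would
        # undercount by one at the radius boundary)
        d <- abs(mcols(peaks)$center[queryHits(hits)] -
                 mcols(annotation)$tss[subjectHits(hits)])
        near[queryHits(hits)] <- d <= radius
    }
    mean(near)
}

#' Classify a cistrome as promoter- or enhancer-dominant
#'
#' Peaks are ranked by significance (-log10 p-value, descending; ties
#' keep input file order) and the fraction of peaks within `radius` of
#' the nearest TSS is computed for the top 2000, 5000 and 10000 peaks
#' (each subset only when at least that many peaks exist) and for all
#' peaks. If any fraction exceeds `threshold` the TF is
#' promoter-dominant and the default decay distance is 1 kb; otherwise
#' enhancer-dominant with 10 kb. When peaks carry no significance
#' scores only the "all" subset is evaluated.
#'
#' @inheritParams fractionNearTss
#' @param threshold Fraction that any subset must exceed (strictly) for
#'   the promoter-dominant call; default 0.20.
#' @param d0Override Optional user-supplied decay distance in bp that
#'   replaces the label-implied default (the report is still computed).
#' @return A [TFClassification-class] object.
#' @export
classifyTF <- function(peaks, annotation, threshold = 0.20, radius = 1000,
                       d0Override = NULL) {
    score <- mcols(peaks)$score
    scored <- !all(is.na(score))
    subsets <- c(2000L, 5000L, 10000L)
    fractions <- c()
    if (scored) {
        ord <- order(-ifelse(is.na(score), -Inf, score))
        for (n in subsets[subsets <= length(peaks)])
            fractions[as.character(n)] <-
                fractionNearTss(peaks[ord[seq_len(n)]], annotation, radius)
    }
    fractions["all"] <- fractionNearTss(peaks, annotation, radius)
    label <- if (any(fractions > threshold)) "promoter-dominant"
             else "enhancer-dominant"
    d0 <- if (!is.null(d0Override)) d0Override
          else if (label == "promoter-dominant") 1000 else 10000
    new("TFClassification", fractions = fractions, label = label,
        threshold = threshold, radius = radius, chosenD0 = as.numeric(d0))
}

#' Serialize a classification report to JSON
#'
#' @param object A [TFClassification-class] object.
#' @param path Output path (`classification.json`).
#' @return `path`, invisibly.
#' @export
writeClassification <- function(object, path) {
    jsonlite::write_json(
        list(fractions = as.list(object@fractions),
             threshold = object@threshold,
             radius_bp = object@radius,
             label = object@label,
             chosen_d0 = object@chosenD0),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
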