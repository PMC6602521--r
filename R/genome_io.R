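#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

.dataLines <- function(path) {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    list(lines = lines[keep], lineno = which(keep))
}

#' Read ChIP-seq peaks from a BED or narrowPeak file
#'
#' Peaks are returned as a [GenomicRanges::GRanges] in standard 1-based
#' closed coordinates with two metadata columns: `center`, the 0-based
#' peak center `floor((start0 + end0) / 2)` used for all TSS distance
#' computations, and `score`, a -log10 p-value or `NA` when absent.
#'
#' For the `bed` dialect the score is taken from column 5 only when it is
#' numeric and strictly positive (BED placeholder scores of 0 are treated
#' as "no score"); for `narrowPeak` the -log10 p-value in column 8 is
#' authoritative. Lines starting with `track`, `browser` or `#` are
#' skipped. Input order is preserved.
#'
#' @param path Path to a tab-separated BED3+/BED5 or narrowPeak file.
#' @param dialect `"bed"` (default) or `"narrowPeak"`.
#' @return A `GRanges`; a `parse_report` attribute is attached via
#'   [S4Vectors::metadata()] with counts of kept lines.
#' @export
readPeaks <- function(path, dialect = c("bed", "narrowPeak")) {
    dialect <- match.arg(dialect)
    stopifnot(file.exists(path))
    dl <- .dataLines(path)
    if (!length(dl$lines))
        stop("no peak records in '", path, "'")
    fields <- strsplit(dl$lines, "\t", fixed = TRUE)
    ncol <- lengths(fields)
    minc <- if (dialect == "narrowPeak") 8L else 3L
    if (any(ncol < minc))
        stop("line ", dl$lineno[which(ncol < minc)[1L]], " of '", path,
             "': fewer than ", minc, " tab-separated columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- is.na(start0) | is.na(end0) | start0 != floor(start0) |
        end0 != floor(end0) | start0 < 0 | start0 >= end0
    if (any(bad))
        stop("line ", dl$lineno[which(bad)[1L]], " of '", path,
             "': malformed coordinates")
    score <- rep(NA_real_, length(fields))
    if (dialect == "narrowPeak") {
        score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 8L)))
        score[!is.na(score) & score < 0] <- NA_real_
    } else {
        has5 <- ncol >= 5L
        s5 <- rep(NA_real_, length(fields))
        s5[has5] <- suppressWarnings(
            as.numeric(vapply(fields[has5], `[[`, "", 5L)))
        score[!is.na(s5) & s5 > 0] <- s5[!is.na(s5) & s5 > 0]
    }
    gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end0))
    mcols(gr)$center <- floor((start0 + end0) / 2)
    mcols(gr)$score <- score
    S4Vectors::metadata(gr)$parse_report <-
        list(kept = length(gr), dropped = 0L)
    gr
}

#' Write peaks back to BED
#'
#' Inverse of [readPeaks()] for the `bed` dialect: columns chrom,
#' 0-based start, end, a generated name, and score (absent scores are
#' written as the BED placeholder 0, which [readPeaks()] maps back to
#' "no score").
#'
#' @param peaks A `GRanges` as returned by [readPeaks()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(peaks, path) {
    score <- mcols(peaks)$score
    score <- ifelse(is.na(score), "0", formatC(score, format = "g",
                                               digits = 10))
    lines <- paste(as.character(GenomicRanges::seqnames(peaks)),
                   GenomicRanges::start(peaks) - 1L,
                   GenomicRanges::end(peaks),
                   paste0("peak_", seq_along(peaks)),
                   score, sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects a tab-separated file with header columns `gene_id`, `chrom`,
#' `tss` (0-based bp) and `strand`. A gene may appear on several rows
#' (isoform TSSs); all rows are retained and the multi-TSS policy (gene RP
#' = maximum over its TSSs) is applied downstream by [rawRP()].
#'
#' @param path Path to the annotation TSV.
#' @return A `GRanges` of width-1 ranges at each TSS with metadata columns
#'   `gene_id` and `tss` (the 0-based coordinate).
#' @export
readTss <- function(path) {
    stopifnot(file.exists(path))
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character")
    need <- c("gene_id", "chrom", "tss", "strand")
    missing <- setdiff(need, colnames(tab))
    if (length(missing))
        stop("annotation '", path, "' lacks required column(s): ",
             paste(missing, collapse = ", "))
    if (!nrow(tab))
        stop("annotation '", path, "' has no data rows")
    tss <- suppressWarnings(as.numeric(tab$tss))
    if (anyNA(tss) || any(tss != floor(tss)) || any(tss < 0))
        stop("annotation '", path, "': non-integer or negative tss")
    strand <- ifelse(tab$strand %in% c("+", "-"), tab$strand, "*")
    gr <- GRanges(tab$chrom, IRanges(start = tss + 1, width = 1),
                  strand = strand)
    mcols(gr)$gene_id <- tab$gene_id
    mcols(gr)$tss <- tss
    gr
}

#' Read a differential-gene-expression table
#'
#' Expects DESeq2-style columns (`gene_id`, `log2FoldChange`, `pvalue`,
#' `padj` by default; remappable via `columnMap`). Rows with missing
#' p-values are dropped (count reported via `message()`); p-values of
#' exactly 0 are replaced by the smallest positive double; duplicated
#' gene ids keep the row with the smallest p-value.
#'
#' @param path Path to the DGE TSV.
#' @param columnMap Optional named character vector remapping the
#'   canonical names to the file's column names, e.g.
#'   `c(pvalue = "P.Value")`.
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `pvalue`,
#'   `padj` (`NA` when absent); attribute `parse_report` carries drop
#'   counts.
#' @export
readDge <- function(path, columnMap = NULL) {
    stopifnot(file.exists(path))
    tab <- utils::read.delim(path, header = TRUE, sep = "\t")
    names <- c(gene_id = "gene_id", log2fc = "log2FoldChange",
               pvalue = "pvalue", padj = "padj")
    if (!is.null(columnMap))
        names[names(columnMap)] <- columnMap
    if (!names[["pvalue"]] %in% colnames(tab))
        stop("DGE table '", path, "' has no recognizable p-value column ('",
             names[["pvalue"]], "')")
    for (req in c("gene_id", "log2fc"))
        if (!names[[req]] %in% colnames(tab))
            stop("DGE table '", path, "' lacks column '", names[[req]], "'")
    out <- data.frame(
        gene_id = as.character(tab[[names[["gene_id"]]]]),
        log2fc = as.numeric(tab[[names[["log2fc"]]]]),
        pvalue = as.numeric(tab[[names[["pvalue"]]]]),
        padj = if (names[["padj"]] %in% colnames(tab))
            as.numeric(tab[[names[["padj"]]]]) else NA_real_,
        stringsAsFactors = FALSE
    )
    n_in <- nrow(out)
    out <- out[!is.na(out$pvalue), , drop = FALSE]
    n_na <- n_in - nrow(out)
    if (n_na)
        message("readDge: dropped ", n_na, " row(s) with missing p-value")
    n_zero <- sum(out$pvalue == 0)
    if (n_zero) {
        out$pvalue[out$pvalue == 0] <- .Machine$double.xmin
        message("readDge: replaced ", n_zero,
                " zero p-value(s) by the smallest positive double")
    }
    if (anyDuplicated(out$gene_id)) {
        out <- out[order(out$pvalue), , drop = FALSE]
        dup <- duplicated(out$gene_id)
        message("readDge: collapsed ", sum(dup),
                " duplicate gene id row(s), keeping the smallest p-value")
        out <- out[!dup, , drop = FALSE]
    }
    rownames(out) <- NULL
    attr(out, "parse_report") <- list(kept = nrow(out), dropped_na = n_na,
                                      zero_replaced = n_zero)
    out
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id TAB description TAB gene TAB gene ...`.
#' Duplicate member genes within a line are removed; sets with no members
#' are dropped with a warning; a repeated `set_id` is an error (the file
#' is ambiguous). Input order is preserved.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (members per set) with a
#'   `descriptions` attribute (named character vector).
#' @export
readGmt <- function(path) {
    stopifnot(file.exists(path))
    dl <- .dataLines(path)
    fields <- strsplit(dl$lines, "\t", fixed = TRUE)
    short <- lengths(fields) < 3L
    if (any(short)) {
        ids <- vapply(fields, function(f) f[1L], "")
        empty <- lengths(fields) == 2L
        if (any(empty & short)) {
            warning("readGmt: dropped ", sum(empty), " empty set(s): ",
                    paste(ids[empty], collapse = ", "))
            fields <- fields[!empty]
            dl$lineno <- dl$lineno[!empty]
            short <- lengths(fields) < 3L
        }
        if (any(short))
            stop("line ", dl$lineno[which(short)[1L]], " of '", path,
                 "': fewer than 3 tab-separated fields")
    }
    ids <- vapply(fields, `[[`, "", 1L)
    if (anyDuplicated(ids))
        stop("readGmt: duplicate set id '", ids[duplicated(ids)][1L],
             "' in '", path, "'")
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- ids
    attr(sets, "descriptions") <-
        stats::setNames(vapply(fields, `[[`, "", 2L), ids)
    sets
}

#' Write a data.frame or DataFrame as TSV
#'
#' Floating-point columns are printed with 6 significant digits; p-value
#' and FDR columns in scientific notation, for stable diffs across runs.
#'
#' @param tab Table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(tab, path) {
    tab <- as.data.frame(tab)
    for (col in colnames(tab)) {
        x <- tab[[col]]
        if (is.double(x)) {
            fmt <- if (grepl("pvalue|fdr|mhg", col)) "e" else "g"
            tab[[col]] <- ifelse(is.na(x), "NA",
                                 formatC(x, format = fmt, digits = 6))
        }
    }
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
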