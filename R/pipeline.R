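#' Configuration of an analysis run
#'
#' Collects input paths and tunable parameters for [runSolo()] /
#' [runEnsemble()]. The mode is auto-selected: ensemble when a DGE path
#' is supplied, solo otherwise; an explicit `mode` forces solo even when
#' a DGE file is present. Solo mode has no notion of expression
#' direction, so it requires `direction = "all"`.
#'
#' @param peaks,annotation,gmt,dge,baseline,outdir Input file paths
#'   (`gmt` may name several collections; `dge` and `baseline` are
#'   optional) and the output directory.
#' @param mode `"auto"` (default), `"solo"` or `"ensemble"`.
#' @param d0 Optional decay-distance override in bp; when `NULL` the
#'   classification picks 1000 or 10000.
#' @param windowMultiple Peak inclusion window as a multiple of d0
#'   (default 15).
#' @param direction DE genes to analyze: `"all"`, `"up"`, `"down"`.
#' @param fdrCutoff FDR threshold of the reported enrichment tables
#'   (default 0.2).
#' @param classifyThreshold Promoter-dominant threshold (default 0.20).
#' @param deCutoff Significance cutoff of the DE label rule for ROC/PR
#'   (default 0.05).
#' @param peakDialect `"bed"` or `"narrowPeak"`.
#' @return A list of class `runConfig`.
#' @export
runConfig <- function(peaks, annotation, gmt, outdir, dge = NULL,
                      baseline = NULL, mode = c("auto", "solo", "ensemble"),
                      d0 = NULL, windowMultiple = 15,
                      direction = c("all", "up", "down"), fdrCutoff = 0.2,
                      classifyThreshold = 0.20, deCutoff = 0.05,
                      peakDialect = c("bed", "narrowPeak")) {
    mode <- match.arg(mode)
    direction <- match.arg(direction)
    peakDialect <- match.arg(peakDialect)
    if (mode == "auto")
        mode <- if (is.null(dge)) "solo" else "ensemble"
    if (mode == "ensemble" && is.null(dge))
        stop("runConfig: ensemble mode requires a DGE file")
    if (mode == "solo" && direction != "all")
        stop("runConfig: solo mode has no DE direction; use 'all'")
    for (p in c(peaks, annotation, gmt, dge, baseline))
        if (!file.exists(p))
            stop("runConfig: input file not found: ", p)
    structure(list(peaks = peaks, annotation = annotation, gmt = gmt,
                   dge = dge, baseline = baseline, outdir = outdir,
                   mode = mode, d0 = d0, windowMultiple = windowMultiple,
                   direction = direction, fdrCutoff = fdrCutoff,
                   classifyThreshold = classifyThreshold,
                   deCutoff = deCutoff, peakDialect = peakDialect),
              class = "runConfig")
}

.collectionName <- function(path) {
    sub("\\.[^.]*$", "", basename(path))
}

.writeEnrichment <- function(res, prefix, outdir, written) {
    full <- file.path(outdir, paste0(prefix, ".tsv"))
    rep <- file.path(outdir, paste0(prefix, "_reported.tsv"))
    writeTsv(enrichmentTable(res), full)
    writeTsv(reportedTerms(res), rep)
    c(written, full, rep)
}

.runPipeline <- function(config) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    ok <- FALSE
    on.exit(if (!ok) unlink(written), add = TRUE)

    peaks <- readPeaks(config$peaks, config$peakDialect)
    annotation <- readTss(config$annotation)
    gmts <- lapply(config$gmt, readGmt)
    names(gmts) <- vapply(config$gmt, .collectionName, "")
    pchr <- unique(as.character(GenomicRanges::seqnames(peaks)))
    achr <- unique(as.character(GenomicRanges::seqnames(annotation)))
    lonely <- c(setdiff(pchr, achr), setdiff(achr, pchr))
    if (length(lonely))
        warning("chromosome(s) present in only one of peaks/annotation: ",
                paste(lonely, collapse = ", "))
    baseline <- if (!is.null(config$baseline))
        readBaseline(config$baseline) else NULL

    cls <- classifyTF(peaks, annotation,
                      threshold = config$classifyThreshold,
                      d0Override = config$d0)
    d0 <- chosenD0(cls)
    written <- c(written, file.path(config$outdir, "classification.json"))
    writeClassification(cls, file.path(config$outdir,
                                       "classification.json"))

    rp <- regPotential(annotation, peaks, d0 = d0,
                       windowMultiple = config$windowMultiple,
                       baseline = baseline)
    tab <- rpTable(rp)
    written <- c(written, file.path(config$outdir, "rp_ranks.tsv"))
    writeTsv(tab[order(tab$rank_rp, tab$gene_id), ],
             file.path(config$outdir, "rp_ranks.tsv"))
    adjusted <- stats::setNames(tab$rp_adjusted, tab$gene_id)
    rpRanking <- rankByAdjustedRP(adjusted)

    enrichOne <- function(ranking, prefix) {
        res <- list()
        for (nm in names(gmts)) {
            sets <- dedupByJaccard(
                filterTermSets(gmts[[nm]], ranking$gene_id))
            res[[nm]] <- runEnrichment(ranking, sets,
                                       fdrCutoff = config$fdrCutoff)
            written <<- .writeEnrichment(res[[nm]],
                                         paste0(prefix, nm),
                                         config$outdir, written)
        }
        res
    }

    out <- list(config = config, classification = cls, rp = rp,
                rpRanking = rpRanking)
    summary <- list(mode = config$mode, d0 = d0,
                    window_multiple = config$windowMultiple,
                    n_genes = nrow(tab), n_peaks = length(peaks),
                    label = tfLabel(cls),
                    fdr_cutoff = config$fdrCutoff,
                    direction = config$direction,
                    de_cutoff = config$deCutoff)

    if (config$mode == "solo") {
        out$enrichment <- enrichOne(rpRanking, "enrichment_")
    } else {
        dge <- readDge(config$dge)
        if (!length(intersect(dge$gene_id, tab$gene_id)))
            stop("runEnsemble: the DGE table shares no gene ids with ",
                 "the annotation")
        deRanking <- rankByDE(dge, config$direction)
        ensemble <- rankProduct(rpRanking, deRanking)
        written <- c(written, file.path(config$outdir,
                                        "ensemble_ranks.tsv"))
        writeTsv(ensemble, file.path(config$outdir, "ensemble_ranks.tsv"))
        curves <- bindingExpressionCurves(adjusted, dge,
                                          cutoff = config$deCutoff,
                                          direction = config$direction)
        written <- c(written, file.path(config$outdir, "roc.tsv"),
                     file.path(config$outdir, "pr.tsv"))
        writeTsv(curves$roc, file.path(config$outdir, "roc.tsv"))
        writeTsv(curves$pr, file.path(config$outdir, "pr.tsv"))
        out$deRanking <- deRanking
        out$ensemble <- ensemble
        out$curves <- curves
        summary$auroc <- curves$auroc
        summary$aupr <- curves$aupr
        summary$n_pos <- curves$n_pos
        summary$n_neg <- curves$n_neg
        summary$n_universe <- nrow(ensemble)
        out$soloEnrichment <- enrichOne(rpRanking, "solo_enrichment_")
        out$enrichment <- enrichOne(rankingFromEnsemble(ensemble),
                                    "enrichment_")
    }
    written <- c(written, file.path(config$outdir, "run_summary.json"))
    jsonlite::write_json(summary,
                         file.path(config$outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ok <- TRUE
    out$files <- written
    out
}

#' Run the solo-mode pipeline
#'
#' Classification, decay-distance selection, RP scoring, ranking by
#' adjusted RP, and mHG enrichment per GMT collection. Writes
#' `classification.json`, `rp_ranks.tsv`,
#' `enrichment_<collection>.tsv` (+ `_reported` at FDR < cutoff) and
#' `run_summary.json` under `config$outdir`; partial outputs are
#' removed on failure.
#'
#' @param config A [runConfig()] with `mode = "solo"`.
#' @return A list bundle: `classification`, `rp`, `rpRanking`,
#'   `enrichment` (per collection), `files`.
#' @export
runSolo <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    if (config$mode != "solo")
        stop("runSolo: config selects mode '", config$mode, "'")
    .runPipeline(config)
}

#' Run the ensemble-mode pipeline
#'
#' Everything [runSolo()] does, plus the DE ranking, rank-product
#' integration, mHG enrichment on the combined ranking (solo-ranking
#' enrichment is also written for comparison), and ROC/PR diagnostics
#' of adjusted RP against DE-defined labels (`ensemble_ranks.tsv`,
#' `roc.tsv`, `pr.tsv`, AUCs in `run_summary.json`).
#'
#' @param config A [runConfig()] with `mode = "ensemble"`.
#' @return The [runSolo()] bundle extended with `deRanking`, `ensemble`,
#'   `curves`, `soloEnrichment`.
#' @export
runEnsemble <- function(config) {
    stopifnot(inherits(config, "runConfig"))
    if (config$mode != "ensemble")
        stop("runEnsemble: config selects mode '", config$mode, "'")
    .runPipeline(config)
}
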