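#' Accessors for cistromeGO result objects
#'
#' `rpTable()` returns the per-gene RP score table of a
#' [RegulatoryPotential-class] object; `enrichmentTable()` the full
#' per-term table of a [MhgResults-class] object; `reportedTerms()` the
#' subset passing the FDR cutoff; `tfLabel()` and `chosenD0()` the label
#' and selected decay distance of a [TFClassification-class] object;
#' `tssFractions()` its per-subset promoter-proximal fractions.
#'
#' @param object A result object of the documented class.
#' @return `rpTable`, `enrichmentTable`, `reportedTerms`: a
#'   [S4Vectors::DataFrame]. `tfLabel`: a character scalar.
#'   `chosenD0`: a numeric scalar (bp). `tssFractions`: a named numeric
#'   vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rpTable", function(object) standardGeneric("rpTable"))

#' @rdname accessors
#' @export
setGeneric("enrichmentTable",
    function(object) standardGeneric("enrichmentTable"))

#' @rdname accessors
#' @export
setGeneric("reportedTerms", function(object) standardGeneric("reportedTerms"))

#' @rdname accessors
#' @export
setGeneric("tfLabel", function(object) standardGeneric("tfLabel"))

#' @rdname accessors
#' @export
setGeneric("chosenD0", function(object) standardGeneric("chosenD0"))

#' @rdname accessors
#' @export
setGeneric("tssFractions", function(object) standardGeneric("tssFractions"))

#' @rdname accessors
#' @export
setMethod("rpTable", "RegulatoryPotential", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("enrichmentTable", "MhgResults", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("reportedTerms", "MhgResults", function(object)
    object@table[object@table$fdr < object@fdrCutoff, , drop = FALSE])

#' @rdname accessors
#' @export
setMethod("tfLabel", "TFClassification", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("chosenD0", "TFClassification", function(object) object@chosenD0)

#' @rdname accessors
#' @export
setMethod("tssFractions", "TFClassification", function(object)
    object@fractions)

setMethod("show", "TFClassification", function(object) {
    cat("TFClassification:", object@label, "\n")
    cat("  chosen d0:", object@chosenD0, "bp\n")
    cat("  threshold:", object@threshold,
        "| radius:", object@radius, "bp\n")
    cat("  fraction of peaks near TSS per subset:\n")
    for (nm in names(object@fractions))
        cat(sprintf("    %-6s %.4f\n", nm, object@fractions[[nm]]))
})

setMethod("show", "RegulatoryPotential", function(object) {
    cat("RegulatoryPotential over", nrow(object@table), "genes\n")
    cat("  d0 =", object@d0, "bp; window =", object@windowMultiple,
        "x d0\n")
    top <- object@table[order(object@table$rank_rp), , drop = FALSE]
    show(utils::head(top, 5L))
})

setMethod("show", "MhgResults", function(object) {
    cat("MhgResults:", nrow(object@table), "tested term(s) over",
        object@universeSize, "ranked genes;",
        sum(object@table$fdr < object@fdrCutoff), "at FDR <",
        object@fdrCutoff, "\n")
    keep <- setdiff(colnames(object@table), "genes")
    show(utils::head(object@table[, keep, drop = FALSE], 5L))
})
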