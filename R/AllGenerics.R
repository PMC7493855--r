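#' @include AllClasses.R
NULL

#' Accessors for IPMSelect classes
#'
#' \code{quantRecords}, \code{crapomeRecords}, \code{interactorCalls},
#' \code{filterLedger}, \code{stageLedgers}, \code{gsTerms},
#' \code{gsMembers}, \code{networkNodes}, \code{termEdges} and
#' \code{proteinEdges} extract the corresponding tables from the package's
#' S4 containers; \code{ledgerCounts} flattens a \linkS4class{FilterLedger}
#' to a named integer vector.
#'
#' @param x an IPMSelect object.
#' @return A \link[S4Vectors]{DataFrame}, list or named integer vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("quantRecords", function(x) standardGeneric("quantRecords"))
#' @rdname accessors
#' @export
setMethod("quantRecords", "QuantTable", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("crapomeRecords", function(x) standardGeneric("crapomeRecords"))
#' @rdname accessors
#' @export
setMethod("crapomeRecords", "CrapomeTable", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("interactorCalls", function(x) standardGeneric("interactorCalls"))
#' @rdname accessors
#' @export
setMethod("interactorCalls", "InteractorCalls", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("filterLedger", function(x) standardGeneric("filterLedger"))
#' @rdname accessors
#' @export
setMethod("filterLedger", "InteractorCalls", function(x) x@ledger)

#' @rdname accessors
#' @export
setGeneric("stageLedgers", function(x) standardGeneric("stageLedgers"))
#' @rdname accessors
#' @export
setMethod("stageLedgers", "InteractorCalls", function(x) x@stageLedgers)

#' @rdname accessors
#' @export
setGeneric("gsTerms", function(x) standardGeneric("gsTerms"))
#' @rdname accessors
#' @export
setMethod("gsTerms", "GeneSetCollection", function(x) x@terms)

#' @rdname accessors
#' @export
setGeneric("gsMembers", function(x) standardGeneric("gsMembers"))
#' @rdname accessors
#' @export
setMethod("gsMembers", "GeneSetCollection", function(x) {
    m <- x@members
    names(m) <- x@terms$term_id
    m
})

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setMethod("networkNodes", "TermNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("termEdges", function(x) standardGeneric("termEdges"))
#' @rdname accessors
#' @export
setMethod("termEdges", "TermNetwork", function(x) x@termEdges)

#' @rdname accessors
#' @export
setGeneric("proteinEdges", function(x) standardGeneric("proteinEdges"))
#' @rdname accessors
#' @export
setMethod("proteinEdges", "TermNetwork", function(x) x@proteinEdges)

#' @rdname accessors
#' @export
setGeneric("ledgerCounts", function(x) standardGeneric("ledgerCounts"))
#' @rdname accessors
#' @export
setMethod("ledgerCounts", "FilterLedger", function(x) {
    c(n_identified = x@nIdentified, n_lineage_removed = x@nLineageRemoved,
      n_after_lineage = x@nAfterLineage, n_enrichment_pass = x@nEnrichmentPass,
      n_contaminants = x@nContaminants, n_final = x@nFinal)
})

#' Venn partition accessors
#'
#' @param x a \linkS4class{VennPartition}.
#' @return A character vector of elements.
#' @name venn-accessors
NULL

#' @rdname venn-accessors
#' @export
setGeneric("vennShared", function(x) standardGeneric("vennShared"))
#' @rdname venn-accessors
#' @export
setMethod("vennShared", "VennPartition", function(x) x@shared)

#' @rdname venn-accessors
#' @export
setGeneric("vennASpecific", function(x) standardGeneric("vennASpecific"))
#' @rdname venn-accessors
#' @export
setMethod("vennASpecific", "VennPartition", function(x) x@aSpecific)

#' @rdname venn-accessors
#' @export
setGeneric("vennBSpecific", function(x) standardGeneric("vennBSpecific"))
#' @rdname venn-accessors
#' @export
setMethod("vennBSpecific", "VennPartition", function(x) x@bSpecific)

setMethod("show", "QuantTable", function(object) {
    rec <- object@records
    cat(sprintf("QuantTable: %d records, %d proteins, %d experiment(s)\n",
                nrow(rec), length(unique(rec$protein_id)),
                length(unique(rec$experiment_id))))
})

setMethod("show", "CrapomeTable", function(object) {
    cat(sprintf("CrapomeTable: %d proteins\n", nrow(object@records)))
})

setMethod("show", "GeneSetCollection", function(object) {
    cat(sprintf("GeneSetCollection: %d terms (%s); member sizes %s\n",
                nrow(object@terms),
                paste(unique(object@terms$category), collapse = "/"),
                if (length(object@members))
                    paste(range(lengths(object@members)), collapse = "-")
                else "-"))
})

setMethod("show", "FilterLedger", function(object) {
    v <- ledgerCounts(object)
    cat("FilterLedger:\n")
    for (nm in names(v)) cat(sprintf("  %-18s %d\n", nm, v[[nm]]))
})

setMethod("show", "InteractorCalls", function(object) {
    cat(sprintf("InteractorCalls: %d (protein, stage) calls, %d final interactors\n",
                nrow(object@calls), object@ledger@nFinal))
    show(object@ledger)
})

setMethod("show", "VennPartition", function(object) {
    cat(sprintf("VennPartition: shared %d | A-specific %d | B-specific %d\n",
                length(object@shared), length(object@aSpecific),
                length(object@bSpecific)))
})

setMethod("show", "TermNetwork", function(object) {
    cat(sprintf("TermNetwork: %d term nodes, %d kappa edges, %d term-protein edges\n",
                nrow(object@nodes), nrow(object@termEdges),
                nrow(object@proteinEdges)))
})

setMethod("show", "SimulationParams", function(object) {
    cat(sprintf(paste0("SimulationParams: %d proteins (%.0f%% interactors, ",
                       "%.0f%% contaminants, %.0f%% non-lineage), %d genes, ",
                       "seed %d\n"),
                object@nProteins, 100 * object@fracTrueInteractors,
                100 * object@fracContaminants, 100 * object@fracNonLineage,
                object@nGenes, object@seed))
})

setMethod("show", "SyntheticStudy", function(object) {
    cat(sprintf("SyntheticStudy: %d proteins, %d genes, %d gene sets, seed %d\n",
                object@params@nProteins, object@params@nGenes,
                nrow(object@geneSets@terms), object@params@seed))
})

#' Number of terms in a collection
#' @param x a \linkS4class{GeneSetCollection}.
#' @return Integer count of terms.
#' @export
setMethod("length", "GeneSetCollection", function(x) nrow(x@terms))

#' Subset a GeneSetCollection
#' @param x a \linkS4class{GeneSetCollection}.
#' @param i index or term_id character vector.
#' @param j,drop,... ignored.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i))
        i <- match(i, x@terms$term_id)
    new("GeneSetCollection", terms = x@terms[i, , drop = FALSE],
        members = x@members[i])
})
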