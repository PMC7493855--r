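#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.QUANT_COLUMNS <- c("protein_id", "gene_symbol", "experiment_id", "channel",
                    "lfq_intensity", "spectral_count")
.QUANT_CHANNELS <- c("bait", "control")
.CRAPOME_COLUMNS <- c("protein_id", "n_experiments", "max_spectral_count",
                      "avg_spectral_count")
.STAGES <- c("OPC", "OL")

#' Per-protein label-free quantification records
#'
#' A \code{QuantTable} holds one row per (protein, experiment, channel)
#' combination of an IP-MS experiment: the bait pulldown channel and the
#' matched IgG control channel, with LFQ intensity and spectral count.
#'
#' @slot records A \link[S4Vectors]{DataFrame} with columns
#'   \code{protein_id}, \code{gene_symbol}, \code{experiment_id},
#'   \code{channel} (\code{"bait"} or \code{"control"}),
#'   \code{lfq_intensity} (non-negative), \code{spectral_count}
#'   (non-negative integer).
#' @aliases QuantTable
#' @exportClass QuantTable
setClass("QuantTable", representation(records = "DFrame"))

setValidity("QuantTable", function(object) {
    rec <- object@records
    missing <- setdiff(.QUANT_COLUMNS, colnames(rec))
    if (length(missing))
        return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    if (nrow(rec) == 0L)
        return(TRUE)
    if (!all(rec$channel %in% .QUANT_CHANNELS))
        return("channel must be 'bait' or 'control'")
    if (any(!is.finite(rec$lfq_intensity)) || any(rec$lfq_intensity < 0))
        return("lfq_intensity must be finite and >= 0")
    if (any(rec$spectral_count < 0) || any(rec$spectral_count != round(rec$spectral_count)))
        return("spectral_count must be a non-negative integer")
    key <- paste(rec$protein_id, rec$experiment_id, rec$channel, sep = "\r")
    if (anyDuplicated(key))
        return("(protein_id, experiment_id, channel) must be unique")
    TRUE
})

#' Construct a QuantTable
#'
#' @param records a \code{data.frame} or \code{DataFrame} with the columns
#'   documented in \linkS4class{QuantTable}. Extra columns are dropped.
#' @return A \linkS4class{QuantTable}.
#' @examples
#' QuantTable(data.frame(protein_id = "P1", gene_symbol = "G1",
#'     experiment_id = "e1", channel = c("bait", "control"),
#'     lfq_intensity = c(1e5, 2e4), spectral_count = c(10L, 2L)))
#' @export
QuantTable <- function(records = data.frame()) {
    rec <- DataFrame(records)
    if (nrow(rec) == 0L && !all(.QUANT_COLUMNS %in% colnames(rec))) {
        rec <- DataFrame(protein_id = character(), gene_symbol = character(),
                         experiment_id = character(), channel = character(),
                         lfq_intensity = numeric(), spectral_count = integer())
    } else {
        missing <- setdiff(.QUANT_COLUMNS, colnames(rec))
        if (length(missing))
            stop(sprintf("quant table format error: missing column(s): %s",
                         paste(missing, collapse = ", ")), call. = FALSE)
        rec <- rec[, .QUANT_COLUMNS]
        rec$protein_id <- as.character(rec$protein_id)
        rec$gene_symbol <- as.character(rec$gene_symbol)
        rec$experiment_id <- as.character(rec$experiment_id)
        rec$channel <- as.character(rec$channel)
        rec$lfq_intensity <- as.numeric(rec$lfq_intensity)
        rec$spectral_count <- as.integer(round(as.numeric(rec$spectral_count)))
    }
    rownames(rec) <- NULL
    new("QuantTable", records = rec)
}

#' Contaminant-repository evidence table
#'
#' One row per protein of repository evidence used for contaminant flagging:
#' the number of repository control experiments detecting the protein and the
#' maximum / average spectral count observed there.
#'
#' @slot records A \link[S4Vectors]{DataFrame} with columns
#'   \code{protein_id}, \code{n_experiments} (>= 1),
#'   \code{max_spectral_count}, \code{avg_spectral_count}
#'   (with \code{avg <= max}).
#' @aliases CrapomeTable
#' @exportClass CrapomeTable
setClass("CrapomeTable", representation(records = "DFrame"))

setValidity("CrapomeTable", function(object) {
    rec <- object@records
    missing <- setdiff(.CRAPOME_COLUMNS, colnames(rec))
    if (length(missing))
        return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    if (nrow(rec) == 0L)
        return(TRUE)
    if (any(rec$n_experiments < 1))
        return("n_experiments must be >= 1")
    if (any(rec$max_spectral_count < 0) || any(rec$avg_spectral_count < 0))
        return("spectral counts must be non-negative")
    if (any(rec$avg_spectral_count > rec$max_spectral_count))
        return("avg_spectral_count must not exceed max_spectral_count")
    if (anyDuplicated(rec$protein_id))
        return("protein_id must be unique")
    TRUE
})

#' Construct a CrapomeTable
#'
#' @param records a \code{data.frame} or \code{DataFrame} with columns
#'   documented in \linkS4class{CrapomeTable}.
#' @return A \linkS4class{CrapomeTable}.
#' @export
CrapomeTable <- function(records = data.frame()) {
    rec <- DataFrame(records)
    if (nrow(rec) == 0L && !all(.CRAPOME_COLUMNS %in% colnames(rec))) {
        rec <- DataFrame(protein_id = character(), n_experiments = integer(),
                         max_spectral_count = integer(),
                         avg_spectral_count = numeric())
    } else {
        missing <- setdiff(.CRAPOME_COLUMNS, colnames(rec))
        if (length(missing))
            stop(sprintf("contaminant table format error: missing column(s): %s",
                         paste(missing, collapse = ", ")), call. = FALSE)
        rec <- rec[, .CRAPOME_COLUMNS]
        rec$protein_id <- as.character(rec$protein_id)
        rec$n_experiments <- as.integer(rec$n_experiments)
        rec$max_spectral_count <- as.integer(rec$max_spectral_count)
        rec$avg_spectral_count <- as.numeric(rec$avg_spectral_count)
    }
    rownames(rec) <- NULL
    new("CrapomeTable", records = rec)
}

#' Stage-labelled expression count matrix
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} subclass carrying a
#' \code{"counts"} assay, per-gene lengths in \code{rowData()$gene_length_bp}
#' and a two-stage design (\code{"OPC"} / \code{"OL"}) in
#' \code{colData()$stage}.
#'
#' @aliases StageExpression
#' @exportClass StageExpression
setClass("StageExpression", contains = "SummarizedExperiment")

setValidity("StageExpression", function(object) {
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0))
        return("counts must be finite and non-negative")
    rd <- SummarizedExperiment::rowData(object)
    if (!"gene_length_bp" %in% colnames(rd))
        return("rowData column 'gene_length_bp' is required")
    if (any(rd$gene_length_bp <= 0))
        return("gene_length_bp must be > 0")
    cd <- SummarizedExperiment::colData(object)
    if (!"stage" %in% colnames(cd))
        return("colData column 'stage' is required")
    if (any(is.na(cd$stage)) || !all(cd$stage %in% .STAGES))
        return("every sample must be labelled 'OPC' or 'OL'")
    if (!all(.STAGES %in% cd$stage))
        return("each stage (OPC, OL) needs at least one sample")
    TRUE
})

#' Construct a StageExpression object
#'
#' @param counts gene x sample matrix of non-negative counts with gene ids as
#'   rownames and sample names as colnames.
#' @param geneLength per-gene transcript length in bp (recycled against rows).
#' @param stage per-sample stage label, \code{"OPC"} or \code{"OL"}.
#' @return A \linkS4class{StageExpression}.
#' @export
StageExpression <- function(counts, geneLength, stage) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        stop("counts must have gene ids as rownames", call. = FALSE)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(gene_length_bp = as.integer(geneLength),
                            row.names = rownames(counts)),
        colData = DataFrame(stage = as.character(stage),
                            row.names = colnames(counts)))
    new("StageExpression", se)
}

#' Collection of annotated gene sets
#'
#' Terms (GO / KEGG / Reactome style) with their member gene symbols, as read
#' from a GMT file or produced by the synthetic generator.
#'
#' @slot terms A \link[S4Vectors]{DataFrame} with columns \code{term_id}
#'   (unique), \code{term_name} and \code{category}.
#' @slot members A list, parallel to \code{terms}, of unique member gene
#'   symbols (non-empty).
#' @aliases GeneSetCollection
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(terms = "DFrame", members = "list"))

setValidity("GeneSetCollection", function(object) {
    tm <- object@terms
    need <- c("term_id", "term_name", "category")
    missing <- setdiff(need, colnames(tm))
    if (length(missing))
        return(sprintf("missing term column(s): %s", paste(missing, collapse = ", ")))
    if (nrow(tm) != length(object@members))
        return("terms and members must be parallel")
    if (anyDuplicated(tm$term_id))
        return("term_id must be unique")
    if (any(lengths(object@members) == 0L))
        return("every term must have at least one member")
    TRUE
})

#' Construct a GeneSetCollection
#'
#' Duplicate member symbols within a term are collapsed.
#'
#' @param termId,termName,category parallel character vectors describing the
#'   terms; \code{category} is recycled.
#' @param members list of character vectors of member gene symbols.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(termId = character(), termName = termId,
                              category = "GO", members = list()) {
    members <- lapply(members, function(m) unique(as.character(m)))
    tm <- DataFrame(term_id = as.character(termId),
                    term_name = as.character(termName),
                    category = rep_len(as.character(category),
                                       length(termId)))
    rownames(tm) <- NULL
    new("GeneSetCollection", terms = tm, members = unname(members))
}

#' Filter-cascade configuration
#'
#' Thresholds of the three-stage interactor filter. Defaults follow the
#' standard stringent IP-MS selection: a strict log2 bait/IgG LFQ ratio
#' threshold of 2, contaminant flagging for a repository max spectral count
#' over 200 or (number of IP experiments x max spectral count) over 100, and
#' union combination of replicate experiments.
#'
#' @slot log2RatioThreshold strict lower bound on log2(bait/control) LFQ.
#' @slot crapomeMaxCount strict repository max-spectral-count bound.
#' @slot crapomeProduct strict bound on experiments x max spectral count.
#' @slot pseudoIntensity pseudo-intensity added to both channels when forming
#'   a ratio with a non-zero control.
#' @slot nIpExperiments number of IP experiments in the study, the default
#'   multiplier of the product rule.
#' @slot productUsesRepositoryCount if \code{TRUE}, the product rule uses the
#'   repository's own detection count instead of \code{nIpExperiments}.
#' @slot replicateCombination \code{"union"} or \code{"intersection"}.
#' @aliases FilterConfig
#' @exportClass FilterConfig
setClass("FilterConfig",
         representation(log2RatioThreshold = "numeric",
                        crapomeMaxCount = "numeric",
                        crapomeProduct = "numeric",
                        pseudoIntensity = "numeric",
                        nIpExperiments = "integer",
                        productUsesRepositoryCount = "logical",
                        replicateCombination = "character"))

setValidity("FilterConfig", function(object) {
    if (object@log2RatioThreshold <= 0 || object@crapomeMaxCount <= 0 ||
        object@crapomeProduct <= 0)
        return("thresholds must be > 0")
    if (object@pseudoIntensity <= 0)
        return("pseudoIntensity must be > 0")
    if (object@nIpExperiments < 1L)
        return("nIpExperiments must be >= 1")
    if (!object@replicateCombination %in% c("union", "intersection"))
        return("replicateCombination must be 'union' or 'intersection'")
    TRUE
})

#' Construct a FilterConfig
#'
#' @param log2RatioThreshold,crapomeMaxCount,crapomeProduct,pseudoIntensity
#'   numeric thresholds, see \linkS4class{FilterConfig}.
#' @param nIpExperiments integer count of IP experiments in the study.
#' @param productUsesRepositoryCount logical, see \linkS4class{FilterConfig}.
#' @param replicateCombination \code{"union"} (default) or
#'   \code{"intersection"}.
#' @return A \linkS4class{FilterConfig}.
#' @export
FilterConfig <- function(log2RatioThreshold = 2, crapomeMaxCount = 200,
                         crapomeProduct = 100, pseudoIntensity = 1,
                         nIpExperiments = 2L,
                         productUsesRepositoryCount = FALSE,
                         replicateCombination = c("union", "intersection")) {
    new("FilterConfig",
        log2RatioThreshold = log2RatioThreshold,
        crapomeMaxCount = crapomeMaxCount,
        crapomeProduct = crapomeProduct,
        pseudoIntensity = pseudoIntensity,
        nIpExperiments = as.integer(nIpExperiments),
        productUsesRepositoryCount = productUsesRepositoryCount,
        replicateCombination = match.arg(replicateCombination))
}

#' Filter-cascade accounting
#'
#' Stage-by-stage accounting of the interactor filter: proteins identified,
#' removed by the lineage (transcriptome-presence) filter, passing the
#' enrichment filter, flagged as contaminants, and retained.
#'
#' @slot nIdentified,nLineageRemoved,nAfterLineage,nEnrichmentPass,nContaminants,nFinal
#'   non-negative integers satisfying
#'   \code{nAfterLineage == nIdentified - nLineageRemoved},
#'   \code{nFinal == nEnrichmentPass - nContaminants} and
#'   \code{nEnrichmentPass <= nAfterLineage}.
#' @aliases FilterLedger
#' @exportClass FilterLedger
setClass("FilterLedger",
         representation(nIdentified = "integer", nLineageRemoved = "integer",
                        nAfterLineage = "integer", nEnrichmentPass = "integer",
                        nContaminants = "integer", nFinal = "integer"))

setValidity("FilterLedger", function(object) {
    v <- c(object@nIdentified, object@nLineageRemoved, object@nAfterLineage,
           object@nEnrichmentPass, object@nContaminants, object@nFinal)
    if (any(v < 0L))
        return("ledger counts must be non-negative")
    if (object@nAfterLineage != object@nIdentified - object@nLineageRemoved)
        return("nAfterLineage must equal nIdentified - nLineageRemoved")
    if (object@nFinal != object@nEnrichmentPass - object@nContaminants)
        return("nFinal must equal nEnrichmentPass - nContaminants")
    if (object@nEnrichmentPass > object@nAfterLineage)
        return("nEnrichmentPass cannot exceed nAfterLineage")
    TRUE
})

#' Build a FilterLedger from the four observed counts
#'
#' The two derived counts (\code{nAfterLineage}, \code{nFinal}) are computed
#' from the accounting identities, so the returned ledger is consistent by
#' construction or errors if the inputs cannot be.
#'
#' @param nIdentified proteins identified by MS.
#' @param nLineageRemoved proteins removed for absence from the lineage
#'   transcriptome.
#' @param nEnrichmentPass proteins passing the bait/IgG enrichment rule.
#' @param nContaminants enrichment-passing proteins flagged via the
#'   contaminant repository.
#' @return A \linkS4class{FilterLedger}.
#' @examples
#' ledgerFromCounts(2760, 217, 1265, 54)  # nFinal 1211
#' @export
ledgerFromCounts <- function(nIdentified, nLineageRemoved, nEnrichmentPass,
                             nContaminants) {
    new("FilterLedger",
        nIdentified = as.integer(nIdentified),
        nLineageRemoved = as.integer(nLineageRemoved),
        nAfterLineage = as.integer(nIdentified - nLineageRemoved),
        nEnrichmentPass = as.integer(nEnrichmentPass),
        nContaminants = as.integer(nContaminants),
        nFinal = as.integer(nEnrichmentPass - nContaminants))
}

#' Per-protein interactor calls with accounting
#'
#' Result of \code{\link{runCascade}}: one row per (protein, stage) with the
#' three independent filter flags and the final call, the pooled
#' \linkS4class{FilterLedger}, per-stage ledgers, and the number of
#' control-only records dropped before filtering.
#'
#' @slot calls A \link[S4Vectors]{DataFrame} with columns \code{protein_id},
#'   \code{gene_symbol}, \code{stage}, \code{detected_in_control},
#'   \code{log2_enrichment} (NA when the control is undetected),
#'   \code{transcriptome_pass}, \code{enrichment_pass}, \code{contaminant},
#'   \code{final_pass}.
#' @slot ledger pooled \linkS4class{FilterLedger} (unique proteins across
#'   stages).
#' @slot stageLedgers named list of per-stage \linkS4class{FilterLedger}s.
#' @slot nControlOnly integer count of proteins seen only in the control
#'   channel and dropped.
#' @aliases InteractorCalls
#' @exportClass InteractorCalls
setClass("InteractorCalls",
         representation(calls = "DFrame", ledger = "FilterLedger",
                        stageLedgers = "list", nControlOnly = "integer"))

setValidity("InteractorCalls", function(object) {
    cl <- object@calls
    if (nrow(cl) &&
        !all(cl$final_pass == (cl$transcriptome_pass & cl$enrichment_pass &
                               !cl$contaminant)))
        return("final_pass must equal transcriptome_pass & enrichment_pass & !contaminant")
    TRUE
})

#' Two-set Venn partition
#'
#' @slot shared elements in both sets.
#' @slot aSpecific elements only in the first set.
#' @slot bSpecific elements only in the second set.
#' @aliases VennPartition
#' @exportClass VennPartition
setClass("VennPartition",
         representation(shared = "character", aSpecific = "character",
                        bSpecific = "character"))

setValidity("VennPartition", function(object) {
    if (length(intersect(object@shared, object@aSpecific)) ||
        length(intersect(object@shared, object@bSpecific)) ||
        length(intersect(object@aSpecific, object@bSpecific)))
        return("partition sets must be pairwise disjoint")
    TRUE
})

#' Kappa-linked term network
#'
#' Enriched terms as nodes, joined by edges wherever the kappa similarity of
#' their query-gene memberships reaches the threshold, plus a bipartite layer
#' of term-protein membership edges.
#'
#' @slot nodes A \link[S4Vectors]{DataFrame}: \code{term_id},
#'   \code{term_name}, \code{p_value}, \code{fdr}, \code{size} (query genes in
#'   the term) and \code{neg_log10_p} (the node-size attribute).
#' @slot termEdges A \link[S4Vectors]{DataFrame}: \code{from}, \code{to},
#'   \code{kappa}.
#' @slot proteinEdges A \link[S4Vectors]{DataFrame}: \code{term_id},
#'   \code{gene_symbol}.
#' @aliases TermNetwork
#' @exportClass TermNetwork
setClass("TermNetwork",
         representation(nodes = "DFrame", termEdges = "DFrame",
                        proteinEdges = "DFrame"))

setValidity("TermNetwork", function(object) {
    ed <- object@termEdges
    if (nrow(ed)) {
        if (any(ed$kappa < -1 - 1e-12) || any(ed$kappa > 1 + 1e-12))
            return("kappa must lie in [-1, 1]")
        if (!all(c(ed$from, ed$to) %in% object@nodes$term_id))
            return("term edges must reference known nodes")
    }
    pe <- object@proteinEdges
    if (nrow(pe) && !all(pe$term_id %in% object@nodes$term_id))
        return("protein edges must reference known nodes")
    TRUE
})

#' Synthetic-study parameters
#'
#' Parameters of the ground-truth generator emulating the study design: two
#' IP replicate experiments per stage, a two-stage transcriptome in
#' triplicate, log-normal LFQ intensities with bait-specific enrichment for
#' true interactors, repository contaminants with high spectral counts, and a
#' negative-binomial transcriptome with a set fraction of DE genes.
#'
#' @slot nProteins number of proteins identified per study.
#' @slot fracTrueInteractors,fracContaminants,fracNonLineage label fractions
#'   (the remainder is non-specific background).
#' @slot fracSharedInteractors,fracOpcSpecific among true interactors, the
#'   fraction present at both stages and the fraction specific to OPC (the
#'   rest are OL-specific).
#' @slot baitEnrichmentLog2Mean,baitEnrichmentLog2Sd log2 bait-over-control
#'   enrichment distribution of true interactors.
#' @slot backgroundLfqLog10Mean,backgroundLfqLog10Sd log10 LFQ intensity
#'   distribution of protein abundance.
#' @slot replicateNoiseLog10Sd per-replicate, per-channel log10 measurement
#'   noise.
#' @slot detectionProb per-replicate, per-channel detection probability.
#' @slot fracControlUndetected fraction of true interactors never detected in
#'   the control channel.
#' @slot nReplicates IP replicate experiments per stage.
#' @slot nGenes,nRnaReplicates transcriptome size and samples per stage.
#' @slot fracDe,deLog2fc fraction of DE genes and their planted |log2 FC|.
#' @slot nbDispersion negative-binomial dispersion of counts.
#' @slot nTerms,nPlantedTerms,plantedTermPurity gene-set collection size,
#'   number of planted (interactor-enriched) terms and their interactor-gene
#'   fraction.
#' @slot seed integer seed; the same seed reproduces every table exactly.
#' @aliases SimulationParams
#' @exportClass SimulationParams
setClass("SimulationParams",
         representation(nProteins = "integer",
                        fracTrueInteractors = "numeric",
                        fracContaminants = "numeric",
                        fracNonLineage = "numeric",
                        fracSharedInteractors = "numeric",
                        fracOpcSpecific = "numeric",
                        baitEnrichmentLog2Mean = "numeric",
                        baitEnrichmentLog2Sd = "numeric",
                        backgroundLfqLog10Mean = "numeric",
                        backgroundLfqLog10Sd = "numeric",
                        replicateNoiseLog10Sd = "numeric",
                        detectionProb = "numeric",
                        fracControlUndetected = "numeric",
                        nReplicates = "integer",
                        nGenes = "integer",
                        nRnaReplicates = "integer",
                        fracDe = "numeric",
                        deLog2fc = "numeric",
                        nbDispersion = "numeric",
                        nTerms = "integer",
                        nPlantedTerms = "integer",
                        plantedTermPurity = "numeric",
                        seed = "integer"))

setValidity("SimulationParams", function(object) {
    fr <- c(object@fracTrueInteractors, object@fracContaminants,
            object@fracNonLineage, object@fracSharedInteractors,
            object@fracOpcSpecific, object@fracDe, object@detectionProb,
            object@fracControlUndetected, object@plantedTermPurity)
    if (any(fr < 0) || any(fr > 1))
        return("fractions and probabilities must lie in [0, 1]")
    if (object@fracTrueInteractors + object@fracContaminants +
        object@fracNonLineage > 1)
        return("label fractions must sum to <= 1")
    if (object@fracSharedInteractors + object@fracOpcSpecific > 1)
        return("fracSharedInteractors + fracOpcSpecific must be <= 1")
    sc <- c(object@baitEnrichmentLog2Sd, object@backgroundLfqLog10Sd,
            object@replicateNoiseLog10Sd, object@deLog2fc)
    if (any(sc <= 0))
        return("scale parameters must be > 0")
    if (object@nbDispersion < 0)
        return("nbDispersion must be >= 0")
    if (object@nProteins < 1L || object@nGenes < object@nProteins ||
        object@nReplicates < 1L || object@nRnaReplicates < 1L)
        return("invalid size parameters (need nGenes >= nProteins)")
    if (object@nPlantedTerms > object@nTerms)
        return("nPlantedTerms cannot exceed nTerms")
    TRUE
})

#' Construct SimulationParams
#'
#' All arguments default to the study-like scenario documented in
#' \linkS4class{SimulationParams}.
#'
#' @param nProteins,fracTrueInteractors,fracContaminants,fracNonLineage see
#'   \linkS4class{SimulationParams}.
#' @param fracSharedInteractors,fracOpcSpecific see
#'   \linkS4class{SimulationParams}.
#' @param baitEnrichmentLog2Mean,baitEnrichmentLog2Sd see
#'   \linkS4class{SimulationParams}.
#' @param backgroundLfqLog10Mean,backgroundLfqLog10Sd,replicateNoiseLog10Sd
#'   see \linkS4class{SimulationParams}.
#' @param detectionProb,fracControlUndetected,nReplicates see
#'   \linkS4class{SimulationParams}.
#' @param nGenes,nRnaReplicates,fracDe,deLog2fc,nbDispersion see
#'   \linkS4class{SimulationParams}.
#' @param nTerms,nPlantedTerms,plantedTermPurity,seed see
#'   \linkS4class{SimulationParams}.
#' @return A \linkS4class{SimulationParams}.
#' @export
SimulationParams <- function(nProteins = 600L,
                             fracTrueInteractors = 0.25,
                             fracContaminants = 0.08,
                             fracNonLineage = 0.07,
                             fracSharedInteractors = 0.45,
                             fracOpcSpecific = 0.30,
                             baitEnrichmentLog2Mean = 3.5,
                             baitEnrichmentLog2Sd = 0.8,
                             backgroundLfqLog10Mean = 5,
                             backgroundLfqLog10Sd = 0.5,
                             replicateNoiseLog10Sd = 0.1,
                             detectionProb = 0.95,
                             fracControlUndetected = 0.3,
                             nReplicates = 2L,
                             nGenes = 3000L,
                             nRnaReplicates = 3L,
                             fracDe = 0.12,
                             deLog2fc = 2,
                             nbDispersion = 0.1,
                             nTerms = 40L,
                             nPlantedTerms = 4L,
                             plantedTermPurity = 0.7,
                             seed = 1L) {
    new("SimulationParams",
        nProteins = as.integer(nProteins),
        fracTrueInteractors = fracTrueInteractors,
        fracContaminants = fracContaminants,
        fracNonLineage = fracNonLineage,
        fracSharedInteractors = fracSharedInteractors,
        fracOpcSpecific = fracOpcSpecific,
        baitEnrichmentLog2Mean = baitEnrichmentLog2Mean,
        baitEnrichmentLog2Sd = baitEnrichmentLog2Sd,
        backgroundLfqLog10Mean = backgroundLfqLog10Mean,
        backgroundLfqLog10Sd = backgroundLfqLog10Sd,
        replicateNoiseLog10Sd = replicateNoiseLog10Sd,
        detectionProb = detectionProb,
        fracControlUndetected = fracControlUndetected,
        nReplicates = as.integer(nReplicates),
        nGenes = as.integer(nGenes),
        nRnaReplicates = as.integer(nRnaReplicates),
        fracDe = fracDe,
        deLog2fc = deLog2fc,
        nbDispersion = nbDispersion,
        nTerms = as.integer(nTerms),
        nPlantedTerms = as.integer(nPlantedTerms),
        plantedTermPurity = plantedTermPurity,
        seed = as.integer(seed))
}

#' A complete synthetic study with ground truth
#'
#' @slot quant named list (per stage) of lists of replicate
#'   \linkS4class{QuantTable}s.
#' @slot crapome a \linkS4class{CrapomeTable} covering every protein.
#' @slot expression a \linkS4class{StageExpression}.
#' @slot geneSets a \linkS4class{GeneSetCollection}.
#' @slot tfList character vector of transcription-factor gene symbols.
#' @slot truth list with \code{proteinLabel} (named), \code{geneSymbol}
#'   (named map protein -> gene), \code{stageMembership},
#'   \code{deClass} (named), \code{expressedGenes}, \code{plantedTerms}.
#' @slot params the \linkS4class{SimulationParams} used.
#' @aliases SyntheticStudy
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
         representation(quant = "list", crapome = "CrapomeTable",
                        expression = "StageExpression",
                        geneSets = "GeneSetCollection",
                        tfList = "character", truth = "list",
                        params = "SimulationParams"))

#' Orchestrated-run configuration
#'
#' @slot simulation \linkS4class{SimulationParams} driving input generation.
#' @slot filter \linkS4class{FilterConfig}.
#' @slot deFdr,deLfc differential-expression thresholds (FDR and |log2 FC|).
#' @slot enrichAlpha raw-p significance level for term enrichment.
#' @slot kappaThreshold minimum kappa for a term-term edge.
#' @slot topTerms number of top terms reported per stage.
#' @slot seed integer seed of the run.
#' @slot logLevel \code{"info"} or \code{"quiet"}.
#' @aliases PipelineConfig
#' @exportClass PipelineConfig
setClass("PipelineConfig",
         representation(simulation = "SimulationParams",
                        filter = "FilterConfig",
                        deFdr = "numeric", deLfc = "numeric",
                        enrichAlpha = "numeric", kappaThreshold = "numeric",
                        topTerms = "integer", seed = "integer",
                        logLevel = "character"))

setValidity("PipelineConfig", function(object) {
    if (object@deFdr <= 0 || object@deFdr > 1)
        return("deFdr must lie in (0, 1]")
    if (object@enrichAlpha <= 0 || object@enrichAlpha > 1)
        return("enrichAlpha must lie in (0, 1]")
    if (object@kappaThreshold < -1 || object@kappaThreshold > 1)
        return("kappaThreshold must lie in [-1, 1]")
    if (object@deLfc < 0)
        return("deLfc must be >= 0")
    if (object@topTerms < 1L)
        return("topTerms must be >= 1")
    if (!object@logLevel %in% c("info", "quiet"))
        return("logLevel must be 'info' or 'quiet'")
    TRUE
})
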