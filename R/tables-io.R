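#' @include AllClasses.R
NULL

.read_tsv <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "",
                      fileEncoding = "UTF-8")
}

.write_tsv <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
}

#' Read a protein quantification table
#'
#' Reads a TSV with one row per (protein, experiment, channel). A dialect
#' mapping adapts foreign column headers (e.g. a MaxQuant-style export) to
#' the canonical names; unknown columns are ignored, never silently dropped
#' rows: any invalid row raises an error naming its position.
#'
#' @param path TSV file with a header row.
#' @param dialect optional named character vector mapping canonical column
#'   names (\code{protein_id}, \code{gene_symbol}, \code{experiment_id},
#'   \code{channel}, \code{lfq_intensity}, \code{spectral_count}) to the
#'   column names used in the file.
#' @return A \linkS4class{QuantTable}.
#' @seealso \code{\link{writeQuantTable}}
#' @export
readQuantTable <- function(path, dialect = NULL) {
    df <- .read_tsv(path)
    if (!is.null(dialect)) {
        for (canon in names(dialect)) {
            if (!dialect[[canon]] %in% colnames(df))
                stop(sprintf("quant table format error: missing column(s): %s",
                             dialect[[canon]]), call. = FALSE)
            colnames(df)[colnames(df) == dialect[[canon]]] <- canon
        }
    }
    missing <- setdiff(.QUANT_COLUMNS, colnames(df))
    if (length(missing))
        stop(sprintf("quant table format error: missing column(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    bad <- which(!is.finite(df$lfq_intensity) | df$lfq_intensity < 0)
    if (length(bad))
        stop(sprintf("quant table validation error: negative or non-finite lfq_intensity at row %d",
                     bad[1]), call. = FALSE)
    bad <- which(df$spectral_count < 0)
    if (length(bad))
        stop(sprintf("quant table validation error: negative spectral_count at row %d",
                     bad[1]), call. = FALSE)
    QuantTable(df)
}

#' Write a protein quantification table
#'
#' @param x a \linkS4class{QuantTable}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeQuantTable <- function(x, path) {
    stopifnot(is(x, "QuantTable"))
    .write_tsv(quantRecords(x), path)
    invisible(path)
}

#' Read a contaminant-repository table
#'
#' @param path TSV with columns \code{protein_id}, \code{n_experiments},
#'   \code{max_spectral_count}, \code{avg_spectral_count}.
#' @return A \linkS4class{CrapomeTable}. An empty (header-only) file yields
#'   an empty table with a warning.
#' @export
readCrapome <- function(path) {
    df <- .read_tsv(path)
    missing <- setdiff(.CRAPOME_COLUMNS, colnames(df))
    if (length(missing))
        stop(sprintf("contaminant table format error: missing column(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    if (nrow(df) == 0L) {
        warning("contaminant table is empty", call. = FALSE)
        return(CrapomeTable())
    }
    bad <- which(df$avg_spectral_count > df$max_spectral_count)
    if (length(bad))
        stop(sprintf("contaminant table validation error: avg_spectral_count > max_spectral_count at row %d",
                     bad[1]), call. = FALSE)
    CrapomeTable(df)
}

#' Write a contaminant-repository table
#'
#' @param x a \linkS4class{CrapomeTable}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeCrapome <- function(x, path) {
    stopifnot(is(x, "CrapomeTable"))
    .write_tsv(crapomeRecords(x), path)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: \code{term_id TAB description TAB gene TAB gene ...},
#' one term per line. Duplicate member symbols within a term are collapsed;
#' duplicate term ids are an error.
#'
#' @param path GMT file.
#' @param category category label attached to every term (GMT itself carries
#'   none); recycled.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, category = "GO") {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop(sprintf("GMT format error: fewer than 3 fields at line %d",
                     short[1]), call. = FALSE)
    ids <- vapply(fields, `[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop(sprintf("GMT format error: duplicate term_id '%s'",
                     ids[duplicated(ids)][1]), call. = FALSE)
    GeneSetCollection(
        termId = ids,
        termName = vapply(fields, `[`, character(1), 2L),
        category = category,
        members = lapply(fields, function(f) f[-(1:2)]))
}

#' Write a GeneSetCollection as GMT
#'
#' The term name is stored in the GMT description field; the category label
#' is not representable in GMT and is dropped.
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output GMT path.
#' @return Invisibly, \code{path}.
#' @export
writeGmt <- function(x, path) {
    stopifnot(is(x, "GeneSetCollection"))
    tm <- gsTerms(x)
    lines <- vapply(seq_len(nrow(tm)), function(i) {
        paste(c(tm$term_id[i], tm$term_name[i], x@members[[i]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path, useBytes = FALSE)
    invisible(path)
}

#' Read a stage-labelled expression count matrix
#'
#' Expects a TSV with columns \code{gene_id}, \code{gene_length_bp} and one
#' integer count column per sample. Stage labels come either from
#' \code{stageMap} or, by default, from the sample-name prefix before the
#' first underscore (e.g. \code{OPC_1}).
#'
#' @param path TSV file.
#' @param stageMap optional named character vector, sample name -> stage.
#' @return A \linkS4class{StageExpression}.
#' @export
readExpression <- function(path, stageMap = NULL) {
    df <- .read_tsv(path)
    need <- c("gene_id", "gene_length_bp")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop(sprintf("expression table format error: missing column(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    samples <- setdiff(colnames(df), need)
    if (!length(samples))
        stop("expression table format error: no sample columns", call. = FALSE)
    counts <- as.matrix(df[, samples, drop = FALSE])
    rownames(counts) <- df$gene_id
    if (is.null(stageMap))
        stageMap <- structure(sub("_.*$", "", samples), names = samples)
    StageExpression(counts, geneLength = df$gene_length_bp,
                    stage = unname(stageMap[samples]))
}

#' Write a StageExpression as TSV
#'
#' Sample columns are written as \code{<stage>_<sample>} when the sample name
#' does not already encode its stage, so the file round-trips through
#' \code{\link{readExpression}} without a stage map.
#'
#' @param x a \linkS4class{StageExpression}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeExpression <- function(x, path) {
    stopifnot(is(x, "StageExpression"))
    cts <- SummarizedExperiment::assay(x, "counts")
    stage <- SummarizedExperiment::colData(x)$stage
    nm <- colnames(cts)
    fix <- sub("_.*$", "", nm) != stage
    nm[fix] <- paste0(stage[fix], "_", nm[fix])
    df <- data.frame(gene_id = rownames(cts),
                     gene_length_bp = SummarizedExperiment::rowData(x)$gene_length_bp,
                     cts, check.names = FALSE)
    colnames(df)[-(1:2)] <- nm
    .write_tsv(df, path)
    invisible(path)
}

#' Read a transcription-factor list
#'
#' One gene symbol per line; blank lines and duplicates are dropped.
#'
#' @param path plain-text file.
#' @return Character vector of symbols.
#' @export
readTfList <- function(path) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    x <- trimws(readLines(path, encoding = "UTF-8"))
    unique(x[nzchar(x)])
}

#' Serialize a term network
#'
#' \code{"graphml"} writes the full network (term and protein nodes, node
#' attributes, kappa edge weights) through \pkg{igraph};
#' \code{"tsv"} writes a plain edge list (\code{from}, \code{to},
#' \code{edge_type}, \code{kappa}) that round-trips through
#' \code{\link{readNetworkEdges}}.
#'
#' @param network a \linkS4class{TermNetwork}.
#' @param path output file.
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @export
writeNetwork <- function(network, path, format = c("graphml", "tsv")) {
    stopifnot(is(network, "TermNetwork"))
    if (length(format) == 1L && !format %in% c("graphml", "tsv"))
        stop(sprintf("unsupported network format '%s'", format), call. = FALSE)
    format <- match.arg(format)
    ed <- .network_edge_frame(network)
    if (format == "tsv") {
        .write_tsv(ed, path)
        return(invisible(path))
    }
    g <- asIgraph(network)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

.network_edge_frame <- function(network) {
    te <- as.data.frame(termEdges(network))
    pe <- as.data.frame(proteinEdges(network))
    parts <- list(data.frame(from = character(), to = character(),
                             edge_type = character(), kappa = numeric()))
    if (nrow(te))
        parts <- c(parts, list(data.frame(from = te$from, to = te$to,
                                          edge_type = "kappa",
                                          kappa = te$kappa)))
    if (nrow(pe))
        parts <- c(parts, list(data.frame(from = pe$term_id,
                                          to = pe$gene_symbol,
                                          edge_type = "membership",
                                          kappa = NA_real_)))
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    out
}

#' Convert a TermNetwork to an igraph graph
#'
#' Term nodes carry \code{p_value}, \code{fdr}, \code{size} and
#' \code{neg_log10_p}; protein nodes are flagged by \code{node_type}.
#'
#' @param network a \linkS4class{TermNetwork}.
#' @return An undirected \pkg{igraph} graph.
#' @export
asIgraph <- function(network) {
    stopifnot(is(network, "TermNetwork"))
    nd <- as.data.frame(networkNodes(network))
    pe <- as.data.frame(proteinEdges(network))
    proteins <- unique(pe$gene_symbol)
    vertices <- rbind(
        if (nrow(nd)) data.frame(name = nd$term_id, node_type = "term",
                                 term_name = nd$term_name,
                                 p_value = nd$p_value, fdr = nd$fdr,
                                 size = nd$size,
                                 neg_log10_p = nd$neg_log10_p)
        else NULL,
        if (length(proteins)) data.frame(name = proteins,
                                         node_type = "protein",
                                         term_name = NA_character_,
                                         p_value = NA_real_, fdr = NA_real_,
                                         size = NA_real_,
                                         neg_log10_p = NA_real_)
        else NULL,
        make.row.names = FALSE)
    ed <- .network_edge_frame(network)
    if (is.null(vertices))
        return(igraph::make_empty_graph(0, directed = FALSE))
    igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vertices)
}

#' Read a TSV network edge list
#'
#' @param path file written by \code{writeNetwork(..., format = "tsv")}.
#' @return A \code{data.frame} with columns \code{from}, \code{to},
#'   \code{edge_type}, \code{kappa}.
#' @export
readNetworkEdges <- function(path) {
    df <- .read_tsv(path)
    need <- c("from", "to", "edge_type", "kappa")
    missing <- setdiff(need, colnames(df))
    if (length(missing))
        stop(sprintf("edge list format error: missing column(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    df$kappa <- as.numeric(df$kappa)
    df
}

#' Write / read a filter ledger as JSON
#'
#' @param ledger a \linkS4class{FilterLedger}.
#' @param path JSON path.
#' @return \code{writeLedger} returns \code{path} invisibly;
#'   \code{readLedger} returns a \linkS4class{FilterLedger}.
#' @export
writeLedger <- function(ledger, path) {
    stopifnot(is(ledger, "FilterLedger"))
    jsonlite::write_json(as.list(ledgerCounts(ledger)), path,
                         auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeLedger
#' @export
readLedger <- function(path) {
    v <- jsonlite::read_json(path, simplifyVector = TRUE)
    ledgerFromCounts(v$n_identified, v$n_lineage_removed,
                     v$n_enrichment_pass, v$n_contaminants)
}
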