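#' @include AllClasses.R
NULL

#' RPKM from a stage-labelled count matrix
#'
#' \code{rpkm = count * 1e9 / (library_size * gene_length_bp)} with library
#' size the per-sample count total.
#'
#' @param matrix a \linkS4class{StageExpression}.
#' @return Numeric gene x sample matrix of RPKM values.
#' @export
computeRpkm <- function(matrix) {
    stopifnot(is(matrix, "StageExpression"))
    cts <- SummarizedExperiment::assay(matrix, "counts")
    libsize <- colSums(cts)
    if (any(libsize <= 0))
        stop(sprintf("zero library size in sample(s): %s",
                     paste(colnames(cts)[libsize <= 0], collapse = ", ")),
             call. = FALSE)
    len <- SummarizedExperiment::rowData(matrix)$gene_length_bp
    sweep(cts, 2, libsize, `/`) * 1e9 / len
}

#' Common negative-binomial dispersion by adjusted profile likelihood
#'
#' Estimates a single dispersion shared across genes from within-stage
#' replicate variation, maximizing the Cox-Reid adjusted profile likelihood
#' (the adjustment removes the bias from estimating a per-gene, per-stage
#' mean on few replicates). Returns 0 for Poisson-like data.
#'
#' @param matrix a \linkS4class{StageExpression}.
#' @param minMeanCount genes below this mean raw count are ignored.
#' @return Non-negative dispersion estimate (variance = mu + phi * mu^2).
#' @export
estimateCommonDispersion <- function(matrix, minMeanCount = 1) {
    stopifnot(is(matrix, "StageExpression"))
    cts <- SummarizedExperiment::assay(matrix, "counts")
    stage <- SummarizedExperiment::colData(matrix)$stage
    s <- colSums(cts)
    keep <- rowMeans(cts) >= minMeanCount
    if (!any(keep))
        return(0)
    groups <- split(seq_along(stage), stage)
    groups <- groups[lengths(groups) >= 2L]
    if (!length(groups))
        return(0)
    nll <- function(lphi) {
        phi <- exp(lphi)
        tot <- 0
        for (g in groups) {
            q <- rowSums(cts[keep, g, drop = FALSE]) / sum(s[g])
            m <- pmax(outer(q, s[g]), 1e-8)
            v <- m + phi * m^2
            ll <- rowSums(stats::dnbinom(cts[keep, g, drop = FALSE],
                                         mu = m, size = 1 / phi, log = TRUE))
            cr <- 0.5 * log(rowSums(sweep(1 / v, 2, s[g]^2, `*`)))
            tot <- tot + sum(ll - cr)
        }
        -tot
    }
    phi <- exp(stats::optimize(nll, c(log(1e-8), log(10)))$minimum)
    if (phi < 1e-6) 0 else phi
}

#' Two-stage differential expression on pooled counts
#'
#' For each gene, counts are pooled within stage and compared as proportions
#' of the pooled library sizes with a two-proportion z-statistic whose
#' variance is computed under a negative-binomial model with a common
#' dispersion estimated by \code{\link{estimateCommonDispersion}} (for
#' Poisson-like data the statistic reduces to the classic two-proportion
#' z-test). P-values are two-sided normal tails, adjusted by
#' Benjamini-Hochberg. The log2 fold change is computed from mean RPKM with a
#' pseudo-RPKM of 1 added to both means; positive values are OL-up. The DE
#' class is \code{OL_up} when \code{fdr < fdrThreshold} and
#' \code{log2_fold_change > lfcThreshold}, \code{OPC_up} for the mirrored
#' condition, otherwise \code{NS}. Genes with zero counts in all samples get
#' p = 1, class NS and \code{all_zero = TRUE}.
#'
#' @param matrix a \linkS4class{StageExpression}.
#' @param fdrThreshold,lfcThreshold DE thresholds (defaults 0.05 and 1).
#' @param dispersion optional fixed dispersion; default estimates it.
#' @return A \link[S4Vectors]{DataFrame}: \code{gene_id},
#'   \code{mean_rpkm_opc}, \code{mean_rpkm_ol}, \code{log2_fold_change},
#'   \code{p_value}, \code{fdr}, \code{de_class}, \code{all_zero}.
#' @export
deTest <- function(matrix, fdrThreshold = 0.05, lfcThreshold = 1,
                   dispersion = NULL) {
    stopifnot(is(matrix, "StageExpression"))
    cts <- SummarizedExperiment::assay(matrix, "counts")
    stage <- SummarizedExperiment::colData(matrix)$stage
    g1 <- which(stage == "OPC")
    g2 <- which(stage == "OL")
    if (!length(g1) || !length(g2))
        stop("deTest needs at least one sample per stage", call. = FALSE)
    s <- colSums(cts)
    if (is.null(dispersion))
        dispersion <- estimateCommonDispersion(matrix)
    X1 <- rowSums(cts[, g1, drop = FALSE])
    X2 <- rowSums(cts[, g2, drop = FALSE])
    n1 <- sum(s[g1]); n2 <- sum(s[g2])
    q <- (X1 + X2) / (n1 + n2)
    mu1 <- outer(q, s[g1]); mu2 <- outer(q, s[g2])
    V1 <- rowSums(mu1 + dispersion * mu1^2) / n1^2
    V2 <- rowSums(mu2 + dispersion * mu2^2) / n2^2
    z <- (X2 / n2 - X1 / n1) / sqrt(V1 + V2)
    p <- 2 * stats::pnorm(-abs(z))
    all_zero <- X1 + X2 == 0
    p[all_zero] <- 1
    if (any(all_zero))
        message(sprintf("%d gene(s) with zero counts in all samples (p = 1, NS)",
                        sum(all_zero)))
    fdr <- stats::p.adjust(p, method = "BH")
    rpkm <- computeRpkm(matrix)
    m_opc <- rowMeans(rpkm[, g1, drop = FALSE])
    m_ol <- rowMeans(rpkm[, g2, drop = FALSE])
    lfc <- log2((m_ol + 1) / (m_opc + 1))
    cls <- rep("NS", nrow(cts))
    cls[fdr < fdrThreshold & lfc > lfcThreshold] <- "OL_up"
    cls[fdr < fdrThreshold & lfc < -lfcThreshold] <- "OPC_up"
    cls[all_zero] <- "NS"
    DataFrame(gene_id = rownames(cts), mean_rpkm_opc = unname(m_opc),
              mean_rpkm_ol = unname(m_ol), log2_fold_change = unname(lfc),
              p_value = unname(p), fdr = unname(fdr), de_class = cls,
              all_zero = unname(all_zero), row.names = NULL)
}

#' Two-set Venn partition
#'
#' @param setA,setB character vectors (duplicates ignored).
#' @return A \linkS4class{VennPartition} with \code{shared = A n B},
#'   \code{aSpecific = A \\ B}, \code{bSpecific = B \\ A}.
#' @export
vennPartition <- function(setA, setB) {
    setA <- unique(as.character(setA))
    setB <- unique(as.character(setB))
    new("VennPartition",
        shared = intersect(setA, setB),
        aSpecific = setdiff(setA, setB),
        bSpecific = setdiff(setB, setA))
}

#' Cross-tabulate stage-specific interactors by expression class
#'
#' For each stage-specific interactor set, counts the members up-regulated in
#' their own stage, up-regulated in the other stage, and without significant
#' expression difference (NS). Members missing from the DE table are counted
#' as NS and logged. Percentages are reported to two decimals.
#'
#' @param specific named list with elements \code{OPC} and \code{OL}: the
#'   stage-specific interactor gene sets.
#' @param de DE table from \code{\link{deTest}} (or any table with
#'   \code{gene_id} and \code{de_class}).
#' @return A \link[S4Vectors]{DataFrame} with one row per stage:
#'   \code{stage}, \code{n_total}, \code{n_up_own}, \code{n_up_other},
#'   \code{n_ns}, and the matching two-decimal percentages.
#' @export
stageCrosstab <- function(specific, de) {
    stopifnot(all(c("OPC", "OL") %in% names(specific)))
    cls <- structure(as.character(de$de_class), names = de$gene_id)
    rows <- lapply(c("OPC", "OL"), function(stage) {
        genes <- unique(as.character(specific[[stage]]))
        g_cls <- cls[genes]
        if (anyNA(g_cls)) {
            message(sprintf("%d %s-specific gene(s) missing from DE table; counted as NS",
                            sum(is.na(g_cls)), stage))
            g_cls[is.na(g_cls)] <- "NS"
        }
        own <- paste0(stage, "_up")
        other <- paste0(setdiff(c("OPC", "OL"), stage), "_up")
        n <- length(genes)
        counts <- c(sum(g_cls == own), sum(g_cls == other), sum(g_cls == "NS"))
        pct <- if (n) round(100 * counts / n, 2) else c(0, 0, 0)
        DataFrame(stage = stage, n_total = n,
                  n_up_own = counts[1], n_up_other = counts[2],
                  n_ns = counts[3], pct_up_own = pct[1],
                  pct_up_other = pct[2], pct_ns = pct[3])
    })
    do.call(rbind, rows)
}

#' Clustered log2 expression matrix for heatmap display
#'
#' Builds \code{log2(rpkm + 1)} for the requested genes, orders rows and
#' columns by agglomerative hierarchical clustering (average linkage,
#' Euclidean distance; ties resolved deterministically by input order, as in
#' \code{\link[stats]{hclust}}), and additionally returns a display copy
#' clipped to \code{[0, 8]}. Analysis should use the unclipped matrix.
#'
#' @param rpkm numeric gene x sample RPKM matrix (rownames = genes).
#' @param genes character vector of genes to include, all present in
#'   \code{rpkm}.
#' @param clipRange display clip range, default \code{c(0, 8)}.
#' @return List with \code{matrix} (unclipped log2), \code{display}
#'   (clipped), \code{rowOrder}, \code{colOrder} (integer permutations) and
#'   the two \code{hclust} trees (\code{rowTree}, \code{colTree}; NULL when
#'   fewer than 2 rows/columns).
#' @export
heatmapMatrix <- function(rpkm, genes, clipRange = c(0, 8)) {
    genes <- as.character(genes)
    absent <- setdiff(genes, rownames(rpkm))
    if (length(absent))
        stop(sprintf("gene(s) absent from rpkm matrix: %s",
                     paste(absent, collapse = ", ")), call. = FALSE)
    m <- log2(rpkm[genes, , drop = FALSE] + 1)
    rowTree <- colTree <- NULL
    rowOrder <- seq_len(nrow(m))
    colOrder <- seq_len(ncol(m))
    if (nrow(m) >= 2L) {
        rowTree <- stats::hclust(stats::dist(m, method = "euclidean"),
                                 method = "average")
        rowOrder <- rowTree$order
    }
    if (ncol(m) >= 2L) {
        colTree <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                                 method = "average")
        colOrder <- colTree$order
    }
    display <- pmin(pmax(m, clipRange[1]), clipRange[2])
    list(matrix = m, display = display, rowOrder = rowOrder,
         colOrder = colOrder, rowTree = rowTree, colTree = colTree)
}

#' Transcription factors among stage interactomes
#'
#' Intersects each stage's interactor set with a transcription-factor list
#' and partitions the resulting TF sets into shared and stage-specific
#' components.
#'
#' @param interactors named list (stage -> character vector of gene symbols);
#'   must contain \code{OPC} and \code{OL}.
#' @param tfList non-empty character vector of TF gene symbols.
#' @return List with per-stage TF vectors (\code{OPC}, \code{OL}) and a
#'   \code{partition} (\linkS4class{VennPartition}, A = OPC).
#' @export
intersectTf <- function(interactors, tfList) {
    if (!length(tfList))
        stop("tfList must be non-empty", call. = FALSE)
    stopifnot(all(c("OPC", "OL") %in% names(interactors)))
    tf_opc <- intersect(unique(interactors$OPC), tfList)
    tf_ol <- intersect(unique(interactors$OL), tfList)
    list(OPC = tf_opc, OL = tf_ol,
         partition = vennPartition(tf_opc, tf_ol))
}
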