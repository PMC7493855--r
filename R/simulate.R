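#' @include AllClasses.R
NULL

# Sub-generators derive their seed from params@seed with fixed offsets, so
# each is individually reproducible and the full study is reproducible as a
# whole.
.seed_offset <- c(quant = 1L, crapome = 2L, transcriptome = 3L,
                  annotations = 4L, tf = 5L)

#' Simulate bait/IgG quantification tables with ground truth
#'
#' Generates per-stage, per-replicate \linkS4class{QuantTable}s emulating an
#' IP-MS study: protein abundance is log-normal; background binders have
#' equal bait and control intensity up to replicate measurement noise; true
#' interactors carry a log-normal bait-over-control enrichment, with a
#' fraction never detected in the control channel; repository contaminants
#' appear bait-enriched but with high spectral counts in both channels;
#' non-lineage proteins look like interactors yet their genes are absent
#' from the simulated transcriptome. Spectral counts are Poisson with mean
#' increasing in LFQ rank. Stage-specific interactors appear in only one
#' stage's tables.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return List with \code{quant} (stage -> list of replicate
#'   \linkS4class{QuantTable}s) and \code{truth} (protein labels, protein ->
#'   gene map, stage membership, control-undetected flags).
#' @export
simulateQuant <- function(params = SimulationParams()) {
    stopifnot(is(params, "SimulationParams"))
    set.seed(params@seed + .seed_offset[["quant"]])
    n <- params@nProteins
    protein_id <- sprintf("P%04d", seq_len(n))
    gene_symbol <- sprintf("G%04d", seq_len(n))
    n_true <- round(n * params@fracTrueInteractors)
    n_cont <- round(n * params@fracContaminants)
    n_nl <- round(n * params@fracNonLineage)
    label <- rep("background", n)
    shuffled <- sample(n)
    label[shuffled[seq_len(n_true)]] <- "true_interactor"
    label[shuffled[n_true + seq_len(n_cont)]] <- "contaminant"
    label[shuffled[n_true + n_cont + seq_len(n_nl)]] <- "non_lineage"
    names(label) <- protein_id

    membership <- rep("both", n)
    ti <- which(label == "true_interactor")
    if (length(ti)) {
        grp <- sample(c("both", "OPC", "OL"), length(ti), replace = TRUE,
                      prob = c(params@fracSharedInteractors,
                               params@fracOpcSpecific,
                               1 - params@fracSharedInteractors -
                                   params@fracOpcSpecific))
        membership[ti] <- grp
    }
    names(membership) <- protein_id

    base <- 10^stats::rnorm(n, params@backgroundLfqLog10Mean,
                            params@backgroundLfqLog10Sd)
    ctrl_undet <- rep(FALSE, n)
    ctrl_undet[ti] <- stats::runif(length(ti)) < params@fracControlUndetected
    names(ctrl_undet) <- protein_id

    enriched_like <- label %in% c("true_interactor", "non_lineage")
    quant <- list()
    for (stage in .STAGES) {
        present <- membership %in% c("both", stage)
        x <- numeric(n)  # per-protein, per-stage log2 bait enrichment
        x[enriched_like] <- stats::rnorm(sum(enriched_like),
                                         params@baitEnrichmentLog2Mean,
                                         params@baitEnrichmentLog2Sd)
        x[label == "contaminant"] <- stats::rnorm(sum(label == "contaminant"),
                                                  3.0, 1.0)
        reps <- list()
        for (r in seq_len(params@nReplicates)) {
            exp_id <- sprintf("%s_rep%d", stage, r)
            noise <- function(k) 10^stats::rnorm(k, 0, params@replicateNoiseLog10Sd)
            det <- function(k) stats::runif(k) < params@detectionProb
            idx <- which(present)
            bait_det <- det(length(idx))
            ctrl_det <- det(length(idx)) & !ctrl_undet[idx]
            bait_lfq <- base[idx] * 2^x[idx] * noise(length(idx))
            ctrl_lfq <- base[idx] * noise(length(idx))
            rows <- rbind(
                data.frame(protein_id = protein_id[idx][bait_det],
                           gene_symbol = gene_symbol[idx][bait_det],
                           experiment_id = exp_id, channel = "bait",
                           lfq_intensity = bait_lfq[bait_det]),
                data.frame(protein_id = protein_id[idx][ctrl_det],
                           gene_symbol = gene_symbol[idx][ctrl_det],
                           experiment_id = exp_id, channel = "control",
                           lfq_intensity = ctrl_lfq[ctrl_det]))
            sc_mean <- 1 + 40 * rank(rows$lfq_intensity) / nrow(rows)
            is_cont <- label[rows$protein_id] == "contaminant"
            sc_mean[is_cont] <- 300
            rows$spectral_count <- stats::rpois(nrow(rows), sc_mean)
            reps[[r]] <- QuantTable(rows)
        }
        quant[[stage]] <- reps
    }
    list(quant = quant,
         truth = list(proteinLabel = label,
                      geneSymbol = structure(gene_symbol, names = protein_id),
                      stageMembership = membership,
                      controlUndetected = ctrl_undet))
}

#' Simulate a contaminant-repository table
#'
#' Every protein is present. Truth-contaminants receive a max spectral count
#' over 200 with probability 0.7 and otherwise a count in (50, 200] that
#' triggers the product rule at two IP experiments; non-contaminants receive
#' max counts of at most 40, below both rules.
#'
#' @param truth truth list from \code{\link{simulateQuant}}.
#' @param params a \linkS4class{SimulationParams}.
#' @return A \linkS4class{CrapomeTable}.
#' @export
simulateCrapome <- function(truth, params = SimulationParams()) {
    stopifnot(is(params, "SimulationParams"))
    set.seed(params@seed + .seed_offset[["crapome"]])
    label <- truth$proteinLabel
    n <- length(label)
    is_cont <- label == "contaminant"
    maxct <- integer(n)
    high <- is_cont & stats::runif(n) < 0.7
    maxct[high] <- sample(201:600, sum(high), replace = TRUE)
    prod_rule <- is_cont & !high
    maxct[prod_rule] <- sample(60:200, sum(prod_rule), replace = TRUE)
    maxct[!is_cont] <- sample(1:40, sum(!is_cont), replace = TRUE)
    n_exp <- integer(n)
    n_exp[is_cont] <- sample(50:350, sum(is_cont), replace = TRUE)
    n_exp[!is_cont] <- sample(1:50, sum(!is_cont), replace = TRUE)
    CrapomeTable(data.frame(
        protein_id = names(label),
        n_experiments = n_exp,
        max_spectral_count = maxct,
        avg_spectral_count = round(maxct * stats::runif(n, 0.1, 0.8), 1)))
}

#' Simulate a two-stage transcriptome
#'
#' Negative-binomial counts for \code{nGenes} genes (the protein gene
#' namespace plus additional genes) across triplicate samples per stage. A
#' fraction \code{fracDe} of expressed genes is shifted by the planted
#' |log2 FC|, split evenly between OPC-up and OL-up. Genes of non-lineage
#' proteins receive zero counts in all samples. Gene lengths are log-uniform
#' in [500, 10000] bp.
#'
#' @param truth truth list from \code{\link{simulateQuant}}.
#' @param params a \linkS4class{SimulationParams}.
#' @return List with \code{expression} (a \linkS4class{StageExpression}) and
#'   the input \code{truth} extended with \code{deClass}, per-stage
#'   \code{expressedGenes} and \code{geneIds}.
#' @export
simulateTranscriptome <- function(truth, params = SimulationParams()) {
    stopifnot(is(params, "SimulationParams"))
    set.seed(params@seed + .seed_offset[["transcriptome"]])
    prot_genes <- unname(truth$geneSymbol)
    n_extra <- params@nGenes - length(prot_genes)
    gene_id <- c(prot_genes,
                 sprintf("G%04d", length(prot_genes) + seq_len(n_extra)))
    mu <- c(exp(stats::runif(length(prot_genes), log(50), log(2000))),
            exp(stats::rnorm(n_extra, log(60), 1.3)))
    nl_genes <- unname(truth$geneSymbol[truth$proteinLabel == "non_lineage"])
    mu[gene_id %in% nl_genes] <- 0

    de_class <- rep("NS", params@nGenes)
    eligible <- which(mu > 0)
    n_de <- round(params@fracDe * params@nGenes)
    de_idx <- sample(eligible, min(n_de, length(eligible)))
    half <- length(de_idx) %/% 2
    ol_up <- de_idx[seq_len(half)]
    opc_up <- setdiff(de_idx, ol_up)
    de_class[ol_up] <- "OL_up"
    de_class[opc_up] <- "OPC_up"

    mu_opc <- mu; mu_ol <- mu
    mu_ol[ol_up] <- mu[ol_up] * 2^params@deLog2fc
    mu_opc[opc_up] <- mu[opc_up] * 2^params@deLog2fc

    n_rep <- params@nRnaReplicates
    sf <- exp(stats::rnorm(2 * n_rep, 0, 0.05))
    draw <- function(m) {
        if (params@nbDispersion > 0)
            stats::rnbinom(length(m), mu = m, size = 1 / params@nbDispersion)
        else stats::rpois(length(m), m)
    }
    counts <- vapply(seq_len(2 * n_rep), function(j) {
        m <- if (j <= n_rep) mu_opc else mu_ol
        draw(m * sf[j])
    }, numeric(params@nGenes))
    rownames(counts) <- gene_id
    colnames(counts) <- c(sprintf("OPC_%d", seq_len(n_rep)),
                          sprintf("OL_%d", seq_len(n_rep)))
    se <- StageExpression(counts,
                          geneLength = round(exp(stats::runif(
                              params@nGenes, log(500), log(10000)))),
                          stage = rep(.STAGES, each = n_rep))
    truth$deClass <- structure(de_class, names = gene_id)
    cts <- SummarizedExperiment::assay(se, "counts")
    truth$expressedGenes <- list(
        OPC = gene_id[rowSums(cts[, seq_len(n_rep), drop = FALSE]) > 0],
        OL = gene_id[rowSums(cts[, n_rep + seq_len(n_rep), drop = FALSE]) > 0])
    truth$geneIds <- gene_id
    list(expression = se, truth = truth)
}

#' Simulate an annotated gene-set collection
#'
#' Random gene sets of 10-80 members over the expressed-gene universe, plus
#' planted terms whose membership is dominated (default 70%) by
#' true-interactor genes so they are detectably enriched in the recovered
#' interactome.
#'
#' @param truth truth list from \code{\link{simulateTranscriptome}} (needs
#'   \code{expressedGenes}).
#' @param params a \linkS4class{SimulationParams}.
#' @return List with \code{geneSets} (a \linkS4class{GeneSetCollection}) and
#'   \code{truth} extended with \code{plantedTerms}.
#' @export
simulateAnnotations <- function(truth, params = SimulationParams()) {
    stopifnot(is(params, "SimulationParams"))
    if (is.null(truth$expressedGenes))
        stop("truth lacks expressedGenes; run simulateTranscriptome first",
             call. = FALSE)
    set.seed(params@seed + .seed_offset[["annotations"]])
    universe <- unique(unlist(truth$expressedGenes))
    inter_genes <- intersect(
        unname(truth$geneSymbol[truth$proteinLabel == "true_interactor"]),
        universe)
    other_genes <- setdiff(universe, inter_genes)
    n_terms <- params@nTerms
    term_id <- sprintf("T%03d", seq_len(n_terms))
    planted <- seq_len(params@nPlantedTerms)
    members <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
        if (i %in% planted) {
            size <- sample(20:40, 1)
            n_int <- min(round(params@plantedTermPurity * size),
                         length(inter_genes))
            members[[i]] <- c(sample(inter_genes, n_int),
                              sample(other_genes, size - n_int))
        } else {
            members[[i]] <- sample(universe, sample(10:80, 1))
        }
    }
    gs <- GeneSetCollection(
        termId = term_id,
        termName = sprintf("synthetic term %d", seq_len(n_terms)),
        category = sample(c("GO", "KEGG", "Reactome"), n_terms,
                          replace = TRUE),
        members = members)
    truth$plantedTerms <- term_id[planted]
    list(geneSets = gs, truth = truth)
}

#' Simulate a complete study
#'
#' Chains \code{\link{simulateQuant}}, \code{\link{simulateCrapome}},
#' \code{\link{simulateTranscriptome}} and \code{\link{simulateAnnotations}}
#' and adds a transcription-factor list containing both interactor and
#' non-interactor genes. Fully deterministic under \code{params@seed}.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @return A \linkS4class{SyntheticStudy}.
#' @export
simulateStudy <- function(params = SimulationParams()) {
    q <- simulateQuant(params)
    crapome <- simulateCrapome(q$truth, params)
    tx <- simulateTranscriptome(q$truth, params)
    an <- simulateAnnotations(tx$truth, params)
    truth <- an$truth
    set.seed(params@seed + .seed_offset[["tf"]])
    inter_genes <- unname(
        truth$geneSymbol[truth$proteinLabel == "true_interactor"])
    other <- setdiff(truth$geneIds, inter_genes)
    tf <- c(sample(inter_genes, min(12L, length(inter_genes))),
            sample(other, 18L))
    new("SyntheticStudy", quant = q$quant, crapome = crapome,
        expression = tx$expression, geneSets = an$geneSets,
        tfList = tf, truth = truth, params = params)
}
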