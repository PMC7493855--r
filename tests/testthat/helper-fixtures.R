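# Small in-code fixtures shared across test files.

toy_quant_df <- function(proteins = c("P1", "P2"),
                         genes = paste0("G", seq_along(proteins)),
                         experiment = "e1",
                         bait = rep(1e5, length(proteins)),
                         control = rep(1e4, length(proteins))) {
    rbind(
        data.frame(protein_id = proteins, gene_symbol = genes,
                   experiment_id = experiment, channel = "bait",
                   lfq_intensity = bait, spectral_count = 10L),
        data.frame(protein_id = proteins, gene_symbol = genes,
                   experiment_id = experiment, channel = "control",
                   lfq_intensity = control, spectral_count = 2L))
}

toy_quant <- function(...) QuantTable(toy_quant_df(...))

toy_crapome <- function(proteins, maxct, nexp = 10L) {
    CrapomeTable(data.frame(protein_id = proteins,
                            n_experiments = nexp,
                            max_spectral_count = as.integer(maxct),
                            avg_spectral_count = pmin(maxct, 5)))
}

toy_expression <- function(counts, lengths = NULL, stage = NULL) {
    if (is.null(lengths)) lengths <- rep(1000L, nrow(counts))
    if (is.null(stage)) stage <- sub("_.*", "", colnames(counts))
    StageExpression(counts, geneLength = lengths, stage = stage)
}

# Independent oracles ------------------------------------------------------

# Exhaustive hypergeometric upper tail: enumerate all size-n draws with
# utils::combn and count those overlapping the K marked elements in >= k.
enum_hyper_tail <- function(k, K, n, N) {
    draws <- utils::combn(N, n)
    marked <- seq_len(K)
    hits <- colSums(matrix(draws %in% marked, nrow = n))
    mean(hits >= k)
}

# Kappa via an explicit 2x2 contingency table built from membership factors.
contingency_kappa <- function(A, B, universe) {
    fa <- factor(universe %in% A, levels = c(FALSE, TRUE))
    fb <- factor(universe %in% B, levels = c(FALSE, TRUE))
    tab <- table(fa, fb)
    N <- sum(tab)
    po <- sum(diag(tab)) / N
    pe <- sum(rowSums(tab) * colSums(tab)) / N^2
    if (abs(1 - pe) < 1e-12) return(1)
    (po - pe) / (1 - pe)
}

# Brute-force re-evaluation of the three filter predicates for a single
# stage, independent of runCascade's vectorized path.
brute_force_final <- function(bait_tab, crapome, expressed, cfg) {
    rec <- quantRecords(bait_tab)
    bait <- rec[rec$channel == "bait" & rec$lfq_intensity > 0, ]
    ctrl <- rec[rec$channel == "control" & rec$lfq_intensity > 0, ]
    crec <- as.data.frame(crapomeRecords(crapome))
    out <- character()
    for (i in seq_len(nrow(bait))) {
        p <- bait$protein_id[i]
        g <- bait$gene_symbol[i]
        b <- bait$lfq_intensity[i]
        cl <- ctrl$lfq_intensity[match(p, ctrl$protein_id)]
        if (is.na(cl)) cl <- 0
        trans <- g %in% expressed
        enr <- if (cl == 0) b > 0 else
            log2((b + cfg@pseudoIntensity) / (cl + cfg@pseudoIntensity)) >
                cfg@log2RatioThreshold
        row <- crec[crec$protein_id == p, ]
        cont <- nrow(row) == 1 &&
            (row$max_spectral_count > cfg@crapomeMaxCount ||
             cfg@nIpExperiments * row$max_spectral_count > cfg@crapomeProduct)
        if (trans && enr && !cont) out <- c(out, p)
    }
    out
}

random_stage_quant <- function(n) {
    proteins <- sprintf("Q%02d", seq_len(n))
    toy_quant(proteins = proteins,
              bait = round(runif(n, 0, 5e5)),
              control = round(runif(n, 0, 2e5) * rbinom(n, 1, 0.8)))
}

# Benjamini-Hochberg by the sorted-correction definition.
bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
}
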