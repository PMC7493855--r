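#' @include AllClasses.R
NULL

.config_defaults <- function() {
    list(seed = 1L, log_level = "info",
         filter = list(log2_ratio_threshold = 2, crapome_max_count = 200,
                       crapome_product = 100, pseudo_intensity = 1,
                       n_ip_experiments = 2L,
                       product_uses_repository_count = FALSE,
                       combine = "union"),
         de = list(fdr = 0.05, lfc = 1),
         enrichment = list(p = 0.01, kappa = 0.4, top = 20L),
         simulation = list())
}

.sim_param_keys <- c(
    n_proteins = "nProteins", frac_true_interactors = "fracTrueInteractors",
    frac_contaminants = "fracContaminants", frac_non_lineage = "fracNonLineage",
    frac_shared_interactors = "fracSharedInteractors",
    frac_opc_specific = "fracOpcSpecific",
    bait_enrichment_log2_mean = "baitEnrichmentLog2Mean",
    bait_enrichment_log2_sd = "baitEnrichmentLog2Sd",
    background_lfq_log10_mean = "backgroundLfqLog10Mean",
    background_lfq_log10_sd = "backgroundLfqLog10Sd",
    replicate_noise_log10_sd = "replicateNoiseLog10Sd",
    detection_prob = "detectionProb",
    frac_control_undetected = "fracControlUndetected",
    n_replicates = "nReplicates", n_genes = "nGenes",
    n_rna_replicates = "nRnaReplicates", frac_de = "fracDe",
    de_log2fc = "deLog2fc", nb_dispersion = "nbDispersion",
    n_terms = "nTerms", n_planted_terms = "nPlantedTerms",
    planted_term_purity = "plantedTermPurity", seed = "seed")

#' Validate and default a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration, fills in documented defaults,
#' range-checks every threshold and rejects unknown keys by name. The
#' simulation seed defaults to the run seed unless given explicitly.
#'
#' @param path path to a YAML/JSON file, or an equivalent named list.
#' @return A \linkS4class{PipelineConfig}.
#' @export
validateConfig <- function(path) {
    cfg <- if (is.list(path)) path else yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    defaults <- .config_defaults()
    unknown <- setdiff(names(cfg), names(defaults))
    if (length(unknown))
        stop(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
    for (section in c("filter", "de", "enrichment")) {
        extra <- setdiff(names(cfg[[section]]), names(defaults[[section]]))
        if (length(extra))
            stop(sprintf("unknown config key(s) in '%s': %s", section,
                         paste(extra, collapse = ", ")), call. = FALSE)
    }
    extra <- setdiff(names(cfg$simulation), names(.sim_param_keys))
    if (length(extra))
        stop(sprintf("unknown config key(s) in 'simulation': %s",
                     paste(extra, collapse = ", ")), call. = FALSE)
    merged <- utils::modifyList(defaults, cfg)
    rng_check <- function(value, lo, hi, field) {
        if (!is.numeric(value) || value < lo || value > hi)
            stop(sprintf("config field '%s' must lie in [%s, %s]",
                         field, lo, hi), call. = FALSE)
    }
    rng_check(merged$de$fdr, 1e-12, 1, "de.fdr")
    rng_check(merged$de$lfc, 0, Inf, "de.lfc")
    rng_check(merged$enrichment$p, 1e-12, 1, "enrichment.p")
    rng_check(merged$enrichment$kappa, -1, 1, "enrichment.kappa")
    rng_check(merged$enrichment$top, 1, Inf, "enrichment.top")
    sim_args <- merged$simulation
    names(sim_args) <- unname(.sim_param_keys[names(sim_args)])
    if (is.null(sim_args$seed))
        sim_args$seed <- merged$seed
    sim <- do.call(SimulationParams, sim_args)
    filt <- FilterConfig(
        log2RatioThreshold = merged$filter$log2_ratio_threshold,
        crapomeMaxCount = merged$filter$crapome_max_count,
        crapomeProduct = merged$filter$crapome_product,
        pseudoIntensity = merged$filter$pseudo_intensity,
        nIpExperiments = merged$filter$n_ip_experiments,
        productUsesRepositoryCount = merged$filter$product_uses_repository_count,
        replicateCombination = merged$filter$combine)
    new("PipelineConfig", simulation = sim, filter = filt,
        deFdr = merged$de$fdr, deLfc = merged$de$lfc,
        enrichAlpha = merged$enrichment$p,
        kappaThreshold = merged$enrichment$kappa,
        topTerms = as.integer(merged$enrichment$top),
        seed = as.integer(merged$seed),
        logLevel = merged$log_level)
}

#' Run the full interactome pipeline
#'
#' Simulates (or accepts) a study, runs the filter cascade, stage-resolved
#' expression analysis (DE, Venn partition, cross-tabulation, clustered
#' heatmap matrix, TF intersection), per-stage term enrichment and the kappa
#' term networks, and writes every result plus a machine-readable summary to
#' a run directory. A rerun with the same configuration and seed produces an
#' identical summary.
#'
#' @param config a \linkS4class{PipelineConfig} (see
#'   \code{\link{validateConfig}}) or a path/list accepted by it.
#' @param outdir run directory (created, existing files overwritten).
#' @param study optional pre-built \linkS4class{SyntheticStudy}; by default
#'   one is generated from \code{config}.
#' @return Invisibly, a list with the run directory, the summary list and
#'   the main result objects (\code{calls}, \code{de}, \code{venn},
#'   \code{crosstab}, \code{enrichment}, \code{networks}, \code{study}).
#' @export
runPipeline <- function(config, outdir, study = NULL) {
    if (!is(config, "PipelineConfig"))
        config <- validateConfig(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    log_lines <- character()
    say <- function(fmt, ...) {
        line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                        sprintf(fmt, ...))
        log_lines <<- c(log_lines, line)
        if (config@logLevel == "info") message(line)
    }

    cfg_list <- list(
        seed = config@seed, log_level = config@logLevel,
        filter = list(log2_ratio_threshold = config@filter@log2RatioThreshold,
                      crapome_max_count = config@filter@crapomeMaxCount,
                      crapome_product = config@filter@crapomeProduct,
                      pseudo_intensity = config@filter@pseudoIntensity,
                      n_ip_experiments = config@filter@nIpExperiments,
                      combine = config@filter@replicateCombination),
        de = list(fdr = config@deFdr, lfc = config@deLfc),
        enrichment = list(p = config@enrichAlpha,
                          kappa = config@kappaThreshold,
                          top = config@topTerms),
        simulation = list(seed = config@simulation@seed,
                          n_proteins = config@simulation@nProteins,
                          n_genes = config@simulation@nGenes))
    cfg_path <- file.path(outdir, "config.json")
    jsonlite::write_json(cfg_list, cfg_path, auto_unbox = TRUE, digits = NA)
    cfg_hash <- unname(tools::md5sum(cfg_path))
    say("run seed %d, config hash %s", config@seed, cfg_hash)

    run_stage <- function(name, expr) {
        say("stage %s: start", name)
        t0 <- proc.time()[["elapsed"]]
        out <- tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
        say("stage %s: done (%.2f s)", name, proc.time()[["elapsed"]] - t0)
        out
    }

    if (is.null(study))
        study <- run_stage("simulate", simulateStudy(config@simulation))

    calls <- run_stage("filter", suppressMessages(runCascade(
        quant = study@quant, crapome = study@crapome,
        expressed = study@truth$expressedGenes, config = config@filter)))
    .write_tsv(interactorCalls(calls), file.path(outdir, "interactor_calls.tsv"))
    writeLedger(filterLedger(calls), file.path(outdir, "filter_ledger.json"))
    jsonlite::write_json(lapply(stageLedgers(calls),
                                function(l) as.list(ledgerCounts(l))),
                         file.path(outdir, "stage_ledgers.json"),
                         auto_unbox = TRUE)

    de <- run_stage("de", suppressMessages(
        deTest(study@expression, fdrThreshold = config@deFdr,
               lfcThreshold = config@deLfc)))
    .write_tsv(de, file.path(outdir, "de_table.tsv"))

    interactome <- lapply(structure(.STAGES, names = .STAGES),
                          function(s) finalInteractors(calls, stage = s))
    venn <- run_stage("venn", vennPartition(interactome$OPC, interactome$OL))
    jsonlite::write_json(
        list(shared = vennShared(venn), opc_specific = vennASpecific(venn),
             ol_specific = vennBSpecific(venn)),
        file.path(outdir, "venn.json"))

    crosstab <- run_stage("crosstab", suppressMessages(stageCrosstab(
        list(OPC = vennASpecific(venn), OL = vennBSpecific(venn)), de)))
    jsonlite::write_json(as.data.frame(crosstab),
                         file.path(outdir, "crosstab.json"), digits = NA)

    rpkm <- computeRpkm(study@expression)
    hm_genes <- unique(c(
        intersect(vennASpecific(venn), de$gene_id[de$de_class != "NS"]),
        intersect(vennBSpecific(venn), de$gene_id[de$de_class != "NS"])))
    hm <- NULL
    if (length(hm_genes)) {
        hm <- run_stage("heatmap", heatmapMatrix(rpkm, hm_genes))
        mat <- hm$matrix[hm$rowOrder, hm$colOrder, drop = FALSE]
        .write_tsv(data.frame(gene_id = rownames(mat), mat,
                              check.names = FALSE),
                   file.path(outdir, "heatmap_matrix.tsv"))
        writeLines(rownames(hm$matrix)[hm$rowOrder],
                   file.path(outdir, "heatmap_row_order.txt"))
        writeLines(colnames(hm$matrix)[hm$colOrder],
                   file.path(outdir, "heatmap_col_order.txt"))
    } else say("heatmap skipped: no stage-specific DE interactors")

    tf <- run_stage("tf", intersectTf(interactome, study@tfList))
    jsonlite::write_json(list(OPC = tf$OPC, OL = tf$OL,
                              shared = vennShared(tf$partition)),
                         file.path(outdir, "tf_intersection.json"))

    enrichment <- list(); networks <- list()
    for (stage in .STAGES) {
        universe <- study@truth$expressedGenes[[stage]]
        query <- intersect(interactome[[stage]], universe)
        res <- run_stage(paste0("enrich_", stage), enrichTerms(
            query, study@geneSets, universe, alpha = config@enrichAlpha))
        enrichment[[stage]] <- res
        .write_tsv(res, file.path(outdir, sprintf("enrichment_%s.tsv", stage)))
        top <- suppressWarnings(topTerms(res, config@topTerms))
        .write_tsv(top, file.path(outdir, sprintf("top_terms_%s.tsv", stage)))
        net <- run_stage(paste0("network_", stage), buildTermNetwork(
            res, study@geneSets, query,
            kappaThreshold = config@kappaThreshold))
        networks[[stage]] <- net
        writeNetwork(net, file.path(outdir, sprintf("network_%s.graphml", stage)),
                     format = "graphml")
        writeNetwork(net, file.path(outdir, sprintf("network_%s_edges.tsv", stage)),
                     format = "tsv")
    }

    summary <- list(
        seed = config@seed, config_hash = cfg_hash,
        ledger = as.list(ledgerCounts(filterLedger(calls))),
        stage_ledgers = lapply(stageLedgers(calls),
                               function(l) as.list(ledgerCounts(l))),
        venn = list(shared = length(vennShared(venn)),
                    opc_specific = length(vennASpecific(venn)),
                    ol_specific = length(vennBSpecific(venn)),
                    opc_interactome = length(interactome$OPC),
                    ol_interactome = length(interactome$OL)),
        de = list(n_opc_up = sum(de$de_class == "OPC_up"),
                  n_ol_up = sum(de$de_class == "OL_up"),
                  n_ns = sum(de$de_class == "NS")),
        crosstab = as.data.frame(crosstab),
        enrichment = lapply(enrichment, function(r)
            list(n_tested = nrow(r), n_enriched = sum(r$enriched))),
        networks = lapply(networks, function(n)
            list(n_nodes = nrow(networkNodes(n)),
                 n_kappa_edges = nrow(termEdges(n)))),
        tf = list(n_opc = length(tf$OPC), n_ol = length(tf$OL),
                  n_shared = length(vennShared(tf$partition))))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(outdir, "run.log"))
    say("pipeline complete: %s", outdir)
    invisible(list(outdir = outdir, summary = summary, calls = calls,
                   de = de, venn = venn, crosstab = crosstab,
                   heatmap = hm, tf = tf, enrichment = enrichment,
                   networks = networks, study = study))
}
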