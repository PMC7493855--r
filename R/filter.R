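#' @include AllClasses.R
NULL

#' Normalize bait intensities against the IgG control
#'
#' Rescales the bait channel of each experiment so its intensities are
#' directly comparable to the IgG control before ratios are formed.
#' \code{"median-ratio"} (the default) divides the bait channel by the median
#' per-protein bait/control ratio over proteins detected in both channels —
#' the size-factor convention, robust as long as most co-detected proteins
#' are non-specific background, which an IgG comparison presumes.
#' \code{"equal-total"} instead matches the two channels' total intensity;
#' it is simpler but biased when specific interactors carry an appreciable
#' share of the bait channel's total signal.
#'
#' @param table a \linkS4class{QuantTable} containing both channels.
#' @param method \code{"median-ratio"} (default) or \code{"equal-total"}.
#' @return A \linkS4class{QuantTable} with rescaled bait intensities.
#' @export
normalizeAgainstControl <- function(table,
                                    method = c("median-ratio", "equal-total")) {
    stopifnot(is(table, "QuantTable"))
    method <- match.arg(method)
    rec <- quantRecords(table)
    for (exp_id in unique(rec$experiment_id)) {
        in_exp <- rec$experiment_id == exp_id
        is_bait <- in_exp & rec$channel == "bait"
        is_ctrl <- in_exp & rec$channel == "control"
        bait_total <- sum(rec$lfq_intensity[is_bait])
        ctrl_total <- sum(rec$lfq_intensity[is_ctrl])
        if (ctrl_total <= 0)
            stop(sprintf("control channel absent or zero in experiment '%s'",
                         exp_id), call. = FALSE)
        if (bait_total <= 0)
            stop(sprintf("bait channel absent or zero in experiment '%s'",
                         exp_id), call. = FALSE)
        scale <- ctrl_total / bait_total
        if (method == "median-ratio") {
            bait_lfq <- structure(rec$lfq_intensity[is_bait],
                                  names = rec$protein_id[is_bait])
            ctrl_lfq <- structure(rec$lfq_intensity[is_ctrl],
                                  names = rec$protein_id[is_ctrl])
            shared <- intersect(names(bait_lfq)[bait_lfq > 0],
                                names(ctrl_lfq)[ctrl_lfq > 0])
            if (length(shared)) {
                scale <- 1 / stats::median(bait_lfq[shared] / ctrl_lfq[shared])
            } else {
                message(sprintf("experiment '%s': no protein detected in both channels; falling back to equal-total scaling",
                                exp_id))
            }
        }
        rec$lfq_intensity[is_bait] <- rec$lfq_intensity[is_bait] * scale
    }
    QuantTable(rec)
}

#' Bait-over-control enrichment call
#'
#' A protein is called enriched when it is detected in the bait channel but
#' not in the control (bait-only detection), or when the log2 bait/control
#' LFQ ratio strictly exceeds the threshold. The pseudo-intensity is added to
#' both channels only when the control is non-zero; the log2 enrichment is
#' undefined (NA) for bait-only proteins.
#'
#' @param baitLfq,controlLfq non-negative LFQ intensities (vectorized).
#' @param config a \linkS4class{FilterConfig}.
#' @return A list with logical \code{pass} and numeric \code{log2Enrichment}
#'   (NA where the control is undetected).
#' @examples
#' enrichmentCall(500, 0)$pass        # bait-only: TRUE
#' enrichmentCall(4000, 1000)$pass    # ratio exactly 2: FALSE (strict)
#' enrichmentCall(4100, 1000)$pass    # log2(4.1) > 2: TRUE
#' @export
enrichmentCall <- function(baitLfq, controlLfq, config = FilterConfig()) {
    stopifnot(is(config, "FilterConfig"))
    if (any(baitLfq < 0) || any(controlLfq < 0))
        stop("LFQ intensities must be non-negative", call. = FALSE)
    n <- max(length(baitLfq), length(controlLfq))
    baitLfq <- rep_len(baitLfq, n)
    controlLfq <- rep_len(controlLfq, n)
    log2e <- rep(NA_real_, n)
    has_ctrl <- controlLfq > 0
    eps <- config@pseudoIntensity
    log2e[has_ctrl] <- log2((baitLfq[has_ctrl] + eps) /
                            (controlLfq[has_ctrl] + eps))
    pass <- (!has_ctrl & baitLfq > 0) |
        (has_ctrl & !is.na(log2e) & log2e > config@log2RatioThreshold)
    list(pass = pass, log2Enrichment = log2e)
}

#' Lineage (transcriptome-presence) filter
#'
#' Keeps the proteins whose genes are expressed in the relevant lineage
#' transcriptome and removes the rest.
#'
#' @param proteins character vector of gene symbols detected by MS.
#' @param expressed character vector of genes with non-zero expression.
#' @return A list with \code{kept} and \code{removed} character vectors
#'   (\code{kept} and \code{removed} partition \code{proteins}).
#' @export
lineageFilter <- function(proteins, expressed) {
    if (!length(expressed))
        stop("expressed gene set is empty: transcriptome missing",
             call. = FALSE)
    proteins <- unique(proteins)
    list(kept = intersect(proteins, expressed),
         removed = setdiff(proteins, expressed))
}

#' Contaminant flag from repository evidence
#'
#' A protein is flagged as a contaminant when its repository max spectral
#' count strictly exceeds \code{crapomeMaxCount}, or when the product of the
#' number of experiments and the max spectral count strictly exceeds
#' \code{crapomeProduct}. The multiplier is the study's IP experiment count
#' by default; set \code{productUsesRepositoryCount} in the config to use the
#' repository's own detection count instead. Proteins absent from the table
#' carry no repository evidence and are not flagged.
#'
#' @param crapome a \linkS4class{CrapomeTable}.
#' @param proteinIds character vector of proteins to flag.
#' @param config a \linkS4class{FilterConfig}.
#' @return Named logical vector, TRUE = contaminant.
#' @examples
#' tab <- CrapomeTable(data.frame(protein_id = c("P1", "P2", "P3"),
#'     n_experiments = 10L, max_spectral_count = c(201L, 60L, 40L),
#'     avg_spectral_count = 10))
#' crapomeFlag(tab, c("P1", "P2", "P3"))  # TRUE TRUE FALSE at defaults
#' @export
crapomeFlag <- function(crapome, proteinIds, config = FilterConfig()) {
    stopifnot(is(crapome, "CrapomeTable"), is(config, "FilterConfig"))
    rec <- crapomeRecords(crapome)
    idx <- match(proteinIds, rec$protein_id)
    absent <- is.na(idx)
    if (any(absent))
        message(sprintf("%d protein(s) absent from the contaminant repository; treated as non-contaminant",
                        sum(absent)))
    maxct <- rec$max_spectral_count[idx]
    mult <- if (config@productUsesRepositoryCount) rec$n_experiments[idx]
            else config@nIpExperiments
    flag <- (maxct > config@crapomeMaxCount) |
        (mult * maxct > config@crapomeProduct)
    flag[absent] <- FALSE
    names(flag) <- proteinIds
    flag
}

#' Combine replicate IP experiments
#'
#' In \code{"union"} mode a protein appears if detected in any replicate; in
#' \code{"intersection"} mode it must appear in all. Per protein and channel
#' the maximum LFQ intensity and maximum spectral count across replicates are
#' retained; the combined records carry \code{experiment_id = "combined"}.
#'
#' @param tables list of replicate \linkS4class{QuantTable}s.
#' @param config a \linkS4class{FilterConfig} (its
#'   \code{replicateCombination} is used).
#' @return A \linkS4class{QuantTable}.
#' @export
combineReplicates <- function(tables, config = FilterConfig()) {
    stopifnot(is(config, "FilterConfig"))
    if (is(tables, "QuantTable"))
        tables <- list(tables)
    if (!length(tables))
        stop("combineReplicates needs at least one table", call. = FALSE)
    stopifnot(all(vapply(tables, is, logical(1), "QuantTable")))
    rec <- do.call(rbind, lapply(tables, quantRecords))
    if (config@replicateCombination == "intersection") {
        n_rep <- length(tables)
        seen <- lapply(tables, function(t) unique(quantRecords(t)$protein_id))
        keep <- Reduce(intersect, seen)
        rec <- rec[rec$protein_id %in% keep, , drop = FALSE]
    }
    if (nrow(rec) == 0L)
        return(QuantTable())
    key <- paste(rec$protein_id, rec$channel, sep = "\r")
    first <- !duplicated(key)
    out <- rec[first, , drop = FALSE]
    grp <- match(key, key[first])
    out$lfq_intensity <- as.numeric(tapply(rec$lfq_intensity, grp, max))
    out$spectral_count <- as.integer(tapply(rec$spectral_count, grp, max))
    out$experiment_id <- "combined"
    QuantTable(out)
}

#' Run the three-stage interactor filter cascade
#'
#' Per stage: replicate experiments are normalized against their IgG control,
#' combined, proteins seen only in the control channel are dropped (logged),
#' then the three independent predicates are evaluated for every bait-detected
#' protein — lineage presence (\code{\link{lineageFilter}}), bait/IgG
#' enrichment (\code{\link{enrichmentCall}}) and contaminant-repository
#' flagging (\code{\link{crapomeFlag}}). The final interactor set is the
#' proteins passing all three. Ledger accounting follows the cascade order:
#' enrichment is counted among lineage-kept proteins and contaminants among
#' enrichment-passing ones; the pooled ledger counts unique proteins across
#' stages.
#'
#' @param quant named list (stage -> \linkS4class{QuantTable} or list of
#'   replicate \linkS4class{QuantTable}s).
#' @param crapome a \linkS4class{CrapomeTable}.
#' @param expressed named list (stage -> character vector of expressed gene
#'   symbols).
#' @param config a \linkS4class{FilterConfig}.
#' @param normalize normalization applied to each replicate before
#'   combination: \code{"median-ratio"} (default), \code{"equal-total"}, or
#'   \code{"none"} for pre-normalized intensities.
#' @return An \linkS4class{InteractorCalls}.
#' @export
runCascade <- function(quant, crapome, expressed, config = FilterConfig(),
                       normalize = c("median-ratio", "equal-total", "none")) {
    normalize <- match.arg(normalize)
    stopifnot(is(crapome, "CrapomeTable"), is(config, "FilterConfig"))
    if (is.null(names(quant)) || !all(names(quant) %in% names(expressed)))
        stop("quant must be a named list with an expressed gene set per stage",
             call. = FALSE)
    all_calls <- list()
    stage_ledgers <- list()
    n_control_only <- 0L
    pass_sets <- list(); kept_sets <- list(); ident_sets <- list()
    contam_sets <- list(); final_sets <- list()
    for (stage in names(quant)) {
        tabs <- quant[[stage]]
        if (is(tabs, "QuantTable"))
            tabs <- list(tabs)
        if (normalize != "none")
            tabs <- lapply(tabs, normalizeAgainstControl, method = normalize)
        comb <- combineReplicates(tabs, config)
        rec <- quantRecords(comb)
        bait <- rec[rec$channel == "bait" & rec$lfq_intensity > 0, , drop = FALSE]
        ctrl <- rec[rec$channel == "control" & rec$lfq_intensity > 0, , drop = FALSE]
        ctrl_lfq <- structure(ctrl$lfq_intensity, names = ctrl$protein_id)
        dropped <- setdiff(ctrl$protein_id, bait$protein_id)
        n_control_only <- n_control_only + length(dropped)

        ids <- bait$protein_id
        genes <- bait$gene_symbol
        ctrl_of <- ctrl_lfq[ids]
        ctrl_of[is.na(ctrl_of)] <- 0
        lin <- lineageFilter(genes, expressed[[stage]])
        trans_pass <- genes %in% lin$kept
        enr <- enrichmentCall(bait$lfq_intensity, unname(ctrl_of), config)
        contam <- unname(crapomeFlag(crapome, ids, config))
        final <- trans_pass & enr$pass & !contam
        all_calls[[stage]] <- DataFrame(
            protein_id = ids, gene_symbol = genes, stage = stage,
            detected_in_control = unname(ctrl_of) > 0,
            log2_enrichment = enr$log2Enrichment,
            transcriptome_pass = trans_pass,
            enrichment_pass = enr$pass,
            contaminant = contam,
            final_pass = final)
        stage_ledgers[[stage]] <- ledgerFromCounts(
            nIdentified = length(ids),
            nLineageRemoved = sum(!trans_pass),
            nEnrichmentPass = sum(trans_pass & enr$pass),
            nContaminants = sum(trans_pass & enr$pass & contam))
        ident_sets[[stage]] <- ids
        kept_sets[[stage]] <- ids[trans_pass]
        pass_sets[[stage]] <- ids[trans_pass & enr$pass]
        contam_sets[[stage]] <- ids[trans_pass & enr$pass & contam]
        final_sets[[stage]] <- ids[final]
    }
    if (n_control_only)
        message(sprintf("%d control-only protein record(s) dropped before filtering",
                        n_control_only))
    ident <- unique(unlist(ident_sets))
    kept <- unique(unlist(kept_sets))
    pass <- unique(unlist(pass_sets))
    final <- unique(unlist(final_sets))
    contam <- setdiff(pass, final)
    pooled <- ledgerFromCounts(
        nIdentified = length(ident),
        nLineageRemoved = length(setdiff(ident, kept)),
        nEnrichmentPass = length(pass),
        nContaminants = length(contam))
    if (pooled@nFinal == 0L)
        warning("final interactor set is empty", call. = FALSE)
    new("InteractorCalls",
        calls = do.call(rbind, unname(all_calls)),
        ledger = pooled, stageLedgers = stage_ledgers,
        nControlOnly = n_control_only)
}

#' Final interactors of a cascade run
#'
#' @param x an \linkS4class{InteractorCalls}.
#' @param stage optional stage name; default pools all stages.
#' @param what \code{"gene_symbol"} (default) or \code{"protein_id"}.
#' @return Character vector of unique identifiers with \code{final_pass}.
#' @export
finalInteractors <- function(x, stage = NULL, what = c("gene_symbol", "protein_id")) {
    stopifnot(is(x, "InteractorCalls"))
    what <- match.arg(what)
    cl <- interactorCalls(x)
    if (!is.null(stage))
        cl <- cl[cl$stage == stage, , drop = FALSE]
    unique(cl[[what]][cl$final_pass])
}
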