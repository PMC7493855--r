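test_that("equal-total normalization matches the forced scaling", {
    qt <- toy_quant(proteins = c("P1", "P2"), bait = c(1.5e6, 0.5e6),
                    control = c(0.6e6, 0.4e6))
    norm <- normalizeAgainstControl(qt, method = "equal-total")
    rec <- quantRecords(norm)
    expect_equal(rec$lfq_intensity[rec$channel == "bait"],
                 c(1.5e6, 0.5e6) / 2)  # bait total 2e6 vs control 1e6
    # identical totals: identity
    qt2 <- toy_quant(bait = c(2e5, 1e5), control = c(1e5, 2e5))
    expect_equal(as.data.frame(quantRecords(
        normalizeAgainstControl(qt2, method = "equal-total"))),
        as.data.frame(quantRecords(qt2)))
    # zero-total control errors with the experiment name
    qt3 <- toy_quant(control = c(0, 0))
    expect_error(normalizeAgainstControl(qt3), "e1")
})

test_that("median-ratio normalization centres background at ratio 1", {
    # 3 background proteins at ratio 2, one interactor at ratio 64
    qt <- toy_quant(proteins = paste0("P", 1:4),
                    bait = c(2e5, 2e5, 2e5, 6.4e6),
                    control = c(1e5, 1e5, 1e5, 1e5))
    rec <- quantRecords(normalizeAgainstControl(qt))
    bait <- rec$lfq_intensity[rec$channel == "bait"]
    expect_equal(bait[1:3], rep(1e5, 3))  # background ratio now 1
    expect_equal(bait[4], 3.2e6)          # interactor keeps 32x enrichment
})

test_that("enrichment calls follow the strict log2 threshold and bait-only rule", {
    cfg <- FilterConfig(pseudoIntensity = 1e-9)
    res <- enrichmentCall(c(500, 4000, 4100, 0), c(0, 1000, 1000, 0), cfg)
    expect_equal(res$pass, c(TRUE, FALSE, TRUE, FALSE))
    expect_true(is.na(res$log2Enrichment[1]))     # bait-only: undefined
    expect_equal(res$log2Enrichment[2], 2, tolerance = 1e-9)
    expect_equal(res$log2Enrichment[3], log2(4.1), tolerance = 1e-9)
    expect_error(enrichmentCall(-1, 0), "non-negative")
})

test_that("lineage filter partitions the protein set", {
    lf <- lineageFilter(c("A", "B", "C"), c("A", "C", "D"))
    expect_setequal(lf$kept, c("A", "C"))
    expect_equal(lf$removed, "B")
    expect_error(lineageFilter("A", character()), "empty")
    # property: kept and removed always partition the input
    set.seed(4)
    for (i in 1:20) {
        prots <- sample(letters, sample(5:20, 1))
        expr <- sample(letters, sample(1:20, 1))
        lf <- lineageFilter(prots, expr)
        expect_setequal(c(lf$kept, lf$removed), unique(prots))
        expect_length(intersect(lf$kept, lf$removed), 0)
    }
})

test_that("contaminant flags apply max-count and product rules strictly", {
    tab <- toy_crapome(paste0("P", 1:5), maxct = c(201, 200, 60, 50, 40))
    flags <- crapomeFlag(tab, paste0("P", 1:5))  # nIpExperiments = 2
    # 201 > 200; 2*200 = 400 > 100; 2*60 = 120 > 100; 2*50 = 100 not > 100
    expect_equal(unname(flags), c(TRUE, TRUE, TRUE, FALSE, FALSE))
    # missing protein: no repository evidence, not flagged
    expect_message(f2 <- crapomeFlag(tab, "P99"), "absent")
    expect_false(unname(f2))
    # repository-count reading of the product rule
    cfg <- FilterConfig(productUsesRepositoryCount = TRUE)
    tab2 <- toy_crapome("P1", maxct = 30, nexp = 5L)   # 5*30 = 150 > 100
    expect_true(unname(crapomeFlag(tab2, "P1", cfg)))
})

test_that("replicate combination takes union or intersection with max rule", {
    t1 <- toy_quant(proteins = c("A", "B"), experiment = "e1",
                    bait = c(10, 10), control = c(1, 1))
    t2 <- toy_quant(proteins = c("B", "C"), experiment = "e2",
                    bait = c(30, 5), control = c(2, 1))
    un <- quantRecords(combineReplicates(list(t1, t2)))
    expect_setequal(unique(un$protein_id), c("A", "B", "C"))
    expect_equal(un$lfq_intensity[un$protein_id == "B" & un$channel == "bait"], 30)
    it <- quantRecords(combineReplicates(
        list(t1, t2), FilterConfig(replicateCombination = "intersection")))
    expect_setequal(unique(it$protein_id), "B")
    expect_error(combineReplicates(list()), "at least one")
})

test_that("run_cascade equals brute-force predicate evaluation on random toys", {
    set.seed(71)
    cfg <- FilterConfig()
    for (rep in 1:10) {
        n <- sample(10:50, 1)
        qt <- random_stage_quant(n)
        proteins <- sprintf("Q%02d", seq_len(n))
        crap <- toy_crapome(sample(proteins, n %/% 2),
                            maxct = sample(c(10, 40, 60, 150, 250),
                                           n %/% 2, replace = TRUE))
        expressed <- sample(paste0("G", seq_len(n)), sample(seq_len(n), 1))
        cascade <- suppressMessages(suppressWarnings(runCascade(
            list(OPC = qt, OL = qt), crap,
            list(OPC = expressed, OL = expressed), cfg, normalize = "none")))
        expect_setequal(finalInteractors(cascade, what = "protein_id"),
                        brute_force_final(qt, crap, expressed, cfg))
    }
})

test_that("cascade ledger counts are conserved and stage-consistent", {
    set.seed(91)
    for (rep in 1:5) {
        n <- sample(20:50, 1)
        qt <- random_stage_quant(n)
        proteins <- sprintf("Q%02d", seq_len(n))
        crap <- toy_crapome(proteins,
                            maxct = sample(c(10, 250), n, replace = TRUE,
                                           prob = c(0.9, 0.1)))
        expressed <- paste0("G", sample(n, max(2, n - 5)))
        res <- suppressMessages(suppressWarnings(runCascade(
            list(OPC = qt), crap, list(OPC = expressed), normalize = "none")))
        for (led in c(list(filterLedger(res)), stageLedgers(res))) {
            v <- ledgerCounts(led)
            expect_equal(v[["n_after_lineage"]],
                         v[["n_identified"]] - v[["n_lineage_removed"]])
            expect_equal(v[["n_final"]],
                         v[["n_enrichment_pass"]] - v[["n_contaminants"]])
            # full conservation: every identified protein lands in one bin
            expect_equal(v[["n_identified"]],
                         v[["n_lineage_removed"]] +
                         (v[["n_after_lineage"]] - v[["n_enrichment_pass"]]) +
                         v[["n_contaminants"]] + v[["n_final"]])
        }
    }
})

test_that("tightening the ratio threshold never grows the final set and crapome thresholds never shrink it", {
    set.seed(17)
    qt <- random_stage_quant(40)
    crap <- toy_crapome(sprintf("Q%02d", 1:40),
                        maxct = sample(c(10, 60, 250), 40, replace = TRUE))
    expressed <- paste0("G", 1:40)
    run <- function(cfg) finalInteractors(suppressMessages(suppressWarnings(
        runCascade(list(OPC = qt), crap, list(OPC = expressed), cfg,
                   normalize = "none"))), what = "protein_id")
    base <- run(FilterConfig())
    stricter <- run(FilterConfig(log2RatioThreshold = 3))
    expect_true(all(stricter %in% base))
    looser_crap <- run(FilterConfig(crapomeMaxCount = 500, crapomeProduct = 1500))
    expect_true(all(base %in% looser_crap))
})

test_that("predicate order does not matter: flags are independent", {
    set.seed(23)
    qt <- random_stage_quant(30)
    crap <- toy_crapome(sprintf("Q%02d", 1:30),
                        maxct = sample(c(10, 250), 30, replace = TRUE))
    expressed <- paste0("G", 1:30)
    res <- suppressMessages(suppressWarnings(runCascade(
        list(OPC = qt), crap, list(OPC = expressed), normalize = "none")))
    cl <- interactorCalls(res)
    # applying crapome first then enrichment gives the same final set as the
    # recorded per-protein conjunction
    manual <- cl$protein_id[!cl$contaminant & cl$enrichment_pass &
                            cl$transcriptome_pass]
    expect_setequal(manual, finalInteractors(res, what = "protein_id"))
})

test_that("the printed-accounting ledger reproduces the worked example", {
    led <- ledgerFromCounts(2760, 217, 1265, 54)
    expect_equal(unname(ledgerCounts(led)[["n_final"]]), 1211L)
    expect_equal(unname(ledgerCounts(led)[["n_after_lineage"]]), 2543L)
    # inconsistent counts are rejected by the validity method
    expect_error(ledgerFromCounts(10, 2, 9, 0), "nEnrichmentPass")
})
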