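test_that("RPKM follows the count/length/depth formula", {
    counts <- matrix(c(10, 0, 990, 500, 20, 480), 3,
                     dimnames = list(c("g1", "g2", "g3"),
                                     c("OPC_1", "OL_1")))
    # library sizes: 1000, 1000; lengths 1000 bp
    se <- toy_expression(counts * c(1, 1, 1))
    # scale library to 1e6 by inflating g3
    counts2 <- counts; counts2[3, ] <- c(1e6 - 10, 1e6 - 520)
    se2 <- toy_expression(counts2)
    rpkm <- computeRpkm(se2)
    expect_equal(rpkm["g1", "OPC_1"], 10 * 1e9 / (1e6 * 1000))  # = 10
    expect_equal(rpkm["g2", "OPC_1"], 0)
    # doubling the library size halves the RPKM
    counts3 <- cbind(counts2, OPC_2 = counts2[, 1] * 2)
    rpkm3 <- computeRpkm(toy_expression(counts3))
    expect_equal(rpkm3[, "OPC_2"], rpkm3[, "OPC_1"])
    # invariant to sample order
    perm <- counts2[, c(2, 1)]
    expect_equal(computeRpkm(toy_expression(perm))[, colnames(counts2)],
                 rpkm[, colnames(counts2)])
    # zero library size errors
    counts0 <- counts2; counts0[, 2] <- 0
    expect_error(computeRpkm(toy_expression(counts0)), "library size")
})

test_that("deTest is symmetric under identical stages and flags all-zero genes", {
    counts <- matrix(rep(c(50, 80, 0), 4), nrow = 3, byrow = FALSE,
                     dimnames = list(c("g1", "g2", "gz"),
                                     c("OPC_1", "OPC_2", "OL_1", "OL_2")))
    de <- suppressMessages(deTest(toy_expression(counts), dispersion = 0))
    expect_equal(de$log2_fold_change, rep(0, 3))
    expect_equal(de$p_value[1:2], c(1, 1))
    expect_true(de$all_zero[3])
    expect_equal(de$de_class, rep("NS", 3))
})

test_that("deTest type-I error is near nominal under a negative-binomial null", {
    p <- SimulationParams(seed = 5L, nGenes = 2000L, fracDe = 0)
    tx <- simulateTranscriptome(simulateQuant(p)$truth, p)
    de <- suppressMessages(deTest(tx$expression))
    typeI <- mean(de$p_value[!de$all_zero] < 0.05)
    expect_gt(typeI, 0.05 - 0.015)
    expect_lt(typeI, 0.05 + 0.015)
})

test_that("deTest recovers planted fold changes at high counts", {
    p <- SimulationParams(seed = 8L)
    tx <- simulateTranscriptome(simulateQuant(p)$truth, p)
    de <- suppressMessages(deTest(tx$expression))
    cts <- SummarizedExperiment::assay(tx$expression, "counts")
    s <- colSums(cts)
    high <- rowMeans(sweep(cts, 2, mean(s) / s, `*`)) >= 100
    planted <- tx$truth$deClass[de$gene_id] != "NS"
    recovery <- mean((de$de_class == tx$truth$deClass[de$gene_id])[planted & high])
    expect_gte(recovery, 0.95)
})

test_that("BH adjustment matches the sorted-correction oracle", {
    set.seed(33)
    for (i in 1:20) {
        p <- runif(sample(1:20, 1))^sample(1:3, 1)
        expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
    }
    # and the fdr column of deTest is the BH correction of its p-values
    pp <- SimulationParams(seed = 2L, nProteins = 100L, nGenes = 300L)
    tx <- simulateTranscriptome(simulateQuant(pp)$truth, pp)
    de <- suppressMessages(deTest(tx$expression))
    expect_equal(de$fdr, bh_oracle(de$p_value), tolerance = 1e-12)
})

test_that("venn partition equals exhaustive set enumeration", {
    vp <- vennPartition(c("a", "b", "c"), c("b", "c", "d"))
    expect_setequal(vennShared(vp), c("b", "c"))
    expect_equal(vennASpecific(vp), "a")
    expect_equal(vennBSpecific(vp), "d")
    identical_sets <- vennPartition(letters[1:3], letters[1:3])
    expect_length(vennASpecific(identical_sets), 0)
    expect_length(vennBSpecific(identical_sets), 0)
    set.seed(12)
    for (i in 1:20) {
        A <- sample(1:100, sample(0:60, 1))
        B <- sample(1:100, sample(0:60, 1))
        vp <- vennPartition(A, B)
        # brute-force: classify every element of the union individually
        for (el in union(A, B)) {
            bin <- if (el %in% A && el %in% B) vennShared(vp)
                   else if (el %in% A) vennASpecific(vp)
                   else vennBSpecific(vp)
            expect_true(as.character(el) %in% bin)
        }
        expect_length(vennShared(vp), length(intersect(A, B)))
        expect_equal(length(vennShared(vp)) + length(vennASpecific(vp)),
                     length(unique(A)))
    }
})

test_that("stage crosstab tallies expression classes with two-decimal percentages", {
    de <- S4Vectors::DataFrame(
        gene_id = sprintf("g%03d", 1:500),
        de_class = rep("NS", 500))
    de$de_class[1:30] <- "OPC_up"
    de$de_class[31:60] <- "OL_up"
    opc_specific <- sprintf("g%03d", c(1:14, 31:40, 101:479))  # 14 own, 10 other, 379 NS
    ol_specific <- sprintf("g%03d", c(41:56, 481:500))         # 16 own, 20 NS
    ct <- stageCrosstab(list(OPC = opc_specific, OL = ol_specific), de)
    opc <- as.data.frame(ct[ct$stage == "OPC", ])
    expect_equal(opc$n_up_own, 14)
    expect_equal(opc$n_up_other, 10)
    expect_equal(opc$n_ns, 379)
    expect_equal(opc$pct_ns, round(100 * 379 / 403, 2))
    # counts always sum to the set size
    expect_equal(opc$n_total, 403)
    ol <- as.data.frame(ct[ct$stage == "OL", ])
    expect_equal(ol$n_up_own + ol$n_up_other + ol$n_ns, ol$n_total)
    # empty specific set yields an all-zero row
    ct0 <- stageCrosstab(list(OPC = character(), OL = character()), de)
    expect_true(all(as.data.frame(ct0)[, c("n_total", "n_ns")] == 0))
    # genes missing from the DE table are counted NS with a message
    expect_message(
        ct2 <- stageCrosstab(list(OPC = "unknown_gene", OL = character()), de),
        "missing")
    expect_equal(as.data.frame(ct2)$n_ns[1], 1)
})

test_that("heatmap matrix clips for display and clusters deterministically", {
    rpkm <- rbind(g1 = c(0, 255), g2 = c(255, 0), g3 = c(0, 255),
                  g4 = c(0, 63))
    colnames(rpkm) <- c("OPC_1", "OL_1")
    hm <- heatmapMatrix(rpkm, c("g1", "g2", "g3", "g4"))
    expect_equal(hm$matrix["g1", ], c(OPC_1 = 0, OL_1 = 8))  # log2(256) = 8
    expect_equal(max(hm$display), 8)
    # identical rows g1 and g3 merge first: adjacent in the ordering
    ord <- rownames(hm$matrix)[hm$rowOrder]
    expect_equal(abs(diff(match(c("g1", "g3"), ord))), 1)
    # manual average-linkage trace in log2 space: g1 = g3 = (0,8),
    # g4 = (0,6), g2 = (8,0); (g1,g3) merge at 0, g4 joins at 2
    # (g2 is 11.3 from g1/g3 and 10 from g4), g2 last — so g1, g3, g4
    # sit together with g2 outside the block
    expect_true(all(ord %in% rownames(rpkm)))
    expect_equal(diff(range(match(c("g1", "g3", "g4"), ord))), 2)
    # absent genes raise an error listing them
    expect_error(heatmapMatrix(rpkm, c("g1", "gX")), "gX")
})

test_that("TF intersection respects the subset law and partitions by stage", {
    res <- intersectTf(list(OPC = c("Olig2", "Hdac1", "Vamp3"),
                            OL = c("Hdac1", "Mbp")),
                       c("Olig2", "Hdac1"))
    expect_setequal(res$OPC, c("Olig2", "Hdac1"))
    expect_equal(res$OL, "Hdac1")
    expect_equal(vennShared(res$partition), "Hdac1")
    expect_true(all(res$OPC %in% c("Olig2", "Hdac1", "Vamp3")))
    # disjoint TF list
    none <- intersectTf(list(OPC = "a", OL = "b"), "zzz")
    expect_length(none$OPC, 0)
    expect_error(intersectTf(list(OPC = "a", OL = "b"), character()),
                 "non-empty")
})
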