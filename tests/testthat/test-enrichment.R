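test_that("hypergeometric p-values match exhaustive enumeration on small universes", {
    # frozen worked example: full overlap of a 5-gene term in a 5-gene query
    # drawn from 10 genes has probability 1/choose(10, 5)
    expect_equal(hypergeomPValue(5, 5, 5, 10), 1 / 252, tolerance = 1e-12)
    expect_equal(hypergeomPValue(0, 3, 4, 10), 1)     # upper tail at 0
    expect_equal(hypergeomPValue(1, 7, 1, 7), 1)      # forced overlap
    # exhaustive check over all (k, K, n) configurations for N <= 9
    for (N in c(4, 7, 9)) {
        for (K in 0:N) for (n in 0:N) for (k in 0:min(K, n)) {
            if (n == 0 || N == 0) next
            expect_equal(hypergeomPValue(k, K, n, N),
                         enum_hyper_tail(k, K, n, N), tolerance = 1e-10,
                         info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
    }
    # non-increasing in k
    p <- hypergeomPValue(0:5, 5, 5, 12)
    expect_true(all(diff(p) <= 1e-12))
    expect_error(hypergeomPValue(6, 5, 5, 10), "invalid")
})

test_that("term enrichment counts overlaps against the universe", {
    gs <- GeneSetCollection(c("T1", "T2", "T3"),
                            members = list(letters[1:5], letters[6:9],
                                           c("z1", "z2", "a")))
    universe <- letters[1:20]
    query <- letters[1:5]
    res <- enrichTerms(query, gs, universe)
    expect_equal(res$p_value[1], hypergeomPValue(5, 5, 5, 20))
    # members outside the universe are dropped before counting (z1, z2)
    expect_equal(res$K[3], 1L)
    # zero-overlap terms are reported with k = 0, p = 1
    expect_equal(res$k[2], 0L)
    expect_equal(res$p_value[2], 1)
    # saturation: query = universe makes every term k = K with p = 1
    sat <- enrichTerms(universe, gs, universe)
    expect_equal(sat$k, sat$K)
    expect_equal(sat$p_value, rep(1, 3))
    expect_error(enrichTerms(c("a", "nope"), gs, universe), "subset")
    expect_error(enrichTerms(character(), gs, universe), "non-empty")
    # fdr column equals the sorted-correction oracle
    expect_equal(res$fdr, bh_oracle(res$p_value), tolerance = 1e-12)
})

test_that("top terms order by p, then overlap size, then term id", {
    res <- S4Vectors::DataFrame(
        term_id = c("B", "A", "C", "D"),
        p_value = c(0.01, 0.01, 0.001, 0.5),
        k = c(3L, 5L, 2L, 7L))
    top <- topTerms(res, 3)
    expect_equal(top$term_id, c("C", "A", "B"))  # tie on p: larger k first
    expect_warning(all4 <- topTerms(res, 10), "exceeds")
    expect_equal(nrow(all4), 4L)
    expect_error(topTerms(res, 0), ">= 1")
    # shared-term logic between two stages
    resB <- S4Vectors::DataFrame(term_id = c("C", "X"),
                                 p_value = c(0.2, 0.3), k = c(1L, 1L))
    shared <- intersect(topTerms(res, 2)$term_id, topTerms(resB, 2)$term_id)
    expect_equal(shared, "C")
})

test_that("kappa agreement matches an independent contingency-table computation", {
    universe <- sprintf("u%03d", 1:100)
    A <- universe[1:50]; B <- universe[51:100]
    expect_equal(kappaScore(A, B, universe), -1)      # disjoint halves
    expect_equal(kappaScore(A, A, universe), 1)       # perfect agreement
    expect_equal(kappaScore(universe, universe, universe), 1)  # Pe = 1 case
    expect_error(kappaScore(A, B, character()), "non-empty")
    set.seed(99)
    for (i in 1:200) {
        N <- sample(5:80, 1)
        uni <- sprintf("g%03d", seq_len(N))
        A <- sample(uni, sample(0:N, 1))
        B <- sample(uni, sample(0:N, 1))
        expect_equal(kappaScore(A, B, uni), contingency_kappa(A, B, uni),
                     tolerance = 1e-12)
    }
    # symmetry and bounds
    set.seed(7)
    for (i in 1:50) {
        uni <- sprintf("g%02d", 1:30)
        A <- sample(uni, 10); B <- sample(uni, 15)
        k1 <- kappaScore(A, B, uni)
        expect_equal(k1, kappaScore(B, A, uni))
        expect_gte(k1, -1); expect_lte(k1, 1)
    }
})

test_that("term networks connect terms at or above the kappa threshold", {
    query <- sprintf("q%02d", 1:20)
    gs <- GeneSetCollection(
        c("T1", "T2", "T3"),
        members = list(query[1:6], query[1:6], query[15:20]))
    res <- enrichTerms(query, gs, c(query, sprintf("bg%02d", 1:80)))
    net <- buildTermNetwork(res, gs, query, kappaThreshold = 0.4)
    expect_equal(nrow(networkNodes(net)), 3L)
    ed <- as.data.frame(termEdges(net))
    # identical query overlap: kappa 1 edge between T1 and T2 only
    expect_equal(nrow(ed), 1L)
    expect_setequal(unlist(ed[, c("from", "to")]), c("T1", "T2"))
    expect_equal(ed$kappa, 1)
    # every term links to its query members in the bipartite layer
    pe <- as.data.frame(proteinEdges(net))
    expect_setequal(pe$gene_symbol[pe$term_id == "T3"], query[15:20])
    # node size attribute is -log10(p)
    expect_equal(networkNodes(net)$neg_log10_p,
                 -log10(networkNodes(net)$p_value))

    # kappa exactly at the threshold keeps the edge (inclusive rule)
    uni <- sprintf("x%02d", 1:8)
    A <- uni[1:4]; B <- uni[3:6]
    kab <- kappaScore(A, B, uni)
    gs2 <- GeneSetCollection(c("TA", "TB"), members = list(A, B))
    res2 <- enrichTerms(uni, gs2, uni)
    res2$enriched <- TRUE  # force both nodes in
    net2 <- buildTermNetwork(res2, gs2, uni, kappaThreshold = kab)
    expect_equal(nrow(termEdges(net2)), 1L)
    net3 <- buildTermNetwork(res2, gs2, uni, kappaThreshold = kab + 1e-9)
    expect_equal(nrow(termEdges(net3)), 0L)
})

test_that("network edge sets match all-pairs brute force and ignore input order", {
    set.seed(41)
    query <- sprintf("q%02d", 1:30)
    members <- lapply(1:5, function(i) sample(query, sample(5:15, 1)))
    gs <- GeneSetCollection(paste0("T", 1:5), members = members)
    res <- enrichTerms(query, gs, query)
    res$enriched <- TRUE
    net <- buildTermNetwork(res, gs, query, kappaThreshold = 0.2)
    ed <- as.data.frame(termEdges(net))
    got <- sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)))
    want <- character()
    for (i in 1:4) for (j in (i + 1):5) {
        if (contingency_kappa(members[[i]], members[[j]], query) >= 0.2)
            want <- c(want, paste(paste0("T", i), paste0("T", j)))
    }
    expect_equal(got, sort(want))
    # permuting the result rows leaves the edge set unchanged
    perm <- res[sample(nrow(res)), ]
    net2 <- buildTermNetwork(perm, gs, query, kappaThreshold = 0.2)
    ed2 <- as.data.frame(termEdges(net2))
    expect_setequal(paste(ed2$from, ed2$to, round(ed2$kappa, 10)),
                    paste(ed$from, ed$to, round(ed$kappa, 10)))
})
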