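#' @include AllClasses.R
NULL

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \code{P[X >= k]} for a hypergeometric draw of
#' \code{n} genes from a universe of \code{N} containing \code{K} term
#' members.
#'
#' @param k observed query genes in the term.
#' @param K universe genes in the term.
#' @param n query size.
#' @param N universe size.
#' @return Numeric p-value(s) in (0, 1]; arguments are recycled.
#' @examples
#' hypergeomPValue(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeomPValue <- function(k, K, n, N) {
    len <- max(length(k), length(K), length(n), length(N))
    k <- rep_len(k, len); K <- rep_len(K, len)
    n <- rep_len(n, len); N <- rep_len(N, len)
    if (any(k < 0) || any(K > N) || any(n > N) || any(k > pmin(K, n)))
        stop("invalid hypergeometric counts: need 0 <= k <= min(K, n), K <= N, n <= N",
             call. = FALSE)
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation analysis
#'
#' Tests each term of a collection for over-representation in a query gene
#' set against a universe, with term memberships intersected with the
#' universe before counting. Significance follows the raw-p convention of
#' ClueGO-style analyses (\code{p < alpha}); the BH-adjusted FDR is always
#' reported and can be made the significance criterion instead.
#'
#' @param query character vector of query genes (must lie in
#'   \code{universe}).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param universe character vector of background genes.
#' @param alpha significance level (default 0.01).
#' @param method \code{"pvalue"} (default) or \code{"fdr"}: which statistic
#'   \code{alpha} applies to.
#' @param perCategory apply BH within each term category instead of across
#'   all tested terms (default FALSE).
#' @return A \link[S4Vectors]{DataFrame} with one row per term:
#'   \code{term_id}, \code{term_name}, \code{category}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p_value}, \code{fdr}, \code{enriched},
#'   \code{overlap} (comma-separated query genes in the term).
#' @export
enrichTerms <- function(query, collection, universe, alpha = 0.01,
                        method = c("pvalue", "fdr"), perCategory = FALSE) {
    stopifnot(is(collection, "GeneSetCollection"))
    method <- match.arg(method)
    query <- unique(as.character(query))
    universe <- unique(as.character(universe))
    if (!length(universe) || !length(query))
        stop("query and universe must be non-empty", call. = FALSE)
    if (!all(query %in% universe))
        stop("query must be a subset of the universe", call. = FALSE)
    tm <- gsTerms(collection)
    members <- lapply(collection@members, intersect, universe)
    K <- lengths(members)
    overlap <- lapply(members, intersect, query)
    k <- lengths(overlap)
    n <- length(query); N <- length(universe)
    p <- hypergeomPValue(k, K, n, N)
    fdr <- if (perCategory) {
        out <- numeric(length(p))
        for (cat in unique(tm$category)) {
            sel <- tm$category == cat
            out[sel] <- stats::p.adjust(p[sel], method = "BH")
        }
        out
    } else stats::p.adjust(p, method = "BH")
    enriched <- if (method == "pvalue") p < alpha else fdr < alpha
    DataFrame(term_id = tm$term_id, term_name = tm$term_name,
              category = tm$category, k = as.integer(k), K = as.integer(K),
              n = as.integer(n), N = as.integer(N), p_value = p, fdr = fdr,
              enriched = enriched,
              overlap = vapply(overlap, paste, character(1), collapse = ","),
              row.names = NULL)
}

#' Most significant terms
#'
#' Orders results by ascending p-value, breaking ties by descending overlap
#' \code{k} and then lexicographic \code{term_id}, and returns the first
#' \code{m}.
#'
#' @param results output of \code{\link{enrichTerms}}.
#' @param m number of terms to keep.
#' @return The ordered subset (all results, with a warning, when \code{m}
#'   exceeds their number).
#' @export
topTerms <- function(results, m) {
    if (m < 1)
        stop("m must be >= 1", call. = FALSE)
    if (m > nrow(results)) {
        warning(sprintf("m = %d exceeds the %d available results; returning all",
                        m, nrow(results)), call. = FALSE)
        m <- nrow(results)
    }
    ord <- order(results$p_value, -results$k, results$term_id)
    results[ord[seq_len(m)], , drop = FALSE]
}

#' Cohen's kappa between two gene sets
#'
#' Chance-corrected agreement of the 2x2 membership table of two sets over a
#' universe: with \code{a = |A n B|}, \code{b = |A \\ B|}, \code{c = |B \\ A|},
#' \code{d} the remainder, \code{Po = (a + d) / N} and
#' \code{Pe = ((a+b)(a+c) + (c+d)(b+d)) / N^2},
#' \code{kappa = (Po - Pe) / (1 - Pe)}, defined as 1 when \code{Pe = 1}.
#'
#' @param membersA,membersB character vectors (subsets of \code{universe}).
#' @param universe non-empty character vector.
#' @return Kappa in [-1, 1].
#' @export
kappaScore <- function(membersA, membersB, universe) {
    universe <- unique(as.character(universe))
    if (!length(universe))
        stop("universe must be non-empty", call. = FALSE)
    A <- unique(intersect(membersA, universe))
    B <- unique(intersect(membersB, universe))
    N <- length(universe)
    a <- length(intersect(A, B))
    b <- length(setdiff(A, B))
    cc <- length(setdiff(B, A))
    d <- N - a - b - cc
    po <- (a + d) / N
    pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / N^2
    if (abs(1 - pe) < .Machine$double.eps * 4)
        return(1)
    (po - pe) / (1 - pe)
}

#' Build the kappa-linked term network
#'
#' Nodes are the enriched terms of an over-representation result; two terms
#' are joined when the kappa agreement of their query-gene memberships
#' reaches the threshold (inclusive), with the kappa score as edge weight. A
#' bipartite layer links each term to its query genes. Following the ClueGO
#' convention, the kappa universe is the query gene set itself (override via
#' \code{universe}). Node size is carried as \code{-log10(p)}.
#'
#' @param results output of \code{\link{enrichTerms}} (only rows with
#'   \code{enriched} become nodes).
#' @param collection the \linkS4class{GeneSetCollection} tested.
#' @param query the query gene set used for the enrichment.
#' @param kappaThreshold minimum kappa for an edge (default 0.4, inclusive).
#' @param universe kappa universe; defaults to \code{query}.
#' @return A \linkS4class{TermNetwork}; empty when no term is enriched.
#' @export
buildTermNetwork <- function(results, collection, query, kappaThreshold = 0.4,
                             universe = NULL) {
    stopifnot(is(collection, "GeneSetCollection"))
    query <- unique(as.character(query))
    if (is.null(universe))
        universe <- query
    sel <- which(results$enriched)
    empty_df <- function(...) DataFrame(..., row.names = NULL)
    if (!length(sel))
        return(new("TermNetwork",
                   nodes = empty_df(term_id = character(),
                                    term_name = character(),
                                    p_value = numeric(), fdr = numeric(),
                                    size = integer(),
                                    neg_log10_p = numeric()),
                   termEdges = empty_df(from = character(), to = character(),
                                        kappa = numeric()),
                   proteinEdges = empty_df(term_id = character(),
                                           gene_symbol = character())))
    res <- results[sel, , drop = FALSE]
    all_members <- gsMembers(collection)
    qmembers <- lapply(all_members[res$term_id], intersect, query)
    nodes <- DataFrame(term_id = res$term_id, term_name = res$term_name,
                       p_value = res$p_value, fdr = res$fdr,
                       size = as.integer(lengths(qmembers)),
                       neg_log10_p = -log10(res$p_value), row.names = NULL)
    ord <- order(nodes$term_id)  # edge set invariant to input order
    from <- character(); to <- character(); kap <- numeric()
    if (length(ord) >= 2L) {
        for (i in seq_len(length(ord) - 1L)) {
            for (j in seq((i + 1L), length(ord))) {
                ti <- nodes$term_id[ord[i]]; tj <- nodes$term_id[ord[j]]
                kv <- kappaScore(qmembers[[ti]], qmembers[[tj]], universe)
                if (kv >= kappaThreshold) {
                    from <- c(from, ti); to <- c(to, tj); kap <- c(kap, kv)
                }
            }
        }
    }
    pe_term <- rep(nodes$term_id, lengths(qmembers[nodes$term_id]))
    pe_gene <- unlist(qmembers[nodes$term_id], use.names = FALSE)
    if (is.null(pe_gene)) pe_gene <- character()
    new("TermNetwork", nodes = nodes,
        termEdges = DataFrame(from = from, to = to, kappa = kap,
                              row.names = NULL),
        proteinEdges = DataFrame(term_id = pe_term, gene_symbol = pe_gene,
                                 row.names = NULL))
}
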