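# Phase VI: hypergeometric over-representation analysis with BH FDR.
#
# Self-contained replacement for web annotation tools: the gene-set
# content is supplied by the user (GMT), the test is the plain
# hypergeometric upper tail (one-sided over-representation), with the
# EASE-style penalized variant available as an option.

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(M, K, n): the probability of observing
#' at least `k` annotated genes in a query of size `n` drawn from a
#' universe of `M` genes of which `K` are annotated. Evaluated through
#' `stats::phyper` (log-space-stable tail).
#'
#' @param k Observed overlap.
#' @param K Annotated genes in the universe.
#' @param n Query size.
#' @param M Universe size.
#' @return Upper-tail probability in (0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, M) {
  if (K < 0 || K > M || n < 0 || n > M || k < 0 || k > min(n, K))
    stop("inconsistent counts: need 0 <= K <= M, 0 <= n <= M, 0 <= k <= min(n, K)")
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene list
#'
#' Tests each gene set for over-representation in `query` relative to
#' `universe` with the hypergeometric upper tail, then adjusts across all
#' tested sets with Benjamini-Hochberg. Query genes outside the universe
#' are dropped with a warning; each set is intersected with the universe
#' and sets left empty are skipped. Sets with BH q < 0.05 are flagged
#' enriched.
#'
#' @param query Character vector of genes of interest (e.g. the retained
#'   genes of a [dice_table()]).
#' @param sets Named list of gene sets (see [read_gene_sets()]).
#' @param universe Character vector defining the background. The natural
#'   default in this pipeline is the set of genes entering the condition
#'   networks; all expressed genes are a defensible alternative and give
#'   systematically smaller p-values.
#' @param ease If `TRUE`, apply the EASE penalty (test the overlap minus
#'   one), a conservative variant used by some annotation servers.
#' @return Data frame sorted by p: `set`, `k`, `K`, `n`, `M`, `p`, `q`,
#'   `enriched`.
#' @export
ora <- function(query, sets, universe, ease = FALSE) {
  universe <- unique(universe)
  query0 <- unique(query)
  query <- intersect(query0, universe)
  if (length(query) < length(query0))
    warning("dropped ", length(query0) - length(query),
            " query gene(s) outside the universe")
  if (!length(query)) stop("query is empty after intersecting with the universe")
  M <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    if (K == 0) return(NULL)
    k <- length(intersect(s, query))
    kk <- if (ease) max(k - 1, 0) else k
    data.frame(set = nm, k = k, K = K, n = n, M = M,
               p = hypergeom_upper_tail(kk, K, n, M),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no gene set overlaps the universe")
  rows$q <- bh_adjust(rows$p)
  rows$enriched <- rows$q < 0.05
  rows <- rows[order(rows$p, rows$set), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
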