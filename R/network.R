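# Phase III: condition-specific correlation-weighted PPI networks.
#
# Both condition networks share one topology (the PPI scaffold induced on
# the IG-retained genes, minus edge-less genes); only the per-edge Pearson
# correlation, and hence distance = 1 - |cc| and affinity = |cc|, differ.

#' Per-edge Pearson correlations within one condition
#'
#' Computes, for every edge whose endpoints are both in `genes`, the
#' Pearson correlation of the two genes' expression across the samples of
#' one condition. Undefined correlations (a gene with zero variance within
#' the condition) are set to 0 (distance 1) and counted in a message.
#'
#' @param es An [expression_set].
#' @param genes Character vector of genes to restrict edges to.
#' @param edges Edge data frame (`gene1`, `gene2`, ...).
#' @param condition One of `levels(es$condition)`.
#' @return Numeric vector of correlations, one per retained edge, with the
#'   retained edge data frame as attribute `edges`.
#' @export
condition_correlations <- function(es, genes, edges, condition) {
  stopifnot(inherits(es, "expression_set"))
  if (!condition %in% levels(es$condition))
    stop("unknown condition: ", condition)
  idx <- which(es$condition == condition)
  if (length(idx) < 3)
    stop("condition ", condition, " has < 3 samples; correlations unreliable")
  keep <- edges$gene1 %in% genes & edges$gene2 %in% genes
  edges <- edges[keep, , drop = FALSE]
  x <- es$expr[, idx, drop = FALSE]
  cc <- vapply(seq_len(nrow(edges)), function(k) {
    suppressWarnings(stats::cor(x[edges$gene1[k], ], x[edges$gene2[k], ]))
  }, numeric(1))
  nbad <- sum(!is.finite(cc))
  if (nbad) {
    message(nbad, " edge correlation(s) undefined (zero variance); set to 0")
    cc[!is.finite(cc)] <- 0
  }
  attr(cc, "edges") <- edges
  cc
}

#' Build the two condition-specific weighted networks
#'
#' Induces the PPI scaffold on the IG-retained genes, drops genes left
#' without any edge (their count is reported, mirroring the routine removal
#' of unconnected genes), and attaches per-condition edge weights:
#' `cc` (Pearson correlation within the condition), `distance = 1 - |cc|`
#' (shortest-path length) and `affinity = |cc|` (connection strength).
#' Disconnected components are retained.
#'
#' @param es An [expression_set].
#' @param kept_genes Character vector (typically `ig$gene[ig$kept]`).
#' @param edges Confidence-filtered edge data frame (see [edge_list()]).
#' @return List of two `condition_network` objects (one per condition, in
#'   level order), with attribute `dropped` (edge-less genes). Each network
#'   is a list with `condition`, `nodes` and `edges`
#'   (`gene1, gene2, cc, distance, affinity`).
#' @export
build_condition_networks <- function(es, kept_genes, edges) {
  stopifnot(inherits(es, "expression_set"))
  keep <- edges$gene1 %in% kept_genes & edges$gene2 %in% kept_genes
  sub <- edges[keep, c("gene1", "gene2"), drop = FALSE]
  if (!nrow(sub))
    stop("no PPI edges connect the retained genes; cannot build networks")
  nodes <- sort(unique(c(sub$gene1, sub$gene2)))
  dropped <- setdiff(intersect(kept_genes, rownames(es$expr)), nodes)
  if (length(dropped))
    message("excluding ", length(dropped), " gene(s) lacking connections")
  nets <- lapply(levels(es$condition), function(lv) {
    cc <- condition_correlations(es, nodes, sub, lv)
    structure(list(
      condition = lv,
      nodes = nodes,
      edges = data.frame(gene1 = sub$gene1, gene2 = sub$gene2,
                         cc = as.numeric(cc),
                         distance = 1 - abs(as.numeric(cc)),
                         affinity = abs(as.numeric(cc)),
                         stringsAsFactors = FALSE)
    ), class = "condition_network")
  })
  names(nets) <- levels(es$condition)
  attr(nets, "dropped") <- dropped
  nets
}

#' @export
print.condition_network <- function(x, ...) {
  cat(sprintf("condition_network [%s]: %d nodes, %d edges, mean |cc| = %.3f\n",
              x$condition, length(x$nodes), nrow(x$edges),
              mean(x$edges$affinity)))
  invisible(x)
}
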