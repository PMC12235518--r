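# Synthetic two-condition expression data with planted network rewiring.
#
# The generator emulates the data regime the differential-centrality
# method targets: a scale-free PPI-like scaffold whose gene-pair
# correlations follow the network, a minority of "rewired" hub genes whose
# incident correlations collapse in one condition while their expression
# shifts only subtly, conventional DEGs with clear mean shifts and no
# rewiring, and pervasive weak background fold changes as seen in real
# tumor/normal cohorts. Everything is a pure function of its parameters
# and seed.

#' Scale-free scaffold network
#'
#' Connected preferential-attachment (Barabasi-Albert) graph built with
#' `igraph::sample_pa`, giving the heavy-tailed degree distribution of
#' curated PPI networks. Edge confidences default to the constant 999
#' (top of the STRING 0-1000 scale); supply a range to draw integer
#' confidences uniformly, which gives threshold-robustness studies a
#' non-degenerate confidence distribution.
#'
#' @param n_genes Number of genes (>= attach + 2).
#' @param attach Edges added per new node (preferential attachment).
#' @param seed Integer seed; the result is deterministic given it.
#' @param confidence Length-2 integer range for edge confidences
#'   (default `c(999, 999)`, i.e. constant).
#' @return Edge data frame `gene1`, `gene2`, `confidence` over genes named
#'   `G0001`, `G0002`, ...
#' @export
make_scaffold <- function(n_genes, attach = 8, seed = 1,
                          confidence = c(999, 999)) {
  if (n_genes < attach + 2)
    stop("need n_genes >= attach + 2")
  set.seed(seed)
  g <- igraph::sample_pa(n_genes, m = attach, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  # sample_pa can emit duplicate multi-edges; collapse them
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[!duplicated(key), , drop = FALSE]
  gene_names <- sprintf("G%04d", seq_len(n_genes))
  conf <- if (confidence[1] == confidence[2]) rep(confidence[1], nrow(el))
          else sample(seq(confidence[1], confidence[2]), nrow(el), replace = TRUE)
  data.frame(gene1 = gene_names[pmin(el[, 1], el[, 2])],
             gene2 = gene_names[pmax(el[, 1], el[, 2])],
             confidence = conf,
             stringsAsFactors = FALSE)
}

#' Assign per-condition target correlations to scaffold edges
#'
#' Condition-1 targets are drawn uniformly from `base_range` in magnitude.
#' Signs come from per-gene latent signs (edge sign = product of endpoint
#' signs), which models coherent up/down co-regulation modules and avoids
#' frustrated triangles that a per-edge random sign would create.
#' Condition-2 targets are identical except on edges incident to a rewired
#' gene, whose magnitude is reduced by `rewire_drop` (floored at 0.05,
#' sign kept) — the correlation collapse that moves both betweenness
#' (longer paths through the gene) and eigenvector centrality (weaker
#' affinities).
#'
#' @param scaffold Edge data frame from [make_scaffold()].
#' @param rewired Character vector of rewired genes (subset of scaffold
#'   nodes).
#' @param base_range Magnitude range for condition-1 correlations.
#' @param rewire_drop Magnitude reduction on rewired genes' edges, in
#'   (0, `base_range[2]`\].
#' @param seed Integer seed.
#' @return Data frame `gene1`, `gene2`, `target_c1`, `target_c2`.
#' @export
assign_edge_correlations <- function(scaffold, rewired = character(),
                                     base_range = c(0.4, 0.8),
                                     rewire_drop = 0.6, seed = 1) {
  nodes <- sort(unique(c(scaffold$gene1, scaffold$gene2)))
  if (!all(rewired %in% nodes))
    stop("rewired genes must be scaffold nodes")
  if (rewire_drop <= 0 || rewire_drop > base_range[2])
    stop("rewire_drop must lie in (0, base_range[2]]")
  if (base_range[2] > 0.95)
    stop("target correlations must stay within [-0.95, 0.95]")
  set.seed(seed)
  s <- stats::setNames(sample(c(-1, 1), length(nodes), replace = TRUE), nodes)
  m <- nrow(scaffold)
  mag <- stats::runif(m, base_range[1], base_range[2])
  sgn <- s[scaffold$gene1] * s[scaffold$gene2]
  t1 <- unname(mag * sgn)
  inc <- scaffold$gene1 %in% rewired | scaffold$gene2 %in% rewired
  t2 <- t1
  t2[inc] <- sign(t1[inc]) * pmax(mag[inc] - rewire_drop, 0.05)
  data.frame(gene1 = scaffold$gene1, gene2 = scaffold$gene2,
             target_c1 = t1, target_c2 = t2, stringsAsFactors = FALSE)
}

# internal: nearest-PD projection of a target correlation matrix
# (eigenvalue clipping at 1e-6 followed by rescaling to unit diagonal).
# Returns the projected matrix with the maximum absolute entry change as
# attribute "max_shift".
.pd_project <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 1e-6)
  R2 <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(R2))
  if (any(d <= 0)) stop("positive-definite projection failed")
  R2 <- R2 / outer(d, d)
  diag(R2) <- 1
  attr(R2, "max_shift") <- max(abs(R2 - R))
  R2
}

#' Simulate a two-condition expression matrix from edge correlation targets
#'
#' Builds one target correlation matrix per condition (off-scaffold pairs
#' 0), projects each to the nearest positive-definite correlation matrix
#' (eigenvalue clipping + diagonal rescaling), draws multivariate normal
#' log-expression with marginal standard deviation `noise_sd` around
#' `baseline`, and adds the requested mean shifts (`log2FC`) to
#' condition-2 samples. Projection distortion is unavoidable for strong
#' correlations at hubs (a hub of degree d cannot hold uniform neighbor
#' correlations above ~1/sqrt(d)); the realized post-projection targets
#' and the maximum per-entry change are stored in the returned truth.
#'
#' @param targets Data frame from [assign_edge_correlations()].
#' @param n_per_condition Samples per condition (>= 20 recommended for
#'   correlation fidelity).
#' @param deg_lfc Named numeric vector gene -> log2 fold change to add in
#'   condition 2 (may be empty).
#' @param noise_sd Marginal standard deviation of log-expression within a
#'   condition.
#' @param baseline Mean log-expression level.
#' @param seed Integer seed.
#' @param conditions Length-2 character vector of condition labels.
#' @return List with `es` (an [expression_set]) and `truth` (list holding
#'   the scaffold, raw and realized per-condition targets, planted log2FC,
#'   projection shifts and the seed).
#' @export
simulate_expression <- function(targets, n_per_condition = 60,
                                deg_lfc = numeric(), noise_sd = 0.25,
                                baseline = 8, seed = 1,
                                conditions = c("c1", "c2")) {
  nodes <- sort(unique(c(targets$gene1, targets$gene2)))
  p <- length(nodes)
  if (length(deg_lfc) && !all(names(deg_lfc) %in% nodes))
    stop("deg_lfc names must be scaffold genes")
  i <- match(targets$gene1, nodes)
  j <- match(targets$gene2, nodes)
  build <- function(tt) {
    R <- diag(p)
    R[cbind(i, j)] <- tt
    R[cbind(j, i)] <- tt
    R
  }
  P1 <- .pd_project(build(targets$target_c1))
  P2 <- .pd_project(build(targets$target_c2))
  set.seed(seed)
  draw <- function(P, n) {
    L <- chol(P + diag(1e-10, p))
    baseline + noise_sd * crossprod(L, matrix(stats::rnorm(p * n), p, n))
  }
  X1 <- draw(P1, n_per_condition)
  X2 <- draw(P2, n_per_condition)
  if (length(deg_lfc)) {
    k <- match(names(deg_lfc), nodes)
    X2[k, ] <- X2[k, ] + deg_lfc
  }
  X <- cbind(X1, X2)
  rownames(X) <- nodes
  colnames(X) <- c(sprintf("%s_s%03d", conditions[1], seq_len(n_per_condition)),
                   sprintf("%s_s%03d", conditions[2], seq_len(n_per_condition)))
  groups <- data.frame(sample = colnames(X),
                       condition = rep(conditions, each = n_per_condition),
                       stringsAsFactors = FALSE)
  realized <- data.frame(gene1 = targets$gene1, gene2 = targets$gene2,
                         realized_c1 = P1[cbind(i, j)],
                         realized_c2 = P2[cbind(i, j)],
                         stringsAsFactors = FALSE)
  truth <- list(targets = targets, realized = realized,
                planted_lfc = deg_lfc, noise_sd = noise_sd,
                projection_shift = c(attr(P1, "max_shift"),
                                     attr(P2, "max_shift")),
                seed = seed)
  list(es = expression_set(X, groups), truth = truth)
}

#' One-call synthetic benchmark dataset
#'
#' Generates a scaffold, plants rewired genes at hubs (drawn from the
#' `hub_pool` highest-degree nodes, where rewiring has the network-wide
#' reach the method looks for), plants conventional DEGs with
#' `|log2FC| = deg_lfc` at random non-rewired genes, gives rewired genes a
#' subtle shift `|log2FC| = rewired_lfc`, and adds weak background fold
#' changes `N(0, background_lfc_sd)` to all remaining genes (the pervasive
#' low-level dysregulation of real two-condition cohorts). Returns the
#' expression set, the scaffold edge list and a ground-truth record.
#'
#' @param n_genes,attach,confidence Scaffold parameters, see
#'   [make_scaffold()].
#' @param n_per_condition Samples per condition.
#' @param n_rewired,rewire_drop Number of rewired hub genes and the
#'   correlation attenuation on their edges.
#' @param n_deg Number of conventional DEGs.
#' @param rewired_lfc,deg_lfc Absolute log2 fold changes for rewired genes
#'   and DEGs (random signs).
#' @param background_lfc_sd SD of the background fold changes (0 for a
#'   clean null outside the planted genes).
#' @param base_range,noise_sd,baseline See [assign_edge_correlations()] /
#'   [simulate_expression()].
#' @param hub_pool Rewired genes are sampled from this many top-degree
#'   nodes.
#' @param seed Integer seed.
#' @return List `es`, `edges`, `truth` where `truth` additionally records
#'   `rewired` and `deg` gene sets.
#' @export
simulate_dice_data <- function(n_genes = 300, attach = 8,
                               n_per_condition = 60,
                               n_rewired = 10, rewire_drop = 0.6,
                               n_deg = 20, rewired_lfc = 0.3, deg_lfc = 0.6,
                               background_lfc_sd = 0.15,
                               base_range = c(0.4, 0.8), noise_sd = 0.25,
                               baseline = 8, hub_pool = 40,
                               confidence = c(999, 999), seed = 1) {
  scaffold <- make_scaffold(n_genes, attach = attach, seed = seed,
                            confidence = confidence)
  nodes <- sort(unique(c(scaffold$gene1, scaffold$gene2)))
  deg_count <- table(factor(c(scaffold$gene1, scaffold$gene2), levels = nodes))
  set.seed(seed + 1000003L)
  hubs <- names(sort(deg_count, decreasing = TRUE))[seq_len(min(hub_pool, length(nodes)))]
  rewired <- sort(sample(hubs, n_rewired))
  degs <- sort(sample(setdiff(nodes, rewired), n_deg))
  lfc <- stats::setNames(stats::rnorm(length(nodes), 0, background_lfc_sd), nodes)
  if (background_lfc_sd == 0) lfc[] <- 0
  lfc[degs] <- sample(c(-1, 1), n_deg, replace = TRUE) * deg_lfc
  lfc[rewired] <- sample(c(-1, 1), n_rewired, replace = TRUE) * rewired_lfc
  targets <- assign_edge_correlations(scaffold, rewired = rewired,
                                      base_range = base_range,
                                      rewire_drop = rewire_drop,
                                      seed = seed + 2000003L)
  sim <- simulate_expression(targets, n_per_condition = n_per_condition,
                             deg_lfc = lfc[lfc != 0 | names(lfc) %in% c(degs, rewired)],
                             noise_sd = noise_sd, baseline = baseline,
                             seed = seed + 3000017L)
  sim$truth$rewired <- rewired
  sim$truth$deg <- degs
  sim$truth$all_lfc <- lfc
  list(es = sim$es, edges = scaffold, truth = sim$truth)
}
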