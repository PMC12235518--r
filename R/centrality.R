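# Phase IV: weighted betweenness and eigenvector centrality per condition.
#
# Betweenness runs Brandes' accumulation over Dijkstra shortest-path DAGs
# with `distance` as edge length; tied shortest paths are split
# fractionally. Zero distances (|cc| = 1) are legal: relaxation only ever
# targets unfinalized nodes, so the predecessor relation stays acyclic.
# Eigenvector centrality is the dominant eigenvector of the
# affinity-weighted adjacency matrix, computed by shifted power iteration,
# non-negative and scaled to unit Euclidean norm. In disconnected graphs
# components not carrying the dominant eigenvalue receive (near-)zero
# values.

# internal: adjacency structure from a condition_network-like edge table
.adjacency <- function(nodes, edges, weight) {
  n <- length(nodes)
  i <- match(edges$gene1, nodes)
  j <- match(edges$gene2, nodes)
  w <- edges[[weight]]
  adj <- vector("list", n)
  for (k in seq_along(i)) {
    adj[[i[k]]] <- rbind(adj[[i[k]]], c(j[k], w[k]))
    adj[[j[k]]] <- rbind(adj[[j[k]]], c(i[k], w[k]))
  }
  adj
}

#' Weighted betweenness centrality
#'
#' Fraction of all-pairs shortest paths passing through each node, with
#' `distance` (= 1 - |cc|) as the edge length. Tied shortest paths
#' contribute fractionally (standard Brandes dependency splitting);
#' endpoints are excluded. Values are normalized by (n-1)(n-2)/2, the
#' number of node pairs an inner node can bridge in an undirected graph of
#' n nodes, so results lie in \[0, 1\] and are comparable between the two
#' same-sized condition networks. Graphs with fewer than 3 nodes score 0
#' everywhere.
#'
#' @param network A `condition_network` (see [build_condition_networks()]),
#'   or any list with `nodes` and an `edges` data frame containing a
#'   `distance` column.
#' @return Named numeric vector of normalized betweenness values.
#' @export
weighted_betweenness <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  if (any(edges$distance < 0)) stop("negative edge distance")
  n <- length(nodes)
  cb <- numeric(n)
  names(cb) <- nodes
  if (n < 3) return(cb)
  adj <- .adjacency(nodes, edges, "distance")
  tol <- 1e-12
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sigma <- numeric(n); sigma[s] <- 1
    preds <- vector("list", n)
    done <- logical(n)
    order_out <- integer(0)
    repeat {
      cand <- which(!done & is.finite(d))
      if (!length(cand)) break
      u <- cand[which.min(d[cand])]
      done[u] <- TRUE
      order_out <- c(order_out, u)
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (done[v]) next
        nd <- d[u] + nb[r, 2]
        if (nd < d[v] - tol) {
          d[v] <- nd
          sigma[v] <- sigma[u]
          preds[[v]] <- u
        } else if (abs(nd - d[v]) <= tol) {
          sigma[v] <- sigma[v] + sigma[u]
          preds[[v]] <- c(preds[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (u in rev(order_out)) {
      for (p in preds[[u]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[u] * (1 + delta[u])
      }
      if (u != s) cb[u] <- cb[u] + delta[u]
    }
  }
  # each unordered pair counted twice (once per endpoint as source)
  cb / 2 / (((n - 1) * (n - 2)) / 2)
}

#' Eigenvector centrality of an affinity-weighted network
#'
#' Dominant eigenvector of the symmetric adjacency matrix weighted by edge
#' `affinity` (= |cc|); larger weights mean stronger connections, which is
#' the orientation eigenvector centrality requires (distances are only used
#' for shortest paths). Computed by power iteration with a small positive
#' diagonal shift (which leaves eigenvectors unchanged but prevents
#' oscillation on bipartite graphs), tolerance 1e-10 on the L-infinity
#' change, at most `max_iter` iterations. The result is non-negative with
#' Euclidean norm 1.
#'
#' @param network A `condition_network`, or any list with `nodes` and an
#'   `edges` data frame containing an `affinity` column.
#' @param weighting `"affinity"` (default) uses |cc| as edge weight;
#'   `"unweighted"` uses 1 for every edge.
#' @param tol Convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000); exceeding it is an error
#'   reporting the residual.
#' @return Named numeric vector (unit Euclidean norm, entries >= 0).
#' @export
eigenvector_centrality <- function(network, weighting = c("affinity", "unweighted"),
                                   tol = 1e-10, max_iter = 1000) {
  weighting <- match.arg(weighting)
  nodes <- network$nodes
  edges <- network$edges
  n <- length(nodes)
  w <- if (weighting == "affinity") edges$affinity else rep(1, nrow(edges))
  if (any(w < 0)) stop("negative affinity weight")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  i <- match(edges$gene1, nodes)
  j <- match(edges$gene2, nodes)
  A[cbind(i, j)] <- w
  A[cbind(j, i)] <- w
  if (max(A) == 0) {
    warning("all affinities are zero; eigenvector centrality undefined, returning zeros")
    return(stats::setNames(numeric(n), nodes))
  }
  # Components decouple in the eigenproblem: the dominant eigenvector of
  # the whole graph is the dominant eigenvector of the component with the
  # largest leading eigenvalue, padded with zeros. Iterating per component
  # keeps convergence fast even when two components have near-tied
  # eigenvalues (where full-matrix power iteration stalls). Exact ties go
  # to the component holding the lexicographically smallest node.
  comp <- .components(n, A)
  best <- NULL
  for (members in comp) {
    Ak <- A[members, members, drop = FALSE]
    if (max(Ak) == 0) next
    pw <- .power_iterate(Ak, tol, max_iter)
    if (is.null(best) || pw$lambda > best$lambda + 1e-12) {
      best <- pw
      best$members <- members
    }
  }
  if (is.null(best)) {
    warning("all affinities are zero; eigenvector centrality undefined, returning zeros")
    return(stats::setNames(numeric(n), nodes))
  }
  v <- numeric(n)
  v[best$members] <- best$vector
  v[v < 0] <- 0                          # tiny negative rounding only
  v <- v / sqrt(sum(v^2))
  stats::setNames(v, nodes)
}

# connected components of a dense symmetric adjacency (BFS)
.components <- function(n, A) {
  seen <- logical(n)
  out <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      nb <- which(A[u, ] > 0 & !seen)
      if (length(nb)) {
        seen[nb] <- TRUE
        members <- c(members, nb)
        queue <- c(queue, nb)
      }
    }
    out[[length(out) + 1]] <- sort(members)
  }
  out
}

# shifted power iteration on one (connected) component; the diagonal shift
# leaves eigenvectors unchanged and prevents oscillation on bipartite
# graphs, where the spectrum is symmetric
.power_iterate <- function(A, tol, max_iter) {
  n <- nrow(A)
  if (n == 1) return(list(vector = 1, lambda = 0))
  shift <- 0.05 * max(rowSums(A))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    av <- as.numeric(A %*% v)
    v1 <- av + shift * v
    v1 <- v1 / sqrt(sum(v1^2))
    res <- max(abs(v1 - v))
    if (res < tol)
      return(list(vector = v1, lambda = sum(v1 * (A %*% v1))))
    v <- v1
  }
  stop(sprintf("power iteration did not converge in %d iterations (residual %.3g)",
               max_iter, res))
}

#' Per-gene centrality table with cross-condition differences
#'
#' Computes betweenness and eigenvector centrality in each condition
#' network and the per-gene absolute differences, the quantities the
#' ensemble ranking consumes.
#'
#' @param networks List of two `condition_network`s over the same node and
#'   edge set (see [build_condition_networks()]).
#' @param eigen_weight Weighting passed to [eigenvector_centrality()].
#' @return An object of class `centrality_table`: data frame with columns
#'   `gene`, `betweenness_c1`, `betweenness_c2`, `eigen_c1`, `eigen_c2`,
#'   `delta_betweenness`, `delta_eigenvector`; attribute `conditions` holds
#'   the two condition labels.
#' @export
centrality_table <- function(networks, eigen_weight = "affinity") {
  stopifnot(length(networks) == 2)
  n1 <- networks[[1]]; n2 <- networks[[2]]
  if (!identical(n1$nodes, n2$nodes))
    stop("condition networks have different node sets")
  b1 <- weighted_betweenness(n1)
  b2 <- weighted_betweenness(n2)
  e1 <- eigenvector_centrality(n1, weighting = eigen_weight)
  e2 <- eigenvector_centrality(n2, weighting = eigen_weight)
  out <- data.frame(gene = n1$nodes,
                    betweenness_c1 = unname(b1), betweenness_c2 = unname(b2),
                    eigen_c1 = unname(e1), eigen_c2 = unname(e2),
                    delta_betweenness = abs(unname(b2 - b1)),
                    delta_eigenvector = abs(unname(e2 - e1)),
                    stringsAsFactors = FALSE)
  attr(out, "conditions") <- c(n1$condition, n2$condition)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Absolute centrality differences from two per-condition tables
#'
#' Convenience for precomputed centralities: given two data frames with
#' columns `gene`, `betweenness`, `eigenvector` over the same gene set,
#' returns the per-gene absolute differences. Symmetric in its arguments.
#'
#' @param tab1,tab2 Data frames with columns `gene`, `betweenness`,
#'   `eigenvector`.
#' @return Data frame `gene`, `delta_betweenness`, `delta_eigenvector`.
#' @export
centrality_delta <- function(tab1, tab2) {
  if (!setequal(tab1$gene, tab2$gene))
    stop("the two tables cover different gene sets")
  m <- match(tab1$gene, tab2$gene)
  data.frame(gene = tab1$gene,
             delta_betweenness = abs(tab2$betweenness[m] - tab1$betweenness),
             delta_eigenvector = abs(tab2$eigenvector[m] - tab1$eigenvector),
             stringsAsFactors = FALSE)
}
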