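# Independent oracles and fixture builders used across the suite.
# Every oracle is deliberately brute-force and shares no code with the
# implementation it checks.

# --- exhaustive betweenness oracle -----------------------------------------
# Enumerates all simple paths between every node pair, finds the minimal
# total distance, and credits intermediate nodes fractionally over the tied
# minimal paths. Same (n-1)(n-2)/2 normalization as the implementation.
oracle_betweenness <- function(net, tol = 1e-9) {
  nodes <- net$nodes
  n <- length(nodes)
  score <- stats::setNames(numeric(n), nodes)
  if (n < 3) return(score)
  i <- match(net$edges$gene1, nodes)
  j <- match(net$edges$gene2, nodes)
  w <- net$edges$distance
  nbr <- lapply(seq_len(n), function(v) {
    rbind(cbind(j[i == v], w[i == v]), cbind(i[j == v], w[j == v]))
  })
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, seen, len) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(via = seen[-c(1, length(seen))],
                                            len = len)
        return()
      }
      nb <- nbr[[v]]
      if (!nrow(nb)) return()
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (u %in% seen) next
        walk(u, c(seen, u), len + nb[r, 2])
      }
    }
    walk(s, s, 0)
    paths
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- all_paths(s, t)
    if (!length(ps)) next
    lens <- vapply(ps, `[[`, 0, "len")
    best <- min(lens)
    min_ps <- ps[lens <= best + tol]
    cnt <- numeric(n)
    for (p in min_ps) cnt[p$via] <- cnt[p$via] + 1
    score <- score + cnt / length(min_ps)
  }
  score / ((n - 1) * (n - 2) / 2)
}

# --- dense eigendecomposition oracle ---------------------------------------
oracle_eigen <- function(net, weight = "affinity") {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n)
  i <- match(net$edges$gene1, nodes)
  j <- match(net$edges$gene2, nodes)
  w <- if (weight == "affinity") net$edges$affinity else rep(1, length(i))
  A[cbind(i, j)] <- w
  A[cbind(j, i)] <- w
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)
  stats::setNames(v / sqrt(sum(v^2)), nodes)
}

# --- hand-evaluated BH step-up ---------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) {
    min(ps[i:m] * m / (i:m), 1)
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# --- exact hypergeometric upper tail by term-wise summation ----------------
oracle_hyper <- function(k, K, n, M) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(M - K, n - i)) / choose(M, n)
}

# --- Welch t-test p-value from the textbook formula ------------------------
oracle_welch_p <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(y) - mean(x)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# --- random connected weighted network -------------------------------------
# Random spanning tree plus extra edges, distances uniform in [0.05, 1].
rand_net <- function(n, extra = 2, seed = 1) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  e <- cbind(2:n, vapply(2:n, function(k) sample.int(k - 1, 1), 0L))
  want <- extra
  while (want > 0) {
    cand <- sort(sample.int(n, 2))
    if (!any(e[, 1] == cand[2] & e[, 2] == cand[1]) && cand[1] != cand[2]) {
      e <- rbind(e, c(cand[2], cand[1]))
      want <- want - 1
    } else want <- want - 1  # skip duplicates without looping forever
  }
  cc <- runif(nrow(e), 0, 0.95)
  list(nodes = nodes,
       edges = data.frame(gene1 = nodes[e[, 2]], gene2 = nodes[e[, 1]],
                          cc = cc, distance = 1 - cc, affinity = cc,
                          stringsAsFactors = FALSE))
}

# --- small deterministic expression set ------------------------------------
# 6 genes x 8 samples, two conditions of 4; gene G1 strongly shifted,
# G6 constant.
tiny_es <- function(seed = 1, n_per = 4) {
  set.seed(seed)
  g <- sprintf("G%d", 1:6)
  s <- sprintf("S%d", seq_len(2 * n_per))
  m <- matrix(rnorm(6 * 2 * n_per, 8, 0.5), 6, 2 * n_per,
              dimnames = list(g, s))
  m[1, (n_per + 1):(2 * n_per)] <- m[1, (n_per + 1):(2 * n_per)] + 3
  m[6, ] <- 5
  groups <- data.frame(sample = s,
                       condition = rep(c("normal", "tumor"), each = n_per))
  expression_set(m, groups, min_per_condition = 3)
}
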