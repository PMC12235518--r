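# Phase II: information-gain feature selection.
#
# Entropies are in bits (log base 2). For a two-class design the dataset
# entropy D is at most 1 bit and 0 <= IG(g) <= D for every gene.

#' Entropy of a class-label distribution
#'
#' D = -sum_i (S_i/N) log2(S_i/N), with 0 log2(0) taken as 0.
#'
#' @param labels Vector of class labels, one per sample (any number of
#'   classes).
#' @return Entropy in bits.
#' @export
dataset_entropy <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  pr <- table(labels) / length(labels)
  pr <- pr[pr > 0]
  -sum(pr * log2(pr))
}

#' Discretize expression values into bins
#'
#' `equal_frequency` cuts at type-1 (inverse-ECDF) quantiles, so bin
#' membership depends only on value ranks: any strictly increasing
#' transform of the data yields identical bins. `equal_width` cuts the
#' observed range into equal-length intervals. `distinct` uses each
#' distinct value as its own level (the degenerate mode for continuous
#' data, where every sample may be its own bin). Duplicate cut points
#' (heavily tied data) collapse bins; a constant vector yields a single
#' bin.
#'
#' @param values Numeric vector.
#' @param method One of `"equal_frequency"`, `"equal_width"`, `"distinct"`.
#' @param bins Number of bins (>= 2); ignored for `"distinct"`.
#' @return Integer vector of bin indices, one per sample.
#' @export
discretize_expression <- function(values, method = c("equal_frequency",
                                                     "equal_width", "distinct"),
                                  bins = 10) {
  method <- match.arg(method)
  if (method == "distinct") return(as.integer(factor(values)))
  if (bins < 2) stop("bins must be >= 2")
  if (length(unique(values)) == 1L) return(rep(1L, length(values)))
  if (method == "equal_frequency") {
    if (length(values) < bins)
      stop("need at least `bins` values for equal-frequency discretization")
    br <- unique(stats::quantile(values, probs = seq_len(bins - 1) / bins,
                                 type = 1, names = FALSE))
    findInterval(values, br, left.open = TRUE) + 1L
  } else {
    br <- seq(min(values), max(values), length.out = bins + 1L)
    pmin(pmax(findInterval(values, br, rightmost.closed = TRUE), 1L),
         as.integer(bins))
  }
}

#' Information gain of a discretized gene
#'
#' IG = D - sum_v (|N_v|/N) entropy(N_v), where D is the class-label
#' entropy of the whole dataset and N_v the subset of samples in bin v.
#'
#' @param gene_bins Bin label per sample (see [discretize_expression()]).
#' @param labels Class label per sample.
#' @return Information gain in bits.
#' @export
information_gain <- function(gene_bins, labels) {
  if (length(gene_bins) != length(labels))
    stop("gene_bins and labels must have the same length")
  D <- dataset_entropy(labels)
  N <- length(labels)
  tb <- table(gene_bins, labels)
  wts <- rowSums(tb) / N
  ent <- apply(tb, 1, function(row) {
    pr <- row[row > 0] / sum(row)
    -sum(pr * log2(pr))
  })
  ig <- D - sum(wts * ent)
  # guard tiny negative rounding
  max(ig, 0)
}

#' Information-gain filter over a candidate pool
#'
#' Computes IG for every pool gene on its (z-scored) expression and keeps
#' genes whose IG strictly exceeds the pool mean. If no gene exceeds the
#' mean (all IG equal), all genes are retained with a warning so the
#' pipeline never silently empties.
#'
#' The default bin count adapts to small cohorts:
#' `min(10, floor(N/3), number of distinct values)` with N the total
#' sample count.
#'
#' @param pool A [candidate_pool].
#' @param labels Condition label per sample (defaults are taken from the
#'   pool's expression set when built through [dice()]).
#' @param method Discretization method, see [discretize_expression()].
#' @param bins Bin count; `NULL` for the adaptive default.
#' @return An object of class `ig_result`: data frame with columns `gene`,
#'   `IG`, `kept`, plus attributes `dataset_entropy`, `mean_ig`, `method`,
#'   `bins`.
#' @export
ig_filter <- function(pool, labels, method = "equal_frequency", bins = NULL) {
  stopifnot(inherits(pool, "candidate_pool"))
  N <- ncol(pool$zexpr)
  if (length(labels) != N) stop("one label per sample required")
  if (is.null(bins))
    bins <- max(2L, min(10L, floor(N / 3)))
  ig <- apply(pool$zexpr, 1, function(x) {
    b <- if (method == "distinct") discretize_expression(x, "distinct")
         else discretize_expression(x, method,
                                    bins = max(2L, min(bins, length(unique(x)))))
    information_gain(b, labels)
  })
  mu <- mean(ig)
  kept <- ig > mu
  if (!any(kept)) {
    warning("no gene exceeds the mean IG (all equal); retaining all")
    kept <- rep(TRUE, length(ig))
  }
  res <- data.frame(gene = pool$genes, IG = unname(ig), kept = unname(kept),
                    stringsAsFactors = FALSE)
  attr(res, "dataset_entropy") <- dataset_entropy(labels)
  attr(res, "mean_ig") <- mu
  attr(res, "method") <- method
  attr(res, "bins") <- bins
  class(res) <- c("ig_result", "data.frame")
  res
}

#' @export
print.ig_result <- function(x, ...) {
  cat(sprintf("ig_result: %d/%d genes kept (IG > mean %.4g; D = %.4g bits)\n",
              sum(x$kept), nrow(x), attr(x, "mean_ig"),
              attr(x, "dataset_entropy")))
  invisible(x)
}
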