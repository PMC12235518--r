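# Phase V: rank-product ensemble score and mean-centrality exclusion.
#
# Each |delta centrality| vector is ranked in descending order (rank 1 =
# largest shift, average ranks on ties), normalized to [0, 1] with the top
# rank mapping to exactly 1 and the bottom to exactly 0, and the per-gene
# ensemble score is the product of the normalized ranks. Note the
# normalization makes the bottom of the ranking degenerate: a last-place
# finish in either measure zeroes the product.

#' Descending average-tie ranks
#'
#' Rank 1 = largest value; ties receive the average of the ranks they span.
#'
#' @param values Numeric vector (length >= 2).
#' @return Numeric rank vector.
#' @export
rank_descending <- function(values) {
  if (length(values) < 2) stop("ranking needs at least 2 values")
  rank(-values, ties.method = "average")
}

#' Normalize ranks to \[0, 1\]
#'
#' norm = (N - r) / (N - 1): rank 1 maps to exactly 1 (highest importance),
#' rank N to exactly 0.
#'
#' @param ranks Numeric ranks in \[1, N\].
#' @param N Number of ranked items (defaults to `length(ranks)`).
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_ranks <- function(ranks, N = length(ranks)) {
  if (N < 2) stop("normalization needs N >= 2")
  if (any(ranks < 1 | ranks > N)) stop("ranks must lie in [1, N]")
  (N - ranks) / (N - 1)
}

#' Rank-product ensemble score
#'
#' Product of a gene's normalized ranks across the centrality measures.
#'
#' @param norm_b,norm_e Normalized ranks for the betweenness and
#'   eigenvector differences.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
ensemble_score <- function(norm_b, norm_e) {
  if (length(norm_b) != length(norm_e))
    stop("both measures must be present for every gene")
  if (anyNA(norm_b) || anyNA(norm_e)) stop("missing normalized rank")
  norm_b * norm_e
}

#' Mean-centrality exclusion filter
#'
#' Flags genes whose centralities fall below the mean value computed over
#' all network genes, per measure and per condition. The default mode
#' `all_below` excludes a gene only when it is below the mean for every
#' measure in every condition (the conservative reading); mode
#' `either_measure_below` excludes a gene as soon as one measure is below
#' its mean in both conditions.
#'
#' @param cent A [centrality_table()].
#' @param mode `"all_below"` (default) or `"either_measure_below"`.
#' @return Logical vector (`TRUE` = excluded), with attribute `means`.
#' @export
centrality_mean_filter <- function(cent, mode = c("all_below",
                                                  "either_measure_below")) {
  mode <- match.arg(mode)
  mb1 <- mean(cent$betweenness_c1); mb2 <- mean(cent$betweenness_c2)
  me1 <- mean(cent$eigen_c1);       me2 <- mean(cent$eigen_c2)
  b_below <- cent$betweenness_c1 < mb1 & cent$betweenness_c2 < mb2
  e_below <- cent$eigen_c1 < me1 & cent$eigen_c2 < me2
  excl <- if (mode == "all_below") b_below & e_below else b_below | e_below
  attr(excl, "means") <- c(betweenness_c1 = mb1, betweenness_c2 = mb2,
                           eigen_c1 = me1, eigen_c2 = me2)
  attr(excl, "mode") <- mode
  excl
}

#' Final ensemble gene table
#'
#' Assembles the per-gene ranking table: descending ranks of each
#' |delta centrality|, normalized ranks, ensemble score, exclusion flag
#' from [centrality_mean_filter()], regulation direction from the DE
#' log2FC sign, and the final rank among non-excluded genes. Non-excluded
#' genes are sorted by ensemble score (descending); ties are broken by
#' larger `delta_betweenness`, then lexicographic gene symbol, so the
#' ordering is a reproducible strict total order.
#'
#' @param cent A [centrality_table()].
#' @param de DE table (`gene`, `log2FC`, `p`, `q`).
#' @param exclusion_mode Passed to [centrality_mean_filter()].
#' @return An object of class `dice_table`: data frame with columns `gene`,
#'   `direction`, `log2FC`, `q`, `delta_betweenness`, `delta_eigenvector`,
#'   `rank_b`, `rank_e`, `norm_b`, `norm_e`, `ensemble_score`, `excluded`,
#'   `exclusion_reason`, `final_rank` (NA for excluded genes), ordered by
#'   the final ranking with excluded genes last.
#' @export
dice_table <- function(cent, de, exclusion_mode = "all_below") {
  stopifnot(inherits(cent, "data.frame"))
  N <- nrow(cent)
  if (N < 2) stop("need at least 2 network genes to rank")
  rb <- rank_descending(cent$delta_betweenness)
  re <- rank_descending(cent$delta_eigenvector)
  nb <- normalize_ranks(rb, N)
  ne <- normalize_ranks(re, N)
  score <- ensemble_score(nb, ne)
  excl <- centrality_mean_filter(cent, mode = exclusion_mode)
  m <- match(cent$gene, de$gene)
  lfc <- de$log2FC[m]
  dir <- ifelse(is.na(lfc), NA_character_,
                ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "flat")))
  out <- data.frame(
    gene = cent$gene, direction = dir, log2FC = lfc, q = de$q[m],
    delta_betweenness = cent$delta_betweenness,
    delta_eigenvector = cent$delta_eigenvector,
    rank_b = rb, rank_e = re, norm_b = nb, norm_e = ne,
    ensemble_score = score,
    excluded = as.logical(excl),
    exclusion_reason = ifelse(excl,
                              paste0("below mean centrality (",
                                     attr(excl, "mode"), ")"), ""),
    stringsAsFactors = FALSE)
  ord <- order(out$excluded, -out$ensemble_score, -out$delta_betweenness,
               out$gene, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$final_rank <- NA_real_
  out$final_rank[!out$excluded] <- seq_len(sum(!out$excluded))
  if (!any(!out$excluded))
    stop("every gene was excluded by the mean-centrality filter")
  attr(out, "exclusion_mode") <- exclusion_mode
  attr(out, "means") <- attr(excl, "means")
  class(out) <- c("dice_table", "data.frame")
  out
}

#' @export
print.dice_table <- function(x, n = 10, ...) {
  cat(sprintf("dice_table: %d genes, %d retained (%s exclusion)\n",
              nrow(x), sum(!x$excluded), attr(x, "exclusion_mode")))
  print.data.frame(utils::head(x[!x$excluded,
                                 c("gene", "direction", "log2FC",
                                   "delta_betweenness", "delta_eigenvector",
                                   "ensemble_score", "final_rank")], n),
                   row.names = FALSE, digits = 4)
  invisible(x)
}
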