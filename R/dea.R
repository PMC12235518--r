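# Phase I: candidate gene pool from differential expression.
#
# The recommended route is to ingest a DE table produced by a dedicated
# tool (limma, edgeR, DESeq2) via read_de_table(); de_test() is a
# self-contained fallback (Welch's t, or a paired t when pairing is
# present) for datasets where no external table is available.

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' q_(i) = min over j >= i of p_(j) * m / j, clipped to 1, mapped back to
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene two-condition differential expression (fallback test)
#'
#' Computes, for every gene, `log2FC` = mean(condition 2) - mean(condition 1)
#' on the log scale, a p-value from Welch's two-sample t-test (or a paired
#' t-test on per-pair differences when the expression set is paired), and a
#' BH q-value. Condition order follows the factor levels of
#' `es$condition` (alphabetical unless set explicitly).
#'
#' Genes with zero variance in both groups get p = 1 with the log2FC as
#' computed; paired designs with constant non-zero per-pair differences
#' have a vanishing p-value, reported as 1e-15. Both degenerate rules are
#' reported via a message.
#'
#' @param es An [expression_set] with at least 2 samples per condition
#'   (2 complete pairs when paired).
#' @return Data frame with columns `gene`, `log2FC`, `p`, `q`.
#' @export
de_test <- function(es) {
  stopifnot(inherits(es, "expression_set"))
  lv <- levels(es$condition)
  i1 <- which(es$condition == lv[1])
  i2 <- which(es$condition == lv[2])
  if (length(i1) < 2 || length(i2) < 2)
    stop("each condition needs >= 2 samples for the fallback test")
  paired <- !is.null(es$pair)
  if (paired) {
    # align columns pair-by-pair
    p1 <- es$pair[i1]; p2 <- es$pair[i2]
    i2 <- i2[match(p1, p2)]
  }
  x1 <- es$expr[, i1, drop = FALSE]
  x2 <- es$expr[, i2, drop = FALSE]
  lfc <- rowMeans(x2) - rowMeans(x1)
  n_flat <- 0L; n_sat <- 0L
  p <- vapply(seq_len(nrow(es$expr)), function(i) {
    a <- x1[i, ]; b <- x2[i, ]
    if (paired) {
      d <- b - a
      if (stats::var(d) == 0) {
        if (all(d == 0)) { n_flat <<- n_flat + 1L; return(1) }
        n_sat <<- n_sat + 1L; return(1e-15)
      }
      stats::t.test(d)$p.value
    } else {
      if (stats::var(a) == 0 && stats::var(b) == 0) {
        n_flat <<- n_flat + 1L
        return(1)
      }
      tryCatch(stats::t.test(b, a, var.equal = FALSE)$p.value,
               error = function(e) { n_flat <<- n_flat + 1L; 1 })
    }
  }, numeric(1))
  if (n_flat) message(n_flat, " gene(s) with no variance in either group: p set to 1")
  if (n_sat) message(n_sat, " paired gene(s) with constant non-zero difference: p set to 1e-15")
  data.frame(gene = rownames(es$expr), log2FC = unname(lfc),
             p = unname(p), q = bh_adjust(p),
             stringsAsFactors = FALSE)
}

#' Row-wise z-score normalization
#'
#' Centers and scales each row to mean 0 and sample standard deviation 1
#' (denominator n - 1). Constant rows map to all-zero rows with a warning
#' rather than NaN, keeping downstream correlations defined.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  flat <- sd == 0
  if (any(flat)) {
    warning(sum(flat), " constant row(s) z-scored to all zeros")
    sd[flat] <- 1
  }
  out <- (m - mu) / sd
  out[flat, ] <- 0
  out
}

#' Phase-I candidate gene pool
#'
#' Selects genes from a DE table by loose cutoffs and z-score-normalizes
#' their expression. Exactly one of `p_cutoff`/`q_cutoff` must be given;
#' an optional absolute log2 fold-change cutoff can be added. All
#' inequalities are strict (p or q strictly below the cutoff, |log2FC|
#' strictly above), so boundary genes are excluded.
#'
#' @param de Data frame with columns `gene`, `log2FC`, `p`, `q`
#'   (see [de_test()] / [read_de_table()]).
#' @param es The [expression_set] the pool is drawn from; genes in `de`
#'   but not in `es` are ignored.
#' @param p_cutoff,q_cutoff Significance cutoff on raw p or BH q
#'   (choose one).
#' @param lfc_cutoff Optional cutoff on |log2FC| (`NULL` to skip).
#' @return An object of class `candidate_pool`: list with `genes`
#'   (character), `zexpr` (z-scored expression submatrix), and
#'   `thresholds`.
#' @export
candidate_pool <- function(de, es, p_cutoff = NULL, q_cutoff = NULL,
                           lfc_cutoff = NULL) {
  stopifnot(inherits(es, "expression_set"))
  if (is.null(p_cutoff) == is.null(q_cutoff))
    stop("specify exactly one of `p_cutoff` or `q_cutoff`")
  stat <- if (!is.null(p_cutoff)) de$p else de$q
  cut <- if (!is.null(p_cutoff)) p_cutoff else q_cutoff
  keep <- stat < cut
  if (!is.null(lfc_cutoff)) keep <- keep & abs(de$log2FC) > lfc_cutoff
  genes <- de$gene[keep]
  genes <- genes[genes %in% rownames(es$expr)]
  if (!length(genes))
    stop("empty candidate pool; consider looser cutoffs")
  structure(list(
    genes = genes,
    zexpr = zscore_rows(es$expr[genes, , drop = FALSE]),
    thresholds = list(mode = if (!is.null(p_cutoff)) "p" else "q",
                      cutoff = cut, lfc_cutoff = lfc_cutoff)
  ), class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("candidate_pool: %d genes (%s < %g%s)\n", length(x$genes),
              th$mode, th$cutoff,
              if (is.null(th$lfc_cutoff)) ""
              else sprintf(", |log2FC| > %g", th$lfc_cutoff)))
  invisible(x)
}
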