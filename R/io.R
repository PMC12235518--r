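# Domain containers and file readers/writers shared by all pipeline stages.
#
# Gene identifiers are treated as opaque, case-sensitive symbols throughout;
# no alias or identifier mapping is attempted.

#' Construct a validated two-condition expression set
#'
#' Bundles a genes x samples matrix of log-scale expression values with a
#' sample-to-condition assignment (and optional pairing) and checks the
#' structural invariants every downstream phase relies on.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers). Values are expected
#'   on a log scale (e.g. log2 CPM or log2 intensities) and must be finite.
#' @param groups Data frame with columns `sample`, `condition` and
#'   optionally `pair`. Samples present in only one of `expr`/`groups` are
#'   dropped with a warning.
#' @param min_per_condition Minimum number of samples required in each of
#'   the two conditions (default 3).
#'
#' @return An object of class `expression_set`: a list with elements
#'   `expr` (matrix), `condition` (named factor with two levels, in column
#'   order of `expr`) and `pair` (named character or `NULL`).
#' @export
expression_set <- function(expr, groups, min_per_condition = 3) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("`expr` must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("`expr` must have gene rownames and sample colnames")
  dup_g <- unique(rownames(expr)[duplicated(rownames(expr))])
  if (length(dup_g))
    stop("duplicated gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(expr)[duplicated(colnames(expr))])
  if (length(dup_s))
    stop("duplicated sample identifiers: ", paste(dup_s, collapse = ", "))
  if (!all(is.finite(expr)))
    stop("expression values must be finite")

  groups <- as.data.frame(groups)
  if (!all(c("sample", "condition") %in% names(groups)))
    stop("`groups` needs columns `sample` and `condition`")
  if (anyDuplicated(groups$sample))
    stop("duplicated sample identifiers in groups: ",
         paste(unique(groups$sample[duplicated(groups$sample)]), collapse = ", "))

  common <- intersect(colnames(expr), groups$sample)
  lost_m <- setdiff(colnames(expr), common)
  lost_g <- setdiff(groups$sample, common)
  if (length(lost_m))
    warning("dropping ", length(lost_m), " sample(s) absent from groups: ",
            paste(lost_m, collapse = ", "))
  if (length(lost_g))
    warning("dropping ", length(lost_g), " sample(s) absent from matrix: ",
            paste(lost_g, collapse = ", "))
  if (!length(common)) stop("no samples shared between matrix and groups")
  expr <- expr[, common, drop = FALSE]
  groups <- groups[match(common, groups$sample), , drop = FALSE]

  cond <- factor(as.character(groups$condition))
  if (nlevels(cond) != 2)
    stop("exactly two conditions required, found ", nlevels(cond), ": ",
         paste(levels(cond), collapse = ", "))
  tab <- table(cond)
  if (any(tab < min_per_condition))
    stop("each condition needs >= ", min_per_condition, " samples (found ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")")
  names(cond) <- common

  pair <- NULL
  if ("pair" %in% names(groups) && !all(is.na(groups$pair))) {
    pair <- as.character(groups$pair)
    names(pair) <- common
    for (lv in levels(cond)) {
      pp <- pair[cond == lv]
      if (anyDuplicated(pp))
        stop("pair identifier(s) occur more than once in condition ", lv, ": ",
             paste(unique(pp[duplicated(pp)]), collapse = ", "))
    }
    p1 <- sort(pair[cond == levels(cond)[1]])
    p2 <- sort(pair[cond == levels(cond)[2]])
    if (!identical(unname(p1), unname(p2)))
      stop("pairing is incomplete: every pair identifier must occur exactly once per condition")
  }

  structure(list(expr = expr, condition = cond, pair = pair),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  tab <- table(x$condition)
  cat(sprintf("expression_set: %d genes x %d samples (%s)%s\n",
              nrow(x$expr), ncol(x$expr),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              if (is.null(x$pair)) "" else ", paired"))
  invisible(x)
}

#' Read an expression matrix and sample assignment from TSV files
#'
#' The expression file has a header whose first column is `gene` followed by
#' sample identifiers, one gene per row. The groups file has a header
#' `sample<TAB>condition[<TAB>pair]`.
#'
#' @param expr_path Path to the expression TSV.
#' @param groups_path Path to the sample-to-condition TSV.
#' @inheritParams expression_set
#' @return An [expression_set].
#' @export
read_expression <- function(expr_path, groups_path, min_per_condition = 3) {
  tab <- utils::read.delim(expr_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(tab) >= 2) stop("expression file needs a gene column plus samples")
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  groups <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  expression_set(m, groups, min_per_condition = min_per_condition)
}

#' Read a confidence-scored undirected edge list
#'
#' Accepts a generic 3-column TSV (`gene1`, `gene2`, score; header optional)
#' or the STRING protein-links dialect (header containing `protein1`,
#' `protein2`, `combined_score`, space- or tab-separated). The confidence
#' scale is auto-detected: any score > 1 implies the STRING 0-1000 scale and
#' a cutoff given on the unit scale is multiplied by 1000. Self-loops are
#' removed and duplicate unordered pairs collapsed keeping the maximum
#' confidence.
#'
#' @param path Path to the edge-list file.
#' @param confidence_cutoff Minimum confidence to retain an edge, on the
#'   unit scale (0-1) or the 0-1000 scale; interpreted on the detected scale
#'   of the file. Default 0.4, a standard medium-confidence threshold.
#' @return Data frame with columns `gene1`, `gene2`, `confidence`, carrying
#'   attribute `scale` (`"unit"` or `"string1000"`).
#' @export
read_edge_list <- function(path, confidence_cutoff = 0.4) {
  first <- readLines(path, n = 1L)
  string_style <- grepl("protein1", first) && grepl("combined_score", first)
  if (string_style) {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("protein1", "protein2", "combined_score")
    if (!all(need %in% names(tab)))
      stop("STRING-style file missing columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    tab <- tab[, need]
  } else {
    has_header <- grepl("gene", first, ignore.case = TRUE) ||
      grepl("score|confidence", first, ignore.case = TRUE)
    tab <- utils::read.delim(path, header = has_header, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 3)
      stop("edge list must have 3 columns (gene1, gene2, score)")
    tab <- tab[, 1:3]
  }
  names(tab) <- c("gene1", "gene2", "confidence")
  tab$gene1 <- as.character(tab$gene1)
  tab$gene2 <- as.character(tab$gene2)
  conf <- suppressWarnings(as.numeric(tab$confidence))
  if (anyNA(conf))
    stop("unparseable score at line(s): ",
         paste(utils::head(which(is.na(conf)), 5), collapse = ", "))
  tab$confidence <- conf
  edge_list(tab, confidence_cutoff = confidence_cutoff)
}

#' Validate, deduplicate and confidence-filter an edge list
#'
#' @param edges Data frame with columns `gene1`, `gene2`, `confidence`.
#' @inheritParams read_edge_list
#' @return Filtered edge data frame (see [read_edge_list]).
#' @export
edge_list <- function(edges, confidence_cutoff = 0) {
  edges <- as.data.frame(edges)
  if (!all(c("gene1", "gene2", "confidence") %in% names(edges)))
    stop("edge list needs columns gene1, gene2, confidence")
  scale <- if (any(edges$confidence > 1)) "string1000" else "unit"
  hi <- if (scale == "string1000") 1000 else 1
  if (any(edges$confidence < 0 | edges$confidence > hi))
    stop("confidence outside the detected ", scale, " scale [0, ", hi, "]")
  cutoff <- confidence_cutoff
  if (scale == "string1000" && cutoff <= 1) cutoff <- cutoff * 1000

  edges <- edges[edges$gene1 != edges$gene2, , drop = FALSE]          # self-loops
  if (nrow(edges)) {
    a <- pmin(edges$gene1, edges$gene2)
    b <- pmax(edges$gene1, edges$gene2)
    key <- paste(a, b, sep = "\r")
    conf <- tapply(edges$confidence, key, max)
    ab <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
    edges <- data.frame(gene1 = ab[, 1], gene2 = ab[, 2],
                        confidence = as.numeric(conf),
                        stringsAsFactors = FALSE)
  }
  edges <- edges[edges$confidence >= cutoff, , drop = FALSE]
  if (!nrow(edges))
    stop("no edges remain after confidence filtering at cutoff ", cutoff)
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "scale") <- scale
  edges
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene symbols, with a
#'   `description` attribute (named character vector).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("GMT line(s) without members: ", paste(bad, collapse = ", "))
  nms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicated gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nms
  desc <- vapply(parts, `[[`, "", 2L)
  names(desc) <- nms
  attr(sets, "description") <- desc
  sets
}

#' Read a precomputed differential-expression table
#'
#' TSV with header `gene log2FC p q`; the `q` column is optional and is
#' computed by [bh_adjust()] when absent.
#'
#' @param path Path to the DE TSV.
#' @return Data frame with columns `gene`, `log2FC`, `p`, `q`.
#' @export
read_de_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "log2FC", "p") %in% names(tab)))
    stop("DE table needs columns gene, log2FC, p (q optional)")
  if (anyDuplicated(tab$gene))
    stop("duplicated gene(s) in DE table: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "))
  if (any(tab$p < 0 | tab$p > 1, na.rm = TRUE)) stop("p outside [0,1]")
  if (!"q" %in% names(tab)) tab$q <- bh_adjust(tab$p)
  if (any(tab$q < 0 | tab$q > 1, na.rm = TRUE)) stop("q outside [0,1]")
  tab[, c("gene", "log2FC", "p", "q")]
}

# Byte-stable TSV writer: numbers formatted to 12 significant digits so a
# write/read round trip reproduces values exactly at that precision and
# output files are identical across platforms.
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- sprintf("%.12g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Write an expression set to TSV files
#'
#' Inverse of [read_expression()]; numeric values keep 12 significant digits.
#'
#' @param es An [expression_set].
#' @param expr_path,groups_path Output paths.
#' @return Invisibly, `expr_path`.
#' @export
write_expression <- function(es, expr_path, groups_path) {
  df <- data.frame(gene = rownames(es$expr), es$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, expr_path)
  g <- data.frame(sample = colnames(es$expr),
                  condition = as.character(es$condition),
                  stringsAsFactors = FALSE)
  if (!is.null(es$pair)) g$pair <- unname(es$pair)
  write_tsv(g, groups_path)
  invisible(expr_path)
}
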