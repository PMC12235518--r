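# The main fit: runs the six phases end to end and returns a classed
# object holding every intermediate product, the funnel of retained-gene
# counts, and the final ensemble gene table.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Exactly one of
#' `p_cutoff` / `q_cutoff` must be non-`NULL`.
#'
#' @param p_cutoff Raw-p candidate cutoff (strict `<`); `NULL` to use the
#'   q cutoff instead.
#' @param q_cutoff BH-q candidate cutoff (strict `<`). Default 0.05.
#' @param lfc_cutoff Optional |log2FC| candidate cutoff (strict `>`);
#'   default 0.5, set `NULL` to disable.
#' @param confidence_cutoff PPI confidence cutoff, unit scale (default
#'   0.4, medium confidence).
#' @param ig_method,ig_bins Discretization for the information-gain
#'   filter; `ig_bins = NULL` adapts to the cohort size
#'   (see [ig_filter()]).
#' @param eigen_weight `"affinity"` (edge weight |cc|) or `"unweighted"`
#'   for eigenvector centrality.
#' @param exclusion_mode `"all_below"` or `"either_measure_below"`, see
#'   [centrality_mean_filter()].
#' @param ease Use the EASE-penalized hypergeometric test in enrichment.
#' @param min_per_condition Minimum samples per condition.
#' @param seed Seed recorded in the run manifest (the pipeline itself is
#'   deterministic; the seed governs synthetic-data generation).
#' @return A list of class `dice_config`.
#' @export
dice_config <- function(p_cutoff = NULL, q_cutoff = 0.05, lfc_cutoff = 0.5,
                        confidence_cutoff = 0.4,
                        ig_method = "equal_frequency", ig_bins = NULL,
                        eigen_weight = "affinity",
                        exclusion_mode = "all_below", ease = FALSE,
                        min_per_condition = 3, seed = 1L) {
  if (!is.null(p_cutoff) && missing(q_cutoff)) q_cutoff <- NULL
  if (is.null(p_cutoff) == is.null(q_cutoff))
    stop("specify exactly one of p_cutoff / q_cutoff")
  cut <- if (is.null(p_cutoff)) q_cutoff else p_cutoff
  if (cut <= 0 || cut > 1) stop("significance cutoff must lie in (0, 1]")
  if (!is.null(lfc_cutoff) && lfc_cutoff < 0) stop("lfc_cutoff must be >= 0")
  if (confidence_cutoff < 0 || confidence_cutoff > 1000)
    stop("confidence_cutoff out of range")
  structure(list(p_cutoff = p_cutoff, q_cutoff = q_cutoff,
                 lfc_cutoff = lfc_cutoff,
                 confidence_cutoff = confidence_cutoff,
                 ig_method = ig_method, ig_bins = ig_bins,
                 eigen_weight = eigen_weight,
                 exclusion_mode = exclusion_mode, ease = ease,
                 min_per_condition = min_per_condition,
                 seed = as.integer(seed)),
            class = "dice_config")
}

#' Load a configuration from a YAML file
#'
#' Keys mirror the arguments of [dice_config()]; unknown keys are an
#' error.
#'
#' @param path Path to the YAML file.
#' @return A `dice_config`.
#' @export
read_dice_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(dice_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if ("p_cutoff" %in% names(vals) && !is.null(vals$p_cutoff))
    vals["q_cutoff"] <- list(NULL)
  do.call(dice_config, vals)
}

#' Differential centrality-ensemble gene prioritization
#'
#' Runs the full pipeline on a two-condition expression set and a
#' confidence-scored PPI edge list: (I) a candidate pool from relaxed
#' differential-expression cutoffs (an ingested DE table, or the built-in
#' Welch/paired t fallback), with row-wise z-scoring; (II) an
#' information-gain filter keeping genes above the pool-mean IG; (III) two
#' condition-specific networks on the PPI scaffold with edge distance
#' 1 - |Pearson cc| per condition; (IV) weighted betweenness and
#' eigenvector centrality per condition and their absolute cross-condition
#' differences; (V) the rank-product ensemble score with mean-centrality
#' exclusion; (VI) optional over-representation analysis of the retained
#' genes against supplied gene sets.
#'
#' @param es An [expression_set].
#' @param edges PPI edge data frame (`gene1`, `gene2`, `confidence`), e.g.
#'   from [read_edge_list()] or [make_scaffold()]. Filtered at
#'   `config$confidence_cutoff`.
#' @param de Optional precomputed DE table (`gene`, `log2FC`, `p`, `q`);
#'   when `NULL` the fallback [de_test()] is used.
#' @param gene_sets Optional named list of gene sets for Phase VI.
#' @param universe Background for enrichment: `"network"` (default; genes
#'   entering Phase III), `"expressed"` (all genes in `es`), or a
#'   character vector.
#' @param config A [dice_config()].
#' @return An object of class `dice`: list with elements `config`, `de`,
#'   `pool`, `ig`, `networks`, `centrality`, `table` (the [dice_table()]),
#'   `enrichment` (or `NULL`), `counts` (named funnel vector) and
#'   `conditions`.
#' @export
dice <- function(es, edges, de = NULL, gene_sets = NULL,
                 universe = "network", config = dice_config()) {
  stopifnot(inherits(es, "expression_set"))
  if (!inherits(config, "dice_config")) stop("config must be a dice_config")
  edges <- edge_list(edges, confidence_cutoff = config$confidence_cutoff)

  if (is.null(de)) de <- de_test(es)
  pool <- candidate_pool(de, es, p_cutoff = config$p_cutoff,
                         q_cutoff = config$q_cutoff,
                         lfc_cutoff = config$lfc_cutoff)
  labels <- as.character(es$condition)
  ig <- ig_filter(pool, labels, method = config$ig_method,
                  bins = config$ig_bins)
  kept <- ig$gene[ig$kept]
  networks <- build_condition_networks(es, kept, edges)
  cent <- centrality_table(networks, eigen_weight = config$eigen_weight)
  tab <- dice_table(cent, de, exclusion_mode = config$exclusion_mode)

  enr <- NULL
  if (!is.null(gene_sets)) {
    uni <- if (identical(universe, "network")) networks[[1]]$nodes
           else if (identical(universe, "expressed")) rownames(es$expr)
           else universe
    enr <- ora(tab$gene[!tab$excluded], gene_sets, uni, ease = config$ease)
  }

  counts <- c(expressed = nrow(es$expr),
              candidates = length(pool$genes),
              ig_kept = length(kept),
              networked = length(networks[[1]]$nodes),
              dice_genes = sum(!tab$excluded))
  structure(list(config = config, de = de, pool = pool, ig = ig,
                 networks = networks, centrality = cent, table = tab,
                 enrichment = enr, counts = counts,
                 conditions = levels(es$condition)),
            class = "dice")
}

#' @export
print.dice <- function(x, ...) {
  cat("Differential centrality-ensemble analysis\n")
  cat(sprintf("  conditions: %s vs %s\n", x$conditions[1], x$conditions[2]))
  cat(sprintf("  funnel: %s\n",
              paste(sprintf("%s %d", names(x$counts), x$counts),
                    collapse = " -> ")))
  cat(sprintf("  top genes: %s\n",
              paste(utils::head(x$table$gene[!x$table$excluded], 5),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.dice <- function(object, n = 10, ...) {
  print(object)
  th <- object$pool$thresholds
  cat(sprintf("  candidate cutoff: %s < %g%s\n", th$mode, th$cutoff,
              if (is.null(th$lfc_cutoff)) ""
              else sprintf(" & |log2FC| > %g", th$lfc_cutoff)))
  cat(sprintf("  exclusion mode: %s; eigen weight: %s\n",
              object$config$exclusion_mode, object$config$eigen_weight))
  cat("\nTop of the ensemble ranking:\n")
  print(object$table, n = n)
  if (!is.null(object$enrichment)) {
    cat("\nEnriched sets (q < 0.05):\n")
    print.data.frame(object$enrichment[object$enrichment$enriched, ],
                     row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' @export
as.data.frame.dice <- function(x, ...) as.data.frame(x$table)

#' Plot a fitted ensemble analysis
#'
#' Two base-graphics panels: the retained-gene funnel across phases, and
#' the per-gene centrality differences with retained genes highlighted.
#'
#' @param x A [dice] fit.
#' @param ... Ignored.
#' @export
plot.dice <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$counts, las = 2, ylab = "genes",
                    main = "Retention funnel", col = "steelblue")
  tab <- x$table
  graphics::plot(tab$delta_betweenness, tab$delta_eigenvector,
                 col = ifelse(tab$excluded, "grey70", "firebrick"),
                 pch = 19, cex = 0.7,
                 xlab = expression(Delta ~ "betweenness"),
                 ylab = expression(Delta ~ "eigenvector"),
                 main = "Centrality shifts")
  graphics::legend("topright", legend = c("retained", "excluded"),
                   col = c("firebrick", "grey70"), pch = 19, bty = "n")
  invisible(x)
}

#' Write every pipeline output table of a fit
#'
#' Emits one TSV per phase plus a JSON run manifest recording the
#' configuration, the per-phase retained-gene counts, the package version
#' and the output paths. Tables are byte-stable (12 significant digits),
#' so a rerun with identical inputs reproduces them exactly.
#'
#' @param fit A [dice] fit.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_dice_outputs <- function(fit, dir) {
  stopifnot(inherits(fit, "dice"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write_tsv(df, p)
    paths[[name]] <<- p
    p
  }
  wr(fit$de, "de_table.tsv")
  wr(data.frame(gene = fit$pool$genes, stringsAsFactors = FALSE),
     "candidates.tsv")
  wr(as.data.frame(fit$ig), "ig_table.tsv")
  for (k in 1:2) {
    net <- fit$networks[[k]]
    wr(net$edges[, c("gene1", "gene2", "cc", "distance")],
       sprintf("network_%s.tsv", net$condition))
  }
  wr(as.data.frame(fit$centrality), "centrality.tsv")
  wr(as.data.frame(fit$table), "dice_genes.tsv")
  if (!is.null(fit$enrichment)) wr(fit$enrichment, "enrichment.tsv")
  manifest <- list(
    package = "dicenet",
    version = as.character(utils::packageVersion("dicenet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = fit$config$seed,
    config = fit$config[setdiff(names(fit$config), NULL)],
    counts = as.list(fit$counts),
    conditions = fit$conditions,
    outputs = paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
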