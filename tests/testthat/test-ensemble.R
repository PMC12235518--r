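# Phase V: rank-product ensemble and the mean-centrality exclusion rule.

fake_cent <- function(db, de_, b1 = NULL, b2 = NULL, e1 = NULL, e2 = NULL) {
  n <- length(db)
  out <- data.frame(gene = sprintf("G%02d", seq_len(n)),
                    betweenness_c1 = if (is.null(b1)) db else b1,
                    betweenness_c2 = if (is.null(b2)) rep(0, n) else b2,
                    eigen_c1 = if (is.null(e1)) de_ else e1,
                    eigen_c2 = if (is.null(e2)) rep(0, n) else e2,
                    delta_betweenness = db, delta_eigenvector = de_,
                    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}
fake_de <- function(genes, lfc = 1) {
  data.frame(gene = genes, log2FC = rep_len(lfc, length(genes)),
             p = 0.01, q = 0.01, stringsAsFactors = FALSE)
}

test_that("descending ranks with average ties", {
  expect_equal(rank_descending(c(0.9, 0.5, 0.1)), c(1, 2, 3))
  expect_equal(rank_descending(c(9, 9, 5, 1)), c(1.5, 1.5, 3, 4))
  expect_equal(rank_descending(rep(2, 5)), rep(3, 5))
  expect_error(rank_descending(1), "at least 2")
})

test_that("rank normalization hits exactly 1 and 0 at the extremes", {
  expect_equal(normalize_ranks(c(1, 2, 3)), c(1, 0.5, 0))
  expect_equal(normalize_ranks(1, N = 5), 1)
  expect_equal(normalize_ranks(c(1.5, 1.5, 3, 4)),
               c(2.5 / 3, 2.5 / 3, 1 / 3, 0), tolerance = 1e-9)
  expect_error(normalize_ranks(c(0.5, 2), N = 2), "\\[1, N\\]")
})

test_that("ensemble score is the product of normalized ranks", {
  expect_equal(ensemble_score(1, 1), 1)
  expect_equal(ensemble_score(0.5, 0.4), 0.2)
  expect_equal(ensemble_score(0.9, 0), 0)
  expect_error(ensemble_score(c(1, 0.5), 1), "every gene")
})

test_that("mean filter excludes only genes below every mean in `all_below` mode", {
  cent <- fake_cent(db = c(10, 1, 1, 1), de_ = c(10, 1, 1, 1),
                    b1 = c(10, 1, 1, 5), b2 = c(10, 1, 1, 1),
                    e1 = c(10, 1, 1, 1), e2 = c(10, 1, 1, 1))
  ex <- centrality_mean_filter(cent)
  # G2, G3 below all four means; G4 is above the b1 mean -> retained
  expect_equal(as.logical(ex), c(FALSE, TRUE, TRUE, FALSE))
  ex2 <- centrality_mean_filter(cent, mode = "either_measure_below")
  expect_equal(as.logical(ex2), c(FALSE, TRUE, TRUE, TRUE))
})

test_that("exclusion equals a brute-force mean comparison on a 10-gene table", {
  set.seed(77)
  cent <- fake_cent(db = runif(10), de_ = runif(10),
                    b1 = runif(10), b2 = runif(10),
                    e1 = runif(10), e2 = runif(10))
  ex <- centrality_mean_filter(cent)
  manual <- with(cent, betweenness_c1 < mean(betweenness_c1) &
                        betweenness_c2 < mean(betweenness_c2) &
                        eigen_c1 < mean(eigen_c1) &
                        eigen_c2 < mean(eigen_c2))
  expect_equal(as.logical(ex), manual)
})

test_that("the final table is a reproducible strict total order", {
  cent <- fake_cent(db = c(0.5, 0.5, 0.1, 0.9), de_ = c(0.2, 0.2, 0.1, 0.9))
  tab <- dice_table(cent, fake_de(cent$gene, lfc = c(1, -1, 0.5, 2)))
  expect_identical(tab$gene[1], "G04")            # dominates both deltas
  expect_equal(tab$final_rank[!tab$excluded],
               seq_len(sum(!tab$excluded)))
  expect_equal(tab$ensemble_score, tab$norm_b * tab$norm_e, tolerance = 1e-12)
  # G01/G02 tie on both deltas -> broken lexicographically
  i1 <- which(tab$gene == "G01"); i2 <- which(tab$gene == "G02")
  expect_lt(i1, i2)
  expect_identical(tab$direction[tab$gene == "G02"], "down")
  expect_identical(tab$direction[tab$gene == "G03"], "up")
})

test_that("ordering is invariant under positive rescaling of either delta", {
  set.seed(88)
  cent <- fake_cent(db = runif(12), de_ = runif(12))
  de <- fake_de(cent$gene)
  t0 <- dice_table(cent, de)
  cent2 <- cent
  cent2$delta_betweenness <- cent2$delta_betweenness * 137.5
  cent2$delta_eigenvector <- cent2$delta_eigenvector * 0.003
  t2 <- dice_table(cent2, de)
  expect_identical(t2$gene, t0$gene)
  expect_equal(t2$ensemble_score, t0$ensemble_score, tolerance = 1e-12)
})

test_that("top-in-both scores exactly 1; last in either scores exactly 0", {
  cent <- fake_cent(db = c(4, 3, 2, 1), de_ = c(40, 30, 20, 10))
  tab <- dice_table(cent, fake_de(cent$gene))
  expect_equal(tab$ensemble_score[tab$gene == "G01"], 1)
  expect_equal(tab$ensemble_score[tab$gene == "G04"], 0)
  cent2 <- fake_cent(db = c(4, 3, 2, 1), de_ = c(10, 30, 20, 40))
  tab2 <- dice_table(cent2, fake_de(cent2$gene))
  expect_equal(tab2$ensemble_score[tab2$gene == "G01"], 0)  # last in eigen
})

test_that("score is monotone in a single measure's rank", {
  cent <- fake_cent(db = c(5, 4, 3, 2, 1), de_ = c(1, 2, 3, 4, 5))
  t0 <- dice_table(cent, fake_de(cent$gene))
  cent2 <- cent
  cent2$delta_betweenness[3] <- 10        # promote G03 in betweenness only
  t2 <- dice_table(cent2, fake_de(cent$gene))
  expect_gte(t2$ensemble_score[t2$gene == "G03"],
             t0$ensemble_score[t0$gene == "G03"])
})
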