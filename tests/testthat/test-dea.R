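# Phase I: fallback differential-expression test, BH adjustment and
# candidate selection.

test_that("fallback test matches the Welch formula and handles degenerate genes", {
  n <- 4
  m <- rbind(G1 = c(1, 1, 1, 3, 3, 3) + c(1e-6, -1e-6, 0, 1e-6, -1e-6, 0),
             G2 = c(5, 5, 5, 5, 5, 5),
             G3 = c(1, 2, 3, 2, 3, 4))
  colnames(m) <- sprintf("S%d", 1:6)
  es <- expression_set(m, data.frame(sample = colnames(m),
                                     condition = rep(c("a", "b"), each = 3)))
  de <- suppressMessages(de_test(es))
  expect_equal(de$log2FC[1], 2, tolerance = 1e-5)
  expect_lt(de$p[1], 1e-6)
  expect_equal(de$p[1], oracle_welch_p(m[1, 1:3], m[1, 4:6]), tolerance = 1e-12)
  # constant in both groups: p = 1, log2FC = 0
  expect_equal(de$log2FC[2], 0)
  expect_equal(de$p[2], 1)
  expect_equal(de$p[3], oracle_welch_p(m[3, 1:3], m[3, 4:6]), tolerance = 1e-12)
})

test_that("paired design uses per-pair differences; constant differences degenerate", {
  m <- rbind(G1 = c(1, 2, 3, 4, 2, 3, 4, 5),    # constant difference 1
             G2 = c(1, 2, 3, 4, 1.5, 2.2, 3.9, 4.1))
  colnames(m) <- sprintf("S%d", 1:8)
  g <- data.frame(sample = colnames(m),
                  condition = rep(c("pre", "post"), each = 4),
                  pair = rep(sprintf("P%d", 1:4), 2))
  es <- expression_set(m, g)
  expect_message(de <- de_test(es), "constant non-zero difference")
  expect_lt(de$p[1], 1e-12)
  d <- m[2, 5:8] - m[2, 1:4]
  expect_equal(de$p[2], t.test(d)$p.value, tolerance = 1e-12)
})

test_that("log2FC flips sign and p is invariant when condition labels swap", {
  es <- tiny_es()
  g2 <- data.frame(sample = colnames(es$expr),
                   condition = ifelse(es$condition == "tumor", "a_tumor", "z_normal"))
  es_sw <- expression_set(es$expr, g2)  # level order reversed
  de1 <- suppressMessages(de_test(es))
  de2 <- suppressMessages(de_test(es_sw))
  expect_equal(de2$log2FC, -de1$log2FC, tolerance = 1e-12)
  expect_equal(de2$p, de1$p, tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))^2
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
    expect_gte(min(bh_adjust(p)), min(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("candidate selection uses strict inequalities and z-scores rows", {
  de <- data.frame(gene = c("G1", "G2", "G3"),
                   log2FC = c(0.6, 0.5, 2),
                   p = c(0.001, 0.001, 0.2),
                   q = c(0.01, 0.01, 0.4))
  m <- matrix(rep(c(1, 2, 3, 1, 2, 3), 3), 3, 6, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"), sprintf("S%d", 1:6)))
  es <- expression_set(m, data.frame(sample = colnames(m),
                                     condition = rep(c("a", "b"), 3)))
  pool <- candidate_pool(de, es, q_cutoff = 0.05, lfc_cutoff = 0.5)
  expect_identical(pool$genes, "G1")     # G2 sits exactly on the boundary
  expect_equal(unname(pool$zexpr[1, 1:3]),
               (c(1, 2, 3) - 2) / sd(c(1, 2, 3, 1, 2, 3)), tolerance = 1e-12)
  expect_equal(unname(zscore_rows(matrix(c(1, 2, 3), 1))[1, ]), c(-1, 0, 1))
  expect_error(candidate_pool(de, es, q_cutoff = 1e-9), "looser cutoffs")
  expect_error(candidate_pool(de, es), "exactly one")
  expect_error(candidate_pool(de, es, p_cutoff = 0.05, q_cutoff = 0.05),
               "exactly one")
})

test_that("z-scored rows have mean 0 and sample sd 1; constant rows go to zero", {
  set.seed(7)
  m <- matrix(rnorm(50), 5)
  z <- zscore_rows(m)
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
  expect_warning(z2 <- zscore_rows(rbind(m, 0)), "constant")
  expect_true(all(z2[6, ] == 0))
})

test_that("loosening any threshold never shrinks the pool", {
  set.seed(11)
  de <- data.frame(gene = sprintf("G%03d", 1:80),
                   log2FC = rnorm(80), p = runif(80))
  de$q <- bh_adjust(de$p)
  m <- matrix(rnorm(80 * 6), 80, 6,
              dimnames = list(de$gene, sprintf("S%d", 1:6)))
  es <- expression_set(m, data.frame(sample = colnames(m),
                                     condition = rep(c("a", "b"), 3)))
  base <- candidate_pool(de, es, p_cutoff = 0.2, lfc_cutoff = 0.5)$genes
  expect_true(all(base %in%
    candidate_pool(de, es, p_cutoff = 0.4, lfc_cutoff = 0.5)$genes))
  expect_true(all(base %in%
    candidate_pool(de, es, p_cutoff = 0.2, lfc_cutoff = 0.2)$genes))
  expect_true(all(base %in%
    candidate_pool(de, es, p_cutoff = 0.2)$genes))
})
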