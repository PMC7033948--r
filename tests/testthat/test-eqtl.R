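test_that("eQTL scan matches the normal-equations + t-distribution oracle", {
  dosage <- c(0, 1, 2, 1, 0, 2)
  covar <- data.frame(age = c(0.5, -1.2, 0.3, 1.8, -0.7, 0.9))
  set.seed(20)
  expr <- 0.8 * dosage + 0.4 * covar$age + rnorm(6, 0, 0.3)
  g <- genotype_matrix(matrix(dosage, 6, 1), toy_variants(1))
  e <- expression_matrix(matrix(expr, 6, 1), toy_gene(start = 1000, end = 1200))
  rec <- scan_eqtl(e, g, covar)
  orc <- ols_oracle(expr, cbind(1, dosage, covar$age), 2)
  expect_equal(rec$beta, unname(orc$beta), tolerance = 1e-10)
  expect_equal(rec$se, unname(orc$se), tolerance = 1e-10)
  expect_equal(rec$t, unname(orc$t), tolerance = 1e-10)
  expect_equal(rec$p, unname(orc$p), tolerance = 1e-10)
})

test_that("expression equal to dosage gives unit effect and tiny p", {
  set.seed(21)
  dosage <- rbinom(30, 2, 0.5)
  g <- genotype_matrix(matrix(dosage, 30, 1), toy_variants(1))
  e <- expression_matrix(matrix(as.numeric(dosage), 30, 1), toy_gene())
  rec <- scan_eqtl(e, g, NULL)
  expect_equal(rec$beta, 1, tolerance = 1e-10)
  expect_lt(rec$p, 1e-20)
})

test_that("cis/trans labels follow the 500-kb rule exactly and only coordinates", {
  gene <- toy_gene(start = 1000000, end = 1010000)
  pos <- c(1000000 - 499999, 1000000 - 500001, 1010000 + 500000,
           1010000 + 500001)
  set.seed(22)
  g <- genotype_matrix(matrix(rbinom(40 * 4, 2, 0.4), 40, 4),
                       data.frame(id = paste0("v", 1:4), chrom = "1",
                                  pos = as.integer(sort(pos)), ref = "A",
                                  alt = "G"))
  e <- expression_matrix(matrix(rnorm(40), 40, 1), gene)
  rec <- scan_eqtl(e, g, NULL)
  rec <- rec[order(rec$pos), ]
  expect_identical(rec$type, c("trans", "cis", "cis", "trans"))
  # permuting sample order never changes labels
  perm <- sample(40)
  g2 <- genotype_matrix(g$dosages[perm, ], g$variants,
                        samples = g$samples[perm])
  e2 <- expression_matrix(e$values[perm, , drop = FALSE], gene,
                          samples = e$samples[perm])
  rec2 <- scan_eqtl(e2, g2, NULL)
  expect_identical(rec2$type[order(rec2$pos)], rec$type)
})

test_that("residualized-scan and joint-model effects agree (Frisch-Waugh)", {
  set.seed(23)
  n <- 50
  covar <- data.frame(age = rnorm(n), pc1 = rnorm(n))
  dosage <- rbinom(n, 2, 0.3)
  expr <- 0.5 * dosage + 0.7 * covar$age - 0.2 * covar$pc1 + rnorm(n)
  g <- genotype_matrix(matrix(dosage, n, 1), toy_variants(1))
  e <- expression_matrix(matrix(expr, n, 1), toy_gene())
  rec <- scan_eqtl(e, g, covar)
  joint <- summary(lm(expr ~ dosage + covar$age + covar$pc1))$coefficients
  expect_equal(rec$beta, joint["dosage", "Estimate"], tolerance = 1e-8)
  expect_equal(rec$se, joint["dosage", "Std. Error"], tolerance = 1e-8)
})

test_that("subtype exclusion drops flagged samples before fitting", {
  set.seed(24)
  n <- 30
  dosage <- rbinom(n, 2, 0.5)
  expr <- rnorm(n)
  g <- genotype_matrix(matrix(dosage, n, 1), toy_variants(1))
  e <- expression_matrix(matrix(expr, n, 1), toy_gene())
  subs <- setNames(c(rep("Normal-like", 5), rep("LumA", n - 5)), g$samples)
  rec <- scan_eqtl(e, g, NULL, subtypes = subs)
  keep <- 6:n
  orc <- ols_oracle(expr[keep], cbind(1, dosage[keep]), 2)
  expect_equal(rec$beta, unname(orc$beta), tolerance = 1e-10)
})

test_that("hierarchical FDR reproduces a hand-computed Simes + BH cascade", {
  # 3 genes x 4 variants; gene A clearly signal, gene B marginal, gene C null
  pA <- c(1e-6, 2e-4, 0.03, 0.60)
  pB <- c(0.012, 0.20, 0.45, 0.90)
  pC <- c(0.30, 0.55, 0.75, 0.95)
  rec <- data.frame(gene = rep(c("A", "B", "C"), each = 4),
                    p = c(pA, pB, pC), stringsAsFactors = FALSE)
  out <- hierarchical_fdr(rec, level = 0.05)
  # stage 1 oracle: Simes per gene, then BH over 3 genes
  simes <- vapply(list(pA, pB, pC),
                  function(p) min(sort(p) * length(p) / seq_along(p)),
                  numeric(1))
  gene_adj <- p.adjust(simes, "BH")
  sel <- gene_adj < 0.05
  gt <- attr(out, "genes")
  expect_equal(gt$simes_p, unname(simes), tolerance = 1e-12)
  expect_equal(gt$gene_adj_p, unname(gene_adj), tolerance = 1e-12)
  expect_identical(gt$selected, unname(sel))
  # stage 2 oracle: within-gene BH scaled by G / R
  R <- sum(sel); G <- 3
  for (gn in c("A", "B", "C")) {
    pg <- rec$p[rec$gene == gn]
    expected <- pmin(1, p.adjust(pg, "BH") * G / max(R, 1))
    expect_equal(out$bbfdr[out$gene == gn], expected, tolerance = 1e-12)
  }
  expect_true(all(out$bbfdr >= out$p))
  expect_identical(out$is_esnp, out$is_egene & out$bbfdr < 0.05)
})

test_that("hierarchical FDR degenerate cases behave", {
  # single gene, single variant: bbfdr equals p whether selected or not
  one_sig <- hierarchical_fdr(data.frame(gene = "A", p = 0.01), level = 0.05)
  expect_identical(one_sig$bbfdr, 0.01)
  expect_true(one_sig$is_esnp)
  one_null <- hierarchical_fdr(data.frame(gene = "A", p = 0.40), level = 0.05)
  expect_identical(one_null$bbfdr, 0.40)
  expect_false(one_null$is_egene)
  # all p = 1: nothing called
  flat <- hierarchical_fdr(data.frame(gene = rep(c("A", "B"), each = 3),
                                      p = rep(1, 6)))
  expect_false(any(flat$is_egene))
  expect_false(any(flat$is_esnp))
})

test_that("local-ancestry adjustment matches a two-covariate OLS oracle", {
  g5 <- c(1.2, -0.7, 0.4, 2.1, -1.5)
  s5 <- c(0, 1, 2, 1, 0)
  l5 <- c(2, 0, 1, 2, 0)
  rec <- adjust_local_ancestry(g5, s5, l5, NULL)
  zs <- function(v) (v - mean(v)) / sd(v)
  gz <- zs(g5); sz <- zs(s5); lz <- zs(l5)
  b_unadj <- solve(t(cbind(1, sz)) %*% cbind(1, sz),
                   t(cbind(1, sz)) %*% gz)[2]
  X2 <- cbind(1, sz, lz)
  b_adj <- solve(t(X2) %*% X2, t(X2) %*% gz)[2]
  expect_equal(rec$beta_unadjusted, b_unadj, tolerance = 1e-12)
  expect_equal(rec$beta_ancestry_adjusted, b_adj, tolerance = 1e-12)
})

test_that("ancestry adjustment removes a planted ancestry confounder", {
  set.seed(25)
  n <- 2000
  l <- rbinom(n, 2, 0.6)
  s <- 0.8 * l + rbinom(n, 2, 0.3) * 0.5          # SNP correlated with ancestry
  g_conf <- 1.0 * l + rnorm(n, 0, 0.5)            # expression driven by ancestry
  rec <- adjust_local_ancestry(g_conf, s, l, NULL)
  expect_gt(abs(rec$beta_unadjusted), 0.3)
  expect_lt(abs(rec$beta_ancestry_adjusted), 0.07)
  # no-confounding limit: independent ancestry leaves the effect unchanged
  l2 <- rbinom(n, 2, 0.5)
  s2 <- rbinom(n, 2, 0.4)
  g2 <- 0.4 * s2 + rnorm(n)
  rec2 <- adjust_local_ancestry(g2, s2, l2, NULL)
  expect_lt(abs(rec2$beta_unadjusted - rec2$beta_ancestry_adjusted), 0.05)
  # zero-variance ancestry is flagged, not fitted
  rec3 <- adjust_local_ancestry(g2, s2, rep(2, n), NULL)
  expect_true(rec3$flagged)
})

test_that("enrichment matches the hypergeometric oracle on a fixed table", {
  # background: 1000 positions, 300 inside the annotation (plus window)
  bg <- data.frame(chrom = "1", pos = c(seq(1000, 1000 + 299 * 10, by = 10),
                                        seq(100000, 100000 + 699 * 10, by = 10)))
  ann <- data.frame(chrom = "1", start = 900, end = 4100)
  # 10 eSNPs, 8 inside
  esnps <- data.frame(chrom = "1", pos = c(seq(1000, 1070, by = 10),
                                           100000, 100050))
  res <- enrichment_test(esnps, ann, bg, window = 100, n_reps = 4000,
                         seed = 31)
  expect_identical(res$observed, 8L)
  expect_lt(abs(res$expected_mean - 3), 0.15)   # 10 draws x 30% in-rate
  # independent hypergeometric oracle for the 2x2 (8,2 / 3,7)
  or_grid <- function(tab) fisher.test(tab)  # checked against dhyper below
  p_oracle <- {
    # P(X >= 8) + P(X <= x_lo) under the conditional hypergeometric with
    # margins (10, 10) and (11, 9): enumerate all tables
    m <- 11; nn <- 9; k <- 10
    supp <- max(0, k - nn):min(k, m)
    pr <- dhyper(supp, m, nn, k)
    sum(pr[pr <= dhyper(8, m, nn, k) * (1 + 1e-7)])
  }
  expect_equal(res$p, p_oracle, tolerance = 1e-8)
  expect_equal(unname(res$odds_ratio),
               unname(fisher.test(matrix(c(8, 2, 3, 7), 2, byrow = TRUE))$estimate),
               tolerance = 1e-8)
  expect_false(res$degenerate)
})

test_that("enrichment flags degenerate saturation and rejects bad input", {
  bg <- data.frame(chrom = "1", pos = seq(1000, 5000, by = 100))
  esnps <- bg[1:5, ]
  ann_all <- data.frame(chrom = "1", start = 1, end = 10000)
  res <- enrichment_test(esnps, ann_all, bg, n_reps = 200, seed = 1)
  expect_identical(res$observed, 5L)
  expect_true(res$degenerate)
  expect_error(enrichment_test(esnps, ann_all[0, ], bg), "empty annotation")
  expect_error(enrichment_test(esnps, ann_all, bg, window = -1), "window")
})

test_that("uniformly drawn eSNPs show no enrichment", {
  set.seed(32)
  bg <- data.frame(chrom = "1", pos = sort(sample.int(1e6, 2000)))
  ann <- data.frame(chrom = "1",
                    start = seq(0, 9e5, by = 1e5),
                    end = seq(0, 9e5, by = 1e5) + 20000)
  hits <- replicate(10, {
    es <- bg[sample.int(nrow(bg), 100), ]
    r <- enrichment_test(es, ann, bg, n_reps = 300, seed = sample.int(1e6, 1))
    r$p > 0.05
  })
  expect_gte(mean(hits), 0.8)
})
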