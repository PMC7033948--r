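test_that("config validation rejects impossible study designs", {
  expect_error(sim_config(n_samples_per_stratum = 1), "n_samples_per_stratum")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(event_rate = 0.5, competing_rate = 0.5,
                          censor_rate = 0.2), "sum to 1")
  expect_error(sim_config(event_rate = -0.1, competing_rate = 0.2,
                          censor_rate = 0.9), "negative rate")
  expect_error(sim_config(cis_h2_per_gene = 0.3, n_causal_cis = 0),
               "n_causal_cis")
  expect_error(sim_config(cis_h2_per_gene = 0.95, covariate_var = 0.1),
               "exceed 1")
})

test_that("identical configs give byte-identical cohorts", {
  cfg <- sim_config(n_samples_per_stratum = 60, n_genes = 3, seed = 42)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$genotypes$admix$dosages, c2$genotypes$admix$dosages)
  expect_identical(c1$expression$ref$values, c2$expression$ref$values)
  expect_identical(c1$survival$admix, c2$survival$admix)
  expect_identical(c1$local_ancestry, c2$local_ancestry)
  c3 <- simulate_cohort(sim_config(n_samples_per_stratum = 60, n_genes = 3,
                                   seed = 43))
  expect_false(identical(c1$genotypes$admix$dosages,
                         c3$genotypes$admix$dosages))
})

test_that("realized allele frequencies concentrate at the target MAF", {
  cfg <- sim_config(n_samples_per_stratum = 5000, n_genes = 3,
                    n_variants_per_gene_cis = 30, n_trans_variants = 0,
                    maf_range = c(0.2, 0.2), fst = 0, ld_decay = 0, seed = 5)
  gt <- simulate_genotypes(cfg)
  for (s in names(gt$strata)) {
    af <- colMeans(gt$strata[[s]]$dosages) / 2
    maf <- pmin(af, 1 - af)
    expect_gte(mean(maf >= 0.18 & maf <= 0.22), 0.95)
  }
})

test_that("fst = 0 leaves only binomial-sampling frequency differences", {
  cfg <- sim_config(n_samples_per_stratum = 4000, n_genes = 3,
                    n_variants_per_gene_cis = 30, n_trans_variants = 0,
                    maf_range = c(0.3, 0.3), fst = 0, ld_decay = 0, seed = 6)
  gt <- simulate_genotypes(cfg)
  d <- abs(colMeans(gt$strata$ref$dosages) / 2 -
             colMeans(gt$strata$admix$dosages) / 2)
  # two-sample binomial sd of the difference at p = 0.3, 2n alleles each
  sd_bin <- sqrt(2 * 0.3 * 0.7 / (2 * 4000))
  expect_lt(mean(d), 2.5 * sd_bin)  # mean |N(0,sd)| = sd * sqrt(2/pi) < sd
  expect_lt(max(d), 5 * sd_bin)
})

test_that("ld_decay = 0 gives uncorrelated adjacent variants, > 0 gives LD", {
  cfg0 <- sim_config(n_samples_per_stratum = 2000, n_genes = 2,
                     n_variants_per_gene_cis = 25, n_trans_variants = 0,
                     fst = 0, ld_decay = 0, seed = 7)
  gt0 <- simulate_genotypes(cfg0)
  D <- gt0$strata$ref$dosages
  r_adj <- vapply(seq_len(ncol(D) - 1),
                  function(j) cor(D[, j], D[, j + 1]), numeric(1))
  expect_lt(max(abs(r_adj)), 0.08)
  cfg9 <- sim_config(n_samples_per_stratum = 2000, n_genes = 2,
                     n_variants_per_gene_cis = 25, n_trans_variants = 0,
                     fst = 0, ld_decay = 0.9, seed = 7)
  gt9 <- simulate_genotypes(cfg9)
  D9 <- gt9$strata$ref$dosages
  r9 <- vapply(seq_len(ncol(D9) - 1),
               function(j) cor(D9[, j], D9[, j + 1]), numeric(1))
  expect_gt(mean(abs(r9)), 0.4)
})

test_that("stratum frequency differentiation matches the Balding-Nichols Fst", {
  cfg <- sim_config(n_samples_per_stratum = 500, n_genes = 100,
                    n_variants_per_gene_cis = 50, n_trans_variants = 0,
                    maf_range = c(0.2, 0.4), fst = 0.15, ld_decay = 0,
                    seed = 8)
  gt <- simulate_genotypes(cfg)
  p0 <- gt$ancestral_freqs$shared
  phat <- colMeans(gt$strata$ref$dosages) / 2
  # E[(p_pop - p0)^2] = Fst p0 (1 - p0); subtract the binomial sampling part
  fst_hat <- mean(((phat - p0)^2 - phat * (1 - phat) / (2 * 500)) /
                    (p0 * (1 - p0)))
  expect_lt(abs(fst_hat - 0.15) / 0.15, 0.2)
})

test_that("local ancestry is a valid dosage tied to the admixed stratum", {
  cfg <- sim_config(n_samples_per_stratum = 100, n_genes = 3, seed = 9,
                    admixture_alpha = 8)
  gt <- simulate_genotypes(cfg)
  la <- gt$local_ancestry
  expect_true(all(la %in% 0:2))
  expect_equal(dim(la), dim(gt$strata$admix$dosages))
  # Beta(8, 2) admixture: mean first-ancestry dosage near 2 * 0.8
  expect_gt(mean(la), 1.35)
  expect_lt(mean(la), 1.85)
})

test_that("generated expression hits the configured cis heritability", {
  cfg <- sim_config(n_samples_per_stratum = 1000, n_genes = 4,
                    cis_h2_per_gene = c(0, 0.5, 0.5, 0.5), seed = 10)
  gt <- simulate_genotypes(cfg)
  ex <- simulate_expression(gt, cfg)
  h2 <- ex$truth$true_cis_h2
  expect_equal(unname(h2[1, ]), c(0, 0), tolerance = 1e-12)
  # scaling calibrates the first stratum exactly; the second inherits the
  # shared weights, so its realized h2 drifts with frequency differentiation
  expect_true(all(h2[2:4, "admix"] > 0.45 & h2[2:4, "admix"] < 0.55))
  expect_true(all(h2[2:4, "ref"] > 0.2 & h2[2:4, "ref"] < 0.8))
  # realized ratio matches the recorded truth
  for (s in names(ex$expression)) {
    v <- var(ex$grex_true[[s]][, 2]) / var(ex$expression[[s]]$values[, 2])
    expect_equal(v, h2[2, s], tolerance = 1e-10)
  }
  # shared architecture: identical weight vectors across strata
  w <- ex$truth$causal_weights[[2]]
  expect_identical(w$admix, w$ref)
})

test_that("null cis architecture yields nominal single-variant type-I error", {
  cfg <- sim_config(n_samples_per_stratum = 300, n_genes = 10,
                    cis_h2_per_gene = 0, covariate_var = 0, seed = 11)
  gt <- simulate_genotypes(cfg)
  ex <- simulate_expression(gt, cfg)
  ps <- c()
  for (j in 1:10) {
    e <- ex$expression$ref$values[, j]
    x <- gt$strata$ref$dosages[, (j - 1) * 20 + 3]
    if (sd(x) > 0) ps <- c(ps, summary(lm(e ~ x))$coefficients[2, 4])
  }
  expect_gt(min(ps), 0.0005)   # no wildly significant association
  expect_gt(mean(ps > 0.5), 0.2)
})

test_that("survival generator hits target cause fractions and recovers beta", {
  cfg <- sim_config(n_samples_per_stratum = 5000, n_genes = 2,
                    cis_h2_per_gene = 0.3, survival_beta = c(log(1.3), 0),
                    event_rate = 0.2, competing_rate = 0.1, censor_rate = 0.7,
                    seed = 12)
  co <- simulate_cohort(cfg)
  tab <- table(co$survival$ref$cause) / 5000
  expect_lt(abs(tab["primary"] - 0.2), 0.025)
  expect_lt(abs(tab["competing"] - 0.1), 0.02)
  expect_true(all(co$survival$ref$time > 0))
  # Cox on the true standardized GReX recovers the planted log-hazard
  x <- drop(scale(co$grex_true$ref[, 1]))
  fit <- coxph_cause_specific(x, NULL, co$survival$ref)
  expect_lt(abs(fit$beta - log(1.3)), 0.1)
})

test_that("all-censored cohorts propagate a no-events error downstream", {
  cfg <- sim_config(n_samples_per_stratum = 50, n_genes = 2,
                    event_rate = 0, competing_rate = 0, censor_rate = 1,
                    seed = 13)
  co <- simulate_cohort(cfg)
  expect_true(all(co$survival$admix$cause == "censored"))
  expect_error(coxph_cause_specific(rnorm(50), NULL, co$survival$admix),
               "no primary-cause events")
})

test_that("summary statistics are null-calibrated and respect LD", {
  cfg <- sim_config(n_samples_per_stratum = 400, n_genes = 8,
                    n_variants_per_gene_cis = 25, n_trans_variants = 0,
                    ld_decay = 0.5, seed = 14)
  gt <- simulate_genotypes(cfg)
  ss <- simulate_sumstats(gt$strata$ref, effects = NULL, config = cfg)
  m <- nrow(ss)
  expect_lt(abs(mean(ss$z)), 4 / sqrt(m))  # marginally N(0,1)
  expect_lt(abs(sd(ss$z) - 1), 0.25)
  # perfectly correlated variants get equal expected Z: duplicate a column
  g2 <- gt$strata$ref
  dup <- genotype_matrix(cbind(g2$dosages[, 1, drop = FALSE],
                               g2$dosages[, 1, drop = FALSE]),
                         data.frame(id = c("a", "b"), chrom = "1",
                                    pos = c(100L, 200L), ref = "A", alt = "G"),
                         samples = g2$samples)
  zd <- replicate(40, {
    cfg2 <- sim_config(n_samples_per_stratum = 400, n_genes = 8,
                       seed = sample.int(1e6, 1))
    s2 <- simulate_sumstats(dup, effects = c(a = 0.02), config = cfg2)
    s2$z
  })
  expect_equal(mean(zd[1, ]), mean(zd[2, ]), tolerance = 0.35)
  expect_gt(mean(zd[1, ]), 2)  # effect propagated through sqrt(n)
})

test_that("a single causal variant carries the top summary-statistic signal", {
  hits <- 0
  for (r in 1:10) {
    cfg <- sim_config(n_samples_per_stratum = 300, n_genes = 2,
                      n_variants_per_gene_cis = 15, n_trans_variants = 0,
                      ld_decay = 0.3, n_gwas = 50000, seed = 100 + r)
    gt <- simulate_genotypes(cfg)
    causal <- gt$strata$ref$variants$id[8]
    eff <- setNames(0.03, causal)
    ss <- simulate_sumstats(gt$strata$ref, effects = eff, config = cfg)
    top <- ss$id[which.max(abs(ss$z))]
    # top hit is the causal variant or one of its LD neighbors
    hits <- hits + (abs(ss$pos[ss$id == top] - ss$pos[ss$id == causal]) <= 3000)
  }
  expect_gte(hits, 9)
})
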