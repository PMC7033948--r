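test_that("Cox score test equals the hand-computed log-rank statistic", {
  set.seed(70)
  n <- 24
  group <- rep(c(0, 1), each = n / 2)
  time <- sort(runif(n, 1, 100))[sample(n)]   # distinct times, no censoring
  fit <- survival::coxph(survival::Surv(time, rep(1, n)) ~ group,
                         ties = "efron")
  lr <- logrank_oracle(time, rep(1, n), group)
  expect_equal(unname(fit$score), lr, tolerance = 1e-8)
})

test_that("cause-specific Cox treats competing events as censoring", {
  set.seed(71)
  n <- 400
  x <- rnorm(n)
  surv <- toy_surv(rexp(n, 0.1),
                   sample(c("primary", "competing", "censored"), n, TRUE,
                          prob = c(0.3, 0.2, 0.5)))
  fit <- coxph_cause_specific(x, NULL, surv)
  # identical fit when competing events are relabeled as censored
  surv2 <- surv
  surv2$cause[surv2$cause == "competing"] <- "censored"
  fit2 <- coxph_cause_specific(x, NULL, surv2)
  expect_equal(fit$beta, fit2$beta, tolerance = 1e-12)
  expect_equal(fit$se, fit2$se, tolerance = 1e-12)
  expect_identical(fit$n_events, sum(surv$cause == "primary"))
  # bad inputs
  expect_error(coxph_cause_specific(x[1:3], NULL,
                                    toy_surv(rep(1, 3), rep("censored", 3))),
               "no primary-cause events")
  expect_error(coxph_cause_specific(x[1:3], NULL,
                                    toy_surv(c(-1, 1, 2), rep("primary", 3))))
})

test_that("covariate adjustment changes the fit exactly as coxph does", {
  set.seed(72)
  n <- 300
  age <- rnorm(n)
  x <- 0.5 * age + rnorm(n)
  lp <- 0.4 * x + 0.6 * age
  time <- rexp(n, exp(lp - mean(lp)))
  cens <- rexp(n, 0.05)
  surv <- toy_surv(pmin(time, cens),
                   ifelse(time <= cens, "primary", "censored"))
  fit <- coxph_cause_specific(x, data.frame(age = age), surv)
  ref <- survival::coxph(
    survival::Surv(surv$time, surv$cause == "primary") ~ x + age,
    ties = "efron")
  expect_equal(fit$beta, unname(coef(ref)["x"]), tolerance = 1e-10)
})

test_that("BH adjustment reproduces the step-up hand computation", {
  adj <- bh_adjust(c(0.01, 0.02, 0.03, 0.9), fdr = 0.10)
  expect_equal(adj$p_adjusted, c(0.04, 0.04, 0.04, 0.9), tolerance = 1e-12)
  expect_identical(adj$call, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_adjust(0.2)$p_adjusted, 0.2)
  expect_false(any(bh_adjust(rep(1, 5))$call))
})

test_that("burden statistic matches printed arithmetic and identities", {
  variants2 <- data.frame(id = c("a", "b"), chrom = "1", pos = c(100L, 200L),
                          ref = "A", alt = "G", stringsAsFactors = FALSE)
  model <- list(weights = setNames(c(1, 1), c("a", "b")), variants = variants2)
  ss <- data.frame(id = c("a", "b"), chrom = "1", pos = c(100L, 200L),
                   ref = "A", alt = "G", z = c(2, 2),
                   stringsAsFactors = FALSE)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  bt <- burden_test(model, ss, S)
  expect_equal(bt$z_tilde, 4 / sqrt(3), tolerance = 1e-12)
  expect_true(bt$significant)
  expect_identical(bt$ridge_eps, 0)   # well-conditioned: no ridge applied
  # single variant, unit weight, unit LD: statistic passes through
  m1 <- list(weights = setNames(1.0, "a"), variants = variants2[1, ])
  bt1 <- burden_test(m1, ss[1, ], matrix(1, 1, 1))
  expect_equal(bt1$z_tilde, 2, tolerance = 1e-12)
  # zero Z vector nullifies the statistic
  ss0 <- ss; ss0$z <- 0
  expect_equal(burden_test(model, ss0, S)$z_tilde, 0, tolerance = 1e-12)
})

test_that("burden statistic is invariant to consistent allele flips", {
  set.seed(73)
  n <- 150
  variants3 <- toy_variants(3)
  D <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  ld_ref <- genotype_matrix(D, variants3)
  model <- list(weights = setNames(c(0.4, -0.7, 0.2), variants3$id),
                variants = variants3)
  ss <- data.frame(variants3, z = c(1.5, -2.2, 0.3),
                   stringsAsFactors = FALSE)
  base <- burden_test(model, ss, ld_ref)
  # flip variant 2 everywhere it appears externally: sumstats allele order
  # swapped (z sign flips), reference panel alleles swapped (dosage reflected)
  ss_f <- ss
  ss_f$ref[2] <- variants3$alt[2]; ss_f$alt[2] <- variants3$ref[2]
  ss_f$z[2] <- -ss$z[2]
  D_f <- D; D_f[, 2] <- 2 - D[, 2]
  v_f <- variants3
  v_f$ref[2] <- variants3$alt[2]; v_f$alt[2] <- variants3$ref[2]
  ld_f <- genotype_matrix(D_f, v_f)
  flipped <- burden_test(model, ss_f, ld_f)
  expect_equal(flipped$z_tilde, base$z_tilde, tolerance = 1e-10)
  # degenerate LD (duplicated variant) triggers the documented ridge
  v_dup <- toy_variants(2)
  Ddup <- cbind(D[, 1], D[, 1])
  ld_dup <- genotype_matrix(Ddup, v_dup)
  m_dup <- list(weights = setNames(c(1, 1), v_dup$id), variants = v_dup)
  ss_dup <- data.frame(v_dup, z = c(2, 2), stringsAsFactors = FALSE)
  bdup <- burden_test(m_dup, ss_dup, ld_dup)
  expect_gt(bdup$ridge_eps, 0)
  expect_true(is.finite(bdup$z_tilde))
})

test_that("conditional adjustment distinguishes mediation from independence", {
  set.seed(74)
  n <- 2000
  snp <- rbinom(n, 2, 0.3)
  other <- rbinom(n, 2, 0.3)
  grex_med <- 0.9 * snp                 # GReX built entirely from the SNP
  grex_ind <- 0.9 * other + rnorm(n, 0, 0.1)
  lp <- 0.3 * scale(grex_med)
  time <- rexp(n, exp(lp - mean(lp)))
  cens <- rexp(n, 0.03)
  surv <- toy_surv(pmin(time, cens),
                   ifelse(time <= cens, "primary", "censored"))
  med <- conditional_adjust(grex_med, snp, NULL, surv)
  expect_true(med$unstable)             # |cor| = 1 with its own SNP
  ind <- conditional_adjust(grex_ind, snp, NULL, surv)
  expect_false(ind$unstable)
  expect_lt(abs(ind$beta_conditional - ind$beta_unconditional), 0.08)
})

test_that("conditional attenuation follows the partial-regression oracle", {
  set.seed(75)
  n <- 6000
  snp <- rbinom(n, 2, 0.4)
  grex <- 0.6 * snp + rnorm(n, 0, 0.8)   # partial overlap
  lp <- 0.25 * (grex - mean(grex)) / sd(grex)
  time <- rexp(n, exp(lp))
  cens <- rexp(n, 0.02)
  surv <- toy_surv(pmin(time, cens),
                   ifelse(time <= cens, "primary", "censored"))
  res <- conditional_adjust(grex, snp, NULL, surv)
  # oracle: with hazard loading on grex only, the conditional coefficient
  # (given the SNP) stays near the unconditional one, while a model of the
  # SNP alone would be attenuated by cor^2; check both directions
  expect_lt(abs(res$beta_conditional - res$beta_unconditional),
            2.5 * res$se_conditional)
  snp_only <- coxph_cause_specific(snp, NULL, surv)
  snp_given_grex <- conditional_adjust(snp, grex, NULL, surv)
  expect_gt(abs(snp_only$beta), 2 * abs(snp_given_grex$beta_conditional))
})

test_that("GWAS scan skips monomorphic variants and duplicates agree", {
  set.seed(76)
  n <- 300
  d1 <- rbinom(n, 2, 0.4)
  g <- genotype_matrix(cbind(d1, d1, rep(0, n)), toy_variants(3))
  lp <- 0.4 * d1
  time <- rexp(n, exp(lp - mean(lp)))
  cens <- rexp(n, 0.05)
  surv <- toy_surv(pmin(time, cens),
                   ifelse(time <= cens, "primary", "censored"))
  res <- gwas_scan(g, NULL, surv)
  expect_identical(nrow(res), 2L)       # monomorphic skipped
  expect_equal(res$beta[1], res$beta[2], tolerance = 1e-12)
  expect_equal(res$z[1], res$z[2], tolerance = 1e-12)
})

test_that("TWAS scan is deterministic and honest about failures", {
  set.seed(77)
  n <- 250
  grex <- cbind(gA = rnorm(n), gB = rnorm(n))
  grex <- cbind(grex, gA2 = grex[, "gA"])
  surv <- toy_surv(rexp(n, 0.1),
                   sample(c("primary", "censored"), n, TRUE, c(0.3, 0.7)))
  tw <- twas_scan(grex, NULL, surv, empirical_null = FALSE)
  expect_equal(tw$z[tw$gene == "gA"], tw$z[tw$gene == "gA2"],
               tolerance = 1e-12)
  expect_true(all(tw$hr == exp(tw$log_hr), na.rm = TRUE))
  expect_true(all(tw$p_fdr >= tw$p_corrected - 1e-15, na.rm = TRUE))
  # small panels skip the empirical-null correction with a note
  expect_message(tw2 <- twas_scan(grex, NULL, surv, empirical_null = TRUE),
                 "fewer than 20")
  expect_equal(tw2$z_corrected, tw2$z, tolerance = 1e-12)
})

test_that("empirical-null Gibbs fit is seeded and recovers a pure null", {
  set.seed(78)
  z0 <- rnorm(400)
  b1 <- bacon_correct(z0, iterations = 1500, burn_in = 600, seed = 5)
  b2 <- bacon_correct(z0, iterations = 1500, burn_in = 600, seed = 5)
  expect_identical(b1$bias, b2$bias)
  expect_identical(b1$z_corrected, b2$z_corrected)
  expect_lt(abs(b1$bias), 0.12)
  expect_gt(b1$inflation, 0.85)
  expect_lt(b1$inflation, 1.15)
  expect_lt(b1$split_rhat, 1.1)
  expect_equal(sum(b1$weights), 1, tolerance = 1e-9)
  expect_warning(bacon_correct(rnorm(10), iterations = 200, burn_in = 50),
                 "fewer than 20")
})
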