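# -- Synthetic two-stratum cohort generator ----------------------------------
#
# Generates cohorts with the data structure the pipeline consumes: two
# ancestry strata with Balding-Nichols differentiated allele frequencies,
# first-order (geometrically decaying) LD within gene blocks, admixed local
# ancestry in the first stratum, sparse cis (+ optional trans) eQTL
# architecture with covariate-driven nuisance variation, competing-risks
# survival loaded on the true genetically regulated expression, and
# LD-propagated GWAS summary statistics. Every output is a deterministic
# function of the config seed.

#' Configuration for a synthetic two-stratum cohort
#'
#' Defaults emulate the structure of a two-ancestry breast-cancer cohort at
#' desk scale: two strata of 600 expression-profiled samples (an admixed
#' African-ancestry-like stratum and a European-ancestry-like stratum),
#' allele-frequency differentiation Fst = 0.15 (typical of West
#' African/European contrasts), strong local LD, a panel of genes with cis
#' heritabilities spanning 0 to 0.3 around the few-percent average seen for
#' tumor expression, sparse cis architecture (3 causal variants per gene),
#' and competing-risks survival with roughly 9\% primary-cause mortality,
#' 8.5\% competing mortality and the remainder censored.
#'
#' @param n_samples_per_stratum samples per stratum (>= 2).
#' @param n_genes number of genes.
#' @param n_variants_per_gene_cis cis variants simulated per gene.
#' @param n_trans_variants variants in a distal trans block.
#' @param maf_range ancestral allele-frequency range, in (0, 0.5].
#' @param fst Balding-Nichols differentiation parameter (>= 0).
#' @param ld_decay latent AR(1) autocorrelation between adjacent variants,
#'   in [0, 1).
#' @param cis_h2_per_gene per-gene cis heritability fractions in [0, 1);
#'   recycled to \code{n_genes}.
#' @param n_causal_cis causal cis variants per gene.
#' @param n_causal_trans causal trans variants per gene (0 disables).
#' @param trans_h2 expression variance fraction from trans effects.
#' @param covariate_var expression variance fraction from covariates.
#' @param admixture_alpha first Beta parameter of the admixture proportion
#'   in stratum 1; the second parameter is fixed at 2, so the default 8
#'   gives mean admixture proportion 0.8 from the first ancestral
#'   population.
#' @param covariate_spec named list mapping covariate name to
#'   \code{"normal"} or \code{"binary"}.
#' @param survival_beta per-gene log-hazard on standardized true GReX;
#'   recycled to \code{n_genes}.
#' @param event_rate,competing_rate,censor_rate target fractions of
#'   primary-cause events, competing-cause events and censored records;
#'   must sum to 1.
#' @param shared_architecture logical; draw one causal-weight vector per
#'   gene and share it across strata (default) or redraw per stratum.
#' @param n_gwas GWAS sample size used when simulating summary statistics.
#' @param seed integer seed that fully determines all outputs.
#' @return A validated object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples_per_stratum = 600,
                       n_genes = 10,
                       n_variants_per_gene_cis = 20,
                       n_trans_variants = 10,
                       maf_range = c(0.05, 0.5),
                       fst = 0.15,
                       ld_decay = 0.7,
                       cis_h2_per_gene = rep(c(0, 0.05, 0.1, 0.2, 0.3),
                                             length.out = n_genes),
                       n_causal_cis = 3,
                       n_causal_trans = 0,
                       trans_h2 = 0,
                       covariate_var = 0.1,
                       admixture_alpha = 8,
                       covariate_spec = list(age = "normal", er = "binary",
                                             pc1 = "normal", pc2 = "normal"),
                       survival_beta = rep(0, n_genes),
                       event_rate = 0.09,
                       competing_rate = 0.085,
                       censor_rate = 0.825,
                       shared_architecture = TRUE,
                       n_gwas = 50000,
                       seed = 1L) {
  cfg <- list(n_samples_per_stratum = as.integer(n_samples_per_stratum),
              n_genes = as.integer(n_genes),
              n_variants_per_gene_cis = as.integer(n_variants_per_gene_cis),
              n_trans_variants = as.integer(n_trans_variants),
              maf_range = as.numeric(maf_range), fst = fst,
              ld_decay = ld_decay,
              cis_h2_per_gene = rep(cis_h2_per_gene, length.out = n_genes),
              n_causal_cis = as.integer(n_causal_cis),
              n_causal_trans = as.integer(n_causal_trans),
              trans_h2 = trans_h2,
              covariate_var = covariate_var,
              admixture_alpha = admixture_alpha,
              covariate_spec = covariate_spec,
              survival_beta = rep(survival_beta, length.out = n_genes),
              event_rate = event_rate, competing_rate = competing_rate,
              censor_rate = censor_rate,
              shared_architecture = isTRUE(shared_architecture),
              n_gwas = n_gwas,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_samples_per_stratum < 2) stop("invalid config: n_samples_per_stratum < 2")
    if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1] > maf_range[2])
      stop("invalid config: maf_range must be an increasing pair in (0, 0.5]")
    if (fst < 0) stop("invalid config: fst < 0")
    if (ld_decay < 0 || ld_decay >= 1) stop("invalid config: ld_decay outside [0, 1)")
    if (any(cis_h2_per_gene < 0 | cis_h2_per_gene >= 1))
      stop("invalid config: cis_h2_per_gene outside [0, 1)")
    if (any(cis_h2_per_gene > 0) && n_causal_cis == 0)
      stop("invalid config: positive cis_h2 requested with n_causal_cis = 0")
    if (any(cis_h2_per_gene + covariate_var + trans_h2 > 1))
      stop("invalid config: cis_h2 + nuisance variance fractions exceed 1")
    if (event_rate < 0 || competing_rate < 0 || censor_rate < 0)
      stop("invalid config: negative rate")
    if (abs(event_rate + competing_rate + censor_rate - 1) > 1e-9)
      stop("invalid config: event, competing and censor rates must sum to 1")
    if (admixture_alpha <= 0) stop("invalid config: admixture_alpha <= 0")
  })
  invisible(cfg)
}

# Genome layout on a single synthetic chromosome: genes of 10 kb tiled
# 1.2 Mb apart (so 500-kb cis windows never overlap), then a trans block
# at least 2 Mb beyond the last gene.
sim_layout <- function(cfg) {
  gene_len <- 10000L
  spacing <- 1200000L
  start <- 600000L + (seq_len(cfg$n_genes) - 1L) * spacing
  genes <- data.frame(id = sprintf("gene%02d", seq_len(cfg$n_genes)),
                      chrom = "1", start = start, end = start + gene_len - 1L,
                      stringsAsFactors = FALSE)
  trans_start <- max(genes$end) + 2000000L
  list(genes = genes, gene_len = gene_len, trans_start = trans_start)
}

# Latent-AR(1) haplotype draw: alleles are thresholded standard-normal
# AR(1) series, which preserves the target marginal frequency exactly and
# gives geometrically decaying LD. freq is an n x m matrix of per-copy
# allele frequencies (individual-specific under admixture), blocks a list
# of column ranges within which the AR chain runs (it resets between
# blocks, so distant gene regions are unlinked).
draw_haplotypes <- function(n, freq, ld_decay, blocks) {
  m <- ncol(freq)
  z <- matrix(rnorm(n * m), n, m)
  if (ld_decay > 0) {
    s <- sqrt(1 - ld_decay^2)
    for (blk in blocks) {
      for (j in blk[-1]) z[, j] <- ld_decay * z[, j - 1] + s * z[, j]
    }
  }
  (z < qnorm(freq)) * 1L
}

#' Simulate two-stratum genotypes with admixed local ancestry
#'
#' Per-stratum allele frequencies are drawn around shared ancestral
#' frequencies under a Balding-Nichols model with parameter \code{fst}.
#' Stratum 1 ("admix") is an admixed population: each haplotype's ancestral
#' origin is drawn per gene block from the sample's admixture proportion,
#' and the latent origin dosage is exposed directly as local ancestry.
#' Stratum 2 ("ref") is unadmixed. Dosages are sums of two haplotypes
#' drawn by a latent AR(1) copula with autocorrelation \code{ld_decay}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{strata} (named list of two
#'   \code{\link{genotype_matrix}} objects), \code{local_ancestry}
#'   (stratum-1 samples x variants dosage of first-ancestral-population
#'   alleles in [0, 2]), \code{ancestral_freqs} (per-population allele
#'   frequency vectors) and \code{layout}.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  lay <- sim_layout(config)
  n <- config$n_samples_per_stratum
  mg <- config$n_variants_per_gene_cis
  # variant positions: sorted uniform in each cis window, even grid in trans
  pos_list <- lapply(seq_len(config$n_genes), function(g) {
    win <- c(lay$genes$start[g] - 500000L + 1L, lay$genes$end[g] + 500000L)
    sort(sample(seq(win[1], win[2]), mg))
  })
  blocks <- split(seq_len(config$n_genes * mg),
                  rep(seq_len(config$n_genes), each = mg))
  if (config$n_trans_variants > 0) {
    pos_list <- c(pos_list, list(lay$trans_start +
                                   500L * (seq_len(config$n_trans_variants) - 1L)))
    blocks <- c(blocks, list(config$n_genes * mg + seq_len(config$n_trans_variants)))
  }
  pos <- unlist(pos_list)
  m <- length(pos)
  variants <- data.frame(id = sprintf("snp%05d", seq_len(m)), chrom = "1",
                         pos = as.integer(pos), ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  p0 <- runif(m, config$maf_range[1], config$maf_range[2])
  if (config$fst > 0) {
    a <- p0 * (1 - config$fst) / config$fst
    b <- (1 - p0) * (1 - config$fst) / config$fst
    pA <- rbeta(m, a, b)   # first ancestral population (admixed majority)
    pB <- rbeta(m, a, b)   # second ancestral population
    # keep frequencies polymorphic
    pA <- pmin(pmax(pA, 1e-4), 1 - 1e-4)
    pB <- pmin(pmax(pB, 1e-4), 1 - 1e-4)
  } else {
    pA <- pB <- p0
  }
  # stratum 2: unadmixed population B
  freqB <- matrix(pB, n, m, byrow = TRUE)
  hapB1 <- draw_haplotypes(n, freqB, config$ld_decay, blocks)
  hapB2 <- draw_haplotypes(n, freqB, config$ld_decay, blocks)
  # stratum 1: admixture proportion per sample, origin drawn per block/hap
  q <- rbeta(n, config$admixture_alpha, 2)
  n_blocks <- length(blocks)
  origin1 <- matrix(rbinom(n * n_blocks, 1, q), n, n_blocks)
  origin2 <- matrix(rbinom(n * n_blocks, 1, q), n, n_blocks)
  expand_blocks <- function(o) {
    out <- matrix(0L, n, m)
    for (b in seq_len(n_blocks)) out[, blocks[[b]]] <- o[, b]
    out
  }
  O1 <- expand_blocks(origin1); O2 <- expand_blocks(origin2)
  freqA1 <- matrix(pB, n, m, byrow = TRUE); freqA1[O1 == 1] <- matrix(pA, n, m, byrow = TRUE)[O1 == 1]
  freqA2 <- matrix(pB, n, m, byrow = TRUE); freqA2[O2 == 1] <- matrix(pA, n, m, byrow = TRUE)[O2 == 1]
  hapA1 <- draw_haplotypes(n, freqA1, config$ld_decay, blocks)
  hapA2 <- draw_haplotypes(n, freqA2, config$ld_decay, blocks)
  ids1 <- sprintf("admix%04d", seq_len(n))
  ids2 <- sprintf("ref%04d", seq_len(n))
  g1 <- genotype_matrix(hapA1 + hapA2, variants, samples = ids1, stratum = "admix")
  g2 <- genotype_matrix(hapB1 + hapB2, variants, samples = ids2, stratum = "ref")
  la <- O1 + O2
  dimnames(la) <- list(ids1, variants$id)
  list(strata = list(admix = g1, ref = g2),
       local_ancestry = la,
       ancestral_freqs = list(shared = p0, popA = pA, popB = pB),
       layout = lay)
}

# cis/trans variant index helpers for the synthetic layout
cis_indices <- function(variants, gene_row, cis_window = 500000) {
  which(variants$chrom == gene_row$chrom &
          variants$pos >= gene_row$start - cis_window &
          variants$pos <= gene_row$end + cis_window)
}

#' Simulate expression with sparse cis architecture and covariate nuisance
#'
#' For each gene g and stratum, \eqn{E_g = X_g w_g + X_C \beta_C +
#' \epsilon_g}: weights are drawn on \code{n_causal_cis} cis variants
#' (plus optional trans variants) and scaled so the realized genetic
#' variance fraction matches the configured cis heritability; covariates
#' carry a configured variance fraction; the remainder is Gaussian noise.
#' With \code{shared_architecture} the weight vector is drawn and scaled
#' once (on stratum 1) and applied to both strata.
#'
#' @param genotypes result of \code{\link{simulate_genotypes}}.
#' @param config the same \code{\link{sim_config}}.
#' @return list with per-stratum \code{expression}
#'   (\code{\link{expression_matrix}}), \code{covariates} (data.frame with
#'   a \code{sample} column), \code{grex_true} (samples x genes true
#'   genetic values), and \code{truth} (causal_weights, true_cis_h2 per
#'   stratum, covariate effects).
#' @export
simulate_expression <- function(genotypes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  lay <- genotypes$layout
  strata <- genotypes$strata
  variants <- strata[[1]]$variants
  n_tr <- config$n_trans_variants
  trans_idx <- if (n_tr > 0) {
    nrow(variants) - n_tr + seq_len(n_tr)
  } else integer(0)

  covs <- lapply(strata, function(g) {
    n <- length(g$samples)
    df <- data.frame(sample = g$samples, stringsAsFactors = FALSE)
    for (nm in names(config$covariate_spec)) {
      df[[nm]] <- switch(config$covariate_spec[[nm]],
                         normal = rnorm(n),
                         binary = rbinom(n, 1, 0.5),
                         stop("unknown covariate distribution: ",
                              config$covariate_spec[[nm]]))
    }
    df
  })

  k_strata <- length(strata)
  causal_weights <- vector("list", config$n_genes)
  names(causal_weights) <- lay$genes$id
  true_h2 <- matrix(NA_real_, config$n_genes, k_strata,
                    dimnames = list(lay$genes$id, names(strata)))
  expr <- lapply(strata, function(g) matrix(0, length(g$samples), config$n_genes))
  grex_true <- lapply(strata, function(g) matrix(0, length(g$samples), config$n_genes))
  cov_effects <- vector("list", config$n_genes)

  for (gidx in seq_len(config$n_genes)) {
    h2 <- config$cis_h2_per_gene[gidx]
    ci <- cis_indices(variants, lay$genes[gidx, ])
    causal <- if (h2 > 0) sort(sample(ci, min(config$n_causal_cis, length(ci)))) else integer(0)
    tr_causal <- if (config$trans_h2 > 0 && config$n_causal_trans > 0)
      sort(sample(trans_idx, min(config$n_causal_trans, length(trans_idx)))) else integer(0)
    w_raw <- rnorm(length(causal) + length(tr_causal))
    beta_c_raw <- rnorm(length(config$covariate_spec))
    per_stratum_w <- vector("list", k_strata)
    for (s in seq_len(k_strata)) {
      X <- strata[[s]]$dosages[, c(causal, tr_causal), drop = FALSE]
      Xc <- as.matrix(covs[[s]][, names(config$covariate_spec), drop = FALSE])
      if (!config$shared_architecture && s > 1) w_raw <- rnorm(ncol(X))
      g_tot <- h2 + config$trans_h2
      if (ncol(X) > 0 && g_tot > 0) {
        graw <- drop(X %*% w_raw)
        sc <- sqrt(g_tot / max(var(graw), 1e-12))
        if (config$shared_architecture && s > 1) sc <- per_stratum_w[[1]]$scale
        w <- w_raw * sc
        gval <- drop(X %*% w)
      } else {
        w <- numeric(0); gval <- numeric(length(strata[[s]]$samples))
      }
      craw <- drop(Xc %*% beta_c_raw)
      csc <- if (config$covariate_var > 0) sqrt(config$covariate_var / max(var(craw), 1e-12)) else 0
      cval <- craw * csc
      noise_sd <- sqrt(max(1 - g_tot - config$covariate_var, 1e-8))
      e <- gval + cval + rnorm(length(gval), 0, noise_sd)
      expr[[s]][, gidx] <- e
      grex_true[[s]][, gidx] <- gval
      true_h2[gidx, s] <- if (var(e) > 0) var(gval) / var(e) else 0
      per_stratum_w[[s]] <- list(w = setNames(w, variants$id[c(causal, tr_causal)]),
                                 scale = if (length(w)) w[1] / w_raw[1] else 1)
    }
    causal_weights[[gidx]] <- lapply(per_stratum_w, `[[`, "w")
    names(causal_weights[[gidx]]) <- names(strata)
    cov_effects[[gidx]] <- setNames(beta_c_raw, names(config$covariate_spec))
  }

  out_expr <- lapply(seq_len(k_strata), function(s)
    expression_matrix(expr[[s]], lay$genes, samples = strata[[s]]$samples))
  names(out_expr) <- names(strata)
  grex_true <- lapply(seq_len(k_strata), function(s) {
    gm <- grex_true[[s]]
    dimnames(gm) <- list(strata[[s]]$samples, lay$genes$id)
    gm
  })
  names(grex_true) <- names(strata)
  list(expression = out_expr, covariates = covs, grex_true = grex_true,
       truth = list(causal_weights = causal_weights,
                    true_cis_h2 = true_h2,
                    covariate_effects = cov_effects))
}

#' Simulate competing-risks survival from true GReX
#'
#' Event times follow exponential cause-specific hazards: the primary
#' cause loads \code{survival_beta} on each standardized true GReX column
#' (plus a small age effect), the competing cause and censoring are
#' independent exponentials. Rate constants are tuned by fixed-point
#' iteration so the expected fractions of primary events, competing events
#' and censored records match the config.
#'
#' @param grex_true samples x genes matrix of true genetic expression
#'   values.
#' @param covariates data.frame with a \code{sample} column aligned to
#'   \code{grex_true} rows.
#' @param config a \code{\link{sim_config}}.
#' @return data.frame (SurvivalTable) with columns sample, time, cause
#'   (\code{"primary"}, \code{"competing"} or \code{"censored"}).
#' @export
simulate_survival <- function(grex_true, covariates, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- nrow(grex_true)
  stopifnot(n == nrow(covariates))
  beta <- rep(config$survival_beta, length.out = ncol(grex_true))
  gs <- scale(grex_true)
  gs[is.nan(gs)] <- 0
  eta <- drop(gs %*% beta)
  if ("age" %in% names(covariates)) eta <- eta + 0.2 * as.numeric(covariates$age)
  eta <- eta - mean(eta)
  tgt <- c(config$event_rate, config$competing_rate, config$censor_rate)
  if (tgt[1] + tgt[2] == 0)
    return(data.frame(sample = covariates$sample,
                      time = runif(n, 0.5, 10), cause = "censored",
                      stringsAsFactors = FALSE))
  rel <- exp(eta)
  # fixed-point tuning of (a, b, d): P(cause j) = E[h_j / (h1 + b + d)]
  a <- max(tgt[1], 1e-6); b <- max(tgt[2], 1e-6); d <- max(tgt[3], 1e-6)
  for (it in 1:200) {
    h1 <- a * rel
    tot <- h1 + b + d
    p <- c(mean(h1 / tot), b * mean(1 / tot), d * mean(1 / tot))
    if (max(abs(p - tgt)) < 1e-10) break
    a <- a * max(tgt[1], 1e-12) / max(p[1], 1e-12)
    b <- b * max(tgt[2], 1e-12) / max(p[2], 1e-12)
    d <- d * max(tgt[3], 1e-12) / max(p[3], 1e-12)
  }
  h1 <- a * rel
  tot <- h1 + b + d
  time <- rexp(n, rate = tot)
  u <- runif(n)
  cause <- ifelse(u < h1 / tot, "primary",
                  ifelse(u < (h1 + b) / tot, "competing", "censored"))
  data.frame(sample = covariates$sample, time = time, cause = cause,
             stringsAsFactors = FALSE)
}

#' Simulate GWAS summary statistics propagated through LD
#'
#' Per-variant Z-scores are drawn as \eqn{Z \sim N(\sqrt{n} R \beta, R)}
#' where R is the realized dosage correlation matrix of the reference
#' panel (ridge-stabilized) and \eqn{\beta} the standardized per-variant
#' liability effects (zero by default).
#'
#' @param genotypes a \code{\link{genotype_matrix}} used as LD reference.
#' @param effects named numeric vector of standardized per-variant
#'   effects; variants not named have effect 0. \code{NULL} means all zero.
#' @param config a \code{\link{sim_config}} (uses \code{n_gwas} and
#'   \code{seed}).
#' @param ridge_eps ridge added to the LD matrix diagonal for a stable
#'   Cholesky factor (recorded on the output).
#' @return data.frame with columns id, chrom, pos, ref, alt, z.
#' @export
simulate_sumstats <- function(genotypes, effects = NULL, config,
                              ridge_eps = 1e-6) {
  validate_sim_config(config)
  set.seed(config$seed + 3L)
  g <- genotypes
  Z <- scale(g$dosages)
  keep <- !is.nan(colSums(Z)) & apply(g$dosages, 2, sd) > 0
  Z <- Z[, keep, drop = FALSE]
  v <- g$variants[keep, , drop = FALSE]
  m <- ncol(Z)
  R <- crossprod(Z) / (nrow(Z) - 1)
  R <- R + diag(ridge_eps, m)
  beta <- rep(0, m)
  if (!is.null(effects)) {
    idx <- match(names(effects), v$id)
    beta[idx[!is.na(idx)]] <- effects[!is.na(idx)]
  }
  mu <- sqrt(config$n_gwas) * drop(R %*% beta)
  L <- chol(R)
  z <- mu + drop(crossprod(L, rnorm(m)))
  out <- data.frame(v[, c("id", "chrom", "pos", "ref", "alt")], z = z,
                    stringsAsFactors = FALSE)
  attr(out, "ridge_eps") <- ridge_eps
  out
}

#' Simulate a complete cohort (genotypes, expression, survival, truth)
#'
#' Convenience wrapper running \code{\link{simulate_genotypes}},
#' \code{\link{simulate_expression}} and \code{\link{simulate_survival}}
#' per stratum under one config.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{genotypes}, \code{expression},
#'   \code{covariates}, \code{grex_true}, \code{survival} (per-stratum
#'   list), \code{local_ancestry}, \code{layout} and \code{truth}.
#' @export
simulate_cohort <- function(config) {
  gt <- simulate_genotypes(config)
  ex <- simulate_expression(gt, config)
  surv <- lapply(names(gt$strata), function(s)
    simulate_survival(ex$grex_true[[s]], ex$covariates[[s]], config))
  names(surv) <- names(gt$strata)
  truth <- ex$truth
  truth$local_ancestry <- gt$local_ancestry
  truth$true_survival_beta <- setNames(config$survival_beta, gt$layout$genes$id)
  list(genotypes = gt$strata, expression = ex$expression,
       covariates = ex$covariates, grex_true = ex$grex_true,
       survival = surv, local_ancestry = gt$local_ancestry,
       layout = gt$layout, truth = truth)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes, per stratum, a dosage TSV (or VCF with DS genotypes), an
#' expression TSV, a covariate TSV and a survival TSV, plus a truth JSON
#' and the config as YAML.
#'
#' @param cohort result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if needed).
#' @param config the \code{\link{sim_config}} used.
#' @param genotype_format \code{"tsv"} or \code{"vcf"}.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir, config, genotype_format = c("tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(cohort$genotypes)) {
    g <- cohort$genotypes[[s]]
    if (genotype_format == "tsv") {
      write_genotypes(g, file.path(dir, paste0("genotypes_", s, ".tsv")))
    } else {
      write_vcf_dosages(g, file.path(dir, paste0("genotypes_", s, ".vcf")))
    }
    write_expression(cohort$expression[[s]],
                     file.path(dir, paste0("expression_", s, ".tsv")))
    write_table_tsv(cohort$covariates[[s]],
                    file.path(dir, paste0("covariates_", s, ".tsv")))
    write_table_tsv(cohort$survival[[s]],
                    file.path(dir, paste0("survival_", s, ".tsv")))
  }
  truth <- cohort$truth
  truth$local_ancestry <- NULL  # large matrix; kept in memory only
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write genotype dosages as a minimal VCF with a DS FORMAT field
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output path.
#' @export
write_vcf_dosages <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of alternate allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  body <- vapply(seq_len(nrow(g$variants)), function(j) {
    v <- g$variants[j, ]
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "DS",
            format(g$dosages[, j], trim = TRUE, digits = 15)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
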