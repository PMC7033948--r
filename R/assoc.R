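# -- Survival association (TWAS/GWAS), empirical-null correction, burden ----

#' Cause-specific Cox proportional hazards fit for one exposure
#'
#' Models the cause-specific hazard of the primary event:
#' \eqn{\lambda_k(t) = \lambda_{0k}(t) e^{x\beta + Z_C\beta_C}}.
#' Competing-cause and censored records are both treated as censoring for
#' the primary cause. The partial likelihood is maximized by
#' Newton-Raphson with Efron tie handling; the baseline hazard is never
#' estimated. Wald z = beta / se.
#'
#' @param x numeric exposure vector (e.g. a GReX column or SNP dosage).
#' @param covariates data.frame of adjustment covariates (optionally with
#'   a \code{sample} column), or NULL.
#' @param surv data.frame with columns sample, time, cause (values
#'   \code{"primary"}, \code{"competing"}, \code{"censored"}).
#' @return list(beta, se, z, p, n, n_events, converged).
#' @export
coxph_cause_specific <- function(x, covariates = NULL, surv) {
  stopifnot(all(c("time", "cause") %in% names(surv)),
            all(surv$time > 0),
            all(surv$cause %in% c("primary", "competing", "censored")))
  n <- nrow(surv)
  stopifnot(length(x) == n)
  status <- as.integer(surv$cause == "primary")
  if (sum(status) == 0) stop("no primary-cause events")
  df <- data.frame(time = surv$time, status = status, exposure = x)
  covariates <- align_covariates(covariates,
                                 if ("sample" %in% names(surv)) surv$sample
                                 else seq_len(n))
  if (!is.null(covariates)) {
    X <- covariate_design(covariates, n = n)
    X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
    if (ncol(X)) df <- cbind(df, as.data.frame(X))
  }
  fit <- survival::coxph(survival::Surv(time, status) ~ .,
                         data = df, ties = "efron")
  sm <- summary(fit)$coefficients
  converged <- is.finite(sm["exposure", "se(coef)"])
  list(beta = unname(sm["exposure", "coef"]),
       se = unname(sm["exposure", "se(coef)"]),
       z = unname(sm["exposure", "z"]),
       p = unname(sm["exposure", "Pr(>|z|)"]),
       n = n, n_events = sum(status), converged = converged)
}

#' Survival TWAS scan over imputed GReX
#'
#' Fits \code{\link{coxph_cause_specific}} per gene, then (optionally)
#' corrects the Wald z-statistics for bias and inflation with the
#' empirical-null mixture of \code{\link{bacon_correct}} and adjusts the
#' corrected p-values by Benjamini-Hochberg. Upstream the gene list is
#' expected to be restricted to genes with adequate CV R-squared and
#' significant cis-heritability.
#'
#' @param grex samples x genes imputed GReX matrix (rows aligned with
#'   \code{surv}).
#' @param covariates data.frame of adjustment covariates or NULL.
#' @param surv SurvivalTable (see \code{\link{coxph_cause_specific}}).
#' @param genes character subset of columns to test (default all).
#' @param fdr BH false-discovery level for calls (default 0.10).
#' @param empirical_null apply bacon-style correction (default TRUE when
#'   >= 20 genes are testable; small panels fall back to raw z with a
#'   note).
#' @param seed seed for the Gibbs sampler.
#' @return data.frame of TwasResults: gene, log_hr, hr, se, z, p_raw,
#'   z_corrected, p_corrected, p_fdr, call, n, n_events; the
#'   \code{\link{bacon_correct}} fit is attached as attribute
#'   \code{"bacon"} when used.
#' @export
twas_scan <- function(grex, covariates = NULL, surv, genes = colnames(grex),
                      fdr = 0.10, empirical_null = TRUE, seed = 1) {
  rows <- list()
  for (gn in genes) {
    res <- tryCatch(coxph_cause_specific(grex[, gn], covariates, surv),
                    error = function(e) NULL)
    rows[[gn]] <- if (is.null(res)) {
      data.frame(gene = gn, log_hr = NA_real_, hr = NA_real_, se = NA_real_,
                 z = NA_real_, p_raw = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = gn, log_hr = res$beta, hr = exp(res$beta),
                 se = res$se, z = res$z, p_raw = res$p,
                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$z)
  bacon <- NULL
  if (empirical_null && sum(ok) >= 20) {
    bacon <- bacon_correct(out$z[ok], seed = seed)
    out$z_corrected <- NA_real_
    out$z_corrected[ok] <- bacon$z_corrected
  } else {
    if (empirical_null && sum(ok) < 20)
      message("fewer than 20 testable genes; empirical-null correction skipped")
    out$z_corrected <- out$z
  }
  out$p_corrected <- 2 * pnorm(-abs(out$z_corrected))
  adj <- bh_adjust(out$p_corrected[ok], fdr = fdr)
  out$p_fdr <- NA_real_
  out$p_fdr[ok] <- adj$p_adjusted
  out$call <- !is.na(out$p_fdr) & out$p_fdr < fdr
  attr(out, "bacon") <- bacon
  out
}

#' Empirical-null correction of Z-statistics (three-component mixture)
#'
#' Gibbs sampler for a three-component normal mixture on robustly
#' standardized Z-statistics, with conjugate priors (normal means,
#' inverse-gamma variances, Dirichlet weights strongly favoring the
#' central component). The flanking (signal) components' means are
#' constrained to sit at least 2.5 current null-SDs from the current
#' null location, so true signals are absorbed by the flanks while the
#' central component tracks the empirical null. Bias and inflation are
#' the posterior averages of the median and MAD of the null-assigned
#' statistics (robust summaries: insensitive to the few extreme
#' statistics a mixture inevitably reassigns); corrected statistics are
#' \eqn{(z - bias) / inflation}. Chain mixing is checked by split R-hat
#' on the bias chain (warning above 1.1).
#'
#' @param z numeric vector of Z-statistics (at least 20, or a warning).
#' @param iterations total Gibbs iterations (default 5000).
#' @param burn_in burn-in iterations discarded (default 2000).
#' @param seed RNG seed.
#' @return list: bias, inflation, weights (posterior means),
#'   z_corrected, split_rhat, chain (post-burn-in draws of bias and
#'   inflation).
#' @export
bacon_correct <- function(z, iterations = 5000, burn_in = 2000, seed = 1) {
  m <- length(z)
  if (m < 20) warning("fewer than 20 statistics; empirical-null fit is fragile")
  stopifnot(burn_in < iterations)
  set.seed(seed)
  # fit on robustly standardized statistics so the +-3 flank anchors sit
  # ~3 null-SDs out whatever the actual bias/inflation; map back at the end
  med <- median(z); s_mad <- stats::mad(z)
  if (s_mad <= 0) s_mad <- sd(z)
  zs <- (z - med) / s_mad
  K <- 3
  prior_mean <- c(0, -3, 3)      # null component first, flanks absorb signal
  prior_tau2 <- c(100, 100, 100) # weakly informative locations
  prior_a <- 2; prior_b <- 1     # inverse-gamma on component variances
  prior_alpha <- c(90, 5, 5)     # Dirichlet strongly favoring the null
  sep <- 2.5                     # min flank distance, in null SDs
  mu <- c(0, -3, 3)
  s2 <- rep(1, K)
  w <- c(0.9, 0.05, 0.05)
  rtnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
    pl <- pnorm(lower, mean, sd); pu <- pnorm(upper, mean, sd)
    qnorm(runif(1, min(pl, pu), max(pl, pu)), mean, sd)
  }
  keep <- iterations - burn_in
  chain_bias <- numeric(keep); chain_inf <- numeric(keep)
  sum_w <- numeric(K)
  for (it in seq_len(iterations)) {
    # component assignments
    ll <- vapply(seq_len(K), function(k)
      log(w[k]) + stats::dnorm(zs, mu[k], sqrt(s2[k]), log = TRUE),
      numeric(m))
    ll <- ll - apply(ll, 1, max)
    pr <- exp(ll); pr <- pr / rowSums(pr)
    u <- runif(m)
    cs <- cbind(pr[, 1], pr[, 1] + pr[, 2])
    assign <- 1L + (u > cs[, 1]) + (u > cs[, 2])
    nk <- tabulate(assign, K)
    # weights | assignments
    w <- as.numeric(rgamma(K, prior_alpha + nk, 1))
    w <- w / sum(w)
    s0 <- sqrt(s2[1])
    for (k in seq_len(K)) {
      zk <- zs[assign == k]
      # mean | rest (conjugate normal; flanks truncated away from null)
      post_var <- 1 / (1 / prior_tau2[k] + nk[k] / s2[k])
      post_mean <- post_var * (prior_mean[k] / prior_tau2[k] + sum(zk) / s2[k])
      mu[k] <- if (k == 1L) rnorm(1, post_mean, sqrt(post_var))
      else if (k == 2L) rtnorm1(post_mean, sqrt(post_var),
                                upper = mu[1] - sep * s0)
      else rtnorm1(post_mean, sqrt(post_var), lower = mu[1] + sep * s0)
      # variance | rest (conjugate inverse-gamma)
      a_post <- prior_a + nk[k] / 2
      b_post <- prior_b + sum((zk - mu[k])^2) / 2
      s2[k] <- 1 / rgamma(1, a_post, b_post)
    }
    if (it > burn_in) {
      i <- it - burn_in
      znull <- zs[assign == 1L]
      chain_bias[i] <- median(znull)
      chain_inf[i] <- stats::mad(znull)
      sum_w <- sum_w + w
    }
  }
  bias <- med + s_mad * mean(chain_bias)
  inflation <- s_mad * mean(chain_inf)
  chain_bias <- med + s_mad * chain_bias
  chain_inf <- s_mad * chain_inf
  rhat <- split_rhat(chain_bias)
  if (is.finite(rhat) && rhat > 1.1)
    warning(sprintf("bias chain split R-hat = %.3f > 1.1: poor mixing", rhat))
  list(bias = bias, inflation = inflation, weights = sum_w / keep,
       z_corrected = (z - bias) / inflation, split_rhat = rhat,
       chain = list(bias = chain_bias, inflation = chain_inf))
}

# Split R-hat of a single chain (two halves as pseudo-chains).
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 4) return(NA_real_)
  h <- list(x[seq_len(n)], x[n + seq_len(n)])
  W <- mean(vapply(h, var, numeric(1)))
  B <- n * var(vapply(h, mean, numeric(1)))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Benjamini-Hochberg adjustment with calls
#'
#' @param p numeric p-values in [0, 1].
#' @param fdr call threshold (default 0.10).
#' @return list(p_adjusted, call).
#' @export
bh_adjust <- function(p, fdr = 0.10) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  adj <- p.adjust(p, method = "BH")
  list(p_adjusted = adj, call = !is.na(adj) & adj < fdr)
}

#' SNP-level survival GWAS
#'
#' Cause-specific Cox fit per variant with the same covariates as the
#' TWAS, BH-adjusted. Variants monomorphic in the analysis set are
#' skipped.
#'
#' @param g a \code{\link{genotype_matrix}} (QC'd; rows aligned with
#'   \code{surv}).
#' @param covariates data.frame or NULL.
#' @param surv SurvivalTable.
#' @param fdr BH level (default 0.10).
#' @return data.frame: variant, chrom, pos, beta, se, z, p, p_fdr.
#' @export
gwas_scan <- function(g, covariates = NULL, surv, fdr = 0.10) {
  rows <- lapply(seq_len(ncol(g$dosages)), function(j) {
    x <- g$dosages[, j]
    if (sd(x) < 1e-12) return(NULL)
    res <- tryCatch(coxph_cause_specific(x, covariates, surv),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(variant = g$variants$id[j], chrom = g$variants$chrom[j],
               pos = g$variants$pos[j], beta = res$beta, se = res$se,
               z = res$z, p = res$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable variants")
  out$p_fdr <- bh_adjust(out$p, fdr)$p_adjusted
  out
}

#' Conditional TWAS adjusting for the top local GWAS SNP
#'
#' Refits the cause-specific model for one gene with the dosage of the
#' most significant GWAS survival SNP near the gene appended to the
#' covariates, reporting unconditional and conditional estimates. A SNP
#' nearly collinear with the GReX (|r| > 0.99) flags the conditional
#' estimate as unstable.
#'
#' @param grex_col numeric GReX vector for the gene.
#' @param top_snp_dosage dosage vector of the top GWAS SNP.
#' @param covariates data.frame or NULL.
#' @param surv SurvivalTable.
#' @return one-row data.frame: beta_unconditional, se_unconditional,
#'   p_unconditional, beta_conditional, se_conditional, p_conditional,
#'   snp_grex_cor, unstable.
#' @export
conditional_adjust <- function(grex_col, top_snp_dosage, covariates = NULL,
                               surv) {
  unc <- coxph_cause_specific(grex_col, covariates, surv)
  r <- if (sd(grex_col) > 0 && sd(top_snp_dosage) > 0)
    cor(grex_col, top_snp_dosage) else NA_real_
  cov2 <- if (is.null(covariates)) data.frame(top_snp = top_snp_dosage)
  else cbind(align_covariates(covariates,
                              if ("sample" %in% names(surv)) surv$sample
                              else seq_len(nrow(surv))),
             top_snp = top_snp_dosage)
  cond <- tryCatch(coxph_cause_specific(grex_col, cov2, surv),
                   error = function(e) list(beta = NA_real_, se = NA_real_,
                                            p = NA_real_))
  data.frame(beta_unconditional = unc$beta, se_unconditional = unc$se,
             p_unconditional = unc$p,
             beta_conditional = cond$beta, se_conditional = cond$se,
             p_conditional = cond$p,
             snp_grex_cor = r,
             unstable = !is.na(r) && abs(r) > 0.99,
             stringsAsFactors = FALSE)
}

#' Weighted burden test of a gene against GWAS summary statistics
#'
#' Computes \eqn{\tilde Z = WZ / (W \Sigma_{s,s} W')^{1/2}} where Z is
#' the vector of per-variant GWAS Z-statistics for the model's variants,
#' W the trained expression-model weight row-vector (the finite-sample
#' stand-in for \eqn{\Sigma_{e,s}\Sigma_{s,s}^{-1}}), and
#' \eqn{\Sigma_{s,s}} the LD correlation matrix computed from reference
#' dosages, ridge-stabilized. Variants are matched by (chrom, pos, ref,
#' alt) with dosage/Z/weight reflection for swapped alleles, so the
#' statistic is invariant to consistent allele flips.
#'
#' @param model an \code{expression_model} (or list with
#'   \code{weights} and \code{variants}).
#' @param sumstats data.frame with columns id, chrom, pos, ref, alt, z.
#' @param ld_ref \code{\link{genotype_matrix}} LD reference panel, or a
#'   pre-computed LD correlation matrix over the model's variants (in
#'   model-variant order, model-allele orientation).
#' @param ridge_eps diagonal stabilization added to the LD matrix when it
#'   is numerically singular (default 1e-4; the value actually applied is
#'   recorded in the result, 0 when none was needed).
#' @return list: z_tilde, significant (|z| > 1.96), n_matched,
#'   match_rate, ridge_eps.
#' @export
burden_test <- function(model, sumstats, ld_ref, ridge_eps = 1e-4) {
  w_all <- model$weights
  mv <- model$variants
  if (is.matrix(ld_ref) && !inherits(ld_ref, "genotype_matrix"))
    return(burden_test_core(w_all, sumstats, mv, ld_ref, ridge_eps))
  keyify <- function(chrom, pos, a1, a2) paste(chrom, pos, a1, a2, sep = ":")
  mk <- keyify(mv$chrom, mv$pos, mv$ref, mv$alt)
  sk <- keyify(sumstats$chrom, sumstats$pos, sumstats$ref, sumstats$alt)
  sk_sw <- keyify(sumstats$chrom, sumstats$pos, sumstats$alt, sumstats$ref)
  rk <- keyify(ld_ref$variants$chrom, ld_ref$variants$pos,
               ld_ref$variants$ref, ld_ref$variants$alt)
  rk_sw <- keyify(ld_ref$variants$chrom, ld_ref$variants$pos,
                  ld_ref$variants$alt, ld_ref$variants$ref)
  si <- match(mk, sk); si_f <- match(mk, sk_sw)
  ri <- match(mk, rk); ri_f <- match(mk, rk_sw)
  s_flip <- is.na(si) & !is.na(si_f)
  r_flip <- is.na(ri) & !is.na(ri_f)
  si <- ifelse(is.na(si), si_f, si)
  ri <- ifelse(is.na(ri), ri_f, ri)
  matched <- !is.na(si) & !is.na(ri)
  if (!any(matched)) stop("no model variants matched in sumstats and LD reference")
  w <- unname(w_all[matched])
  zv <- sumstats$z[si[matched]] * ifelse(s_flip[matched], -1, 1)
  D <- ld_ref$dosages[, ri[matched], drop = FALSE]
  fl <- r_flip[matched]
  if (any(fl)) D[, fl] <- 2 - D[, fl]
  sds <- apply(D, 2, sd)
  if (any(sds == 0)) {
    keep <- sds > 0
    w <- w[keep]; zv <- zv[keep]; D <- D[, keep, drop = FALSE]
  }
  if (length(w) == 0) stop("no polymorphic matched variants")
  S <- cor(D)
  finish_burden(w, zv, S, ridge_eps, n_matched = length(w),
                match_rate = mean(matched))
}

# Burden statistic from a supplied LD matrix (sumstats matched by id).
burden_test_core <- function(w_all, sumstats, mv, S, ridge_eps) {
  idx <- match(mv$id, sumstats$id)
  matched <- !is.na(idx)
  if (!any(matched)) stop("no model variants matched in sumstats")
  w <- unname(w_all[matched])
  zv <- sumstats$z[idx[matched]]
  S <- S[matched, matched, drop = FALSE]
  finish_burden(w, zv, S, ridge_eps, n_matched = sum(matched),
                match_rate = mean(matched))
}

finish_burden <- function(w, zv, S, ridge_eps, n_matched, match_rate) {
  applied <- 0
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-8) {
    S <- S + diag(ridge_eps, ncol(S))
    applied <- ridge_eps
  }
  denom2 <- drop(t(w) %*% S %*% w)
  if (denom2 <= 0) stop("non-positive burden denominator after stabilization")
  z_tilde <- sum(w * zv) / sqrt(denom2)
  list(z_tilde = z_tilde, significant = abs(z_tilde) > 1.96,
       n_matched = n_matched, match_rate = match_rate,
       ridge_eps = applied)
}
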