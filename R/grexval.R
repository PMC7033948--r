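# -- GReX imputation and sampling-variability-aware validation ---------------

#' Impute genetically regulated expression into a target cohort
#'
#' Matches each model's variants to the target panel by (chrom, pos, ref,
#' alt); variants present with ref/alt swapped are matched after
#' reflecting dosages (d -> 2 - d); unmatched variants are dropped and
#' the per-gene match rate recorded. GReX is the matched-dosage matrix
#' times the matched weights. Genes with zero matched variants are
#' omitted and listed.
#'
#' @param store a \code{model_store} from \code{\link{train_all}}, or a
#'   single stratum's list of \code{expression_model}s.
#' @param g_new target \code{\link{genotype_matrix}} (QC'd).
#' @param stratum which stratum's models to use when \code{store} is a
#'   full \code{model_store}.
#' @return matrix samples x genes of imputed GReX; attributes
#'   \code{"match_rate"} (named per gene) and \code{"omitted"} (genes
#'   with zero matches).
#' @export
harmonize_and_impute <- function(store, g_new, stratum = NULL) {
  models <- if (inherits(store, "model_store")) {
    if (is.null(stratum)) stop("stratum required for a full model store")
    store[[stratum]]
  } else store
  key <- paste(g_new$variants$chrom, g_new$variants$pos,
               g_new$variants$ref, g_new$variants$alt, sep = ":")
  key_sw <- paste(g_new$variants$chrom, g_new$variants$pos,
                  g_new$variants$alt, g_new$variants$ref, sep = ":")
  n <- length(g_new$samples)
  cols <- list(); rates <- c(); omitted <- character()
  for (gn in names(models)) {
    m <- models[[gn]]
    mk <- paste(m$variants$chrom, m$variants$pos, m$variants$ref,
                m$variants$alt, sep = ":")
    direct <- match(mk, key)
    flipped <- match(mk, key_sw)
    use_flip <- is.na(direct) & !is.na(flipped)
    idx <- ifelse(is.na(direct), flipped, direct)
    matched <- !is.na(idx)
    rates[gn] <- mean(matched)
    if (!any(matched)) { omitted <- c(omitted, gn); next }
    D <- g_new$dosages[, idx[matched], drop = FALSE]
    fl <- use_flip[matched]
    if (any(fl)) D[, fl] <- 2 - D[, fl]
    w <- m$weights[matched]
    cols[[gn]] <- drop(D %*% w)
  }
  grex <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), n, 0)
  if (length(cols)) rownames(grex) <- g_new$samples
  attr(grex, "match_rate") <- rates
  attr(grex, "omitted") <- omitted
  grex
}

#' External-validation R-squared (squared Spearman correlation)
#'
#' Spearman correlation between imputed and observed expression on
#' average ranks (ties averaged); EV R-squared is its square, so it is
#' invariant to any strictly monotone transform of either vector.
#'
#' @param grex numeric vector of imputed expression.
#' @param observed numeric vector of observed expression.
#' @return list(signed_rho, ev_r2); both NA (flagged) if either vector is
#'   constant or fewer than 3 pairs are available.
#' @export
ev_r2 <- function(grex, observed) {
  ok <- complete.cases(grex, observed)
  if (sum(ok) < 3) stop("need at least 3 paired values")
  if (sd(grex[ok]) < 1e-15 || sd(observed[ok]) < 1e-15)
    return(list(signed_rho = NA_real_, ev_r2 = NA_real_, flagged = TRUE))
  rho <- cor(grex[ok], observed[ok], method = "spearman")
  list(signed_rho = rho, ev_r2 = rho^2, flagged = FALSE)
}

#' Permutation test of EV R-squared
#'
#' Permutes the observed expression among samples \code{n_perm} times,
#' recomputing the null EV R-squared each time; the empirical p-value
#' uses the add-one estimator (1 + #\{null >= observed\}) / (1 + B), so
#' it is never exactly zero. The null distribution is returned for
#' confidence-interval inversion.
#'
#' @param grex,observed paired numeric vectors.
#' @param n_perm number of permutations (default 10000; fewer than 100
#'   triggers a warning about CI resolution).
#' @param seed RNG seed.
#' @return list(signed_rho, ev_r2, empirical_p, null_r2).
#' @export
permutation_validate <- function(grex, observed, n_perm = 10000, seed = 1) {
  if (n_perm < 100) warning("n_perm < 100: CI resolution will be coarse")
  obs <- ev_r2(grex, observed)
  set.seed(seed)
  n <- length(grex)
  # Spearman = Pearson on ranks; permuting observations = permuting ranks,
  # so the null can be computed by one crossproduct on standardized ranks
  rg <- drop(scale(rank(grex)))
  ro <- drop(scale(rank(observed)))
  P <- replicate(n_perm, sample.int(n))
  null_rho <- drop(crossprod(matrix(ro[P], n, n_perm), rg)) / (n - 1)
  null_r2 <- null_rho^2
  emp_p <- (1 + sum(null_r2 >= obs$ev_r2)) / (1 + n_perm)
  list(signed_rho = obs$signed_rho, ev_r2 = obs$ev_r2,
       empirical_p = emp_p, null_r2 = null_r2, null_rho = null_rho)
}

#' Storey q-values
#'
#' Estimates the null proportion \eqn{\pi_0 = \#\{p > \lambda\} /
#' (m (1 - \lambda))} at \eqn{\lambda = 0.5} (clipped to 1), then
#' computes q-values as the monotone step-up transform of
#' \eqn{\pi_0 m p_{(i)} / i}.
#'
#' @param p numeric vector of (empirical) p-values, length >= 2.
#' @param lambda tuning constant for the pi0 estimate (default 0.5).
#' @return numeric q-values in input order; attribute \code{"pi0"}.
#' @export
storey_q <- function(p, lambda = 0.5) {
  stopifnot(length(p) >= 2, all(p >= 0 & p <= 1))
  m <- length(p)
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  ord <- order(p, decreasing = TRUE)
  q <- rep(NA_real_, m)
  running <- 1
  for (i in seq_len(m)) {
    j <- ord[i]
    rank_j <- m - i + 1
    running <- min(running, pi0 * m * p[j] / rank_j)
    q[j] <- running
  }
  attr(q, "pi0") <- pi0
  q
}

#' Invert the permutation acceptance region into a confidence interval
#'
#' Translation-pivot construction on the variance-stabilized scale: the
#' permutation null of the signed Spearman correlation is mapped through
#' the Fisher z-transform and centered at its mean; its \eqn{\alpha/2}
#' and \eqn{1 - \alpha/2} quantiles give the pivot's spread, the interval
#' \eqn{[z(\hat\rho) - (q_{hi} - \bar q),\; z(\hat\rho) - (q_{lo} - \bar
#' q)]} is mapped back to the correlation scale and squared into an
#' interval for EV R-squared (an interval spanning 0 on the correlation
#' scale has R-squared lower bound 0). The z scale is used because the
#' permutation null carries the sampling spread at \eqn{\rho = 0} only;
#' Fisher's transform makes that spread (approximately) valid at any
#' \eqn{\rho}, which a pivot applied directly on the R-squared scale is
#' not. A degenerate null (all values equal) yields a point interval,
#' flagged.
#'
#' @param signed_rho the observed signed Spearman correlation.
#' @param null_rho numeric vector, the permutation null of the signed
#'   correlation (from \code{\link{permutation_validate}}).
#' @param level confidence level (default 0.90); \code{level = 0} gives a
#'   point interval.
#' @return list(lo, hi, rho_lo, rho_hi, flagged); lo/hi bound EV
#'   R-squared in [0, 1].
#' @export
invert_ci <- function(signed_rho, null_rho, level = 0.90) {
  r2 <- signed_rho^2
  if (level == 0 || sd(null_rho) < 1e-15) {
    return(list(lo = r2, hi = r2, rho_lo = signed_rho, rho_hi = signed_rho,
                flagged = sd(null_rho) < 1e-15))
  }
  clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z_obs <- atanh(clamp(signed_rho))
  z_null <- atanh(clamp(null_rho))
  alpha <- 1 - level
  q <- quantile(z_null, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  m <- mean(z_null)
  rho_lo <- tanh(z_obs - (q[2] - m))
  rho_hi <- tanh(z_obs - (q[1] - m))
  spans_zero <- rho_lo < 0 && rho_hi > 0
  lo <- if (spans_zero) 0 else min(rho_lo^2, rho_hi^2)
  hi <- max(rho_lo^2, rho_hi^2)
  list(lo = max(0, lo), hi = min(1, hi), rho_lo = rho_lo, rho_hi = rho_hi,
       flagged = FALSE)
}

#' Validation report with permutation p, q-values and inverted CIs
#'
#' Runs the full validation chain (EV R-squared, permutation empirical p,
#' Storey q across genes, 90\% inverted CI) per subgroup and overall.
#' Subgroups with fewer than 3 samples are skipped with a reason.
#' Permutations are performed within subgroup (exchangeability holds
#' within subgroup).
#'
#' @param grex samples x genes imputed matrix.
#' @param observed samples x genes observed \code{\link{expression_matrix}}
#'   or matrix with matching column names.
#' @param labels optional character vector of subgroup labels per sample;
#'   NULL gives only the overall stratum.
#' @param n_perm permutations per gene (default 10000).
#' @param level CI level (default 0.90).
#' @param seed RNG seed.
#' @return data.frame: gene, subgroup, n, signed_rho, ev_r2, empirical_p,
#'   q, ci_lo, ci_hi; skipped subgroups listed in attribute
#'   \code{"skipped"}.
#' @export
stratified_report <- function(grex, observed, labels = NULL, n_perm = 10000,
                              level = 0.90, seed = 1) {
  if (inherits(observed, "expression_matrix")) {
    obs <- observed$values
  } else obs <- as.matrix(observed)
  genes <- intersect(colnames(grex), colnames(obs))
  stopifnot(length(genes) >= 1, nrow(grex) == nrow(obs))
  groups <- list(all = seq_len(nrow(grex)))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(grex))
    for (lv in sort(unique(labels))) groups[[lv]] <- which(labels == lv)
  }
  rows <- list(); skipped <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]
    if (length(idx) < 3) {
      skipped[[gname]] <- sprintf("n = %d < 3", length(idx))
      next
    }
    sub <- lapply(seq_along(genes), function(j) {
      gx <- grex[idx, genes[j]]; ox <- obs[idx, genes[j]]
      if (sd(gx) < 1e-15 || sd(ox) < 1e-15)
        return(data.frame(gene = genes[j], subgroup = gname,
                          n = length(idx), signed_rho = NA_real_,
                          ev_r2 = NA_real_, empirical_p = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_,
                          stringsAsFactors = FALSE))
      pv <- permutation_validate(gx, ox, n_perm = n_perm,
                                 seed = seed + j)
      ci <- invert_ci(pv$signed_rho, pv$null_rho, level = level)
      data.frame(gene = genes[j], subgroup = gname, n = length(idx),
                 signed_rho = pv$signed_rho, ev_r2 = pv$ev_r2,
                 empirical_p = pv$empirical_p, ci_lo = ci$lo,
                 ci_hi = ci$hi, stringsAsFactors = FALSE)
    })
    rows[[gname]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  for (gname in unique(out$subgroup)) {
    sel <- out$subgroup == gname & !is.na(out$empirical_p)
    if (sum(sel) >= 2) out$q[sel] <- as.numeric(storey_q(out$empirical_p[sel]))
    else if (sum(sel) == 1) out$q[sel] <- out$empirical_p[sel]
  }
  out <- out[, c("gene", "subgroup", "n", "signed_rho", "ev_r2",
                 "empirical_p", "q", "ci_lo", "ci_hi")]
  attr(out, "skipped") <- skipped
  out
}
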