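# -- Cis-heritability by stratified GREML ------------------------------------

#' Build MAF/LD-stratified genetic relationship matrices for a gene
#'
#' Standardizes cis variants to mean 0, variance 1, computes a per-variant
#' LD score (sum of squared correlations with all cis variants, self
#' included), bins variants by MAF quantiles x LD-score quantiles, and
#' returns one GRM \eqn{A = ZZ'/m} per non-empty bin. Trans variants
#' never enter: heritability here is a cis quantity.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param gene one row of a gene table (id, chrom, start, end) or a list
#'   with those fields.
#' @param cis_window cis window in bp (default 500000).
#' @param n_maf_bins,n_ld_bins number of quantile bins (default 2 each).
#' @return list of GRMs; each has attributes \code{n_variants},
#'   \code{maf_bin}, \code{ld_bin}.
#' @export
build_grms <- function(g, gene, cis_window = 500000, n_maf_bins = 2,
                       n_ld_bins = 2) {
  idx <- cis_indices(g$variants, as.list(gene), cis_window)
  idx <- idx[apply(g$dosages[, idx, drop = FALSE], 2, sd) > 0]
  if (length(idx) < 2) stop("fewer than 2 polymorphic cis variants for gene ", gene$id)
  Z <- scale(g$dosages[, idx, drop = FALSE])
  af <- colMeans(g$dosages[, idx, drop = FALSE]) / 2
  maf <- pmin(af, 1 - af)
  R2 <- cor(Z)^2
  ld_score <- rowSums(R2)
  bin_of <- function(x, k) {
    if (k <= 1 || length(unique(x)) == 1) return(rep(1L, length(x)))
    br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1)))
    if (length(br) < 2) return(rep(1L, length(x)))
    as.integer(cut(x, br, include.lowest = TRUE))
  }
  mb <- bin_of(maf, n_maf_bins)
  lb <- bin_of(ld_score, n_ld_bins)
  grms <- list()
  for (i in sort(unique(mb))) for (j in sort(unique(lb))) {
    sel <- mb == i & lb == j
    if (!any(sel)) next
    Zs <- Z[, sel, drop = FALSE]
    A <- tcrossprod(Zs) / ncol(Zs)
    attr(A, "n_variants") <- ncol(Zs)
    attr(A, "maf_bin") <- i
    attr(A, "ld_bin") <- j
    grms[[length(grms) + 1L]] <- A
  }
  grms
}

# Restricted log-likelihood for y ~ intercept with V = sum(s_k A_k) + s_e I.
reml_loglik <- function(y, grms, sigmas, sigma_e) {
  n <- length(y)
  V <- diag(sigma_e, n)
  for (k in seq_along(grms)) V <- V + sigmas[k] * grms[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Viy <- backsolve(ch, forwardsolve(t(ch), y))
  xvx <- sum(Vi1)
  Py <- Viy - Vi1 * (sum(Vi1 * y) / xvx)
  -0.5 * (logdetV + log(xvx) + sum(y * Py))
}

#' Multi-component REML (GREML) fit of cis-heritability
#'
#' Jointly fits one variance component per GRM plus a residual by average
#' information (AI) REML with an EM-REML fallback for steps that leave
#' the parameter space or decrease the restricted likelihood. Components
#' are constrained non-negative. Convergence is declared when the change
#' in restricted log-likelihood falls below \code{tol} (default 1e-6) or
#' after \code{max_iter} iterations; non-convergence is flagged, never
#' silent. h2 = (sum of genetic components) / (total variance); its
#' standard error comes from the inverse AI matrix by the delta method.
#'
#' @param y numeric response vector (residualized expression).
#' @param grms list of GRMs from \code{\link{build_grms}}.
#' @param max_iter iteration cap (default 100).
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @param method \code{"auto"} uses an eigen-rotated O(n)-per-iteration
#'   path for a single GRM and the dense path otherwise; \code{"dense"}
#'   forces the dense path (same updates, same results).
#' @return An object of class \code{herit_fit}: gene-free list with h2,
#'   se, components, sigma_e, loglik, null_loglik, lrt_stat, p,
#'   converged, n_strata.
#' @export
reml_fit <- function(y, grms, max_iter = 100, tol = 1e-6,
                     method = c("auto", "dense")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(n > 2, length(grms) >= 1)
  for (A in grms) stopifnot(nrow(A) == n, ncol(A) == n)
  K <- length(grms)
  if (K == 1L && method == "auto")
    return(reml_fit_1grm(y, grms[[1]], max_iter, tol))
  vy <- var(y)
  theta <- c(rep(vy / (K + 1), K), vy / (K + 1) * 1)
  theta[K + 1] <- vy * 0.5
  theta[seq_len(K)] <- vy * 0.5 / K
  ll_old <- reml_loglik(y, grms, theta[seq_len(K)], theta[K + 1])
  converged <- FALSE
  AIinv <- NULL
  floor_v <- vy * 1e-8
  for (it in seq_len(max_iter)) {
    V <- diag(theta[K + 1], n)
    for (k in seq_len(K)) V <- V + theta[k] * grms[[k]]
    ch <- chol(V)
    Vinv <- chol2inv(ch)
    Vi1 <- Vinv %*% rep(1, n)
    xvx <- sum(Vi1)
    P <- Vinv - tcrossprod(Vi1) / xvx
    Py <- drop(P %*% y)
    mats <- c(grms, list(diag(1, n)))
    APy <- lapply(mats, function(A) drop(A %*% Py))
    grad <- vapply(seq_len(K + 1), function(k)
      -0.5 * (sum(P * mats[[k]]) - sum(Py * APy[[k]])), numeric(1))
    PAPy <- lapply(APy, function(v) drop(P %*% v))
    AI <- matrix(0, K + 1, K + 1)
    for (a in seq_len(K + 1)) for (b in a:(K + 1)) {
      AI[a, b] <- AI[b, a] <- 0.5 * sum(APy[[a]] * PAPy[[b]])
    }
    # active-set AI step: components pinned at the zero floor with a
    # negative gradient stay fixed; others move by the Newton-like step,
    # halved until the restricted likelihood does not decrease
    active <- theta > floor_v * 2 | grad > 0
    active[K + 1] <- TRUE
    accepted <- FALSE
    if (sum(active) > 0) {
      step_full <- rep(0, K + 1)
      sub <- tryCatch(solve(AI[active, active, drop = FALSE] +
                              diag(1e-10, sum(active)), grad[active]),
                      error = function(e) NULL)
      if (!is.null(sub)) {
        step_full[active] <- sub
        fac <- 1
        for (half in 1:12) {
          prop <- pmax(theta + fac * step_full, floor_v)
          ll_try <- reml_loglik(y, grms, prop[seq_len(K)], prop[K + 1])
          if (is.finite(ll_try) && ll_try >= ll_old - 1e-12) {
            theta <- prop; ll_new <- ll_try; accepted <- TRUE
            break
          }
          fac <- fac / 2
        }
      }
    }
    if (!accepted) {
      # EM-REML fallback step (guaranteed ascent)
      theta_em <- vapply(seq_len(K + 1), function(k)
        (theta[k]^2 * sum(Py * APy[[k]]) + theta[k] * n -
           theta[k]^2 * sum(P * mats[[k]])) / n, numeric(1))
      theta <- pmax(theta_em, floor_v)
      ll_new <- reml_loglik(y, grms, theta[seq_len(K)], theta[K + 1])
    }
    AIinv <- tryCatch(solve(AI), error = function(e) NULL)
    if (is.finite(ll_new) && abs(ll_new - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  sg <- theta[seq_len(K)]
  se2 <- theta[K + 1]
  total <- sum(sg) + se2
  h2 <- min(max(sum(sg) / total, 0), 1)
  h2_se <- NA_real_
  if (!is.null(AIinv)) {
    d <- c(rep(se2 / total^2, K), -sum(sg) / total^2)
    h2_se <- sqrt(max(drop(t(d) %*% AIinv %*% d), 0))
  }
  null_ll <- reml_null_loglik(y)
  lrt <- max(2 * (ll_old - null_ll), 0)
  structure(list(h2 = h2, se = h2_se, components = sg, sigma_e = se2,
                 loglik = ll_old, null_loglik = null_ll,
                 lrt_stat = lrt, p = lrt_h2(lrt),
                 converged = converged, n_strata = K, n = n),
            class = "herit_fit")
}

# Single-GRM AI-REML in the GRM eigenbasis: V is diagonal after rotation,
# so every iteration is O(n). Same updates (AI step with halving, EM
# fallback, non-negativity floor) and same results as the dense path.
reml_fit_1grm <- function(y, A, max_iter = 100, tol = 1e-6) {
  n <- length(y)
  ed <- eigen(A, symmetric = TRUE)
  d <- pmax(ed$values, 0)
  yt <- drop(crossprod(ed$vectors, y))
  ot <- drop(crossprod(ed$vectors, rep(1, n)))
  vy <- var(y)
  floor_v <- vy * 1e-8
  theta <- c(vy * 0.5, vy * 0.5)   # (sigma_g^2, sigma_e^2)
  ll_fun <- function(th) {
    v <- th[1] * d + th[2]
    if (any(v <= 0)) return(-Inf)
    xvx <- sum(ot^2 / v)
    bhat <- sum(ot * yt / v) / xvx
    r <- yt - ot * bhat
    -0.5 * (sum(log(v)) + log(xvx) + sum(r^2 / v))
  }
  ll_old <- ll_fun(theta)
  converged <- FALSE
  AIinv <- NULL
  for (it in seq_len(max_iter)) {
    v <- theta[1] * d + theta[2]
    vinv <- 1 / v
    xvx <- sum(ot^2 * vinv)
    # Py in the rotated basis
    py <- vinv * yt - vinv * ot * (sum(ot * vinv * yt) / xvx)
    papply <- function(x) vinv * x - vinv * ot * (sum(ot * vinv * x) / xvx)
    tr_P_of <- function(dd)   # tr(P * diag(dd) in rotated space)
      sum(dd * vinv) - sum(dd * vinv^2 * ot^2) / xvx
    APy <- list(d * py, py)
    grad <- c(-0.5 * (tr_P_of(d) - sum(py * APy[[1]])),
              -0.5 * (tr_P_of(rep(1, n)) - sum(py * APy[[2]])))
    PAPy <- lapply(APy, papply)
    AI <- matrix(0, 2, 2)
    for (a in 1:2) for (b in a:2)
      AI[a, b] <- AI[b, a] <- 0.5 * sum(APy[[a]] * PAPy[[b]])
    active <- theta > floor_v * 2 | grad > 0
    active[2] <- TRUE
    accepted <- FALSE
    sub <- tryCatch(solve(AI[active, active, drop = FALSE] +
                            diag(1e-10, sum(active)), grad[active]),
                    error = function(e) NULL)
    if (!is.null(sub)) {
      step_full <- c(0, 0); step_full[active] <- sub
      fac <- 1
      for (half in 1:12) {
        prop <- pmax(theta + fac * step_full, floor_v)
        ll_try <- ll_fun(prop)
        if (is.finite(ll_try) && ll_try >= ll_old - 1e-12) {
          theta <- prop; ll_new <- ll_try; accepted <- TRUE
          break
        }
        fac <- fac / 2
      }
    }
    if (!accepted) {
      theta_em <- c(
        (theta[1]^2 * sum(py * APy[[1]]) + theta[1] * n -
           theta[1]^2 * tr_P_of(d)) / n,
        (theta[2]^2 * sum(py * APy[[2]]) + theta[2] * n -
           theta[2]^2 * tr_P_of(rep(1, n))) / n)
      theta <- pmax(theta_em, floor_v)
      ll_new <- ll_fun(theta)
    }
    AIinv <- tryCatch(solve(AI), error = function(e) NULL)
    if (is.finite(ll_new) && abs(ll_new - ll_old) < tol) {
      converged <- TRUE; ll_old <- ll_new
      break
    }
    ll_old <- ll_new
  }
  total <- sum(theta)
  h2 <- min(max(theta[1] / total, 0), 1)
  h2_se <- NA_real_
  if (!is.null(AIinv)) {
    dd <- c(theta[2] / total^2, -theta[1] / total^2)
    h2_se <- sqrt(max(drop(t(dd) %*% AIinv %*% dd), 0))
  }
  null_ll <- reml_null_loglik(y)
  lrt <- max(2 * (ll_old - null_ll), 0)
  structure(list(h2 = h2, se = h2_se, components = theta[1],
                 sigma_e = theta[2], loglik = ll_old, null_loglik = null_ll,
                 lrt_stat = lrt, p = lrt_h2(lrt), converged = converged,
                 n_strata = 1L, n = n),
            class = "herit_fit")
}

# Closed-form restricted log-likelihood of the intercept-only null model.
reml_null_loglik <- function(y) {
  n <- length(y)
  s2 <- sum((y - mean(y))^2) / (n - 1)
  -0.5 * ((n - 1) * log(s2) + log(n) + (n - 1))
}

#' @export
print.herit_fit <- function(x, ...) {
  cat(sprintf("herit_fit: h2 = %.4f (se %.4f), LRT = %.3f, p = %.4g, %s\n",
              x$h2, x$se, x$lrt_stat, x$p,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Boundary likelihood-ratio p-value for h2 > 0
#'
#' The null (all genetic components zero) lies on the boundary of the
#' parameter space, so the LRT statistic is referred to the mixture
#' 0.5 chi-squared(0) + 0.5 chi-squared(1): p = 0.5 P(chi2_1 > LRT),
#' which equals 0.5 at LRT = 0. Negative statistics (numerical) are
#' clipped to 0.
#'
#' @param lrt_stat likelihood-ratio statistic (2 * delta log-likelihood).
#' @return p-value in [0, 1].
#' @export
lrt_h2 <- function(lrt_stat) {
  0.5 * pchisq(pmax(lrt_stat, 0), df = 1, lower.tail = FALSE)
}

#' Estimate cis-heritability for every gene of a panel
#'
#' Runs \code{\link{build_grms}} + \code{\link{reml_fit}} per gene on
#' residualized expression.
#'
#' @param e residualized \code{\link{expression_matrix}}.
#' @param g a \code{\link{genotype_matrix}} (same samples).
#' @param cis_window cis window in bp.
#' @param n_maf_bins,n_ld_bins GRM stratification (default 2 x 2).
#' @return data.frame: gene, h2, se, lrt, p, n_variants, converged.
#' @export
estimate_heritability <- function(e, g, cis_window = 500000,
                                  n_maf_bins = 2, n_ld_bins = 2) {
  al <- align_samples(e$samples, g$samples)
  rows <- lapply(seq_len(ncol(e$values)), function(j) {
    gene <- e$genes[j, ]
    res <- tryCatch({
      grms <- build_grms(
        genotype_matrix(g$dosages[al$b, , drop = FALSE], g$variants,
                        samples = g$samples[al$b], stratum = g$stratum),
        gene, cis_window, n_maf_bins, n_ld_bins)
      list(fit = reml_fit(e$values[al$a, j], grms),
           m = sum(vapply(grms, function(A) attr(A, "n_variants"), integer(1))))
    }, error = function(err) NULL)
    if (is.null(res))
      return(data.frame(gene = gene$id, h2 = NA_real_, se = NA_real_,
                        lrt = NA_real_, p = NA_real_, n_variants = 0L,
                        converged = FALSE, stringsAsFactors = FALSE))
    fit <- res$fit
    data.frame(gene = gene$id, h2 = fit$h2, se = fit$se, lrt = fit$lrt_stat,
               p = fit$p, n_variants = res$m,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select genes with nominally significant cis-heritability
#'
#' @param estimates data.frame from \code{\link{estimate_heritability}}.
#' @param p_max nominal p-value threshold (default 0.10).
#' @return character vector of gene IDs with p < p_max, in input order.
#' @export
select_heritable_genes <- function(estimates, p_max = 0.10) {
  estimates$gene[!is.na(estimates$p) & estimates$p < p_max]
}
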