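# -- Genotype QC -------------------------------------------------------------

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Exact conditional test on genotype counts, enumerating all heterozygote
#' counts compatible with the observed allele counts (the standard
#' biallelic exact test used by PLINK). With \code{midp = TRUE} the
#' observed outcome contributes half its probability (mid-p correction).
#'
#' @param n_het observed heterozygote count.
#' @param n_hom1,n_hom2 observed homozygote counts.
#' @param midp logical, apply the mid-p correction.
#' @return two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_het, n_hom1, n_hom2, midp = TRUE) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  # possible heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized log-probabilities of each heterozygote count
  logp <- vapply(hets, function(h) {
    r_hom <- (n_rare - h) / 2
    c_hom <- n - h - r_hom
    lfactorial(n) - lfactorial(h) - lfactorial(r_hom) - lfactorial(c_hom) +
      h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  if (length(obs) == 0L) stop("observed genotype counts inconsistent with allele counts")
  pv <- sum(p[p <= p[obs] * (1 + 1e-12)])
  if (midp) pv <- pv - p[obs] / 2
  min(1, max(pv, 0))
}

#' Variant quality-control filter
#'
#' Removes variants with dosage-based minor allele frequency below
#' \code{maf_min} and variants whose rounded hard calls deviate from
#' Hardy-Weinberg equilibrium at an exact-test p-value below
#' \code{hwe_p_min}. Each exclusion is recorded with its reason.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min HWE exact-test p-value threshold (default 1e-8).
#' @return The filtered \code{genotype_matrix}; the exclusion report (a
#'   data.frame with columns id, reason, value) is attached as attribute
#'   \code{"exclusions"}.
#' @export
qc_filter <- function(g, maf_min = 0.01, hwe_p_min = 1e-8) {
  stopifnot(inherits(g, "genotype_matrix"))
  af <- colMeans(g$dosages) / 2
  maf <- pmin(af, 1 - af)
  hard <- round(g$dosages)
  hard[hard < 0] <- 0; hard[hard > 2] <- 2
  hwe_p <- vapply(seq_len(ncol(hard)), function(j) {
    tab <- tabulate(hard[, j] + 1L, nbins = 3L)
    hwe_exact_test(tab[2L], tab[1L], tab[3L])
  }, numeric(1))
  fail_maf <- maf < maf_min
  fail_hwe <- !fail_maf & hwe_p < hwe_p_min
  excl <- rbind(
    data.frame(id = g$variants$id[fail_maf],
               reason = rep("maf", sum(fail_maf)),
               value = unname(maf[fail_maf]), stringsAsFactors = FALSE),
    data.frame(id = g$variants$id[fail_hwe],
               reason = rep("hwe", sum(fail_hwe)),
               value = unname(hwe_p[fail_hwe]), stringsAsFactors = FALSE))
  keep <- !(fail_maf | fail_hwe)
  if (!any(keep)) stop("all variants removed by QC: empty panel")
  out <- genotype_matrix(g$dosages[, keep, drop = FALSE],
                         g$variants[keep, , drop = FALSE],
                         samples = g$samples, stratum = g$stratum)
  attr(out, "exclusions") <- excl
  out
}

#' Intersect two genotype panels on shared variants
#'
#' Variants are keyed by (chrom, pos, ref, alt). A variant present in both
#' panels with ref and alt swapped is matched after reflecting the second
#' panel's dosages (d -> 2 - d); such harmonizations are listed in the
#' attached report. Variant order of the first panel is preserved.
#'
#' @param a,b QC'd \code{\link{genotype_matrix}} objects.
#' @return list with elements \code{a} and \code{b} restricted to the
#'   shared variants, plus a \code{report} data.frame of allele flips.
#' @export
intersect_panels <- function(a, b) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  swapped_key <- function(v) paste(v$chrom, v$pos, v$alt, v$ref, sep = ":")
  ka <- key(a$variants); kb <- key(b$variants); kb_sw <- swapped_key(b$variants)
  direct <- match(ka, kb)
  flipped <- match(ka, kb_sw)
  use_flip <- is.na(direct) & !is.na(flipped)
  idx_b <- ifelse(is.na(direct), flipped, direct)
  keep <- !is.na(idx_b)
  if (!any(keep)) stop("no shared variants between panels")
  ia <- which(keep); ib <- idx_b[keep]
  dos_b <- b$dosages[, ib, drop = FALSE]
  flip_cols <- use_flip[keep]
  if (any(flip_cols)) dos_b[, flip_cols] <- 2 - dos_b[, flip_cols]
  # panel b adopts panel a's allele orientation and variant metadata keys
  var_b <- b$variants[ib, , drop = FALSE]
  var_b$ref[flip_cols] <- a$variants$ref[ia][flip_cols]
  var_b$alt[flip_cols] <- a$variants$alt[ia][flip_cols]
  out_a <- genotype_matrix(a$dosages[, ia, drop = FALSE],
                           a$variants[ia, , drop = FALSE],
                           samples = a$samples, stratum = a$stratum)
  out_b <- genotype_matrix(dos_b, var_b, samples = b$samples, stratum = b$stratum)
  report <- data.frame(id = a$variants$id[ia][flip_cols],
                       note = rep("ref/alt swapped in panel b; dosages reflected",
                                  sum(flip_cols)),
                       stringsAsFactors = FALSE)
  list(a = out_a, b = out_b, report = report)
}

# -- Expression normalization ------------------------------------------------

#' Normalize an expression matrix
#'
#' Applies (1) per-sample upper-quartile scaling to the mean upper
#' quartile across samples, (2) a log2(x + 1) variance-stabilizing
#' transform, and (3) removal of \code{k_unwanted} dimensions of unwanted
#' variation estimated by singular decomposition of the centered
#' control-gene submatrix and regressed out of every gene (an RUVg-style
#' correction using housekeeping-type control genes).
#'
#' @param e an \code{\link{expression_matrix}} of non-negative raw values.
#' @param control_genes character IDs of control (housekeeping) genes.
#' @param k_unwanted number of unwanted-variation factors to remove
#'   (default 2; 0 skips the control-gene step).
#' @return A normalized \code{\link{expression_matrix}}.
#' @export
normalize_expression <- function(e, control_genes = character(), k_unwanted = 2) {
  stopifnot(inherits(e, "expression_matrix"))
  if (any(e$values < 0)) stop("raw expression values must be non-negative")
  if (k_unwanted > 0 && length(control_genes) == 0L)
    stop("control gene list is empty but k_unwanted > 0")
  uq <- apply(e$values, 1, quantile, probs = 0.75, names = FALSE)
  if (any(uq <= 0)) stop("sample(s) with non-positive upper quartile")
  scaled <- e$values * (mean(uq) / uq)
  vst <- log2(scaled + 1)
  if (k_unwanted > 0) {
    ctrl_idx <- match(control_genes, e$genes$id)
    if (anyNA(ctrl_idx)) stop("control gene(s) absent from expression matrix: ",
                              paste(control_genes[is.na(ctrl_idx)], collapse = ", "))
    ctrl <- scale(vst[, ctrl_idx, drop = FALSE], center = TRUE, scale = FALSE)
    k <- min(k_unwanted, ncol(ctrl), nrow(ctrl) - 1L)
    W <- svd(ctrl, nu = k, nv = 0)$u
    vst <- residualize_matrix(vst, cbind(1, W)) +
      rep(colMeans(vst), each = nrow(vst))
  }
  expression_matrix(vst, e$genes, samples = e$samples)
}

#' Flag expression outlier samples on principal-component scores
#'
#' Computes robust Mahalanobis distances of samples on the top two
#' principal-component scores (robust location/scatter via MVE) and flags
#' samples beyond the upper-\code{alpha} quantile of a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param e a normalized \code{\link{expression_matrix}}.
#' @param alpha flagging level (default 0.01); \code{alpha = 0} flags
#'   nothing.
#' @return logical vector of flags, named by sample.
#' @export
flag_expression_outliers <- function(e, alpha = 0.01) {
  stopifnot(inherits(e, "expression_matrix"))
  n <- nrow(e$values)
  if (n < 10) stop("need at least 10 samples for outlier statistics")
  pc <- prcomp(e$values, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  rob <- MASS::cov.rob(pc)
  d2 <- mahalanobis(pc, rob$center, rob$cov)
  flags <- d2 > qchisq(1 - alpha, df = 2)
  names(flags) <- e$samples
  flags
}

#' Residualize expression on covariates
#'
#' Per-gene ordinary-least-squares residuals with an intercept always
#' included. Constant or collinear covariates are dropped with a warning.
#'
#' @param e an \code{\link{expression_matrix}}.
#' @param covariates data.frame of numeric covariates, rows aligned to
#'   \code{e$samples} (or containing a \code{sample} column to join on).
#' @return An \code{\link{expression_matrix}} of residuals.
#' @export
residualize <- function(e, covariates = NULL) {
  stopifnot(inherits(e, "expression_matrix"))
  covariates <- align_covariates(covariates, e$samples)
  X <- covariate_design(covariates, n = nrow(e$values))
  res <- residualize_matrix(e$values, X)
  expression_matrix(res, e$genes, samples = e$samples)
}

# Reorder a covariate data.frame to a sample-ID vector; a "sample" column,
# if present, is used as the join key and removed.
align_covariates <- function(covariates, samples) {
  if (is.null(covariates)) return(NULL)
  if ("sample" %in% names(covariates)) {
    idx <- match(samples, covariates$sample)
    if (anyNA(idx)) stop("covariate table missing sample(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    covariates <- covariates[idx, setdiff(names(covariates), "sample"),
                             drop = FALSE]
  } else if (nrow(covariates) != length(samples)) {
    stop("covariate rows do not match samples and no 'sample' column to join on")
  }
  covariates
}
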