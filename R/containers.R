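#' @importFrom stats coef cor cor.test lm model.matrix p.adjust pchisq pnorm
#'   pt qchisq qnorm quantile rbeta rbinom rexp rnorm runif sd var median
#'   complete.cases setNames mahalanobis prcomp cov rgamma fisher.test
#'   ks.test optimize
#' @importFrom utils head tail
NULL

#' Genotype dosage matrix with variant metadata
#'
#' Container for a samples x variants matrix of allelic dosages in
#' \code{[0, 2]} together with per-variant metadata (id, chrom, pos, ref,
#' alt) and an optional stratum label. Dosages may be fractional
#' (imputation posterior mean dosages are kept as-is, never rounded).
#'
#' @param dosages numeric matrix, samples x variants, entries in \code{[0,2]}.
#' @param variants data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt}; one row per column of
#'   \code{dosages}.
#' @param samples character vector of sample IDs (defaults to rownames).
#' @param stratum optional single label (e.g. an ancestry stratum).
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosages, variants, samples = rownames(dosages),
                            stratum = NA_character_) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(dosages),
            length(samples) == nrow(dosages))
  if (anyDuplicated(variants$id))
    stop("variant IDs must be unique")
  if (anyDuplicated(samples))
    stop("sample IDs must be unique")
  # positions non-decreasing within chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) stop("variant positions must be non-decreasing within chromosome")
  }
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants, stringsAsFactors = FALSE),
                 samples = samples,
                 stratum = stratum),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (stratum: %s)\n",
              length(x$samples), nrow(x$variants),
              ifelse(is.na(x$stratum), "-", x$stratum)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Expression matrix with gene coordinates
#'
#' Samples x genes continuous expression values with per-gene genomic
#' coordinates (1-based, inclusive).
#'
#' @param values numeric matrix, samples x genes.
#' @param genes data.frame with columns \code{id}, \code{chrom},
#'   \code{start}, \code{end}; one row per column of \code{values}.
#' @param samples character sample IDs.
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, genes, samples = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(values)))
  stopifnot(is.data.frame(genes),
            all(c("id", "chrom", "start", "end") %in% names(genes)),
            nrow(genes) == ncol(values),
            length(samples) == nrow(values))
  rownames(values) <- samples
  colnames(values) <- genes$id
  structure(list(values = values,
                 genes = as.data.frame(genes, stringsAsFactors = FALSE),
                 samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d samples x %d genes\n",
              length(x$samples), nrow(x$genes)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Align two sample-indexed objects by shared sample IDs, preserving the
# order of the first. Errors if no overlap.
align_samples <- function(ids_a, ids_b) {
  shared <- intersect(ids_a, ids_b)
  if (length(shared) == 0L) stop("no shared samples between objects")
  list(a = match(shared, ids_a), b = match(shared, ids_b), ids = shared)
}

# Build a numeric design matrix from a covariate data.frame: constant
# columns are dropped with a warning, later-listed collinear columns are
# dropped with a warning (deterministic order), an intercept is prepended.
covariate_design <- function(covariates, n = NULL, warn = TRUE) {
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0L)) {
    stopifnot(!is.null(n))
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  cm <- as.matrix(as.data.frame(lapply(covariates, as.numeric)))
  keep <- apply(cm, 2, function(v) sd(v) > 0)
  if (any(!keep) && warn)
    warning("dropping constant covariate(s): ",
            paste(colnames(cm)[!keep], collapse = ", "))
  cm <- cm[, keep, drop = FALSE]
  X <- cbind("(Intercept)" = 1, cm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- sort(setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)]))
    if (warn)
      warning("dropping collinear covariate(s): ",
              paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
  }
  X
}

# Residualize the columns of a matrix on a design matrix via QR.
residualize_matrix <- function(M, X) {
  M <- as.matrix(M)
  qrX <- qr(X)
  M - qr.fitted(qrX, M)
}
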