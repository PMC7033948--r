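# -- Stratified cis/trans eQTL mapping ---------------------------------------

#' Covariate-adjusted cis/trans eQTL scan
#'
#' Fits, for every (gene, variant) pair, the additive model
#' \eqn{E_g = X_s \beta_s + X_C \beta_C + \epsilon} and reports the Wald
#' test of \eqn{H_0: \beta_s = 0}. Computation residualizes both
#' expression and dosages on the covariate design (with intercept), which
#' by the Frisch-Waugh theorem reproduces the joint-model estimate
#' exactly; degrees of freedom account for all fitted coefficients. A
#' variant is labeled cis when its position is within \code{cis_window}
#' of either gene end, trans otherwise — a pure function of coordinates.
#'
#' @param e an \code{\link{expression_matrix}}.
#' @param g a \code{\link{genotype_matrix}}.
#' @param covariates data.frame of adjustment covariates (optionally with
#'   a \code{sample} column to join on), or NULL.
#' @param cis_window cis distance threshold in bp (default 500000).
#' @param subtypes optional named character vector of molecular-subtype
#'   labels per sample; samples whose label is in
#'   \code{exclude_subtypes} are dropped before fitting.
#' @param exclude_subtypes subtype labels to exclude (default
#'   \code{"Normal-like"}, excluded for low tumor content).
#' @return data.frame of EqtlRecords: gene, variant, chrom, pos, ref,
#'   alt, beta, se, t, p, type.
#' @export
scan_eqtl <- function(e, g, covariates = NULL, cis_window = 500000,
                      subtypes = NULL, exclude_subtypes = "Normal-like") {
  stopifnot(inherits(e, "expression_matrix"), inherits(g, "genotype_matrix"))
  al <- align_samples(e$samples, g$samples)
  ids <- al$ids
  if (!is.null(subtypes)) {
    drop <- names(subtypes)[subtypes %in% exclude_subtypes]
    keep <- !(ids %in% drop)
    al$a <- al$a[keep]; al$b <- al$b[keep]; ids <- ids[keep]
  }
  E <- e$values[al$a, , drop = FALSE]
  G <- g$dosages[al$b, , drop = FALSE]
  covariates <- align_covariates(covariates, ids)
  X <- covariate_design(covariates, n = length(ids))
  n <- length(ids)
  if (n < ncol(X) + 2) stop("fewer samples than covariates + 2")
  Er <- residualize_matrix(E, X)
  Gr <- residualize_matrix(G, X)
  gss <- colSums(Gr^2)
  ess <- colSums(Er^2)
  ok <- gss > 1e-12
  cross <- crossprod(Gr[, ok, drop = FALSE], Er)      # variants x genes
  beta <- cross / gss[ok]
  df <- n - ncol(X) - 1L
  rss <- pmax(outer(rep(1, sum(ok)), ess) - beta * cross, 0)
  se <- sqrt(rss / df / gss[ok])
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  vi <- which(ok)
  out <- data.frame(
    gene = rep(e$genes$id, each = length(vi)),
    variant = rep(g$variants$id[vi], times = ncol(E)),
    chrom = rep(g$variants$chrom[vi], times = ncol(E)),
    pos = rep(g$variants$pos[vi], times = ncol(E)),
    ref = rep(g$variants$ref[vi], times = ncol(E)),
    alt = rep(g$variants$alt[vi], times = ncol(E)),
    beta = as.vector(beta), se = as.vector(se),
    t = as.vector(tstat), p = as.vector(pval),
    stringsAsFactors = FALSE)
  gi <- rep(seq_len(ncol(E)), each = length(vi))
  same_chr <- out$chrom == e$genes$chrom[gi]
  in_win <- out$pos >= e$genes$start[gi] - cis_window &
    out$pos <= e$genes$end[gi] + cis_window
  out$type <- ifelse(same_chr & in_win, "cis", "trans")
  out
}

#' Hierarchical (Benjamini-Bogomolov) FDR control over gene families
#'
#' Two-stage procedure: (1) a gene-level p-value is formed for each gene
#' by Simes combination over all of that gene's variant p-values, and
#' genes are selected by Benjamini-Hochberg at \code{level}; (2) within
#' each selected gene, variant p-values are BH-adjusted and scaled by
#' (total genes / selected genes). The resulting adjusted p-value is the
#' \code{bbfdr} column: an eGene is a selected family, an eSNP any record
#' with \code{bbfdr < level} inside an eGene.
#'
#' @param records data.frame from \code{\link{scan_eqtl}} (needs columns
#'   gene, p).
#' @param level target FDR (default 0.05).
#' @return The records with added columns \code{bbfdr}, \code{is_egene},
#'   \code{is_esnp}; the gene-level table (gene, simes_p, gene_adj_p,
#'   selected) is attached as attribute \code{"genes"}.
#' @export
hierarchical_fdr <- function(records, level = 0.05) {
  stopifnot(all(c("gene", "p") %in% names(records)))
  genes <- unique(records$gene)
  simes <- vapply(genes, function(gn) {
    p <- sort(records$p[records$gene == gn])
    min(length(p) * p / seq_along(p))
  }, numeric(1))
  simes <- pmin(simes, 1)
  gene_adj <- p.adjust(simes, method = "BH")
  selected <- gene_adj < level
  G <- length(genes); R <- sum(selected)
  gene_tab <- data.frame(gene = genes, simes_p = simes, gene_adj_p = gene_adj,
                         selected = selected, stringsAsFactors = FALSE)
  records$bbfdr <- NA_real_
  records$is_egene <- records$gene %in% genes[selected]
  for (gn in genes) {
    idx <- which(records$gene == gn)
    within_adj <- p.adjust(records$p[idx], method = "BH")
    records$bbfdr[idx] <- pmin(1, within_adj * G / max(R, 1L))
  }
  records$is_esnp <- records$is_egene & records$bbfdr < level
  attr(records, "genes") <- gene_tab
  records
}

#' Local-ancestry adjustment of a cis-eQTL effect
#'
#' Residualizes expression \code{e_g}, SNP dosage \code{s} and local
#' ancestry dosage \code{l} each on the covariate design, scales all
#' three to zero mean and unit variance, and fits the joint model
#' \eqn{\tilde g = \tilde s + \tilde l + \epsilon}. Both the unadjusted
#' effect (from \eqn{\tilde g \sim \tilde s}) and the ancestry-adjusted
#' effect are reported.
#'
#' @param e_g numeric expression vector for one gene.
#' @param s numeric dosage vector for one SNP.
#' @param l local-ancestry dosage vector in [0, 2] at that SNP.
#' @param covariates data.frame of covariates or NULL.
#' @return one-row data.frame: beta_unadjusted, beta_ancestry_adjusted,
#'   p_unadjusted, p_adjusted, flagged (TRUE when \code{s} or \code{l}
#'   has no variance after residualization; no fit is attempted then).
#' @export
adjust_local_ancestry <- function(e_g, s, l, covariates = NULL) {
  n <- length(e_g)
  stopifnot(length(s) == n, length(l) == n)
  X <- covariate_design(align_covariates(covariates, seq_len(n)), n = n)
  rs <- function(v) drop(residualize_matrix(matrix(v), X))
  gt <- rs(e_g); st <- rs(s); lt <- rs(l)
  if (sd(st) < 1e-12 || sd(lt) < 1e-12 || sd(gt) < 1e-12)
    return(data.frame(beta_unadjusted = NA_real_,
                      beta_ancestry_adjusted = NA_real_,
                      p_unadjusted = NA_real_, p_adjusted = NA_real_,
                      flagged = TRUE))
  gt <- drop(scale(gt)); st <- drop(scale(st)); lt <- drop(scale(lt))
  f1 <- summary(lm(gt ~ st))$coefficients
  f2 <- summary(lm(gt ~ st + lt))$coefficients
  data.frame(beta_unadjusted = f1["st", "Estimate"],
             beta_ancestry_adjusted = f2["st", "Estimate"],
             p_unadjusted = f1["st", "Pr(>|t|)"],
             p_adjusted = f2["st", "Pr(>|t|)"],
             flagged = FALSE)
}

#' Functional enrichment of eSNPs near annotation intervals
#'
#' Counts eSNPs falling within \code{window} bp of any annotation
#' interval, estimates the expected count by drawing \code{n_reps} random
#' variant sets of equal size from the tested background, and compares
#' observed and mean-expected counts with Fisher's exact test.
#'
#' @param esnps data.frame with columns chrom, pos of significant eSNPs.
#' @param annotations data.frame with columns chrom, start, end (1-based
#'   inclusive, as from \code{\link{read_bed}}).
#' @param background data.frame with columns chrom, pos of all tested
#'   variants (the resampling universe).
#' @param window flanking distance in bp (default 1000).
#' @param n_reps resampling replicates (default 10000).
#' @param seed RNG seed.
#' @return list: observed, expected_mean, odds_ratio, ci95, p,
#'   degenerate (TRUE when the 2x2 table has an empty margin and the odds
#'   ratio is reported as infinite or zero).
#' @export
enrichment_test <- function(esnps, annotations, background, window = 1000,
                            n_reps = 10000, seed = 1) {
  if (nrow(annotations) == 0) stop("empty annotation set")
  if (window < 0) stop("window must be non-negative")
  set.seed(seed)
  ann <- GenomicRanges::GRanges(annotations$chrom,
                                IRanges::IRanges(pmax(1, annotations$start - window),
                                                 annotations$end + window))
  hit <- function(df) {
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1))
    sum(IRanges::overlapsAny(gr, ann))
  }
  n_set <- nrow(esnps)
  observed <- hit(esnps)
  bg_gr <- GenomicRanges::GRanges(background$chrom,
                                  IRanges::IRanges(background$pos, width = 1))
  bg_in <- IRanges::overlapsAny(bg_gr, ann)
  exp_counts <- vapply(seq_len(n_reps), function(i)
    sum(bg_in[sample.int(length(bg_in), n_set)]), numeric(1))
  expected <- mean(exp_counts)
  tab <- matrix(c(observed, n_set - observed,
                  round(expected), n_set - round(expected)), 2, byrow = TRUE)
  ft <- fisher.test(tab)
  degenerate <- !is.finite(ft$estimate) || ft$estimate == 0
  list(observed = observed, expected_mean = expected,
       odds_ratio = unname(ft$estimate), ci95 = unname(ft$conf.int),
       p = ft$p.value, degenerate = degenerate)
}
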