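# -- Germline expression models ----------------------------------------------

#' Assemble the feature variant set for a gene
#'
#' The feature set is all cis variants (within \code{cis_window} of
#' either gene end) plus any trans-eQTL variants for that gene with
#' hierarchically adjusted p-value below \code{trans_bbfdr}.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param gene gene record (id, chrom, start, end).
#' @param eqtl_results optional data.frame from
#'   \code{\link{hierarchical_fdr}} supplying trans records (columns
#'   gene, variant, type, bbfdr); NULL means cis-only.
#' @param cis_window cis window in bp (default 500000).
#' @param trans_bbfdr inclusion threshold for trans variants (default
#'   0.01).
#' @return A \code{\link{genotype_matrix}} restricted to the feature set,
#'   or NULL (with a message) when the set is empty.
#' @export
build_feature_matrix <- function(g, gene, eqtl_results = NULL,
                                 cis_window = 500000, trans_bbfdr = 0.01) {
  gene <- as.list(gene)
  idx <- cis_indices(g$variants, gene, cis_window)
  if (!is.null(eqtl_results)) {
    tr <- eqtl_results[eqtl_results$gene == gene$id &
                         eqtl_results$type == "trans" &
                         !is.na(eqtl_results$bbfdr) &
                         eqtl_results$bbfdr < trans_bbfdr, "variant"]
    idx <- sort(union(idx, match(tr, g$variants$id)))
  }
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    message("empty feature set for gene ", gene$id, "; skipped")
    return(NULL)
  }
  genotype_matrix(g$dosages[, idx, drop = FALSE],
                  g$variants[idx, , drop = FALSE],
                  samples = g$samples, stratum = g$stratum)
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of \code{window} variants, while any pair has
#' squared correlation above \code{r2_max}, the later-positioned member
#' of the worst pair is removed; the window then advances by \code{step}
#' variants. Input variant order is preserved in the output.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param window window size in variants (default 50).
#' @param step step size in variants (default 5).
#' @param r2_max squared-correlation threshold (default 0.5).
#' @return The pruned \code{\link{genotype_matrix}}.
#' @export
ld_prune <- function(x, window = 50, step = 5, r2_max = 0.5) {
  m <- ncol(x$dosages)
  keep <- rep(TRUE, m)
  sds <- apply(x$dosages, 2, sd)
  keep[sds == 0] <- FALSE
  start <- 1L
  repeat {
    idx <- which(keep)
    idx <- idx[idx >= start & idx < start + window]
    if (length(idx) > 1) {
      repeat {
        r2 <- cor(x$dosages[, idx, drop = FALSE])^2
        diag(r2) <- 0
        mx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        if (r2[mx[1], mx[2]] <= r2_max) break
        drop_local <- max(mx)          # later-positioned member
        keep[idx[drop_local]] <- FALSE
        idx <- idx[-drop_local]
        if (length(idx) < 2) break
      }
    }
    if (start + window > m) break
    start <- start + step
  }
  sel <- which(keep)
  genotype_matrix(x$dosages[, sel, drop = FALSE],
                  x$variants[sel, , drop = FALSE],
                  samples = x$samples, stratum = x$stratum)
}

#' Elastic-net expression weights
#'
#' Elastic-net path (mixing parameter \code{alpha} = 0.5 by default) with
#' the penalty chosen to minimize cross-validated mean-squared error.
#'
#' @param x a \code{\link{genotype_matrix}} (pruned feature set).
#' @param y numeric residualized expression vector.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param n_folds CV folds for lambda tuning (default 5).
#' @param seed fold seed.
#' @param foldid optional explicit fold assignment (overrides seed).
#' @return named numeric weight vector (per alt-allele dosage), possibly
#'   all zero; attribute \code{"flagged"} is TRUE for zero-variance y.
#' @export
fit_enet <- function(x, y, alpha = 0.5, n_folds = 5, seed = 1, foldid = NULL) {
  X <- x$dosages
  if (sd(y) < 1e-12) {
    w <- setNames(rep(0, ncol(X)), colnames(X))
    attr(w, "flagged") <- TRUE
    return(w)
  }
  if (is.null(foldid)) {
    set.seed(seed)
    foldid <- sample(rep(seq_len(n_folds), length.out = length(y)))
  }
  if (ncol(X) < 2) {
    # glmnet needs >= 2 columns; fall back to OLS with a shrink toward 0
    b <- coef(lm(y ~ X))[-1]
    w <- setNames(ifelse(is.na(b), 0, b), colnames(X))
    attr(w, "flagged") <- FALSE
    return(w)
  }
  cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                             standardize = TRUE)
  w <- drop(coef(cvfit, s = "lambda.min"))[-1]
  w <- setNames(as.numeric(w), colnames(X))
  attr(w, "flagged") <- FALSE
  w
}

#' BLUP expression weights via single-component REML
#'
#' Treats the standardized genotype matrix as random effects, estimates
#' \eqn{(\sigma^2_g, \sigma^2_e)} by REML on the single-GRM model, and
#' returns the best linear unbiased predictor of the variant effects,
#' which equals ridge regression with penalty
#' \eqn{\lambda^* = m \sigma^2_e / \sigma^2_g} on the standardized scale.
#' Weights are returned per alt-allele dosage.
#'
#' @param x a \code{\link{genotype_matrix}}.
#' @param y numeric residualized expression vector.
#' @return named weight vector; attributes \code{"lambda_star"} and
#'   \code{"flagged"} (TRUE when the genetic component is estimated at
#'   the zero boundary, giving all-zero weights).
#' @export
fit_blup <- function(x, y) {
  X <- x$dosages
  sds <- apply(X, 2, sd)
  use <- sds > 0
  Z <- scale(X[, use, drop = FALSE])
  m <- ncol(Z)
  if (m == 0 || sd(y) < 1e-12) {
    w <- setNames(rep(0, ncol(X)), colnames(X))
    attr(w, "flagged") <- TRUE
    return(w)
  }
  A <- tcrossprod(Z) / m
  fit <- reml_fit(y, list(A))
  sg <- fit$components[1]; se2 <- fit$sigma_e
  w <- setNames(rep(0, ncol(X)), colnames(X))
  if (sg <= se2 * 1e-6) {
    attr(w, "flagged") <- TRUE
    attr(w, "lambda_star") <- Inf
    return(w)
  }
  lambda <- m * se2 / sg
  yc <- y - mean(y)
  w_std <- drop(solve(crossprod(Z) + diag(lambda, m), crossprod(Z, yc)))
  w[use] <- w_std / sds[use]
  attr(w, "lambda_star") <- lambda
  attr(w, "flagged") <- FALSE
  w
}

#' Cross-validated scheme selection for one gene
#'
#' Runs every registered scheme under a shared, seeded 5-fold assignment,
#' assembles strictly out-of-fold predictions, scores each scheme by CV
#' R-squared (squared Pearson correlation between out-of-fold prediction
#' and observation, with its correlation-test p-value), and returns the
#' winner. Ties prefer the elastic net (sparser, cheaper to impute).
#' Schemes whose out-of-fold predictions are constant score 0.
#'
#' @param x a \code{\link{genotype_matrix}} (pruned feature set).
#' @param y numeric residualized expression vector.
#' @param schemes character subset of \code{c("enet", "blup")}.
#' @param n_folds CV folds (default 5).
#' @param seed fold seed (recorded on the model).
#' @param gene,stratum labels stored on the model.
#' @return An object of class \code{expression_model}: list with gene,
#'   stratum, scheme, weights, cv_r2, cv_p, per-scheme cv table, seed,
#'   fold assignment.
#' @export
select_scheme <- function(x, y, schemes = c("enet", "blup"), n_folds = 5,
                          seed = 1, gene = NA_character_,
                          stratum = NA_character_) {
  stopifnot(length(schemes) >= 1)
  set.seed(seed)
  n <- length(y)
  foldid <- sample(rep(seq_len(n_folds), length.out = n))
  fit_one <- function(scheme, xs, ys, inner_foldid) {
    switch(scheme,
           enet = fit_enet(xs, ys, foldid = inner_foldid),
           blup = fit_blup(xs, ys),
           stop("unknown scheme: ", scheme))
  }
  cv_tab <- data.frame(scheme = schemes, cv_r2 = NA_real_, cv_p = NA_real_,
                       stringsAsFactors = FALSE)
  preds <- matrix(NA_real_, n, length(schemes))
  for (si in seq_along(schemes)) {
    for (f in seq_len(n_folds)) {
      tr <- foldid != f
      xs <- genotype_matrix(x$dosages[tr, , drop = FALSE], x$variants,
                            samples = x$samples[tr], stratum = x$stratum)
      inner <- sample(rep(seq_len(n_folds), length.out = sum(tr)))
      w <- fit_one(schemes[si], xs, y[tr], inner)
      a <- mean(y[tr]) - mean(drop(x$dosages[tr, , drop = FALSE] %*% w))
      preds[!tr, si] <- a + drop(x$dosages[!tr, , drop = FALSE] %*% w)
    }
    if (sd(preds[, si]) < 1e-12) {
      cv_tab$cv_r2[si] <- 0; cv_tab$cv_p[si] <- 1
    } else {
      ct <- cor.test(preds[, si], y)
      cv_tab$cv_r2[si] <- unname(ct$estimate^2)
      cv_tab$cv_p[si] <- ct$p.value
    }
  }
  # winner: max CV R2; ties (within 1e-12) prefer enet
  ord <- order(-cv_tab$cv_r2, match(cv_tab$scheme, c("enet", "blup")))
  best <- ord[1]
  set.seed(seed + 1L)
  final_inner <- sample(rep(seq_len(n_folds), length.out = n))
  w_final <- fit_one(schemes[best], x, y, final_inner)
  structure(list(gene = gene, stratum = stratum,
                 scheme = schemes[best],
                 weights = w_final,
                 variants = x$variants,
                 cv_r2 = cv_tab$cv_r2[best], cv_p = cv_tab$cv_p[best],
                 cv_table = cv_tab, seed = seed, foldid = foldid),
            class = "expression_model")
}

#' @export
print.expression_model <- function(x, ...) {
  cat(sprintf("expression_model: %s [%s] scheme=%s, CV R2=%.4f (p=%.3g), %d/%d nonzero weights\n",
              x$gene, x$stratum, x$scheme, x$cv_r2, x$cv_p,
              sum(x$weights != 0), length(x$weights)))
  invisible(x)
}

#' Train per-gene, per-stratum expression models
#'
#' For each stratum and each gene passing the heritability filter:
#' feature-matrix assembly, LD pruning, scheme selection by
#' cross-validation. Genes are flagged usable for downstream association
#' when CV R-squared exceeds \code{cv_r2_min}.
#'
#' @param genotypes named list of per-stratum
#'   \code{\link{genotype_matrix}} objects.
#' @param expression named list of per-stratum residualized
#'   \code{\link{expression_matrix}} objects.
#' @param heritable_genes either a character vector applied to all strata
#'   or a named list per stratum.
#' @param eqtl_results optional named list per stratum of
#'   \code{\link{hierarchical_fdr}} outputs (for trans features).
#' @param cis_window,trans_bbfdr feature-set parameters.
#' @param schemes,n_folds,seed passed to \code{\link{select_scheme}}.
#' @param cv_r2_min downstream-use flag threshold (default 0.01).
#' @param min_n minimum stratum size; smaller strata are skipped with a
#'   warning (default 50).
#' @return An object of class \code{model_store}: nested list
#'   store[[stratum]][[gene]] of \code{expression_model}s, with a summary
#'   data.frame attached as attribute \code{"summary"}.
#' @export
train_all <- function(genotypes, expression, heritable_genes,
                      eqtl_results = NULL, cis_window = 500000,
                      trans_bbfdr = 0.01, schemes = c("enet", "blup"),
                      n_folds = 5, seed = 1, cv_r2_min = 0.01, min_n = 50) {
  store <- list()
  summ <- list()
  for (s in names(genotypes)) {
    g <- genotypes[[s]]; e <- expression[[s]]
    if (length(g$samples) < min_n) {
      warning("stratum ", s, " has fewer than ", min_n, " samples; skipped")
      next
    }
    genes_s <- if (is.list(heritable_genes)) heritable_genes[[s]] else heritable_genes
    al <- align_samples(e$samples, g$samples)
    store[[s]] <- list()
    for (gn in genes_s) {
      j <- match(gn, e$genes$id)
      if (is.na(j)) next
      fx <- build_feature_matrix(g, e$genes[j, ],
                                 if (!is.null(eqtl_results)) eqtl_results[[s]] else NULL,
                                 cis_window, trans_bbfdr)
      if (is.null(fx)) next
      fx <- genotype_matrix(fx$dosages[al$b, , drop = FALSE], fx$variants,
                            samples = fx$samples[al$b], stratum = fx$stratum)
      fx <- ld_prune(fx)
      mod <- select_scheme(fx, e$values[al$a, j], schemes = schemes,
                           n_folds = n_folds, seed = seed, gene = gn,
                           stratum = s)
      mod$usable <- mod$cv_r2 > cv_r2_min
      store[[s]][[gn]] <- mod
      summ[[length(summ) + 1L]] <- data.frame(
        stratum = s, gene = gn, scheme = mod$scheme, cv_r2 = mod$cv_r2,
        cv_p = mod$cv_p, usable = mod$usable,
        n_weights = sum(mod$weights != 0), stringsAsFactors = FALSE)
    }
  }
  attr(store, "summary") <- if (length(summ)) do.call(rbind, summ) else
    data.frame()
  class(store) <- "model_store"
  store
}

#' Write/read a model store as per-stratum TSVs with a JSON sidecar
#'
#' @param store a \code{model_store} from \code{\link{train_all}}.
#' @param dir output directory.
#' @export
write_model_store <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list()
  for (s in names(store)) {
    rows <- list()
    for (gn in names(store[[s]])) {
      m <- store[[s]][[gn]]
      nz <- which(m$weights != 0)
      if (length(nz))
        rows[[gn]] <- data.frame(gene = gn,
                                 variant = names(m$weights)[nz],
                                 m$variants[nz, c("chrom", "pos", "ref", "alt")],
                                 weight = unname(m$weights[nz]),
                                 stringsAsFactors = FALSE)
      meta[[s]][[gn]] <- list(scheme = m$scheme, cv_r2 = m$cv_r2,
                              cv_p = m$cv_p, seed = m$seed,
                              usable = isTRUE(m$usable))
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene = character(), variant = character(),
                 chrom = character(), pos = integer(), ref = character(),
                 alt = character(), weight = numeric())
    data.table::fwrite(tab, file.path(dir, paste0("weights_", s, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  jsonlite::write_json(meta, file.path(dir, "models.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
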