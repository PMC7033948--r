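#' Read genotype dosages from VCF or a dosage TSV
#'
#' VCF input takes dosages from the \code{DS} FORMAT field when present,
#' otherwise sums \code{GT} allele calls. Fractional dosages are retained
#' as written. Multi-allelic records are rejected. Missing dosages are
#' mean-imputed per variant at read time (the imputed fraction is attached
#' as an attribute). The dosage-TSV layout is the one written by
#' \code{\link{write_genotypes}}: columns id, chrom, pos, ref, alt then one
#' column per sample.
#'
#' @param path file path.
#' @param format \code{"vcf"} or \code{"dosage-tsv"}.
#' @param stratum optional stratum label attached to the result.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage-tsv"),
                           stratum = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF drops to vector
    fix <- as.data.frame(fix, stringsAsFactors = FALSE)
    if (any(grepl(",", fix$ALT, fixed = TRUE)))
      stop("multi-allelic VCF records are not supported; split or filter them first")
    fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
    if ("DS" %in% fmt_keys) {
      ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    } else if ("GT" %in% fmt_keys) {
      gt <- vcfR::extract.gt(v, element = "GT")
      ds <- apply(gt, 2, function(col) {
        vapply(col, function(g) {
          if (is.na(g)) return(NA_real_)
          sum(as.integer(strsplit(g, "[/|]")[[1]]))
        }, numeric(1))
      })
      ds <- matrix(as.numeric(ds), nrow = nrow(gt), dimnames = dimnames(gt))
    } else {
      stop("VCF has neither DS nor GT in FORMAT")
    }
    ids <- fix$ID
    ids[is.na(ids) | ids == "."] <-
      paste0(fix$CHROM, ":", fix$POS, "_", fix$REF, "_", fix$ALT)[is.na(ids) | ids == "."]
    variants <- data.frame(id = ids, chrom = fix$CHROM,
                           pos = as.integer(fix$POS),
                           ref = fix$REF, alt = fix$ALT,
                           stringsAsFactors = FALSE)
    samples <- colnames(ds)
    dosages <- t(ds)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    meta_cols <- c("id", "chrom", "pos", "ref", "alt")
    if (!all(meta_cols %in% names(dt)))
      stop("dosage TSV must have columns id, chrom, pos, ref, alt")
    variants <- dt[, meta_cols]
    variants$pos <- as.integer(variants$pos)
    samples <- setdiff(names(dt), meta_cols)
    dosages <- t(as.matrix(dt[, samples, drop = FALSE]))
  }
  if (anyDuplicated(samples)) stop("sample-ID collision in ", path)
  imp_frac <- mean(is.na(dosages))
  if (imp_frac > 0) {
    for (j in seq_len(ncol(dosages))) {
      miss <- is.na(dosages[, j])
      if (any(miss)) dosages[miss, j] <- mean(dosages[!miss, j])
    }
  }
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  g <- genotype_matrix(dosages, variants, samples = samples, stratum = stratum)
  attr(g, "imputed_fraction") <- imp_frac
  g
}

#' Write genotype dosages as a TSV
#'
#' Round-trips losslessly with \code{\link{read_genotypes}(format =
#' "dosage-tsv")} at full double precision.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output path.
#' @export
write_genotypes <- function(g, path) {
  out <- cbind(g$variants[, c("id", "chrom", "pos", "ref", "alt")],
               as.data.frame(t(g$dosages)))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read/write an expression matrix TSV (genes in rows, samples in columns)
#'
#' @param path file path.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  meta_cols <- c("id", "chrom", "start", "end")
  if (!all(meta_cols %in% names(dt)))
    stop("expression TSV must have columns id, chrom, start, end")
  genes <- dt[, meta_cols]
  samples <- setdiff(names(dt), meta_cols)
  values <- t(as.matrix(dt[, samples, drop = FALSE]))
  expression_matrix(values, genes, samples = samples)
}

#' @rdname read_expression
#' @param e an \code{\link{expression_matrix}}.
#' @export
write_expression <- function(e, path) {
  out <- cbind(e$genes[, c("id", "chrom", "start", "end")],
               as.data.frame(t(e$values)))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a BED annotation file as 1-based inclusive intervals
#'
#' BED is 0-based half-open on disk; intervals are converted to the
#' package-wide 1-based inclusive convention on read.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end (1-based inclusive).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Read/write simple sample tables (covariates, survival)
#'
#' @param path file path.
#' @return data.frame keyed by a \code{sample} column.
#' @export
read_table_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' @rdname read_table_tsv
#' @param x data.frame to write.
#' @export
write_table_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}
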