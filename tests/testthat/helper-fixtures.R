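# Small in-code fixtures shared across test files.

toy_variants <- function(m, chrom = "1", start = 1000, step = 1000) {
  data.frame(id = sprintf("v%03d", seq_len(m)), chrom = chrom,
             pos = as.integer(start + step * (seq_len(m) - 1L)),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

toy_genotype_matrix <- function(n, m, maf = 0.3, seed = 1, chrom = "1",
                                start = 1000, step = 1000) {
  set.seed(seed)
  genotype_matrix(matrix(rbinom(n * m, 2, maf), n, m),
                  toy_variants(m, chrom, start, step),
                  samples = sprintf("s%03d", seq_len(n)))
}

toy_gene <- function(id = "g1", chrom = "1", start = 1000, end = 2000) {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

toy_surv <- function(time, cause, samples = sprintf("s%03d", seq_along(time))) {
  data.frame(sample = samples, time = time, cause = cause,
             stringsAsFactors = FALSE)
}

# Independent OLS oracle: solve the normal equations explicitly and form
# the Wald t-test for one coefficient.
ols_oracle <- function(y, X, coef_idx) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  r <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  se <- sqrt(s2 * solve(XtX)[coef_idx, coef_idx])
  tval <- b[coef_idx] / se
  list(beta = b[coef_idx], se = se, t = tval,
       p = 2 * pt(-abs(tval), df))
}

# Independent log-rank oracle over distinct event times (no ties, no
# censoring): standard observed-minus-expected form.
logrank_oracle <- function(time, event, group) {
  stopifnot(all(event == 1), !anyDuplicated(time))
  o <- order(time)
  time <- time[o]; group <- group[o]
  n1 <- sum(group == 1); n0 <- sum(group == 0)
  O <- 0; E <- 0; V <- 0
  at1 <- n1; at0 <- n0
  for (i in seq_along(time)) {
    nrisk <- at1 + at0
    d <- 1
    O <- O + (group[i] == 1)
    E <- E + at1 / nrisk
    if (nrisk > 1)
      V <- V + d * (at1 / nrisk) * (1 - at1 / nrisk) * (nrisk - d) / (nrisk - 1)
    if (group[i] == 1) at1 <- at1 - 1 else at0 <- at0 - 1
  }
  (O - E)^2 / V
}
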