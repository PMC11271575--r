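# Small in-code fixtures shared across tests.

# random PSD correlation matrix
random_corr <- function(p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  cov2cor(crossprod(A) + diag(p))
}

# minimal sumstats object over SNP ids with given standardized effects
make_sumstats <- function(r, population = "pop1", ids = NULL, n = 10000,
                          freq = 0.3) {
  p <- length(r)
  if (is.null(ids)) ids <- sprintf("rs%04d", seq_len(p))
  sumstats(data.frame(snp_id = ids, chrom = "1", pos = seq_len(p) * 1000,
                      a1 = "A", a2 = "G", r = r, n = n,
                      freq = rep_len(freq, p)),
           population)
}

# single-block LD set
make_ld <- function(R, population = "pop1", ids = NULL, block_id = 1) {
  p <- nrow(R)
  if (is.null(ids)) ids <- sprintf("rs%04d", seq_len(p))
  ld_blockset(population, list(list(block_id = block_id, snp_ids = ids, R = R)))
}

# dosage-scale panel with given dosage matrix
make_panel <- function(X, ids = NULL, standardized = FALSE) {
  p <- ncol(X)
  if (is.null(ids)) ids <- sprintf("rs%04d", seq_len(p))
  snps <- data.frame(snp_id = ids, chrom = "1", pos = seq_len(p) * 1000,
                     a1 = "A", a2 = "G", freq = colMeans(X) / 2)
  genotype_panel(X, snps, sprintf("s%04d", seq_len(nrow(X))),
                 standardized = standardized)
}
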