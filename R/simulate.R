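#' Configuration of the synthetic multi-ancestry data generator
#'
#' Emulates, at desk scale, the genetic architecture used to study
#' multi-ancestry PRS methods: several populations with block-structured,
#' population-specific AR(1) LD; a configurable fraction of SNPs shared by
#' all populations (the rest population-specific, exercising the lasso-only
#' rule); shared causal SNPs with correlated effects across populations;
#' fixed common-SNP heritability; and GWAS sampling noise at stated n.
#'
#' @param M number of populations.
#' @param populations labels; default `"pop1"..."popM"`.
#' @param p total SNPs across the union of populations.
#' @param block_size SNPs per LD block.
#' @param rho_ld per-population AR(1) LD parameter(s), recycled to length `M`.
#' @param freq_range allele-frequency range (uniform draw per SNP and
#'   population).
#' @param p_causal causal fraction (polygenicity).
#' @param h2 common-SNP heritability, identical across populations.
#' @param rho_effect cross-population correlation of causal effect sizes.
#' @param alpha selection exponent coupling effect variance to
#'   `(2 f (1-f))^alpha` on the standardized scale (0 = strong negative
#'   selection baseline).
#' @param n_gwas per-population GWAS sample sizes, recycled to length `M`.
#' @param n_tune,n_valid tuning / validation cohort sizes.
#' @param shared_frac fraction of SNPs present in every population.
#' @param prevalence case prevalence for binary traits (`NULL` = continuous).
#' @param seed base seed recorded in the config.
#' @return A `maprs_sim_config` list.
#' @export
sim_config <- function(M = 2, populations = NULL, p = 2000, block_size = 100,
                       rho_ld = 0.7, freq_range = c(0.05, 0.95),
                       p_causal = 0.01, h2 = 0.4, rho_effect = 0.8,
                       alpha = 0, n_gwas = c(100000, 15000),
                       n_tune = 10000, n_valid = 10000,
                       shared_frac = 0.9, prevalence = NULL, seed = 1) {
  if (is.null(populations)) populations <- paste0("pop", seq_len(M))
  stopifnot(length(populations) == M, p_causal > 0, p_causal <= 1,
            h2 >= 0, h2 < 1, abs(rho_effect) <= 1, all(n_gwas > 0),
            n_tune > 0, n_valid > 0, shared_frac >= 0, shared_frac <= 1)
  if (!is.null(prevalence) && (prevalence <= 0 || prevalence >= 1))
    stop("sim_config: prevalence must be in (0, 1)")
  structure(list(M = M, populations = populations, p = p,
                 block_size = block_size,
                 rho_ld = rep_len(rho_ld, M), freq_range = freq_range,
                 p_causal = p_causal, h2 = h2, rho_effect = rho_effect,
                 alpha = alpha, n_gwas = rep_len(n_gwas, M),
                 n_tune = n_tune, n_valid = n_valid,
                 shared_frac = shared_frac, prevalence = prevalence,
                 seed = seed),
            class = "maprs_sim_config")
}

# SNP metadata and per-population membership. The first floor(shared_frac*p)
# SNPs (in position order) are present in every population; the remainder are
# assigned round-robin to single populations.
sim_snp_map <- function(config) {
  p <- config$p; M <- config$M
  ids <- sprintf("rs%06d", seq_len(p))
  n_shared <- floor(config$shared_frac * p)
  membership <- matrix(FALSE, p, M, dimnames = list(ids, config$populations))
  membership[seq_len(n_shared), ] <- TRUE
  if (n_shared < p) {
    extra <- (n_shared + 1):p
    membership[cbind(extra, rep_len(seq_len(M), length(extra)))] <- TRUE
  }
  freq <- matrix(runif(p * M, config$freq_range[1], config$freq_range[2]),
                 p, M, dimnames = list(ids, config$populations))
  list(ids = ids, chrom = rep("1", p), pos = seq_len(p) * 1000L,
       a1 = rep("A", p), a2 = rep("G", p),
       membership = membership, freq = freq,
       block = (seq_len(p) - 1L) %/% config$block_size + 1L)
}

#' Generate per-population AR(1) LD block sets
#'
#' Each population's LD within a block is `rho_ld^|j-k|` over the ranks of the
#' SNPs it models in that block; AR(1) correlation matrices are positive
#' definite for `|rho| < 1`. Block boundaries are shared across populations.
#'
#' @param config a [sim_config()].
#' @param snp_map internal SNP map (computed from `config` if omitted).
#' @return Named list of [ld_blockset()] objects, one per population.
#' @export
gen_ld_blocks <- function(config, snp_map = NULL) {
  if (is.null(snp_map)) { set.seed(config$seed); snp_map <- sim_snp_map(config) }
  stopifnot(all(abs(config$rho_ld) < 1))
  out <- list()
  for (i in seq_len(config$M)) {
    rho <- config$rho_ld[i]
    blocks <- lapply(sort(unique(snp_map$block)), function(b) {
      j <- which(snp_map$block == b & snp_map$membership[, i])
      pb <- length(j)
      R <- if (pb) rho^abs(outer(seq_len(pb), seq_len(pb), "-")) else matrix(0, 0, 0)
      list(block_id = b, snp_ids = snp_map$ids[j], R = R)
    })
    out[[config$populations[i]]] <- ld_blockset(config$populations[i], blocks)
  }
  out
}

#' Draw true causal effects for all populations
#'
#' The causal set is a Bernoulli(`p_causal`) draw over SNPs (at least one
#' causal SNP is forced). For a causal SNP modelled by several populations the
#' effects are jointly normal with pairwise correlation `rho_effect`; per-SNP
#' variance is proportional to `(2 f (1-f))^alpha` on the standardized scale,
#' and each population's effects are rescaled so that its true genetic
#' variance equals `h2` (computed as `beta' R beta` when `ld` is supplied,
#' else as `sum(beta^2)`).
#'
#' @param config a [sim_config()].
#' @param ld optional list of [ld_blockset()] per population, used to target
#'   the heritability under LD.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A `maprs_truth` object: `config`, `snp_map`, `causal_ids`, `beta`
#'   (union SNPs x populations, zero rows for non-causal SNPs, `NA` where a
#'   population does not model the SNP), `h2_target`.
#' @export
simulate_effects <- function(config, ld = NULL, seed = config$seed) {
  set.seed(seed)
  snp_map <- sim_snp_map(config)
  if (is.null(ld)) ld <- gen_ld_blocks(config, snp_map)
  p <- config$p; M <- config$M
  causal <- which(runif(p) < config$p_causal)
  if (!length(causal)) {
    warning("simulate_effects: p_causal * p < 1; forcing one causal SNP")
    causal <- sample.int(p, 1)
  }
  C <- matrix(config$rho_effect, M, M); diag(C) <- 1
  A <- chol(C)
  Z <- matrix(rnorm(length(causal) * M), length(causal), M) %*% A
  beta <- matrix(0, p, M, dimnames = list(snp_map$ids, config$populations))
  v <- (2 * snp_map$freq * (1 - snp_map$freq))^config$alpha
  for (i in seq_len(M)) {
    ci <- causal[snp_map$membership[causal, i]]
    zi <- Z[snp_map$membership[causal, i], i]
    if (length(ci)) {
      b <- zi * sqrt(v[ci, i])
      beta[ci, i] <- b
      # rescale to the target heritability under this population's LD
      ids <- snp_map$ids
      gvar <- 0
      for (blk in ld[[i]]$blocks) {
        m <- match(blk$snp_ids, ids)
        bb <- beta[m, i]
        gvar <- gvar + drop(crossprod(bb, blk$R %*% bb))
      }
      if (gvar > 0) beta[, i] <- beta[, i] * sqrt(config$h2 / gvar)
    }
    beta[!snp_map$membership[, i], i] <- NA
  }
  structure(list(config = config, snp_map = snp_map,
                 causal_ids = snp_map$ids[causal], beta = beta,
                 h2_target = config$h2),
            class = "maprs_truth")
}

# symmetric PSD square root, with a small ridge if numerically indefinite
sym_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    warning("sym_sqrt: block not PSD; adding 1e-8 ridge")
    e <- eigen(R + 1e-8 * diag(nrow(R)), symmetric = TRUE)
  }
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# per-population true effect vector in a given population's LD order
truth_beta_pop <- function(truth, ld_pop, population) {
  ids <- ld_snp_ids(ld_pop)
  b <- truth$beta[match(ids, rownames(truth$beta)), population]
  b[is.na(b)] <- 0
  b
}

#' Simulate GWAS summary statistics
#'
#' Direct mode draws, per LD block, `r ~ Normal(R beta, R / n)` using a
#' symmetric square root of `R` — the sampling distribution of standardized
#' marginal effects at GWAS sample size `n`. Cohort mode simulates an
#' individual-level GWAS of size `n` and computes marginal correlations; it
#' exists to cross-validate the direct sampler and is slower.
#'
#' @param truth a [simulate_effects()] result.
#' @param ld the [ld_blockset()] of the population being simulated.
#' @param population population label.
#' @param n_gwas GWAS sample size.
#' @param seed RNG seed (`NULL` = leave RNG state alone).
#' @param mode `"direct"` or `"cohort"`.
#' @return A [sumstats()] object.
#' @export
simulate_sumstats <- function(truth, ld, population, n_gwas,
                              seed = NULL, mode = c("direct", "cohort")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  ids <- ld_snp_ids(ld)
  if (mode == "direct") {
    r <- numeric(0)
    for (blk in ld$blocks) {
      b <- truth$beta[match(blk$snp_ids, rownames(truth$beta)), population]
      b[is.na(b)] <- 0
      pb <- length(b)
      if (!pb) next
      mu <- drop(blk$R %*% b)
      r <- c(r, mu + drop(sym_sqrt(blk$R) %*% rnorm(pb)) / sqrt(n_gwas))
    }
  } else {
    cohort <- simulate_cohort(truth, ld, population, n_gwas)
    X <- cohort$panel$dosage  # standardized
    y <- cohort$phenotype$phenotype
    r <- drop(cor(X, y))  # marginal SNP-trait correlations
  }
  r <- pmin(pmax(r, -0.999), 0.999)
  m <- match(ids, truth$snp_map$ids)
  sumstats(data.frame(snp_id = ids, chrom = truth$snp_map$chrom[m],
                      pos = truth$snp_map$pos[m], a1 = truth$snp_map$a1[m],
                      a2 = truth$snp_map$a2[m], r = r, n = n_gwas,
                      freq = truth$snp_map$freq[m, population]),
           population)
}

#' Simulate an individual-level cohort with phenotypes
#'
#' Genotypes are drawn per LD block from a multivariate normal with covariance
#' `R` (standardized mode, the default) or discretized to 0/1/2 dosages by
#' thresholding two latent haplotypes at the allele-frequency quantile
#' (dosage mode). The phenotype is `X beta + covariates + noise` with noise
#' variance `1 - h2`; in binary mode the liability is thresholded at the
#' configured prevalence.
#'
#' @param truth a [simulate_effects()] result.
#' @param ld the population's [ld_blockset()].
#' @param population population label.
#' @param n cohort size (>= 2).
#' @param covariate_count number of standard-normal covariates with effect
#'   size 0.1 each.
#' @param seed RNG seed (`NULL` = leave RNG state alone).
#' @param mode `"standardized"` or `"dosage"`.
#' @return List `panel` (a [genotype_panel()]), `phenotype` (data frame
#'   `sample_id`, `phenotype`, covariates), `genetic_score` (true `X beta`).
#' @export
simulate_cohort <- function(truth, ld, population, n, covariate_count = 0,
                            seed = NULL, mode = c("standardized", "dosage")) {
  mode <- match.arg(mode)
  if (n < 2) stop("simulate_cohort: n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  ids <- ld_snp_ids(ld)
  m <- match(ids, truth$snp_map$ids)
  freq <- truth$snp_map$freq[m, population]
  X <- matrix(0, n, length(ids))
  off <- 0L
  for (blk in ld$blocks) {
    pb <- length(blk$snp_ids)
    if (!pb) next
    A <- sym_sqrt(blk$R)
    cols <- off + seq_len(pb)
    if (mode == "standardized") {
      X[, cols] <- matrix(rnorm(n * pb), n, pb) %*% A
    } else {
      f <- freq[cols]
      thr <- qnorm(f)
      h1 <- matrix(rnorm(n * pb), n, pb) %*% A
      h2 <- matrix(rnorm(n * pb), n, pb) %*% A
      X[, cols] <- sweep(h1, 2, thr, function(x, t) as.numeric(x < t)) +
        sweep(h2, 2, thr, function(x, t) as.numeric(x < t))
    }
    off <- off + pb
  }
  snps <- data.frame(snp_id = ids, chrom = truth$snp_map$chrom[m],
                     pos = truth$snp_map$pos[m], a1 = truth$snp_map$a1[m],
                     a2 = truth$snp_map$a2[m], freq = freq)
  sample_ids <- sprintf("%s_s%06d", population, seq_len(n))
  panel <- genotype_panel(X, snps, sample_ids,
                          standardized = mode == "standardized")

  b <- truth_beta_pop(truth, ld, population)
  Xs <- if (mode == "standardized") X else standardize_panel(panel)$dosage
  g <- drop(Xs %*% b)
  pheno <- g + rnorm(n, sd = sqrt(1 - truth$config$h2))
  df <- data.frame(sample_id = sample_ids, phenotype = pheno)
  if (covariate_count > 0) {
    for (j in seq_len(covariate_count)) {
      cv <- rnorm(n)
      df$phenotype <- df$phenotype + 0.1 * cv
      df[[paste0("covar", j)]] <- cv
    }
  }
  if (!is.null(truth$config$prevalence)) {
    # liability thresholding at the configured prevalence
    liab <- df$phenotype
    df$phenotype <- as.numeric(liab > quantile(liab, 1 - truth$config$prevalence))
  }
  list(panel = panel, phenotype = df, genetic_score = g)
}
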