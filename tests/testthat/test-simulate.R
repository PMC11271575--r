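test_that("sim_config validates its arguments", {
  sc <- sim_config()
  expect_s3_class(sc, "maprs_sim_config")
  expect_identical(sc$populations, c("pop1", "pop2"))
  expect_equal(sc$n_gwas, c(100000, 15000))
  expect_error(sim_config(p_causal = 0), "p_causal")
  expect_error(sim_config(h2 = 1))
  expect_error(sim_config(rho_effect = 1.2))
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(M = 3, populations = c("a", "b")))
})

test_that("the SNP map splits shared and population-specific SNPs", {
  set.seed(201)
  sc <- sim_config(M = 3, p = 100, shared_frac = 0.8, block_size = 25)
  sm <- sim_snp_map(sc)
  expect_equal(sum(rowSums(sm$membership) == 3), 80)
  expect_equal(sum(rowSums(sm$membership) == 1), 20)
  expect_equal(colSums(sm$membership[81:100, ]),
               setNames(c(7, 7, 6), sc$populations))
  expect_equal(sort(unique(sm$block)), 1:4)
  expect_true(all(sm$freq >= sc$freq_range[1] & sm$freq <= sc$freq_range[2]))
})

test_that("generated LD is AR(1) over each population's modelled SNPs", {
  sc <- sim_config(M = 2, p = 40, block_size = 20, rho_ld = c(0.7, 0.4),
                   shared_frac = 0.5, seed = 5)
  ld <- gen_ld_blocks(sc)
  expect_identical(names(ld), c("pop1", "pop2"))
  for (i in 1:2) {
    rho <- sc$rho_ld[i]
    for (blk in ld[[i]]$blocks) {
      pb <- length(blk$snp_ids)
      expect_equal(unname(blk$R),
                   rho^abs(outer(seq_len(pb), seq_len(pb), "-")))
      expect_gt(min(eigen(blk$R, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }
  # block boundaries shared, contents population-dependent
  ids1 <- ld_snp_ids(ld$pop1); ids2 <- ld_snp_ids(ld$pop2)
  expect_false(identical(ids1, ids2))
  expect_length(intersect(ids1, ids2), 20)   # the shared half
})

test_that("true effects hit the target heritability exactly under LD", {
  sc <- sim_config(M = 2, p = 300, block_size = 50, p_causal = 0.1,
                   h2 = 0.35, seed = 7)
  truth <- simulate_effects(sc)
  ld <- gen_ld_blocks(sc, truth$snp_map)
  for (pop in sc$populations) {
    b <- truth_beta_pop(truth, ld[[pop]], pop)
    gvar <- 0; off <- 0
    for (blk in ld[[pop]]$blocks) {
      pb <- length(blk$snp_ids)
      bb <- b[off + seq_len(pb)]
      gvar <- gvar + drop(crossprod(bb, blk$R %*% bb))
      off <- off + pb
    }
    expect_equal(gvar, 0.35, tolerance = 1e-10)
  }
  # non-causal SNPs are exactly zero; unmodelled entries are NA
  expect_true(all(truth$beta[setdiff(rownames(truth$beta),
                                     truth$causal_ids), ] %in% c(0, NA)))
  unmodelled <- !truth$snp_map$membership
  expect_true(all(is.na(truth$beta[unmodelled])))
})

test_that("causal effects are correlated across populations as configured", {
  sc <- sim_config(M = 2, p = 4000, block_size = 100, p_causal = 0.5,
                   rho_effect = 0.8, shared_frac = 1, seed = 9)
  truth <- simulate_effects(sc)
  ci <- truth$causal_ids
  expect_gt(length(ci), 1500)
  expect_equal(cor(truth$beta[ci, 1], truth$beta[ci, 2]), 0.8,
               tolerance = 0.05)
})

test_that("at least one causal SNP is forced", {
  sc <- sim_config(p = 50, block_size = 25, p_causal = 1e-6, seed = 11)
  expect_warning(truth <- simulate_effects(sc), "forcing one causal")
  expect_length(truth$causal_ids, 1)
})

test_that("sym_sqrt squares back to the input", {
  R <- random_corr(6, 301)
  A <- sym_sqrt(R)
  expect_equal(A %*% A, R, tolerance = 1e-10)
  expect_equal(A, t(A), tolerance = 1e-10)
})

test_that("direct sumstats sampling is centered on R beta with sd 1/sqrt(n)", {
  sc <- sim_config(M = 1, p = 30, block_size = 30, p_causal = 0.2,
                   n_gwas = 400, seed = 13)
  truth <- simulate_effects(sc)
  ld <- gen_ld_blocks(sc, truth$snp_map)
  b <- truth_beta_pop(truth, ld$pop1, "pop1")
  mu <- drop(ld$pop1$blocks[[1]]$R %*% b)
  reps <- 400
  draws <- vapply(seq_len(reps), function(k)
    simulate_sumstats(truth, ld$pop1, "pop1", 400, seed = 10000 + k)$r,
    numeric(30))
  err <- rowMeans(draws) - mu
  # Monte-Carlo tolerance: 5 standard errors of the mean of r-hat
  expect_lt(max(abs(err)), 5 / sqrt(400 * 400))
  # marginal variance of r-hat is diag(R)/n = 1/n
  expect_equal(mean(apply(draws, 1, var)), 1 / 400, tolerance = 0.15)
})

test_that("cohort and direct sumstats agree in distribution", {
  sc <- sim_config(M = 1, p = 20, block_size = 20, p_causal = 0.3,
                   h2 = 0.3, n_gwas = 4000, seed = 15)
  truth <- simulate_effects(sc)
  ld <- gen_ld_blocks(sc, truth$snp_map)
  b <- truth_beta_pop(truth, ld$pop1, "pop1")
  mu <- drop(ld$pop1$blocks[[1]]$R %*% b)
  direct <- simulate_sumstats(truth, ld$pop1, "pop1", 4000, seed = 1,
                              mode = "direct")
  cohort <- simulate_sumstats(truth, ld$pop1, "pop1", 4000, seed = 2,
                              mode = "cohort")
  # both land within sampling noise of the common mean
  expect_lt(max(abs(direct$r - mu)), 5 / sqrt(4000))
  expect_lt(max(abs(cohort$r - mu)), 5 / sqrt(4000))
  expect_identical(direct$snp_id, cohort$snp_id)
})

test_that("standardized cohorts reproduce the LD and the phenotype model", {
  sc <- sim_config(M = 1, p = 40, block_size = 20, p_causal = 0.2,
                   h2 = 0.4, seed = 17)
  truth <- simulate_effects(sc)
  ld <- gen_ld_blocks(sc, truth$snp_map)
  ch <- simulate_cohort(truth, ld$pop1, "pop1", 4000, seed = 3)
  X <- ch$panel$dosage
  expect_true(ch$panel$standardized)
  R_emp <- cor(X[, 1:20])
  expect_lt(max(abs(R_emp - ld$pop1$blocks[[1]]$R)), 0.08)
  # phenotype = genetic score + noise of variance 1 - h2
  noise <- ch$phenotype$phenotype - ch$genetic_score
  expect_equal(var(noise), 0.6, tolerance = 0.08)
  expect_equal(var(ch$genetic_score), 0.4, tolerance = 0.08)
})

test_that("dosage cohorts hit the target allele frequencies and LD sign", {
  sc <- sim_config(M = 1, p = 20, block_size = 20, rho_ld = 0.8,
                   p_causal = 0.5, seed = 19)
  truth <- simulate_effects(sc)
  ld <- gen_ld_blocks(sc, truth$snp_map)
  ch <- simulate_cohort(truth, ld$pop1, "pop1", 3000, seed = 4,
                        mode = "dosage")
  X <- ch$panel$dosage
  expect_true(all(X %in% 0:2))
  f_target <- truth$snp_map$freq[, "pop1"]
  expect_lt(max(abs(colMeans(X) / 2 - f_target)), 0.05)
  # adjacent-SNP dosage correlation stays positive under latent AR(1) 0.8;
  # thresholding at extreme allele frequencies attenuates it, so the floor is
  # loose while the average remains substantial
  adj <- vapply(1:19, function(j) cor(X[, j], X[, j + 1]), 0)
  expect_gt(min(adj), 0.05)
  expect_gt(mean(adj), 0.3)
})

test_that("covariates and binary liability thresholding work", {
  sc <- sim_config(M = 1, p = 20, block_size = 20, p_causal = 0.2,
                   prevalence = 0.2, seed = 21)
  truth <- simulate_effects(sc)
  ld <- gen_ld_blocks(sc, truth$snp_map)
  ch <- simulate_cohort(truth, ld$pop1, "pop1", 1000, covariate_count = 2,
                        seed = 5)
  expect_identical(names(ch$phenotype),
                   c("sample_id", "phenotype", "covar1", "covar2"))
  expect_true(all(ch$phenotype$phenotype %in% c(0, 1)))
  expect_equal(mean(ch$phenotype$phenotype), 0.2, tolerance = 0.01)
  expect_error(simulate_cohort(truth, ld$pop1, "pop1", 1), ">= 2")
})

test_that("simulation is deterministic given the seed", {
  sc <- sim_config(M = 2, p = 60, block_size = 20, seed = 23)
  t1 <- simulate_effects(sc)
  t2 <- simulate_effects(sc)
  expect_identical(t1$beta, t2$beta)
  ld <- gen_ld_blocks(sc, t1$snp_map)
  s1 <- simulate_sumstats(t1, ld$pop1, "pop1", 1000, seed = 99)
  s2 <- simulate_sumstats(t1, ld$pop1, "pop1", 1000, seed = 99)
  expect_identical(s1$r, s2$r)
  s3 <- simulate_sumstats(t1, ld$pop1, "pop1", 1000, seed = 100)
  expect_false(identical(s3$r, s1$r))
})
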