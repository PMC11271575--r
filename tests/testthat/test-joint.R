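test_that("the coordinate update is a scaled soft-threshold", {
  u <- c(-0.5, -0.05, 0, 0.05, 0.5)
  expect_equal(joint_soft_update(u, 0.1),
               c(-0.4, 0, 0, 0, 0.4))
  expect_equal(joint_soft_update(0.5, 0.1, delta = 1, c_sum = 2),
               0.4 / 4)
  # zero extra penalties reduce to the plain lasso update
  expect_equal(joint_soft_update(u, 0.1, 0, 0),
               sign(u) * pmax(0, abs(u) - 0.1))
})

test_that("the lambda scale-factor path has the documented endpoints", {
  s1 <- make_sumstats(c(0.5, -0.2), "EUR")
  s2 <- make_sumstats(c(0.3, 0.1), "AFR", ids = c("rs0001", "rs0003"))
  lam0 <- c(0.25, 0.05)
  path <- build_lambda_path(list(s1, s2), lam0)
  # lambda_max = min(0.5/0.25, 0.3/0.05) = 2
  expect_length(path, 10)
  expect_equal(path[1], 2)
  expect_equal(path[10], 0.002)
  expect_equal(diff(log(path)), rep(diff(log(path))[1], 9))
  # second value of the default path from lambda_max = 2
  expect_equal(path[2], 2 * 0.001^(1 / 9))
  expect_error(build_lambda_path(list(s1), c(0.1, 0.2)))
  expect_error(build_lambda_path(list(s1, s2), c(0, 0.1)), "> 0")
})

test_that("the c path is evenly spaced on the fourth-root scale", {
  cp <- build_c_path()
  expect_length(cp, 10)
  expect_equal(cp[1], 2)
  expect_equal(cp[10], 100)
  expect_equal(cp[5], (2^0.25 + 4 * (100^0.25 - 2^0.25) / 9)^4)
  expect_equal(diff(cp^0.25), rep(diff(cp^0.25)[1], 9))
  expect_error(build_c_path(c_min = 0), "0 < c_min")
  expect_error(build_c_path(c_min = 5, c_max = 2), "0 < c_min")
})

test_that("pair penalties scale for the flagged population only", {
  expect_equal(scale_pair_penalty(10, 1.5, "AFR", c("AFR", "EUR")), 15)
  expect_equal(scale_pair_penalty(10, 1.5, "AFR", c("EUR", "EAS")), 10)
  expect_equal(scale_pair_penalty(10, 0.5, NULL, c("AFR", "EUR")), 10)
  Cm <- pair_penalty_matrix(c("EUR", "AFR", "EAS"), 10, r_scale = 0.5,
                            flagged_pop = "AFR")
  expect_equal(Cm["EUR", "EAS"], 10)
  expect_equal(Cm["EUR", "AFR"], 5)
  expect_equal(Cm["AFR", "EAS"], 5)
  expect_true(isSymmetric(Cm))
  expect_equal(unname(diag(Cm)), rep(0, 3))
})

test_that("hand-derived two-population worked example is recovered", {
  # p = 1, R = 1, delta = 0, r = (0.5, 0.1), lambda = 0.1, c = 1:
  # beta1 = (r1 - lambda + c*beta2)/(1 + c), beta2 likewise ->
  # beta = (4/15, 2/15)
  fit <- solve_joint_block(list(0.5, 0.1), list(diag(1), diag(1)),
                           list("rs1", "rs1"), lambda = c(0.1, 0.1),
                           delta = c(0, 0), c_pairs = 1,
                           tol = 1e-14, max_sweeps = 1e6)
  expect_equal(fit$betas[[1]], 4 / 15, tolerance = 1e-10)
  expect_equal(fit$betas[[2]], 2 / 15, tolerance = 1e-10)
  expect_false(fit$diverged)
})

test_that("a symmetric instance yields identical coefficients", {
  fit <- solve_joint_block(list(0.5, 0.5), list(diag(1), diag(1)),
                           list("rs1", "rs1"), lambda = c(0.1, 0.1),
                           delta = c(0, 0), c_pairs = 7,
                           tol = 1e-14, max_sweeps = 1e6)
  expect_equal(fit$betas[[1]], fit$betas[[2]], tolerance = 1e-10)
  expect_equal(fit$betas[[1]], 0.4, tolerance = 1e-8)
})

test_that("c = 0 decouples the populations into single-ancestry lassos", {
  set.seed(41)
  p <- 8
  R1 <- random_corr(p, 61); R2 <- random_corr(p, 62)
  r1 <- drop(R1 %*% rnorm(p, sd = 0.1)); r2 <- drop(R2 %*% rnorm(p, sd = 0.1))
  ids <- sprintf("rs%04d", 1:p)
  fit <- solve_joint_block(list(r1, r2), list(R1, R2), list(ids, ids),
                           lambda = c(0.03, 0.02), delta = c(0.1, 0.2),
                           c_pairs = 0, tol = 1e-13, max_sweeps = 1e5)
  s1 <- .cd_lassosum_block(R1, r1, 0.1, 0.03, 1e-13, 1e5)
  s2 <- .cd_lassosum_block(R2, r2, 0.2, 0.02, 1e-13, 1e5)
  expect_equal(fit$betas[[1]], drop(s1$betas), tolerance = 1e-10)
  expect_equal(fit$betas[[2]], drop(s2$betas), tolerance = 1e-10)
})

test_that("identity LD gives the closed-form coupled solution", {
  # R = I in both populations: each coordinate is the p = 1 worked example
  r1 <- c(0.5, -0.5); r2 <- c(0.1, -0.1)
  fit <- solve_joint_block(list(r1, r2), list(diag(2), diag(2)),
                           list(c("a", "b"), c("a", "b")),
                           lambda = c(0.1, 0.1), delta = c(0, 0), c_pairs = 1,
                           tol = 1e-14, max_sweeps = 1e6)
  expect_equal(fit$betas[[1]], c(4 / 15, -4 / 15), tolerance = 1e-10)
  expect_equal(fit$betas[[2]], c(2 / 15, -2 / 15), tolerance = 1e-10)
})

test_that("population-specific SNPs see only the lasso penalty", {
  # rs2 exists only in population 1; with identity LD its coefficient is the
  # plain soft-threshold regardless of c
  fit <- solve_joint_block(list(c(0.5, 0.3), 0.1),
                           list(diag(2), diag(1)),
                           list(c("rs1", "rs2"), "rs1"),
                           lambda = c(0.1, 0.1), delta = c(0, 0),
                           c_pairs = 50, tol = 1e-13, max_sweeps = 1e6)
  expect_equal(fit$betas[[1]][2], 0.2, tolerance = 1e-10)
})

test_that("solutions match an independent convex minimizer (partial overlap)", {
  set.seed(42)
  for (trial in 1:4) {
    M <- sample(2:3, 1)
    p_i <- sample(3:6, M, replace = TRUE)
    union_p <- max(p_i) + 2
    union_ids <- sprintf("u%02d", seq_len(union_p))
    ids <- lapply(p_i, function(p) sort(sample(union_ids, p)))
    R <- lapply(p_i, function(p) random_corr(p, sample.int(1e6, 1)))
    r <- lapply(seq_len(M), function(i)
      drop(R[[i]] %*% rnorm(p_i[i], sd = 0.2)))
    lambda <- runif(M, 0.01, 0.08)
    delta <- runif(M, 0.01, 0.5)
    cc <- runif(1, 0.5, 20)
    fit <- solve_joint_block(r, R, ids, lambda, delta, cc,
                             tol = 1e-13, max_sweeps = 1e6)
    orc <- oracle_joint_solve(r, R, ids, lambda, delta, cc)
    expect_false(fit$diverged)
    expect_equal(fit$objective, orc$objective, tolerance = 1e-8)
    gap <- joint_kkt_gap(fit$betas, r, R, ids, lambda, delta,
                         if (is.matrix(cc)) cc else {
                           Cm <- matrix(cc, M, M); diag(Cm) <- 0; Cm
                         })
    expect_lt(gap, 1e-6)
  }
})

test_that("reported objective equals the independently computed objective", {
  set.seed(43)
  p <- 5
  R <- list(random_corr(p, 71), random_corr(p, 72))
  ids <- list(sprintf("rs%d", 1:p), sprintf("rs%d", 1:p))
  r <- lapply(R, function(Ri) drop(Ri %*% rnorm(p, sd = 0.15)))
  Cm <- matrix(c(0, 3, 3, 0), 2, 2)
  fit <- solve_joint_block(r, R, ids, lambda = c(0.02, 0.03),
                           delta = c(0.1, 0.1), c_pairs = Cm,
                           tol = 1e-12, max_sweeps = 1e5)
  expect_equal(fit$objective,
               joint_objective(fit$betas, r, R, union_index(ids),
                               c(0.02, 0.03), c(0.1, 0.1), Cm),
               tolerance = 1e-10)
})

test_that("the objective trace is non-increasing sweep over sweep", {
  set.seed(44)
  p <- 20
  R <- list(random_corr(p, 81), random_corr(p, 82))
  ids <- list(sprintf("rs%d", 1:p), sprintf("rs%d", 1:p))
  r <- lapply(R, function(Ri) drop(Ri %*% rnorm(p, sd = 0.1)))
  fit <- solve_joint_block(r, R, ids, lambda = c(0.01, 0.01),
                           delta = c(0.01, 0.01), c_pairs = 10,
                           tol = 1e-10, max_sweeps = 1e4, trace = TRUE)
  tr <- fit$objective_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) <= 1e-10))
})

test_that("joint_lasso_grid warm starts reach the same optimum as cold starts", {
  set.seed(45)
  p <- 10
  ids <- sprintf("rs%04d", 1:p)
  R <- list(random_corr(p, 91), random_corr(p, 92))
  ss <- lapply(1:2, function(i)
    make_sumstats(drop(R[[i]] %*% rnorm(p, sd = 0.15)),
                  paste0("pop", i), ids = ids))
  ld <- lapply(1:2, function(i) make_ld(R[[i]], paste0("pop", i), ids = ids))
  ref <- list(list(delta0 = 0.01, lambda0 = 0.05),
              list(delta0 = 0.1, lambda0 = 0.04))
  joint <- joint_lasso_grid(ss, ld, ref, grid_length = 4,
                            tol = 1e-12, max_sweeps = 1e5)
  expect_equal(nrow(joint$settings), 16)
  k <- which(joint$settings$lambda_idx == 3 & joint$settings$c_idx == 2)
  cold <- solve_joint_block(
    lapply(ss, `[[`, "r"), R, list(ids, ids),
    lambda = joint$settings$lambda[k] * joint$lambda0,
    delta = joint$delta0,
    c_pairs = joint$settings$c[k], tol = 1e-12, max_sweeps = 1e5)
  expect_equal(joint$betas[[1]][, k], cold$betas[[1]], tolerance = 1e-7)
  expect_equal(joint$betas[[2]][, k], cold$betas[[2]], tolerance = 1e-7)
  expect_identical(names(joint$betas), c("pop1", "pop2"))
})

test_that("joint_lasso_grid requires matching block ids", {
  ids <- sprintf("rs%04d", 1:4)
  R <- diag(4)
  ss <- lapply(1:2, function(i) make_sumstats(rep(0.1, 4), paste0("pop", i),
                                              ids = ids))
  ld1 <- make_ld(R, "pop1", ids = ids, block_id = 1)
  ld2 <- make_ld(R, "pop2", ids = ids, block_id = 2)
  ref <- rep(list(list(delta0 = 0.01, lambda0 = 0.05)), 2)
  expect_error(joint_lasso_grid(ss, list(ld1, ld2), ref, grid_length = 2),
               "block ids")
})

test_that("extreme coupling approaches the fused pooled solution", {
  # r = (0.5, 0.1), lambda = 0.1, c -> infinity: both coefficients tend to
  # the pooled value (0.5 - 0.1 + 0.1 - 0.1)/2 = 0.2. The common mode moves
  # O(1/c) per sweep, hence the tight tolerance and large sweep budget.
  fit <- solve_joint_block(list(0.5, 0.1), list(diag(1), diag(1)),
                           list("rs1", "rs1"), lambda = c(0.1, 0.1),
                           delta = c(0, 0), c_pairs = 1e6,
                           tol = 1e-13, max_sweeps = 3e7)
  expect_equal(fit$betas[[1]], 0.2, tolerance = 1e-4)
  expect_equal(fit$betas[[2]], 0.2, tolerance = 1e-4)
  expect_lt(abs(fit$betas[[1]] - fit$betas[[2]]), 1e-5)
})
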