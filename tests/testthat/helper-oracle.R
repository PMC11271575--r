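# Independent oracle for the joint objective: minimizes the same function by
# smooth bound-constrained quasi-Newton optimization on the positive/negative
# split beta = bp - bn (bp, bn >= 0), which makes the L1 term linear. This
# shares no code with the coordinate-descent solver.

joint_objective <- function(betas, r_list, R_list, idx, lambda, delta, Cmat) {
  M <- length(r_list)
  obj <- 0
  for (i in seq_len(M)) {
    b <- betas[[i]]
    obj <- obj + drop(crossprod(b, R_list[[i]] %*% b)) + delta[i] * sum(b^2) -
      2 * sum(b * r_list[[i]]) + 2 * lambda[i] * sum(abs(b))
  }
  if (M > 1) {
    for (i1 in 1:(M - 1)) for (i2 in (i1 + 1):M) {
      sh <- which(idx[, i1] > 0 & idx[, i2] > 0)
      if (length(sh)) {
        d <- betas[[i1]][idx[sh, i1]] - betas[[i2]][idx[sh, i2]]
        obj <- obj + Cmat[i1, i2] * sum(d^2)
      }
    }
  }
  obj
}

# build the union index matrix from per-population SNP id vectors
union_index <- function(snp_ids_by_pop) {
  union_ids <- unique(unlist(snp_ids_by_pop))
  idx <- vapply(snp_ids_by_pop, function(ids) {
    m <- match(union_ids, ids); m[is.na(m)] <- 0L; m
  }, integer(length(union_ids)))
  matrix(idx, nrow = length(union_ids))
}

oracle_joint_solve <- function(r_list, R_list, snp_ids_by_pop, lambda, delta,
                               c_pairs, maxit = 20000) {
  M <- length(r_list)
  if (is.matrix(c_pairs)) Cmat <- c_pairs
  else { Cmat <- matrix(c_pairs, M, M); diag(Cmat) <- 0 }
  idx <- union_index(snp_ids_by_pop)
  p_i <- vapply(r_list, length, 0L)
  split_betas <- function(x) {
    # first half bp, second half bn, concatenated over populations
    off <- 0
    bp <- bn <- vector("list", M)
    for (i in seq_len(M)) { bp[[i]] <- x[off + seq_len(p_i[i])]; off <- off + p_i[i] }
    for (i in seq_len(M)) { bn[[i]] <- x[off + seq_len(p_i[i])]; off <- off + p_i[i] }
    Map(`-`, bp, bn)
  }
  fn <- function(x) {
    betas <- split_betas(x)
    obj <- joint_objective(betas, r_list, R_list, idx, lambda, rep(0, M), Cmat)
    # delta ridge and L1 handled explicitly on the split variables:
    # joint_objective already charges 2*lambda*|b|; replace with linear term
    obj <- obj - sum(vapply(seq_len(M), function(i)
      2 * lambda[i] * sum(abs(betas[[i]])), 0))
    off <- 0
    for (i in seq_len(M)) {
      obj <- obj + delta[i] * sum(betas[[i]]^2)
      obj <- obj + 2 * lambda[i] * sum(x[off + seq_len(p_i[i])])
      off <- off + p_i[i]
    }
    for (i in seq_len(M)) {
      obj <- obj + 2 * lambda[i] * sum(x[off + seq_len(p_i[i])])
      off <- off + p_i[i]
    }
    obj
  }
  gr <- function(x) {
    betas <- split_betas(x)
    g <- vector("list", M)
    for (i in seq_len(M)) {
      g[[i]] <- 2 * (R_list[[i]] %*% betas[[i]]) +
        2 * delta[i] * betas[[i]] - 2 * r_list[[i]]
    }
    if (M > 1) {
      for (i1 in 1:(M - 1)) for (i2 in (i1 + 1):M) {
        sh <- which(idx[, i1] > 0 & idx[, i2] > 0)
        if (length(sh)) {
          d <- betas[[i1]][idx[sh, i1]] - betas[[i2]][idx[sh, i2]]
          g[[i1]][idx[sh, i1]] <- g[[i1]][idx[sh, i1]] + 2 * Cmat[i1, i2] * d
          g[[i2]][idx[sh, i2]] <- g[[i2]][idx[sh, i2]] - 2 * Cmat[i1, i2] * d
        }
      }
    }
    gp <- unlist(g) + 2 * rep(lambda, p_i)
    gn <- -unlist(g) + 2 * rep(lambda, p_i)
    c(gp, gn)
  }
  x0 <- rep(0, 2 * sum(p_i))
  fit <- optim(x0, fn, gr, method = "L-BFGS-B", lower = 0,
               control = list(maxit = maxit, factr = 10))
  betas <- split_betas(fit$par)
  list(betas = betas,
       objective = joint_objective(betas, r_list, R_list, idx, lambda, delta,
                                   Cmat))
}

# KKT residuals of the joint problem: for each population/SNP returns
# (gradient of the smooth part)/2; at an optimum this equals -lambda*sign(beta)
# for active coordinates and lies in [-lambda, lambda] for zero ones.
joint_kkt_gap <- function(betas, r_list, R_list, snp_ids_by_pop, lambda,
                          delta, c_pairs) {
  M <- length(r_list)
  if (is.matrix(c_pairs)) Cmat <- c_pairs
  else { Cmat <- matrix(c_pairs, M, M); diag(Cmat) <- 0 }
  idx <- union_index(snp_ids_by_pop)
  worst <- 0
  for (i in seq_len(M)) {
    g <- drop(R_list[[i]] %*% betas[[i]]) + delta[i] * betas[[i]] - r_list[[i]]
    for (j in seq_len(M)) if (j != i) {
      sh <- which(idx[, i] > 0 & idx[, j] > 0)
      if (length(sh))
        g[idx[sh, i]] <- g[idx[sh, i]] +
          Cmat[i, j] * (betas[[i]][idx[sh, i]] - betas[[j]][idx[sh, j]])
    }
    b <- betas[[i]]
    active <- b != 0
    if (any(active))
      worst <- max(worst, max(abs(g[active] + lambda[i] * sign(b[active])) /
                                max(lambda[i], 1e-12)))
    if (any(!active))
      worst <- max(worst, max(pmax(0, abs(g[!active]) - lambda[i]) /
                                max(lambda[i], 1e-12)))
  }
  worst
}
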