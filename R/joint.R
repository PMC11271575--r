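#' Lambda scale-factor path for the joint model
#'
#' The per-population lasso penalties are tied together as
#' `lambda_i = lambda * lambda0_i`, with the reference `lambda0_i` from the
#' single-ancestry analysis. The scale-factor path runs from
#' `lambda_max = min_i( max_k |r_ik| / lambda0_i )` (the largest scale at
#' which at least one population still admits a nonzero solution) down to
#' `lambda_min = 0.001 * lambda_max`, evenly spaced on the log scale.
#'
#' @param sumstats_by_pop list of [sumstats()] objects.
#' @param lambda0_by_pop numeric vector of reference lasso penalties.
#' @param length path length; default 10.
#' @return Decreasing numeric vector of scale factors.
#' @export
build_lambda_path <- function(sumstats_by_pop, lambda0_by_pop, length = 10) {
  stopifnot(length(sumstats_by_pop) == base::length(lambda0_by_pop))
  if (any(lambda0_by_pop <= 0)) stop("build_lambda_path: lambda0 must be > 0")
  max_r <- vapply(sumstats_by_pop, function(s) max(abs(s$r)), 0)
  if (any(max_r == 0)) stop("build_lambda_path: a population has all-zero r")
  lambda_max <- min(max_r / lambda0_by_pop)
  exp(seq(log(lambda_max), log(0.001 * lambda_max), length.out = length))
}

#' Quad-root-spaced path for the cross-population ridge penalty
#'
#' `c_j = (c_min^(1/4) + (j-1) * (c_max^(1/4) - c_min^(1/4)) / (length-1))^4`,
#' i.e. evenly spaced on a fourth-root scale between `c_min` and `c_max`.
#'
#' @param c_min,c_max endpoints; defaults 2 and 100.
#' @param length path length; default 10.
#' @return Increasing numeric vector.
#' @export
build_c_path <- function(c_min = 2, c_max = 100, length = 10) {
  if (c_min <= 0 || c_min >= c_max) stop("build_c_path: need 0 < c_min < c_max")
  seq(c_min^0.25, c_max^0.25, length.out = length)^4
}

#' Coordinate update of the joint solver
#'
#' The closed-form update for one coefficient:
#' `sign(u) * max(0, |u| - lambda) / (1 + delta + c_sum)`, where `u` is the
#' partial residual including the cross-population pull and `c_sum` the sum of
#' ridge penalties over partner populations sharing the SNP (0 for
#' population-specific SNPs, reducing to the plain lasso update).
#'
#' @param u partial residual (vectorized).
#' @param lambda lasso penalty (>= 0).
#' @param delta LD regularization (>= 0).
#' @param c_sum total cross-population ridge weight (>= 0).
#' @return Updated coefficient value(s).
#' @export
joint_soft_update <- function(u, lambda, delta = 0, c_sum = 0) {
  sign(u) * pmax(0, abs(u) - lambda) / (1 + delta + c_sum)
}

#' Pairwise ridge penalty with a distance-scaled population
#'
#' Optionally scales the common ridge penalty `c` for every pair involving one
#' designated population (e.g. AFR, whose genetic distance to the others is
#' largest): `c_ij = r_scale * c` if `i` or `j` is the flagged population,
#' else `c`.
#'
#' @param c base ridge penalty.
#' @param r_scale scale factor (typically 0.5, 1 or 1.5).
#' @param flagged_pop label of the designated population (or `NULL` for no
#'   scaling).
#' @param pair character vector of the two population labels.
#' @return The pair-specific penalty.
#' @export
scale_pair_penalty <- function(c, r_scale = 1, flagged_pop = NULL, pair) {
  if (is.null(flagged_pop) || !(flagged_pop %in% pair)) c else r_scale * c
}

# Build the M x M symmetric penalty matrix (zero diagonal) for one c value.
pair_penalty_matrix <- function(pops, c, r_scale = 1, flagged_pop = NULL) {
  M <- length(pops)
  Cmat <- matrix(c, M, M, dimnames = list(pops, pops))
  diag(Cmat) <- 0
  if (!is.null(flagged_pop) && flagged_pop %in% pops) {
    Cmat[flagged_pop, ] <- r_scale * Cmat[flagged_pop, ]
    Cmat[, flagged_pop] <- r_scale * Cmat[, flagged_pop]
  }
  Cmat
}

#' Solve the joint multi-population model for one LD block
#'
#' Cyclic coordinate descent (population-major, then SNP order) on
#' `sum_i [beta_i'(R_i + delta_i I) beta_i - 2 beta_i' r_i + 2 lambda_i ||beta_i||_1]
#'  + sum_{i1<i2} C[i1,i2] ||beta_i1^s - beta_i2^s||_2^2`,
#' the ridge term running over SNPs shared by each pair. Sharing is inferred
#' from the per-population SNP id vectors.
#'
#' @param r_by_pop list of standardized-effect vectors.
#' @param R_by_pop list of LD correlation matrices.
#' @param snp_ids_by_pop list of SNP id vectors naming the entries of each
#'   population's `r`.
#' @param lambda,delta per-population penalty vectors.
#' @param c_pairs symmetric matrix of pairwise ridge penalties (zero
#'   diagonal), or a scalar applied to all pairs.
#' @param beta_init optional warm-start list of coefficient vectors.
#' @param tol,max_sweeps convergence controls.
#' @param trace record the objective after every sweep?
#' @return List `betas` (per population), `objective`, `sweeps`, `diverged`,
#'   `objective_trace`.
#' @export
solve_joint_block <- function(r_by_pop, R_by_pop, snp_ids_by_pop,
                              lambda, delta, c_pairs, beta_init = NULL,
                              tol = 1e-7, max_sweeps = 1000, trace = FALSE) {
  M <- length(r_by_pop)
  if (is.matrix(c_pairs)) Cmat <- c_pairs
  else { Cmat <- matrix(c_pairs, M, M); diag(Cmat) <- 0 }
  union_ids <- unique(unlist(snp_ids_by_pop))
  idx <- vapply(snp_ids_by_pop, function(ids) match(union_ids, ids), integer(length(union_ids)))
  idx <- matrix(idx, nrow = length(union_ids))
  idx[is.na(idx)] <- 0L
  fit <- .cd_joint_block(R_by_pop, r_by_pop, idx, lambda, delta, Cmat,
                         beta_init, tol, max_sweeps, trace)
  fit$betas <- lapply(fit$betas, as.numeric)
  fit
}

#' Fit the joint model over the full (lambda, c) penalty grid
#'
#' For every scale factor `lambda` on the lambda path and every ridge penalty
#' `c` on the c path, solves all LD blocks (treated as independent) with
#' per-population lasso penalties `lambda * lambda0_i` and fixed LD
#' regularization `delta0_i`. Within each `c`, solutions are warm-started
#' along the descending lambda path. Population-specific SNPs (present in a
#' single population's data) are penalized by the lasso only.
#'
#' @param sumstats_by_pop list of [sumstats()] objects, one per population.
#' @param ld_by_pop list of [ld_blockset()] objects with matching `block_id`s
#'   across populations.
#' @param ref_params list per population with elements `delta0` and `lambda0`
#'   (from [select_reference_params()]).
#' @param lambda_path scale-factor path; default [build_lambda_path()] of
#'   length `grid_length`.
#' @param c_path ridge path; default [build_c_path()] of length `grid_length`.
#' @param grid_length default length of both paths (10; use 5 for a reduced
#'   grid).
#' @param r_scale,flagged_pop optional distance scaling of pair penalties
#'   (see [scale_pair_penalty()]).
#' @param tol,max_sweeps convergence controls.
#' @param trace record per-sweep objective traces (for diagnostics)?
#' @return A `maprs_joint` object: `populations`, `snp_ids` and `snps`
#'   metadata per population, `settings` data frame (`lambda_idx`, `c_idx`,
#'   `lambda`, `c`, `diverged`, `objective`), `betas` (list per population,
#'   SNPs x settings), and optionally `traces`.
#' @export
joint_lasso_grid <- function(sumstats_by_pop, ld_by_pop, ref_params,
                             lambda_path = NULL, c_path = NULL,
                             grid_length = 10,
                             r_scale = 1, flagged_pop = NULL,
                             tol = 1e-7, max_sweeps = 1000, trace = FALSE) {
  M <- length(sumstats_by_pop)
  stopifnot(length(ld_by_pop) == M, length(ref_params) == M)
  pops <- vapply(seq_len(M), function(i)
    attr(sumstats_by_pop[[i]], "population") %||% paste0("pop", i), "")
  delta0 <- vapply(ref_params, `[[`, 0, "delta0")
  lambda0 <- vapply(ref_params, `[[`, 0, "lambda0")
  if (is.null(lambda_path))
    lambda_path <- build_lambda_path(sumstats_by_pop, lambda0, grid_length)
  if (is.null(c_path)) c_path <- build_c_path(length = grid_length)
  lambda_path <- sort(lambda_path, decreasing = TRUE)
  c_path <- sort(c_path)

  aligned <- lapply(seq_len(M), function(i)
    align_to_ld(sumstats_by_pop[[i]], ld_by_pop[[i]]))
  block_ids <- lapply(ld_by_pop, function(ld)
    vapply(ld$blocks, `[[`, 0, "block_id"))
  if (M > 1 && !all(vapply(block_ids[-1], identical, TRUE, block_ids[[1]])))
    stop("joint_lasso_grid: block ids must match across populations")
  nblocks <- length(block_ids[[1]])

  settings <- expand.grid(lambda_idx = seq_along(lambda_path),
                          c_idx = seq_along(c_path))
  settings$lambda <- lambda_path[settings$lambda_idx]
  settings$c <- c_path[settings$c_idx]
  nset <- nrow(settings)

  snp_ids <- lapply(seq_len(M), function(i)
    unlist(lapply(aligned[[i]], `[[`, "snp_ids"), use.names = FALSE))
  p_i <- vapply(snp_ids, length, 0L)
  if (any(p_i == 0))
    stop("joint_lasso_grid: a population has no SNPs after LD alignment")
  betas <- lapply(p_i, function(p) matrix(0, p, nset))
  diverged <- logical(nset)
  objective <- numeric(nset)
  traces <- if (trace) vector("list", nset) else NULL

  for (ci in seq_along(c_path)) {
    Cmat <- pair_penalty_matrix(pops, c_path[ci], r_scale, flagged_pop)
    warm <- vector("list", nblocks)  # per block, list of per-pop betas
    for (li in seq_along(lambda_path)) {
      set_id <- which(settings$lambda_idx == li & settings$c_idx == ci)
      lam_i <- lambda_path[li] * lambda0
      offsets <- integer(M)
      if (trace) traces[[set_id]] <- vector("list", nblocks)
      for (b in seq_len(nblocks)) {
        blk <- lapply(aligned, `[[`, b)
        fit <- solve_joint_block(
          lapply(blk, `[[`, "r"), lapply(blk, `[[`, "R"),
          lapply(blk, `[[`, "snp_ids"),
          lambda = lam_i, delta = delta0, c_pairs = Cmat,
          beta_init = warm[[b]], tol = tol, max_sweeps = max_sweeps,
          trace = trace)
        for (i in seq_len(M)) {
          pb <- length(blk[[i]]$snp_ids)
          if (pb) betas[[i]][offsets[i] + seq_len(pb), set_id] <- fit$betas[[i]]
          offsets[i] <- offsets[i] + pb
        }
        diverged[set_id] <- diverged[set_id] || fit$diverged
        objective[set_id] <- objective[set_id] + fit$objective
        if (trace) traces[[set_id]][[b]] <- fit$objective_trace
        warm[[b]] <- if (fit$diverged) NULL else fit$betas
      }
    }
  }
  settings$diverged <- diverged
  settings$objective <- objective
  snps_meta <- lapply(seq_len(M), function(i) {
    ss <- sumstats_by_pop[[i]]
    ss[match(snp_ids[[i]], ss$snp_id), c("snp_id", "chrom", "pos", "a1", "a2")]
  })
  structure(list(populations = pops, snp_ids = snp_ids, snps = snps_meta,
                 settings = settings, betas = setNames(betas, pops),
                 lambda_path = lambda_path, c_path = c_path,
                 delta0 = delta0, lambda0 = lambda0, traces = traces),
            class = "maprs_joint")
}

#' @method print maprs_joint
#' @export
print.maprs_joint <- function(x, ...) {
  cat("maprs_joint:", length(x$populations), "populations x",
      nrow(x$settings), "penalty settings (",
      sum(x$settings$diverged), "flagged )\n")
  invisible(x)
}
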