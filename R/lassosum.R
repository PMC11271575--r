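#' Convert association z-scores to standardized marginal effects
#'
#' Default conversion `r = z / sqrt(n)`, clipped to `[-0.999, 0.999]`; the
#' alternative `r = z / sqrt(n - 1 + z^2)` (which never exceeds 1 in
#' magnitude) is selectable.
#'
#' @param z z-score vector.
#' @param n GWAS sample size (scalar or vector), must exceed 1.
#' @param method `"sqrt_n"` (default) or `"sqrt_n1z"`.
#' @return Standardized effects in `[-0.999, 0.999]`.
#' @export
zscore_to_r <- function(z, n, method = c("sqrt_n", "sqrt_n1z")) {
  method <- match.arg(method)
  if (any(n <= 1)) stop("zscore_to_r: n must be > 1")
  r <- switch(method,
              sqrt_n = z / sqrt(n),
              sqrt_n1z = z / sqrt(n - 1 + z^2))
  pmin(pmax(r, -0.999), 0.999)
}

# Align a sumstats table to an LD block set: returns per-block r vectors in
# the block SNP order, restricted to the intersection of SNP ids.
align_to_ld <- function(ss, ld) {
  lapply(ld$blocks, function(b) {
    m <- match(b$snp_ids, ss$snp_id)
    keep <- which(!is.na(m))
    list(block_id = b$block_id,
         snp_ids = b$snp_ids[keep],
         r = ss$r[m[keep]],
         R = b$R[keep, keep, drop = FALSE])
  })
}

#' Single-ancestry summary-statistic lasso path (lassosum2 style)
#'
#' For each pair on the `(delta, lambda)` grid, minimizes
#' `beta' (R + delta I) beta - 2 beta' r + 2 lambda ||beta||_1`
#' by per-block coordinate descent with warm starts along the descending
#' lambda path (cold start at the largest lambda). Settings whose iterates
#' explode or whose objective rises repeatedly are flagged divergent and
#' excluded from selection.
#'
#' @param ss a [sumstats()] object.
#' @param ld a [ld_blockset()] for the same population.
#' @param delta_grid LD regularization values; default `c(0.001, 0.01, 0.1, 1)`.
#' @param lambda_grid lasso penalties (descending); default 30 values evenly
#'   log-spaced from `max|r|` down to `0.01 max|r|`.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_sweeps sweep cap per block.
#' @return A `maprs_lassosum` object: `snp_ids` (model order), `grid`
#'   (data frame `delta`, `lambda`, `diverged`, `objective`), `betas`
#'   (SNPs x grid settings), `population`.
#' @export
lassosum_path <- function(ss, ld, delta_grid = c(0.001, 0.01, 0.1, 1),
                          lambda_grid = NULL, tol = 1e-7, max_sweeps = 1000) {
  aligned <- align_to_ld(ss, ld)
  p_blocks <- vapply(aligned, function(b) length(b$snp_ids), 0L)
  if (sum(p_blocks) == 0)
    stop("lassosum_path: no SNPs shared between sumstats and LD reference")
  max_r <- max(abs(unlist(lapply(aligned, `[[`, "r"))))
  if (is.null(lambda_grid)) {
    if (max_r == 0) stop("lassosum_path: all r are zero")
    lambda_grid <- exp(seq(log(max_r), log(0.01 * max_r), length.out = 30))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  grid <- expand.grid(lambda = lambda_grid, delta = delta_grid)[, c("delta", "lambda")]
  nset <- nrow(grid)
  betas <- matrix(0, sum(p_blocks), nset)
  diverged <- logical(nset)
  objective <- numeric(nset)
  offset <- 0L
  for (b in aligned) {
    pb <- length(b$snp_ids)
    if (!pb) next
    rows <- offset + seq_len(pb)
    for (d in seq_along(delta_grid)) {
      fit <- .cd_lassosum_block(b$R, b$r, delta_grid[d], lambda_grid,
                                tol, max_sweeps)
      cols <- (d - 1L) * length(lambda_grid) + seq_along(lambda_grid)
      betas[rows, cols] <- fit$betas
      diverged[cols] <- diverged[cols] | fit$diverged
      objective[cols] <- objective[cols] + fit$objective
    }
    offset <- offset + pb
  }
  grid$diverged <- diverged
  grid$objective <- objective
  structure(list(snp_ids = unlist(lapply(aligned, `[[`, "snp_ids")),
                 grid = grid, betas = betas,
                 population = attr(ss, "population")),
            class = "maprs_lassosum")
}

#' Score a standardized panel with one or more SNP-weight vectors
#'
#' @param panel a standardized [genotype_panel()].
#' @param snp_ids SNP ids the rows of `beta` refer to.
#' @param beta numeric vector or matrix (SNPs x models).
#' @return Score matrix (samples x models). SNPs absent from the panel are
#'   dropped from scoring.
#' @export
score_panel <- function(panel, snp_ids, beta) {
  if (!panel$standardized) panel <- standardize_panel(panel)
  beta <- as.matrix(beta)
  m <- match(snp_ids, colnames(panel$dosage))
  keep <- which(!is.na(m))
  if (!length(keep)) stop("score_panel: no overlapping SNPs")
  panel$dosage[, m[keep], drop = FALSE] %*% beta[keep, , drop = FALSE]
}

#' Select the reference tuning parameters from a single-ancestry path
#'
#' Scores every non-divergent `(delta, lambda)` candidate on tuning samples
#' and returns the pair maximizing the metric; ties are broken toward the
#' larger lambda (sparser model).
#'
#' @param path a [lassosum_path()] result.
#' @param tuning a [genotype_panel()] of tuning samples.
#' @param phenotype numeric (or 0/1) phenotype vector for the tuning samples.
#' @param metric `"r2"` (squared correlation) or `"auc"`.
#' @return List `delta0`, `lambda0`, `index`, `metric`, `value`, and `beta`
#'   (the selected coefficient vector).
#' @export
select_reference_params <- function(path, tuning, phenotype,
                                    metric = c("r2", "auc")) {
  metric <- match.arg(metric)
  ok <- which(!path$grid$diverged)
  if (!length(ok)) stop("select_reference_params: all fits diverged")
  scores <- score_panel(tuning, path$snp_ids, path$betas[, ok, drop = FALSE])
  vals <- apply(scores, 2, function(s) {
    if (sd(s) < 1e-12) return(if (metric == "r2") 0 else 0.5)
    if (metric == "r2") cor(s, phenotype)^2 else empirical_auc(phenotype, s)
  })
  # argmax with ties toward larger lambda
  best_val <- max(vals)
  cand <- ok[vals >= best_val - 1e-12]
  best <- cand[which.max(path$grid$lambda[cand])]
  list(delta0 = path$grid$delta[best], lambda0 = path$grid$lambda[best],
       index = best, metric = metric, value = best_val,
       beta = path$betas[, best])
}
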