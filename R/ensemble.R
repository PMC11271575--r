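#' Candidate PRS matrix on tuning samples
#'
#' Scores the tuning panel with every non-divergent `(lambda, c, population)`
#' solution of a [joint_lasso_grid()] fit. Each column is the dot product of
#' standardized tuning dosages with one coefficient vector; SNPs absent from
#' the tuning panel are dropped from scoring (count logged as a message).
#'
#' @param joint a `maprs_joint` object.
#' @param tuning a [genotype_panel()] (standardized internally if needed).
#' @return Numeric matrix (samples x candidates) with attribute `"map"`, a
#'   data frame keying each column to its `setting` index and `population`.
#' @export
candidate_prs_matrix <- function(joint, tuning) {
  if (!tuning$standardized) tuning <- standardize_panel(tuning)
  keep_set <- which(!joint$settings$diverged)
  cols <- list(); map <- list()
  for (i in seq_along(joint$populations)) {
    pop <- joint$populations[i]
    ids <- joint$snp_ids[[i]]
    m <- match(ids, colnames(tuning$dosage))
    usable <- which(!is.na(m))
    n_missing <- length(ids) - length(usable)
    if (n_missing)
      message("candidate_prs_matrix: ", n_missing, " SNP(s) of ", pop,
              " absent from tuning panel, dropped from scoring")
    if (!length(usable)) {
      warning("candidate_prs_matrix: no usable SNPs for population ", pop,
              "; its columns omitted")
      next
    }
    S <- tuning$dosage[, m[usable], drop = FALSE] %*%
      joint$betas[[i]][usable, keep_set, drop = FALSE]
    colnames(S) <- paste0("s", keep_set, "_", pop)
    cols[[pop]] <- S
    map[[pop]] <- data.frame(column = colnames(S), setting = keep_set,
                             population = pop, stringsAsFactors = FALSE)
  }
  out <- do.call(cbind, cols)
  if (is.null(out) || !ncol(out)) stop("candidate_prs_matrix: no candidates")
  rownames(out) <- tuning$sample_ids
  if (any(!is.finite(out))) stop("candidate_prs_matrix: non-finite scores")
  attr(out, "map") <- do.call(rbind, c(map, list(make.row.names = FALSE)))
  out
}

# Linear base learners. Each fit returns the coefficients of a linear score
# a + X %*% b on the (standardized) candidate scale; binary learners return
# their linear predictor coefficients, so every learner is linear in X.
fit_base_learner <- function(name, X, y) {
  p <- ncol(X)
  if (name == "ols") {
    fit <- lm.fit(cbind(1, X), y)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    return(list(a = co[1], b = co[-1]))
  }
  if (name == "logistic") {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                           family = stats::binomial()))
    co <- fit$coefficients
    co[is.na(co)] <- 0
    return(list(a = co[1], b = co[-1]))
  }
  family <- if (name %in% c("lasso_bin")) "binomial" else "gaussian"
  alpha <- if (name %in% c("lasso", "lasso_bin")) 1 else 0
  nfolds <- max(3, min(5, floor(nrow(X) / 2)))
  cv <- if (name == "ridge") {
    # ridge penalty path 1 to 20 in steps of 0.1 (on glmnet's lambda scale)
    glmnet::cv.glmnet(X, y, alpha = 0, family = family,
                      lambda = rev(seq(1, 20, by = 0.1)),
                      nfolds = nfolds, standardize = FALSE)
  } else {
    glmnet::cv.glmnet(X, y, alpha = alpha, family = family, nlambda = 100,
                      nfolds = nfolds, standardize = FALSE)
  }
  co <- as.numeric(coef(cv, s = "lambda.min"))
  list(a = co[1], b = co[-1])
}

predict_learner <- function(fit, X) drop(fit$a + X %*% fit$b)

make_folds <- function(y, folds, stratify = FALSE) {
  n <- length(y)
  folds <- max(2, min(folds, n))
  if (stratify) {
    id <- integer(n)
    for (cls in unique(y)) {
      j <- which(y == cls)
      id[j] <- sample(rep(seq_len(folds), length.out = length(j)))
    }
    id
  } else {
    sample(rep(seq_len(folds), length.out = n))
  }
}

# Non-negative least squares meta-weights on out-of-fold predictions,
# normalized to sum to one (super-learner convention).
meta_nnls <- function(Z, y) {
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  w <- pracma::lsqnonneg(Zc, yc)$x
  if (sum(w) > 0) w / sum(w) else rep(1 / ncol(Z), ncol(Z))
}

# Simplex grid search maximizing the cross-validated AUC of the combined
# out-of-fold linear predictors.
meta_auc <- function(Z, y, step = 0.02) {
  L <- ncol(Z)
  if (L == 1) return(1)
  grid <- seq(0, 1, by = step)
  best_w <- rep(1 / L, L); best_auc <- -Inf
  combos <- if (L == 2) lapply(grid, function(g) c(g, 1 - g)) else {
    out <- list()
    for (g1 in grid) for (g2 in seq(0, 1 - g1, by = step))
      out[[length(out) + 1]] <- c(g1, g2, 1 - g1 - g2)
    out
  }
  for (w in combos) {
    a <- empirical_auc(y, drop(Z %*% w))
    if (a > best_auc) { best_auc <- a; best_w <- w }
  }
  best_w
}

#' Combine candidate PRSs with a cross-validated super learner
#'
#' Stacks linear base learners fitted to the candidate PRS matrix:
#' for continuous traits, lasso (100-value glmnet path), ridge (penalty path
#' 1 to 20 in steps of 0.1) and ordinary least squares, with meta-weights
#' from non-negative least squares on the out-of-fold predictions; for binary
#' traits, lasso and a linear (logistic-link) model, with meta-weights
#' maximizing the out-of-fold AUC over a simplex grid. All base learners are
#' linear in the candidates, so the stack collapses to effective per-candidate
#' weights.
#'
#' @param candidates matrix from [candidate_prs_matrix()].
#' @param phenotype numeric (continuous) or 0/1 (binary) outcome for the
#'   candidate rows.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param folds cross-validation folds (default 10; stratified for binary).
#' @param seed fold seed (recorded on the result).
#' @return A `maprs_ensemble` object: `weights` (effective per-candidate
#'   weights on the original candidate scale), `intercept`, `meta_weights`,
#'   `learners`, `fitted` (in-sample stacked score), `map`, `folds`, `seed`.
#' @export
superlearn_combine <- function(candidates, phenotype,
                               trait_type = c("continuous", "binary"),
                               folds = 10, seed = NULL) {
  trait_type <- match.arg(trait_type)
  X_all <- as.matrix(candidates)
  n <- nrow(X_all)
  stopifnot(length(phenotype) == n)
  if (ncol(X_all) > n)
    warning("superlearn_combine: more candidates (", ncol(X_all),
            ") than tuning samples (", n, "); penalized learners are used ",
            "but overfitting is likely - a tuning set of 1000-3000 samples ",
            "per ~500 candidates is recommended")
  if (!is.null(seed)) set.seed(seed)

  # deduplicate exactly repeated columns and drop constant ones before fitting
  keep <- which(apply(X_all, 2, sd) > 1e-12)
  dup <- keep[duplicated(as.data.frame(t(X_all[, keep, drop = FALSE])))]
  keep <- setdiff(keep, dup)
  if (!length(keep)) {
    w <- setNames(numeric(ncol(X_all)), colnames(X_all))
    return(structure(list(weights = w, intercept = mean(phenotype),
                          meta_weights = NULL, learners = NULL,
                          fitted = rep(mean(phenotype), n),
                          map = attr(candidates, "map"),
                          folds = folds, seed = seed, trait_type = trait_type),
                     class = "maprs_ensemble"))
  }
  X <- X_all[, keep, drop = FALSE]
  mu <- colMeans(X); sds <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")

  learner_names <- if (trait_type == "continuous")
    c("lasso", "ridge", "ols") else c("lasso_bin", "logistic")
  fold_id <- make_folds(phenotype, folds, stratify = trait_type == "binary")

  Z <- matrix(NA_real_, n, length(learner_names),
              dimnames = list(NULL, learner_names))
  for (f in sort(unique(fold_id))) {
    tr <- fold_id != f
    for (l in learner_names) {
      fit <- fit_base_learner(l, Xs[tr, , drop = FALSE], phenotype[tr])
      Z[!tr, l] <- predict_learner(fit, Xs[!tr, , drop = FALSE])
    }
  }
  meta <- if (trait_type == "continuous") meta_nnls(Z, phenotype)
          else meta_auc(Z, phenotype)
  names(meta) <- learner_names

  full_fits <- lapply(setNames(learner_names, learner_names),
                      function(l) fit_base_learner(l, Xs, phenotype))
  b_std <- Reduce(`+`, Map(function(w, f) w * f$b, meta, full_fits))
  a <- sum(unlist(Map(function(w, f) w * f$a, meta, full_fits)))
  # back-transform from standardized candidate columns to the original scale
  b_orig <- b_std / sds
  intercept <- a - sum(b_std * mu / sds)
  weights <- setNames(numeric(ncol(X_all)), colnames(X_all))
  weights[keep] <- b_orig

  structure(list(weights = weights, intercept = intercept,
                 meta_weights = meta, learners = full_fits,
                 fitted = drop(X_all %*% weights) + intercept,
                 map = attr(candidates, "map"),
                 folds = folds, seed = seed, trait_type = trait_type),
            class = "maprs_ensemble")
}

#' @method print maprs_ensemble
#' @export
print.maprs_ensemble <- function(x, ...) {
  cat("maprs_ensemble:", length(x$weights), "candidates,",
      sum(x$weights != 0), "with nonzero weight; meta weights:\n")
  print(round(x$meta_weights, 4))
  invisible(x)
}

#' Collapse ensemble weights to a single per-SNP weight table
#'
#' The stacked score is linear in the candidates and each candidate is linear
#' in the genotypes, so the final per-SNP weight is
#' `sum over (lambda, c, population) of w_{lambda,c,pop} * beta_{lambda,c,pop,k}`.
#' Scoring standardized genotypes with the collapsed weights reproduces the
#' stacked score minus its intercept.
#'
#' @param model a `maprs_ensemble` from [superlearn_combine()].
#' @param joint the `maprs_joint` the candidates were computed from.
#' @return Weight table data frame (`snp_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `weight`) over the union of population SNP sets, with the ensemble
#'   intercept as attribute `"intercept"`.
#' @export
collapse_weights <- function(model, joint) {
  map <- model$map
  snps <- do.call(rbind, joint$snps)
  snps <- snps[!duplicated(snps$snp_id), , drop = FALSE]
  w <- setNames(numeric(nrow(snps)), snps$snp_id)
  for (i in seq_along(joint$populations)) {
    pop <- joint$populations[i]
    rows <- map[map$population == pop, , drop = FALSE]
    if (!nrow(rows)) next
    wv <- model$weights[rows$column]
    if (all(wv == 0)) next
    contrib <- joint$betas[[i]][, rows$setting, drop = FALSE] %*% wv
    w[joint$snp_ids[[i]]] <- w[joint$snp_ids[[i]]] + drop(contrib)
  }
  out <- data.frame(snps, weight = unname(w), row.names = NULL)
  attr(out, "intercept") <- model$intercept
  out
}

#' Weighted-PRS baseline: linear combination of single-ancestry PRSs
#'
#' Ordinary least squares of the phenotype on one optimal single-ancestry PRS
#' per population (with intercept), the classical weighted-PRS multi-ancestry
#' baseline. Collinear columns get zero weight with a warning.
#'
#' @param prs_by_pop matrix (samples x populations) of single-ancestry scores.
#' @param phenotype outcome vector.
#' @return List `weights` (per population), `intercept`, `score` (combined).
#' @export
weighted_prs_baseline <- function(prs_by_pop, phenotype) {
  X <- as.matrix(prs_by_pop)
  fit <- lm.fit(cbind(1, X), phenotype)
  co <- fit$coefficients
  if (anyNA(co)) {
    warning("weighted_prs_baseline: collinear PRS columns; dropped from fit")
    co[is.na(co)] <- 0
  }
  list(weights = setNames(co[-1], colnames(X)), intercept = co[1],
       score = drop(X %*% co[-1]) + co[1])
}
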