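#' Run the full multi-ancestry PRS pipeline
#'
#' Orchestrates the three stages on either synthetic or file-based inputs:
#' (1) single-ancestry lassosum-style paths per population, tuned on the
#' target population's tuning samples to obtain the reference parameters
#' `(delta0, lambda0)`; (2) the joint cross-population penalty grid;
#' (3) the super-learning ensemble collapsed to final per-SNP weights, plus
#' the weighted-PRS baseline; followed by evaluation on validation samples.
#'
#' `config` is a list with either
#' \describe{
#'   \item{`sim`}{a [sim_config()]: all inputs are generated (GWAS summary
#'     statistics by direct sampling; tuning/validation cohorts for the
#'     target population).}
#'   \item{file inputs}{`sumstats` (named vector of paths), `ld_prefix`
#'     (named vector of PLINK prefixes for LD reference panels), `blocks`
#'     (BED-like data frame or path), `tuning_prefix`, `validation_prefix`
#'     (PLINK prefixes), `phenotype` (path to a tab-delimited table
#'     `sample_id`, `phenotype`, covariates...).}
#' }
#' plus `target` (target population label), optional `grid_length` (10),
#' `trait_type` (`"continuous"`), `folds` (10), and `seed`.
#'
#' @param config configuration list (see Details).
#' @param out_dir optional directory; when given, final weights, the manifest
#'   and per-stage artifacts are written there.
#' @return List with `weights` (collapsed weight table), `ensemble`, `joint`,
#'   `ref_params`, `baseline` (weighted PRS), `metrics`, and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  seed <- config$seed %||% 1L
  grid_length <- config$grid_length %||% 10
  trait_type <- config$trait_type %||% "continuous"
  folds <- config$folds %||% 10
  target <- config$target
  manifest <- list(config = config[setdiff(names(config), "sim")],
                   seed = seed, version = as.character(utils::packageVersion("maprs")),
                   stages = list())

  t0 <- Sys.time()
  if (!is.null(config$sim)) {
    sc <- config$sim
    if (is.null(target)) target <- sc$populations[sc$M]
    if (!(target %in% sc$populations))
      stop("run_pipeline: unknown target population")
    set.seed(seed)
    truth <- simulate_effects(sc, seed = seed)
    ld <- gen_ld_blocks(sc, truth$snp_map)
    ss <- lapply(seq_len(sc$M), function(i)
      simulate_sumstats(truth, ld[[i]], sc$populations[i], sc$n_gwas[i],
                        seed = seed + i))
    tune <- simulate_cohort(truth, ld[[target]], target, sc$n_tune,
                            seed = seed + 101L)
    valid <- simulate_cohort(truth, ld[[target]], target, sc$n_valid,
                             seed = seed + 202L)
    tuning_panel <- tune$panel
    tuning_pheno <- tune$phenotype
    validation_panel <- valid$panel
    validation_pheno <- valid$phenotype
    manifest$stages$simulate <- list(populations = sc$populations,
                                     causal = length(truth$causal_ids))
  } else {
    if (is.null(config$sumstats) || is.null(config$ld_prefix))
      stop("run_pipeline: stage 'lassosum' prerequisite missing: ",
           "sumstats and ld_prefix are required")
    if (is.null(config$tuning_prefix) || is.null(config$phenotype))
      stop("run_pipeline: stage 'ensemble' prerequisite missing: ",
           "tuning fileset and phenotype table are required")
    blocks <- config$blocks
    if (is.character(blocks))
      blocks <- read.table(blocks, header = FALSE,
                           col.names = c("chrom", "start", "end"))
    pops <- names(config$sumstats)
    ld_panels <- lapply(pops, function(p)
      read_genotypes(config$ld_prefix[[p]]))
    ld <- setNames(lapply(seq_along(pops), function(i)
      compute_block_ld(ld_panels[[i]], blocks, population = pops[i])), pops)
    ref_meta <- do.call(rbind, lapply(ld_panels, function(pn)
      pn$snps[c("snp_id", "chrom", "pos", "a1", "a2")]))
    ref_meta <- ref_meta[!duplicated(ref_meta$snp_id), ]
    ss <- lapply(pops, function(p)
      read_sumstats(config$sumstats[[p]], p, ref_meta,
                    col_map = config$col_map))
    tuning_panel <- read_genotypes(config$tuning_prefix)
    pheno_tab <- read.table(config$phenotype, header = TRUE,
                            stringsAsFactors = FALSE)
    m <- match(tuning_panel$sample_ids, pheno_tab$sample_id)
    tuning_pheno <- pheno_tab[m, , drop = FALSE]
    if (!is.null(config$validation_prefix)) {
      validation_panel <- read_genotypes(config$validation_prefix)
      m <- match(validation_panel$sample_ids, pheno_tab$sample_id)
      validation_pheno <- pheno_tab[m, , drop = FALSE]
    } else validation_panel <- validation_pheno <- NULL
    if (is.null(target)) target <- pops[length(pops)]
  }
  pops <- vapply(ss, function(s) attr(s, "population"), "")
  if (!(target %in% pops)) stop("run_pipeline: unknown target population")

  # stage 1: single-ancestry paths, reference parameters tuned on the target
  metric <- if (trait_type == "binary") "auc" else "r2"
  tuning_std <- standardize_panel(tuning_panel)
  covar_cols <- setdiff(names(tuning_pheno), c("sample_id", "phenotype"))
  paths <- lapply(seq_along(pops), function(i) lassosum_path(ss[[i]], ld[[i]]))
  ref_params <- lapply(paths, select_reference_params, tuning = tuning_std,
                       phenotype = tuning_pheno$phenotype, metric = metric)
  names(ref_params) <- pops
  manifest$stages$lassosum <- list(
    delta0 = vapply(ref_params, `[[`, 0, "delta0"),
    lambda0 = vapply(ref_params, `[[`, 0, "lambda0"))

  # stage 2: joint cross-population penalty grid
  joint <- joint_lasso_grid(ss, ld, ref_params, grid_length = grid_length,
                            r_scale = config$r_scale %||% 1,
                            flagged_pop = config$flagged_pop)
  manifest$stages$joint <- list(settings = nrow(joint$settings),
                                flagged = sum(joint$settings$diverged))

  # stage 3: ensemble + weighted-PRS baseline
  candidates <- candidate_prs_matrix(joint, tuning_std)
  ensemble <- superlearn_combine(candidates, tuning_pheno$phenotype,
                                 trait_type = trait_type, folds = folds,
                                 seed = seed + 303L)
  weights <- collapse_weights(ensemble, joint)
  single_prs <- vapply(seq_along(pops), function(i)
    drop(score_panel(tuning_std, paths[[i]]$snp_ids, ref_params[[i]]$beta)),
    numeric(nrow(tuning_std$dosage)))
  colnames(single_prs) <- pops
  baseline <- weighted_prs_baseline(single_prs, tuning_pheno$phenotype)
  manifest$stages$ensemble <- list(candidates = ncol(candidates),
                                   fold_seed = ensemble$seed,
                                   meta_weights = as.list(ensemble$meta_weights))

  # evaluation on validation samples
  metrics <- NULL
  if (!is.null(validation_panel)) {
    valid_std <- standardize_panel(validation_panel)
    final_score <- drop(score_panel(valid_std, weights$snp_id, weights$weight))
    ti <- which(pops == target)
    single_score <- drop(score_panel(valid_std, paths[[ti]]$snp_ids,
                                     ref_params[[ti]]$beta))
    vc <- if (length(covar_cols)) validation_pheno[covar_cols] else NULL
    if (trait_type == "binary") {
      metrics <- list(
        auc = empirical_auc(validation_pheno$phenotype, final_score),
        auc_single_ancestry = empirical_auc(validation_pheno$phenotype,
                                            single_score))
    } else {
      r2 <- residualized_r2(validation_pheno$phenotype, vc, final_score)
      r2_single <- residualized_r2(validation_pheno$phenotype, vc, single_score)
      metrics <- list(r2 = r2, r2_single_ancestry = r2_single,
                      relative_improvement =
                        if (r2_single > 0) relative_improvement(r2, r2_single)
                        else NA_real_)
    }
    manifest$stages$evaluate <- metrics
  }
  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wpath <- file.path(out_dir, "final_weights.tsv")
    write_weights(weights, wpath)
    manifest$outputs <- list(final_weights = list(
      path = wpath, md5 = tools::md5sum(wpath)[[1]]))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(weights = weights, ensemble = ensemble, joint = joint,
       ref_params = ref_params, baseline = baseline, metrics = metrics,
       manifest = manifest)
}
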