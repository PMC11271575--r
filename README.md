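# maprs — multi-ancestry polygenic risk scores

`maprs` builds polygenic risk scores (PRSs) for a target population by
**jointly** modelling GWAS summary statistics from several populations. Most
PRS training data is European-ancestry; scores trained on one ancestry
transfer poorly to others because linkage disequilibrium (LD), allele
frequencies and GWAS sample sizes differ. `maprs` lets an underpowered
target GWAS borrow strength from larger auxiliary GWAS without assuming
effect sizes are identical across ancestries.

## Method in one paragraph

For each population *i* with standardized marginal effects *r*<sub>i</sub>
and block-diagonal LD matrix *R*<sub>i</sub>, `maprs` minimizes

> Σ<sub>i</sub> [ β<sub>i</sub>ᵀ(R<sub>i</sub> + δ<sub>i</sub>I)β<sub>i</sub> − 2 β<sub>i</sub>ᵀr<sub>i</sub> + 2 λ<sub>i</sub>‖β<sub>i</sub>‖₁ ] + Σ<sub>i₁&lt;i₂</sub> c<sub>i₁i₂</sub> ‖β<sub>i₁</sub>ˢ − β<sub>i₂</sub>ˢ‖₂²

by coordinate descent (C++ core): a per-population lasso keeps each score
sparse, and a cross-population ridge penalty on effect-size *differences*
(over shared SNPs; population-specific SNPs feel only the lasso) couples the
populations. Tuning is kept tractable by anchoring (δ<sub>i</sub>,
λ<sub>i</sub>) to a single-ancestry lassosum-style reference fit and
searching only a 10 × 10 grid over a common λ scale factor and the coupling
c. Finally, *all* grid solutions for *all* populations are scored on a
target-population tuning cohort and combined by a cross-validated super
learner (lasso + ridge + ordinary least squares, non-negative meta-weights;
AUC-optimal stacking for binary traits). Because every stage is linear, the
whole ensemble collapses to a single per-SNP weight table.

See `vignette("multi-ancestry-prs")` for the full model, parameter
rationale, and the simulator's design.

## Quick start

The package ships a first-class synthetic data generator, so a full run
needs nothing external. Two populations, 2000 SNPs in 100-SNP LD blocks,
dense signal (25% causal, h² = 0.4, cross-ancestry effect correlation 0.8),
a well-powered auxiliary GWAS (n = 20 000) and a small target GWAS
(n = 1 500):

```r
library(maprs)

sc <- sim_config(M = 2, p = 2000, block_size = 100, p_causal = 0.25,
                 h2 = 0.4, rho_effect = 0.8, n_gwas = c(20000, 1500),
                 n_tune = 3000, n_valid = 3000, seed = 1)
res <- run_pipeline(list(sim = sc, seed = 1))

print(res$joint)
#> maprs_joint: 2 populations x 100 penalty settings ( 0 flagged )
print(res$ensemble)
#> maprs_ensemble: 200 candidates, 200 with nonzero weight; meta weights:
#>  lasso  ridge    ols
#> 0.7612 0.1460 0.0928
head(res$weights)
#>     snp_id chrom  pos a1 a2        weight
#> 1 rs000001     1 1000  A  G  0.0021942850
#> 2 rs000002     1 2000  A  G  0.0011987441
#> 3 rs000003     1 3000  A  G  0.0082812872
#> 4 rs000004     1 4000  A  G  0.0008467317
#> 5 rs000005     1 5000  A  G -0.0035072881
#> 6 rs000006     1 6000  A  G -0.0020341907
res$metrics
#> joint R2 = 0.292   single-ancestry R2 = 0.189   relative gain = 54.4%
```

(Output from an actual run, ~30 s on one desktop core.) The joint model
beats the target-only lassosum-style score by 54% here because the target
GWAS is power-limited; when the target GWAS is already saturated the two
match and the gain is ~0.

## Real-data workflow

Each stage is also exposed as a function and a CLI subcommand
(`inst/cli/maprs`):

```sh
maprs ld       --bfile ref_EUR --blocks blocks.bed --out ld_EUR --population EUR
maprs lassosum --sumstats gwas_EUR.tsv --ld ld_EUR --tuning tune --pheno pheno.tsv --out eur
maprs run      --config config.json --out results/
maprs evaluate --weights results/final_weights.tsv --bfile valid --pheno pheno.tsv --out eval.json
```

File formats: PLINK 1 `.bed/.bim/.fam` genotypes, tab-delimited summary
statistics (`snp_id chrom pos a1 a2 r|z n freq`, arbitrary column names via
`col_map`), BED-style LD block intervals. Harmonization
(`read_sumstats()`) drops strand-ambiguous SNPs, resolves strand flips and
reversed alleles (negating effects), and reports counts. Final weights are
written at full precision with an md5-checksummed manifest.

## Tests

```r
testthat::test_dir("tests/testthat", package = "maprs", load_package = "installed")
```

The suite is oracle- and property-based: the coordinate-descent solver is
checked against an independent L-BFGS-B minimizer on random instances with
Karush–Kuhn–Tucker certificates at every coordinate, limiting cases reduce
to closed forms (c = 0 → single-ancestry lasso, R = I → soft-thresholding,
c → ∞ → fused pooled solution), the objective descends monotonically on
every grid cell, and the collapsed weight table reproduces the stacked
ensemble score on held-out samples. `tests/testthat/test-acceptance.R`
carries the end-to-end acceptance criteria; one directional-recovery
criterion pinned to a saturated-regime configuration is a known failure:
the target GWAS there is powerful enough that the single-ancestry score
already sits at R² ≈ 0.39 against the h² = 0.4 ceiling, leaving no headroom,
and the equivalent power-limited check passes in `test-pipeline.R`.
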