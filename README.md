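# eigensurv

Integrative methylation–expression network modules for survival risk
stratification in AML-like cohorts.

## The problem

Gene-coexpression network analysis summarizes transcriptome-wide structure
into a small number of gene *modules*, each represented by an *eigengene* —
the first principal component of the module's standardized expression.
Eigengenes are robust *n*-of-thousands biomarkers and natural covariates for
survival models. In myeloid malignancies, DNA methylation carries prognostic
signal that expression alone misses; `eigensurv` builds the network from
**both** platforms, so that modules are coherent in expression *and*
methylation, while eigengenes remain expression-only — which is exactly what
lets a trained model score validation cohorts that have no methylation data.

The pipeline:

1. **Preprocess** — optional `ln(x + offset)` on expression; drop features
   with low variance, excess missingness, or `|r| < τ` Pearson correlation
   with overall survival (default `τ = 0.2`); aggregate each gene's retained
   methylation loci into an *effective gene methylation* value (mean over
   loci); keep the union of genes relevant on either platform.
2. **Network** — per-platform pairwise Pearson correlations on each
   platform's full sample set; combined similarity
   `s_ij = w·|r_expr| + (1−w)·|r_meth|` (default `w = 0.5`; pairs missing one
   platform fall back to the other); soft-power adjacency `a = s^β`
   (default `β = 6`).
3. **Modules** — average-linkage hierarchical clustering of `1 − a` with an
   adaptive (largest merge-height gap) or static cut; clusters smaller than
   `min_module_size` become background.
4. **Eigengenes** — per-module first principal component of standardized
   expression, sign-oriented to the module mean profile; unit-norm gene
   weight vectors are stored so new cohorts can be *projected*.
5. **Prognosis** — L1-penalized Cox regression on the eigengenes
   (cross-validated penalty, seeded folds) selects the prognostic modules; a
   log-normal accelerated failure time model
   `log T = μ + Σ β_k E_k + σ ε` predicts each patient's expected survival
   time; tertile cutpoints of training predictions stratify patients into
   low / intermediate / high risk.
6. **Evaluation** — Kaplan–Meier curves, log-rank tests, hypergeometric
   tests, chi-square/p conversion, multiple-testing adjustment, risk-group
   cross-tabulation.

A synthetic-cohort generator (`generate_cohort()`) plants modules via shared
latent factors that drive expression (loading `ρ_expr`), locus-level
methylation (loading `ρ_meth`, anticorrelated by default) and survival
through the same AFT law, with right censoring by a uniform horizon — so
every stage can be validated against ground truth.

## Worked example

```r
library(eigensurv)

co  <- generate_cohort(simulation_config(seed = 1))   # 600 genes, 10 planted modules, n = 200
res <- run_pipeline(unclass(co$expression), co$clinical,
                    unclass(co$methylation), co$probe_map,
                    config = run_config(seed = 1))
#> preprocess: 72/600 genes retained (63 expression-pass, 70 methylation-pass)
#> modules: 2 modules detected (12 background genes)
#> select: M1, M2

table(res$risk$risk_class)
#>          low intermediate         high
#>           67           66           67

res$report$tests$logrank_low_vs_high$p
#> 4.62e-36

adjusted_rand_index(res$assignment$labels[names(co$truth$labels)], co$truth$labels)
#> 0.985
```

Reading this: only the two *prognostic* planted modules (and a few
background genes) survive the survival-correlation filter — the eight
non-prognostic modules are, by construction, irrelevant to survival. The
two modules are recovered essentially perfectly (ARI 0.985 against planted
truth, background included), the lasso-Cox step selects both, and the
AFT-based tertile stratification separates low- from high-risk patients at
log-rank p ≈ 5·10⁻³⁶ — on the training cohort, so treat it as a sanity
check, not an effect estimate; the held-out behaviour is what the
acceptance suite measures (cross-cohort transfer, criterion 7).

Apply the trained model to an expression-only cohort:

```r
coB   <- generate_cohort(simulation_config(seed = 99))
riskB <- apply_risk_model(res$model, unclass(coB$expression))
```

## Command line

```sh
Rscript inst/cli/eigensurv.R simulate --n-genes 600 --seed 1 --out data/
Rscript inst/cli/eigensurv.R run-all --expression data/expression.tsv \
  --methylation data/methylation.tsv --probe-map data/probe_map.tsv \
  --clinical data/clinical.tsv --out run/
Rscript inst/cli/eigensurv.R classify --model run/model.json \
  --expression other_cohort.tsv --out risk.tsv
```

Stage-wise subcommands (`preprocess`, `network`, `modules`, `eigengenes`,
`select`, `evaluate`) exchange artifacts through a `--dir` working
directory; flags mirror `run_config()` fields.

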