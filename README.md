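# regdyn

Dynamic regulatory module networks from paired expression and chromatin
accessibility time courses.

`regdyn` implements an integrative analysis for experiments that profile
both RNA-seq and ATAC-seq over a shared time course (for example, a root
transcriptional response sampled at 0, 0.25, 0.5, 1, 2, 4, 8 and 24
hours). The package covers the full path from per-bp coverage to
regulator–target edges:

1. **Genomic signal** — turn bedGraph coverage into promoter- and
   motif-level accessibility features: per-region mean coverage is
   log-ratioed against the genome-wide mean, summed over motif instances
   in each gene's −10 kbp..+1 kbp window, and quantile-normalized across
   time points. Per-time-point peak calls are merged into *universal
   peaks* (Jaccard ≥ 0.9 or containment) and annotated against TSSs.
2. **Expression modules** — cluster expression at every time point with a
   one-dimensional Gaussian mixture into `k` level modules (labels
   ordered by expression level), extract *transitioning genes* whose
   module changes over time, and cluster their assignment profiles into
   transitioning gene sets under mismatch-fraction distance.
3. **Correlation** — test promoter accessibility against expression per
   gene with a permutation test (add-one estimator; magnitude or directed
   alternative).
4. **DRMN** — jointly learn per-module, per-time sparse regressions of
   expression on accessibility features with a fused penalty across
   consecutive time points (proximal-gradient solver with exact 1-D
   total-variation prox), cross-validate the penalties, filter
   module–regulator edges, and prioritize regulators whose coefficients
   step at the 1→2 h boundary.
5. **MTG-LASSO** — for each transitioning gene set, a multi-task group
   LASSO (block coordinate descent) in which each member gene is a task
   and each motif is a group; significance comes from leave-one-time-out
   selection frequency compared against randomized nulls.

A synthetic-data generator (`simulate_study()`) plants every structure
the stages assume — level modules with a boundary switch, motif features
wired to expression through sparse stepping coefficients, peak scenarios
with known universal answers — so the whole pipeline is testable without
external data. A bundled generic convex-programming oracle
(`inst/oracle/convex_oracle.py`) independently verifies both custom
solvers.

## Worked example

```r
library(regdyn)

# a full synthetic study: expression, features, coverage, peaks, truth
study <- simulate_study(sim_config(seed = 7))

# expression modules per time point (GMM with multi-start EM)
fit <- fit_modules(study$expr, k = 7, seed = 7)
tidy(fit)
#> # A tibble: 4,000 x 3
#>   gene_id  time module
#>   <chr>   <dbl>  <int>
#> 1 g0001       0      6
#> ...

# transitioning genes and sets
moving <- find_transitioning_genes(fit)
sets <- cluster_transitioning(fit$assignments[moving, ], 
                              distance_threshold = 0.26, min_size = 10)
glance(sets)
#> # A tibble: 1 x 5
#>   n_sets n_genes n_discarded distance_threshold min_size
#> 1      4     100           2               0.26       10

# DRMN: fused-lasso regression of expression on motif features
dr <- fit_drmn(study$expr, study$features, k = 7,
               hyper = drmn_hyper(rho1 = 5, rho2 = 45, rho3 = 0),
               modules = fit$assignments, seed = 1)
autoplot(dr, modules = 1:2)          # coefficient heatmap
cross_validate_drmn(study$expr, study$features, k = 7,
                    hyper = drmn_hyper(5, 45, 0),
                    modules = fit$assignments, seed = 1)$mean_cor
#> [1] 0.84

# MTG-LASSO on one transitioning set (centered: the shared module-mean
# trajectory is removed so motif-driven deviations are the target)
genes <- sets$sets$gene_id[sets$sets$set_id == "set001"]
set <- mtg_set_data(genes, study$expr, study$features,
                    set_id = "set001", center = TRUE)
null_selection(set, lambda = 0.5, n_random = 40, seed = 1)
```

Or run everything at once against a study directory:

```r
dir <- tempfile(); out <- tempfile()
write_study(study, dir)
config <- pipeline_config(dir, out, seed = 7)
manifest <- run_pipeline(config)
# out/ now holds promoter_signal.tsv, universal_peaks.tsv, modules.tsv,
# transitioning_sets.tsv, correlation.tsv, drmn_*.tsv, edges.tsv,
# regulator_ranking.tsv and manifest.json (config hash, output md5s,
# per-stage timings, seed registry). Re-running with the same config
# skips completed stages.
```

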