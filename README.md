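# bulkdecon

Bayesian deconvolution of bulk RNA-seq using a labelled scRNA-seq
reference: joint inference of cell type/state fractions **and**
cell-type-specific gene expression in each bulk sample, for cohorts —
typically tumors — where the populations of interest were profiled at
single-cell resolution in only a few patients.

## The model in brief

Each cell state `s` in the reference is a multinomial over genes with
event probabilities `φ_s·` (row-stochastic matrix `φ`, built by summing
labelled single-cell counts and renormalizing with a pseudo-count
floor). Reads of bulk sample `n` are generated by

```
μ_n ~ Dirichlet(α);   R_ns ~ multinomial(μ_n, R_n);   U_ns· ~ multinomial(φ_s·, R_ns)
```

with `X_ng = Σ_s U_nsg`. A per-sample Gibbs sampler draws from the joint
posterior `p(U_n, μ_n | X_n, φ; α)`; posterior means, summed over the
states of each cell type, give the type fractions `θ0` and per-type
expression `Z`. Because `U_n` is estimated per sample, expression
differences between the reference and the bulk are modelled rather than
assumed away — the property that makes the approach robust to batch
effects and to malignant-cell heterogeneity.

Optionally the reference is then *updated* from the cohort: a per-sample
maximum-likelihood profile for the malignant type (`ψ_mal`), and pooled
maximum-a-posteriori profiles for nonmalignant types under a log-normal
fold-change prior centered on the single-cell profile (`ψ_env`, scale
`σ = 2`), after which fractions are re-estimated (`θ_f`). Further
modules learn `K` malignant gene programs by EM with the nonmalignant
blocks held fixed, screen for genes whose malignant expression tracks a
nonmalignant cell fraction (Spearman ranking plus a likelihood-ratio
regress-out filter and a malignant-specificity filter), score
deconvolved expression against signature profiles, and simulate
pseudo-bulk cohorts with known ground truth.

## Worked example

```r
library(bulkdecon)

# a synthetic tumor cohort with known ground truth: 4 cell types, the
# malignant one with 3 states, 30 pseudo-bulks of 50k reads, and
# log-normal noise (sigma = 0.5) between reference and bulk profiles
coh <- simulate_cohort(n_types = 4, states_per_type = c(3, 1, 1, 1),
                       n_genes = 1000, n_samples = 30, depth = 5e4,
                       sigma_noise = 0.5, malignant_type = 1, seed = 11)

res <- deconvolve(coh$bulk, coh$ref, gibbs_config(seed = 11))
benchmark_metrics(res$estimate$theta0, coh$truth$type_fractions)
#>        type pearson_r          mse
#> 1 malignant 0.9998277 1.251828e-05
#> 2     type2 0.9999284 1.014374e-05
#> 3     type3 0.9999507 1.609971e-05
#> 4     type4 0.9997873 1.810818e-05

cor(as.numeric(res$estimate$theta0), as.numeric(res$theta_f))
#> [1] 0.9997589
```

Per cell type, `pearson_r` is the correlation across samples between
estimated and true read fractions and `mse` the mean squared error —
here the fractions are recovered nearly exactly despite the simulated
reference-vs-bulk batch effect. The last line shows that the
reference-updated fractions `θ_f` agree closely with the first-pass
`θ0`. The deconvolved malignant expression per sample is in
`res$updated$psi_mal`; `rank_correlation()`, `regress_out_filter()`,
`malignant_specificity_filter()`, `signature_score()`, `nmf_init()` and
`fit_embedding()` take it from there. The same workflow is available
from a shell via `inst/cli/bulkdecon`
(`simulate / deconvolve / update / embed / correlate / score`).

See `vignettes/bulk-deconvolution.Rmd` for the model, priors, numerical
choices, and what the synthetic benchmarks do and do not demonstrate.

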