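# assemblage

Infers the ecological processes that assemble microbial communities —
selection, dispersal, drift — from OTU count tables and phylogenies, the
question behind rare-biosphere surveys of disturbed habitats (e.g. cave
rock surfaces in resistant, impacted and recovering states, sampled per
domain of life).

For microbial ecologists with rarefied OTU × sample tables, a rooted tree
over the OTUs, and sample metadata, the package provides the full chain:

* **Abundance categories** — always-rare (< 0.01% everywhere),
  conditionally rare, moderate, dominant (≥ 1%), via `classify_otus()`.
* **Sloan's neutral community model** — occurrence frequency vs mean
  relative abundance,
  `Freq_i = 1 − I_{1/N}(N m p_i, N m (1 − p_i))`,
  fitted by nonlinear least squares for the migration rate *m*
  (`fit_ncm()`), with Wilson score bands, generalized R², and
  AIC/BIC bootstrap competition against binomial and Poisson
  pure-sampling models (`compare_models()`).
* **Phylogenetic null models** — abundance-weighted βMNTD and its
  standardized effect size βNTI under a taxa-shuffle null
  (`beta_mntd()`, `beta_nti()`), and the Bray-Curtis Raup-Crick metric
  RC_bray under a richness- and abundance-preserving assembly null
  (`rc_bray()`).
* **Process partition** — per sample pair: βNTI > 2 heterogeneous
  selection, βNTI < −2 homogeneous selection, else RC > 0.95 dispersal
  limitation, RC < −0.95 homogenizing dispersal, else undominated
  (`partition_processes()`, `aggregate_partition()`).
* **Disturbance scenarios** — the deterministic-fraction trajectory across
  (resistant, impacted, resilient) mapped to four conceptual scenarios
  (`assign_scenario()`).
* **A known-truth simulator** — neutral Moran dynamics, Gaussian
  trait–environment filtering on a Brownian trait, patch-structured
  founder limitation, and a full study-like dataset generator
  (`make_study_like_dataset()`), so every estimator is validated against
  data whose generating process is known.

`run_full_analysis()` orchestrates everything per condition group ×
abundance category; results are tibbles throughout, fitted objects have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

Simulate 20 neutral local communities (N = 1000 individuals, migration
rate m = 0.1) from a log-series metacommunity of 300 OTUs, fit the neutral
model, and partition assembly processes against a simulated phylogeny:

```r
library(assemblage)

meta <- simulate_metacommunity(300, seed = 1)
cm   <- simulate_neutral_local(meta, n_samples = 20, N = 1000, m = 0.1, seed = 2)

fit <- fit_ncm(cm, N = 1000)
fit
#> Sloan neutral community model fit
#>   m = 0.128, N = 1000 (detection threshold 1/N = 0.001)
#>   generalized R-squared = 0.9184 over 276 OTUs, 20 samples
#>   AIC = -531.31, BIC = -524.07
#>   OTUs above/within/below the 95% Wilson band: 23/241/12

tree <- simulate_tree(300, seed = 3)
pr   <- assembly_processes(cm, tree, n_null = 199, seed = 4)
aggregate_partition(pr)
#> # A tibble: 1 × 8
#>   n_pairs heterogeneous_selection homogeneous_selection dispersal_limitation
#>     <int>                   <dbl>                 <dbl>                <dbl>
#> 1     190                  0.0947                0.0158                0.821
#> # ℹ 4 more variables: homogenizing_dispersal <dbl>, undominated <dbl>,
#> #   deterministic_total <dbl>, stochastic_total <dbl>
```

Reading the output: the fitted migration rate 0.128 recovers the simulated
truth of 0.1 (the estimator's modest upward bias is characterised in the
methods vignette), with R² = 0.92 — the neutral curve explains the
occurrence-frequency relationship well. The pairwise partition attributes
most turnover (82% of the 190 sample pairs) to dispersal limitation:
at this low migration rate communities drift apart faster than the
occupancy-preserving null expects, while selection-type classifications
stay near the null's false-positive background. `autoplot(fit)` draws the
occurrence-frequency curve with its Wilson band; `plot_partition()` draws
stacked process fractions.

For the full survey-style analysis see `run_full_analysis()` and the
methods vignette (`vignettes/community-assembly.Rmd`).

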