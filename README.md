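# nichecompare

Comparative statistical analysis of bacterial communities across oral
sampling niches — supragingival plaque, buccal mucosa, tongue dorsum mucosa
and stimulated saliva — in repeated-measures animal studies (14 dogs
sampled on 3 occasions, with duplicate left/right swabs for plaque and
buccal mucosa). The package takes an OTU-by-sample read count table with
sample metadata and taxon annotations and carries it through the full
analysis chain, for microbiome researchers who want each stage reusable and
testable rather than buried in a one-off script.

## What it computes

* **Preprocessing** — exclusion of samples with fewer than 1000 reads
  (strict inequality) and pooling of rare OTUs (mean proportion below 0.05%
  in every niche, or present in fewer than two samples) into one `RARE`
  unit.
* **Differential abundance** — per-unit binomial GLMM with logit link,

  `logit p = beta[niche] + u[dog] + v[occasion]`,  `u ~ N(0, s2_dog)`, `v ~ N(0, s2_day)`,

  fitted by a Laplace approximation with a weak stabilizing penalty
  (sd 10) on the fixed effects; six pairwise niche odds ratios with Wald
  CIs; p-values from within-animal label permutation (add-one estimator
  over the refitted Wald statistics); Benjamini–Hochberg adjustment across
  units within each niche-pair family. The same machinery applies at the
  phylum, Gram-stain and oxygen-requirement levels via count aggregation.
* **Diversity** — per-sample Shannon index and a Gaussian linear mixed
  model (`lme4`) with niche fixed effect and crossed dog/occasion random
  intercepts.
* **Ordination** — multi-group (dog-centred) PCA of log10 proportions with
  per-niche 95% confidence ellipses.
* **Niche sets** — UpSet-style exclusive intersections of per-niche
  presence (mean proportion strictly above 0.5%) and core microbiota at an
  inclusive 0.5% detection threshold with 100/75/50% prevalence.
* **Synthetic data** — a seeded Dirichlet-multinomial generator reproducing
  the study design (251 collected / 243 sequenced / 238 analysed samples)
  with exported ground truth, so calibration and power are verifiable.

## Worked example

```r
library(nichecompare)

sim <- simulate_dataset(sim_config(), seed = 1)
summarize_design(sim$samples)
#>   niche collected sequenced qc_pass
#>  plaque        84        84      82
#>  buccal        84        82      82
#>  tongue        42        36      35
#>  saliva        41        41      39
#>   total       251       243     238

pp <- preprocess(sim$counts, sim$samples, sim$taxa)
pp$report
#> Filter report: 5 sample(s) excluded, 18 rare OTU(s) pooled, 207 analysis units

fit <- fit_binomial_glmm(as.integer(pp$counts["OTU0012", ]),
                         colSums(pp$counts), pp$samples)
fit
#> Binomial logit GLMM (Laplace), niche fixed effect, crossed dog/day random intercepts
#>   var_dog = 0.1806, var_day = 0.007656, logLik = -420691.42
#>   niche log_odds mean_proportion     ci_lo     ci_hi
#>  plaque   -2.532       7.361e-02 5.863e-02 9.206e-02
#>  buccal   -4.843       7.825e-03 6.139e-03 9.968e-03
#>  tongue   -4.678       9.215e-03 7.228e-03 1.174e-02
#>  saliva  -15.198       2.509e-07 1.915e-09 3.286e-05

pt <- permutation_test(as.integer(pp$counts["OTU0012", ]), colSums(pp$counts),
                       pp$samples, n_perm = 199, seed = 2)
round(pt$p, 3)
#> plaque-buccal plaque-tongue plaque-saliva buccal-tongue buccal-saliva tongue-saliva
#>         0.005         0.005         0.890         0.755         0.865         0.880
```

This taxon is the dominant plaque organism of the simulation: it sits near
7.4% of plaque reads against under 1% on the mucosal surfaces (odds ratios
around 10 and 8.5), and those two contrasts reach the smallest attainable
permutation p-value at 199 permutations, 1/200 = 0.005. It is effectively
absent from saliva, so the saliva contrasts carry enormous odds ratios with
almost no information — the permutation p-values near 1 show the
separation-penalized Wald statistics carry no evidence, exactly the
situation the permutation layer exists to guard against.

```r
H <- shannon_samples(to_proportions(pp$counts))
diversity_lmm(H, pp$samples)
#>   niche   mean  ci_lo  ci_hi
#>  plaque 4.2336 4.1619 4.3054
#>  buccal 3.5933 3.5216 3.6651
#>  tongue 3.5017 3.4136 3.5898
#>  saliva 0.8527 0.7674 0.9381
```

Plaque is the most diverse niche, the two mucosal surfaces sit together,
and saliva — built to be extremely variable between samples — is by far the
least diverse, with every plaque and saliva contrast significant.

`diff_abundance()` runs the GLMM + permutation machinery over all units and
`pairwise_summary()` tabulates the significant counts per niche pair;
`multigroup_pca()`, `upset_membership()` and `core_microbiota()` cover the
ordination and set-based analyses. The methods vignette
(`vignettes/niche-comparison-methods.Rmd`) documents the models,
assumptions and numerical choices.

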