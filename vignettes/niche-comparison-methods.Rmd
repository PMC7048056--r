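---
title: "Models and methods for oral niche comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for oral niche comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecompare)
```

# The problem

Repeated-measures 16S amplicon studies of the canine mouth sample several
oral niches — supragingival plaque, buccal mucosa, tongue dorsum mucosa and
stimulated saliva — from the same animals on several occasions, with
duplicate left/right swabs for plaque and buccal mucosa. The analysis
questions are: which taxa differ in relative abundance between niches, how
diversity differs, whether samples cluster by niche once between-animal
variation is removed, which taxa are shared between niches, and which form a
core community. nichecompare implements this analysis chain from the OTU
count table onward, together with a generative simulator so every stage is
testable with known ground truth.

# Data model and preprocessing

The pipeline consumes an OTU-by-sample matrix of read counts
(`count_table()`), per-sample metadata (dog, niche, occasion, side) and a
taxon annotation table (taxonomy, phylum, Gram-stain status, oxygen
requirement). Two cleaning rules are applied before modelling:

* **Sample QC.** A sample is excluded when its total read count is strictly
  below 1000 reads (`exclude_low_count_samples()`). The inequality is
  strict: a sample with exactly 1000 reads is retained.
* **Rare-taxon grouping.** An OTU is pooled into a single `RARE` unit when
  its average proportion is below 0.05% in *every* niche, or when it has a
  nonzero count in fewer than two samples (`group_rare_taxa()`). "Average
  proportion" is the unweighted mean of per-sample proportions over the
  niche's QC-passing samples; a pooled-count alternative is available via
  `average = "pooled"`. Grouping runs after sample QC, since excluded
  samples cannot contribute to the averages. Grouping conserves column
  totals and is idempotent.

When both the abundance and presence clauses are evaluated on 223 named
OTUs, the analysis set is the named survivors plus the single pooled unit,
mirroring the "223 OTUs + 1 rare group = 224 analysis units" convention of
studies in this design.

# The abundance model

For one analysis unit (an OTU row, or a phylum/Gram/oxygen category sum),
let $y_{i}$ be its reads out of $n_i$ total reads in sample $i$. The model
is a binomial GLMM with a logit link:

$$
y_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
\mathrm{logit}(p_i) = \beta_{\text{niche}(i)} + u_{\text{dog}(i)} + v_{\text{day}(i)},
$$

with cell-means coding for the four niche log-odds $\beta$, and crossed
Gaussian random intercepts $u \sim N(0, \sigma^2_{\text{dog}})$ for animal
and $v \sim N(0, \sigma^2_{\text{day}})$ for sampling occasion (the
occasion index is shared across dogs, i.e. crossed, not nested). Left and
right replicate swabs enter as individual samples; no side effect is
modelled.

**Fitting.** The random-effect integrals are approximated by the Laplace
method. The inner problem maximizes the penalized joint log-likelihood over
$(\beta, u, v)$ by Newton iterations with step halving; the outer problem
minimizes the Laplace deviance over $(\sigma_{\text{dog}},
\sigma_{\text{day}})$ by Nelder–Mead, with the fixed effects profiled into
the inner problem. A weak Gaussian penalty with standard deviation 10 on
the logit scale is placed on the fixed effects; it is negligible wherever
data are informative (shifts below $10^{-3}$ on the logit scale for any
observed cell) but keeps estimates finite under complete separation, which
is routine for taxa absent from a niche. Variance components may be held
fixed (`var_fixed = c(0, 0)` reduces the model to ordinary penalized IRLS,
which is also the unit-test oracle). Boundary fits ($\hat\sigma = 0$) are
legitimate results, reported as variance 0 with `converged = TRUE`;
genuine non-convergence is flagged, never silent.

The engine is implemented in C++ (RcppArmadillo) because the permutation
test below refits the model $O(10^4)$ times per analysis; one fit on the
full 238-sample design takes a few milliseconds.

**Numerical choices.** Outer Nelder–Mead relative tolerance $10^{-6}$ by
default (contrast statistics are stable to $\approx 10^{-3}$ already at
$10^{-5}$, which the large simulation studies use); inner Newton tolerance
$10^{-9}$ on the step with a cap of 50 iterations; SDs below $10^{-6}$ are
treated as exactly zero and their block is dropped from the Laplace
determinant, with prior normalizing constants arranged so the deviance is
continuous across that boundary.

# Permutation inference and FDR

Wald statistics for the six pairwise niche contrasts are taken from the
fixed-effect covariance conditional on the estimated variance components.
Because the binomial model ignores the strong overdispersion of real
amplicon counts, these statistics are not referred to a normal distribution.
Instead, niche labels are randomly permuted *within each animal*
(preserving each animal's multiset of labels; occasion and side stay
attached to their samples), the GLMM is refitted, and all six pairwise
statistics are extracted per permutation. The permutation p-value per pair
is the add-one estimator

$$
p = \frac{1 + \#\{|z^{\text{perm}}| \ge |z^{\text{obs}}|\}}{B + 1},
$$

which is strictly positive and gives exact finite-sample type-I control;
the plain proportion (its $B \to \infty$ form) is available via
`estimator = "proportion"`. "More extreme" is two-sided on the absolute
statistic, as the niche comparisons are non-directional. Refits that fail
are dropped and counted; more than 20% failures abort the unit. One
permutation stream, derived from the user seed, is shared across all units
of a `diff_abundance()` run.

Left/right replicates are permuted as individual samples by default;
`block = TRUE` keeps each left/right pair together as one experimental
unit (labels then shuffle within unit-size classes). Both are defensible
reads of "niche permuted within animal"; the sample-level default matches
treating replicates as plain repeated measurements.

P-values are Benjamini–Hochberg adjusted (`stats::p.adjust`) across all
units within one niche-pair family — six families per run — and
`pairwise_summary()` counts units with adjusted $p < \alpha$, the
"significant OTUs out of N units per pair" table.

**A resolution floor interacts with FDR.** The add-one estimator's smallest
attainable p-value is $1/(B+1)$. With $B = 199$ and a family of $m$ units,
BH can declare $k$ true effects significant at $\alpha$ only if $1/(B+1)
\le \alpha k / m$. For $k = 10$ at $\alpha = 0.05$ this requires $m \le
100$: a 224-unit family is mathematically out of reach regardless of effect
size, while a 60-OTU panel (10 planted, 50 null) is comfortably inside.
The package's power study therefore uses a 60-OTU panel with ten planted
log-odds effects of $\log 4$ between plaque and buccal mucosa; at the
study's sample sizes the observed statistics sit far outside the permuted
distribution and essentially all planted effects are recovered after BH.

# Diversity and ordination

The Shannon index $H = -\sum_{p_i > 0} p_i \ln p_i$ is computed per sample
in nats (the index's common form; `base = 2` is available). Indices are
modelled with a Gaussian linear mixed model, `H ~ 0 + niche + (1 | dog) +
(1 | occasion)`, fitted by REML via lme4; per-niche means, all pairwise
differences, Wald 95% intervals and significance flags are reported.

Ordination uses a multi-group (animal-centred) PCA: proportions are
log10-transformed after adding a pseudocount — half the smallest nonzero
proportion in the table by default, a minimal-distortion convention for
zeros — then each dog's mean profile is subtracted and the grand mean
restored, isolating within-dog (between-niche) variation, and the
column-centred matrix is decomposed by SVD. Per-niche 95% confidence
ellipses use the normal-theory region: sample covariance of the first two
scores scaled by $\chi^2_{0.95,2}$. Ellipse intersection areas (used to
quantify which niches overlap in the score plane) are computed by a
deterministic grid rasterisation.

# Niche sharing and core microbiota

Set membership follows the UpSet convention: an OTU is "present" in a niche
when its mean proportion over that niche's samples strictly exceeds 0.5%,
and exclusive intersections are counted over the 15 non-empty niche
combinations. Core membership uses an *inclusive* detection threshold: an
OTU is core in a niche at prevalence $q$ when its proportion is $\ge$ 0.5%
in at least $\lceil q \, n \rceil$ of the niche's QC-passing samples; the
cross-niche core applies the same rule to the pooled sample set. The strict
presence inequality and the inclusive detection threshold are both kept as
stated in their respective conventions, despite the asymmetry. The ceiling
makes fractional prevalences attainable with integer sample counts.

# The synthetic-data generator

`simulate_dataset()` emulates the study design: 14 dogs × 3 occasions;
duplicate left/right plaque and buccal samples, single tongue and saliva
samples; one never-collected saliva sample; 8 amplification failures
(2 buccal, 6 tongue); and 5 forced sub-1000-read samples (2 plaque,
1 tongue, 2 saliva), giving 251 collected, 243 sequenced and 238 analysed
samples. Counts are hierarchical Dirichlet-multinomial: for each sample a
composition is drawn from a Dirichlet centred on the niche profile after
logit-scale perturbation by per-dog-per-taxon and per-occasion-per-taxon
Gaussian intercepts ($\sigma_{\text{dog}} = 0.5$, $\sigma_{\text{day}} =
0.25$ by default) and any planted effects, and reads are drawn
multinomially at a log-normal depth (median $\approx$ 13,000 reads,
matching the study's reported medians; depths are floored at the QC
threshold except where sub-threshold samples are forced). Logit-normal
perturbation makes the dog/day intercepts exactly the random effects the
GLMM estimates, so parameter recovery is a well-posed test. Replicate
left/right samples share the intercepts but are otherwise independent
draws — this keeps niche labels exchangeable within animal under the null,
which the permutation test requires (and which a shared per-site
composition for replicate pairs would silently break).

Default niche profiles are deterministic rank-abundance curves
$\propto r^{-\gamma}$ with niche-specific evenness and dominant-taxon
ordering: plaque is the most even ($\gamma = 0.85$) with a partially
shifted dominant set; buccal and tongue are near-identical ($\gamma =
1.05$; tongue swaps adjacent ranks); saliva is the steepest ($\gamma =
1.45$) with its dominant block drawn from taxa minor elsewhere, and a
Dirichlet concentration of 1 against 150–300 for the other niches. The
extreme saliva concentration encodes the study's description of saliva as
by far the most variable niche — variable enough that no taxon stays above
0.5% in every saliva sample, so the saliva core at 100% prevalence is
empty. An 8% low-abundance tail sits below the rare cutoff in every niche
and the last 2% of taxa are essentially absent, exercising both rare-rule
clauses. `null_dataset()` equalizes profiles *and* concentrations across
niches (equal means with unequal dispersions would not be a true
exchangeable null) and exports an empty differential truth.

What the generator does *not* emulate: taxonomic correlation structure
(taxa are exchangeable up to their rank), sequencing error and chimeras
(upstream of the pipeline), depth-composition dependence, and phylogenetic
signal in the annotations. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the declared
hierarchical model, not that real canine oral data meet that model.

# Problem sizes used in the shipped studies

The calibration study pools three null replicate datasets of the full
design (about 620 analysis units after rare grouping) at 99 permutations,
rejecting at $p \le 0.05$; the add-one estimator makes the expected rate
exactly 0.05 and the pooled size keeps its Monte-Carlo spread well inside
[0.03, 0.07]. The power study uses the 60-OTU panel described above at 199
permutations. The uniformity property test runs a reduced 8-dog, 60-unit
null at 99 permutations. Variance-component recovery uses 50 replicate
binomial-GLMM datasets simulated directly from the model. These sizes were
chosen so the full suite completes on a single CPU in well under half an
hour while leaving each check statistically sharp.

# Known limitations

* The binomial GLMM deliberately ignores overdispersion; its Wald
  statistics are only permutation-calibrated, and the reported Wald CIs for
  odds ratios inherit the model's optimism. This mirrors the analysis
  being reproduced; a beta-binomial or log-ratio model is out of scope.
* With only three occasions, $\sigma^2_{\text{day}}$ is weakly identified
  and often estimated at the boundary.
* The Laplace approximation with profiled fixed effects can differ from
  other Laplace implementations (e.g. lme4's) by a few percent in variance
  components on small designs; contrasts agree much more closely.
* Ellipse overlap areas depend mildly on the grid resolution (400 × 400 by
  default); orderings of overlaps are stable.
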