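---
title: "Methods: twin heritability as a benchmark for OTU clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin heritability as a benchmark for OTU clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otuherit)
```

## Rationale

Given several OTU tables built from the same twin-cohort samples by
different clustering methods, `otuherit` ranks the methods by the
heritability of the units they define.  The premise: host-genetic
effects act on real biological taxa, so a clustering that groups reads
from organisms with a shared host relationship yields abundance traits
with more additive genetic variance, while a clustering that splits one
organism's reads across units, or lumps unrelated organisms together,
converts that signal into apparent environmental noise.

## The ACE model and its assumptions

For one trait measured on complete twin pairs, both twins are modelled
as bivariate normal with a single common mean $\mu$ and

$$\mathrm{Var}(y) = a^2 + c^2 + e^2, \qquad
  \mathrm{Cov}_{MZ} = a^2 + c^2, \qquad
  \mathrm{Cov}_{DZ} = \tfrac{1}{2} a^2 + c^2,$$

with path coefficients $a, c, e \ge 0$ for additive genetic, common
(shared) environmental and unique environmental influences.  The
standardized proportions $A = a^2/(a^2+c^2+e^2)$ (narrow-sense
heritability), $C$ and $E$ sum to one by construction.  The usual twin
assumptions apply: MZ pairs share all nuclear DNA and DZ pairs half of
their segregating variants on average; the shared-environment
contribution is equal across zygosities; no dominance, assortative
mating, or gene–environment interaction.  Only the full ACE model is
fitted — no AE/CE model selection — so boundary solutions ($a = 0$ or
$c = 0$) are legitimate outcomes, exactly representable under the
path-coefficient parameterization.

### Estimation

`fit_ace()` maximizes the likelihood over $(a, c, e, \mu)$ with bounded
L-BFGS-B from five starts: one at the clipped Falconer closed form
($A = 2(r_{MZ} - r_{DZ})$ on double-entered correlations), the rest
jittered around it with a caller-supplied seed, guarding against local
optima.  Two numerical choices matter:

* The likelihood is evaluated through per-group sufficient statistics
  ($n$, $\sum y_1{+}y_2$, $\sum y_1^2{+}y_2^2$, $\sum y_1 y_2$), making
  each evaluation O(1) in the number of pairs, so thousands of fits and
  profile searches are cheap.
* The trait is standardized internally (optimization on the z-scored
  scale, parameters mapped back), which makes the standardized
  $A, C, E$ exactly invariant to affine rescaling of the trait and
  keeps the optimizer's absolute tolerances meaningful.

Confidence intervals are profile-likelihood intervals: the set of
component values whose likelihood-ratio statistic against the maximum
stays below $\chi^2_1(0.95) = 3.841$, found by root-finding on each side
of the estimate with the two remaining components re-optimized at every
candidate value, clipped to $[0, 1]$.  With variance components on a
boundary the interval is one-sided (lower bound exactly 0), which is the
behaviour the null-calibration check relies on.

## Preprocessing

`prepare_traits()` applies, in order: (1) prevalence recorded on **raw**
counts (an OTU is present when its count is nonzero); (2) pseudo-count
of 1 to every cell; (3) within-sample relative abundances; (4) subset to
OTUs with prevalence ≥ 50% (inclusive boundary); (5) per OTU, a Box–Cox
transform whose $\lambda$ maximizes the profile log-likelihood

$$\ell(\lambda) = -\tfrac{n}{2}\,\log\!\big(\mathrm{RSS}(\lambda)/n\big)
  + (\lambda - 1) \sum \log y$$

of the linear model $y^{(\lambda)} \sim$ covariates, then OLS residuals
on that design, standardized to unit variance.  $\lambda$ is searched on
$[-5, 5]$ by a 0.1-step grid followed by bounded scalar refinement; the
grid step bounds the bracketing error and the refinement recovers the
continuous optimum (verified against a dense-grid oracle and
`MASS::boxcox`).  The transform is continuous at $\lambda = 0$ (natural
log branch).

Covariates default to all metadata columns: numeric ones enter as-is,
categorical ones one-hot with the alphabetically first level as
reference.  Whether to standardize residuals before model fitting is a
free choice (the standardized $A,C,E$ are scale-invariant); we
standardize because it stabilizes optimization and makes traits
comparable across OTUs.  OTUs whose residual variance collapses below
1e-12 are excluded with a warning rather than fitted.

Twin pairs are assembled by `pair_samples()`: only families with exactly
two samples, both present in the table and with complete covariates, are
retained; a singleton twin or a missing covariate drops the co-twin as
well, and exclusion counts are reported on the object.  Incomplete-pair
handling is a design decision of this package — the defensible
alternatives (imputation, singleton retention for means) do not feed a
pairwise likelihood.

## Between-method comparison

`compare_profiles()` runs pairwise Mann–Whitney U tests over the
per-OTU estimates of one component.  $U$ uses midranks; p-values are
exact by enumeration for small tie-free samples
($n_x + n_y \le 12$) and otherwise use the normal approximation with
tie-corrected variance and continuity correction.  The BH family is all
pairwise tests for one component within one analysis — a choice, since
any family definition is defensible; it is recorded in the comparison
table itself (one `q` column per family).

The "heritable units" view (`heritable_subset()`) keeps OTUs with $A$
strictly above the pooled across-methods mean and lower 95% CI ≥ 1%
(0.01).  Pooling the mean across methods gives a single threshold so the
filter cannot favour a method by using its own mean.

## Taxonomic collapse and the taxon/method model

`collapse_by_taxonomy()` sums member-OTU counts under Greengenes-style
lineage prefixes at any rank from phylum to genus; column totals are
conserved, and an empty rank is keyed as
`unclassified_<deepest assigned parent>` so unrelated unclassified taxa
are not merged.  Collapse is idempotent and hierarchical (genus then
phylum equals phylum directly).

`heritability_glm()` fits the Gaussian linear model
`A ~ taxon + method` (treatment coding, alphabetical references) with
per-coefficient two-sided Wald $t$-tests; "significant predictor" means
$p < 0.05$, configurable.  A Gaussian identity link is the natural
reading for a response that is a proportion-scale estimate well inside
$(0,1)$ on average; taxa observed under a single method are dropped as
collinear.

## Alpha diversity and concordance

`alpha_diversity()` rarefies each sample to 10,000 reads 25 times
(multivariate hypergeometric via `vegan::rrarefy`; replicate $r$ seeds
the RNG with `seed + r`) and averages Shannon, Simpson, Chao1 and
observed-OTU values across replicates.  Samples under the depth are
dropped, not imputed, and concordance uses only the shared retained
samples.  Shannon defaults to log base 2 and Chao1 to the
bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$ — the conventions
of common 16S pipelines — with natural log and the classic
$S_{obs} + F_1^2/(2F_2)$ available (the classic form falls back to
bias-corrected with a warning when $F_2 = 0$).  `compare_alpha()`
contrasts absolute values (Mann–Whitney + BH) and sample rankings
(Kendall τ-b, tie-corrected).

## The synthetic generator

`simulate_twin_otu_table()` emulates the data structure the workflow
consumes, with defaults set to the motivating cohort design: 473 MZ and
402 DZ complete pairs (1,750 samples) and a mean library size of 81,318
reads (Poisson), the post-QC mean read count per sample in that cohort.
Per OTU, a latent twin trait $z = \sqrt{A}\,g + \sqrt{C}\,c +
\sqrt{E}\,e$ (genetic correlation 1 within MZ, 0.5 within DZ) feeds a
log-linear abundance link: expected relative abundances
$\propto \exp(b_j + z + \text{covariate effects})$, by default with a
nonzero age slope (0.1 per SD of age) and a second-sequencing-run offset
(0.3) so the residualization stage is exercised, then structural zeros
and a multinomial read draw.  The log-linear link is itself a modelling
choice: it produces the right-skewed, compositional counts for which the
Box–Cox step is meaningful.  Default truth: $A_j$ cycling over
$\{0, 0.1, 0.2, 0.3, 0.4\}$, $C_j = 0.1$, 50 OTUs with log-abundances
spread over $[-2, 2]$.

`perturb_clustering()` degrades a table the way a worse clustering
would: *split* reassigns each OTU's reads among $k$ children with
sample-dependent Dirichlet proportions (concentration
$1/\text{noise} - 1$, so `noise = 0` is exact equal shares and
`noise = 0.5` a uniform Dirichlet), *merge* sums randomly grouped
unrelated OTUs; both conserve per-sample totals.  Splitting with noise
injects unshared multiplicative noise per twin, inflating $E$;
merging mixes traits with different genetic architecture — both lower
mean $A$, which is the contrast the benchmark measures.

What the generator does **not** emulate: phylogenetic correlation among
OTUs, sequence errors and chimeras, compositional interactions beyond
the shared multinomial denominator, age/cohort structure in the
microbiome, or realistic OTU-count magnitudes (hundreds of thousands of
units).  Passing tests therefore demonstrate correctness and statistical
calibration of the workflow, not that any particular real clustering
method will win.

## Validation scale

The test-suite and `scripts/acceptance.R` simulations run at sizes
chosen to make Monte-Carlo error small relative to the assertions while
keeping a full run in minutes on one CPU: 200 traits for recovery of the
mean $A$, 300 replicates for CI coverage and null calibration (the
binomial standard error of a 95% coverage estimate at 300 replicates is
about 1.3%), 10,000 pairs per group for the Falconer/ML agreement check,
the full 473/402 design with 50 OTUs for the three-table benchmark, and
100 samples × 300 OTUs for the diversity-concordance contrast.  The
per-trait sampling SD of $\hat A$ at the 473/402 design is about 0.10 —
an inherent property of the design, which is why distribution-level
comparisons across many OTUs, not single-OTU estimates, carry the
benchmark.

## Known limitations

* The ACE likelihood assumes bivariate normality; the Box–Cox step makes
  this approximately true for prevalent OTUs but cannot rescue
  highly zero-inflated OTUs, which the 50% prevalence filter exists to
  exclude.
* Profile CIs rely on the asymptotic $\chi^2_1$ calibration, which is
  conservative near the $A = 0$ boundary; a pair-resampling bootstrap
  would be the nonparametric alternative and is not implemented.
* No ADE or sex-limitation models, no covariates inside the ACE model
  (adjustment happens upstream), and no phylogenetic diversity metrics.
* BIOM support is read-only JSON v1.0; HDF5 BIOM files must be converted
  upstream.
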