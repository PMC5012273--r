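# otuherit

Heritability-based comparison of OTU clustering methods in twin microbiome
studies.

## The problem

16S rRNA gene reads must be collapsed into operational taxonomic units
(OTUs) before analysis, and many clustering methods exist (closed/open
reference, de novo greedy algorithms, de-replication, entropy-based
decomposition).  Technical benchmarks — speed, OTU counts, within-cluster
sequence identity — cannot say which method produces units that best
represent the *biological* entities interacting with the host.  In a twin
cohort, a biologically coherent unit should show higher heritability of
its abundance: host-genetic effects act on real taxa, and a clustering
that mixes reads from unrelated organisms dilutes that signal into noise.
`otuherit` implements this idea as a complete, testable workflow for
anyone with several OTU tables built from the same twin samples.

## The model

For each OTU the abundance trait is decomposed with the classical twin
ACE model.  A pair's values are bivariate normal with common mean μ and
covariance structure

```
Var(y)            = a² + c² + e²
Cov(y₁, y₂ | MZ)  = a² + c²
Cov(y₁, y₂ | DZ)  = a²/2 + c²
```

where `a`, `c`, `e` are path coefficients for additive genetic (A),
common-environment (C) and unique-environment (E) influences; MZ twins
share all nuclear DNA, DZ twins on average half of their segregating
variants, and the shared-environment contribution is assumed equal across
zygosities.  Maximum-likelihood estimates are found by bounded
multi-start quasi-Newton optimization (non-negative variance components
by construction), standardized to proportions `A = a²/(a²+c²+e²)` (the
narrow-sense heritability), etc., with 95% profile-likelihood intervals
(χ²₁ cutoff 3.841).  Before fitting, counts receive a pseudo-count of 1,
become within-sample relative abundances, are filtered to OTUs present in
≥ 50% of samples (prevalence on raw counts), and each OTU is Box–Cox
transformed (λ by profile likelihood against the covariate model) and
residualized on gender, age, sequencing run, sequencing depth, collection
method and technician.

Methods are then compared by pairwise Mann–Whitney U tests on their
per-OTU estimate distributions with Benjamini–Hochberg FDR correction,
with a "heritable units" view (A above the pooled mean and lower 95% CI
≥ 1%), by taxonomic collapse plus a linear model `A ~ taxon + method`,
and by rarefaction alpha diversity (Shannon, Simpson, Chao1, observed
OTUs at 10,000 reads × 25 replicates) with Kendall τ-b rank concordance.

A synthetic twin-microbiome generator with known per-OTU A/C/E
components, covariate effects, zero-inflation and "alternative
clustering" perturbations (noisy OTU splits, random merges) makes every
stage testable without any sequence data.

## Worked example

```r
library(otuherit)

cfg <- simulation_config(n_mz = 100, n_dz = 80, n_otus = 12,
                         library_size = 20000, seed = 42)
ds     <- simulate_twin_otu_table(cfg)
pairs  <- pair_samples(ds$table, ds$records)
traits <- prepare_traits(ds$table, pairs)
profile <- fit_all(traits, seed = 1)
profile
#> Heritability profile [truth]: 12 units, mean A = 0.172
head(as.data.frame(profile), 3)
#>   otu_id     A     C     E ci_A_lower ci_A_upper loglik converged
#> 1 OTU001 0.000 0.194 0.806          0      0.311   -507      TRUE
#> 2 OTU002 0.121 0.000 0.879          0      0.286   -509      TRUE
#> 3 OTU003 0.000 0.295 0.705          0      0.381   -502      TRUE

summary(fit_ace(extract_paired_trait(traits, "OTU004"), seed = 1))
#> Twin ACE model fit [OTU004]
#>   pairs: 100 MZ, 80 DZ
#>   A = 0.289  C = 0.107  E = 0.604
#>   log-likelihood: -500.428
#>   estimate lower 95% upper 95%
#> A    0.289     0.000     0.553
#> C    0.107     0.000     0.416
#> E    0.604     0.447     0.799
```

Each row is one OTU's variance decomposition: `A` is the narrow-sense
heritability of its (transformed, covariate-adjusted) abundance,
`ci_A_lower`/`ci_A_upper` its 95% profile interval.  Comparing the true
table against a deliberately degraded variant of itself shows the
benchmark logic:

```r
split  <- perturb_clustering(ds$table, "split", k = 2, noise = 0.5, seed = 2)
report <- run_benchmark(list(truth = ds$table, split = split), ds$records,
                        run_diversity = FALSE, seed = 1)
report
#> Heritability benchmark across 2 method(s)
#>   truth                mean A = 0.172 (12 OTUs)
#>   split                mean A = 0.112 (24 OTUs)
#>   significant pairwise A differences (q < 0.05): 0 of 1
```

Noisily splitting each OTU across two spurious units lowers mean
heritability (0.172 → 0.112); at 12 OTUs the Mann–Whitney test lacks
power, while at the full design (875 pairs, 50 OTUs) the difference is
clearly significant (see the vignette).

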