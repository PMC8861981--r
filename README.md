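# epemix

Tools for analysing **sex-dimorphic temporal transcriptomes**: longitudinal
bulk expression studies in which both sexes are profiled over a shared age
grid (e.g. mouse bone at 3, 6, 9, 12 and 18 months with 4 replicates per
sex-age group) and the questions are *which genes differ quantitatively
between the sexes* and *which genes follow different temporal trajectories
in males and females*.

The package implements two complementary tracks around a model-based
clustering core:

**Quantitative track.** Per gene, a pooled-variance two-sample t test of
male versus female samples across all ages on unlogged expression, with
Benjamini–Hochberg FDR control, yields a signed *sex signature* (+1 higher
in males, −1 higher in females) at a chosen q threshold. The signature can
be projected onto any expression compendium with an openSESAME-style scan:
each sample receives a signature-association (SA) score — the mean of the
direction-signed within-dataset z-scores over signature genes — and each
dataset is tested by a two-sided Fisher exact test for enrichment in
samples with strong (pooled upper-quantile) |SA| scores.

**Temporal track.** Replicate-averaged, per-profile standardized
time courses of every gene in every sex are treated as distinct objects and
clustered jointly with an entropy-penalized EM (EPEM) fit of a mixture of
polynomial mixed-effects models:

```
y_i | cluster k  ~  N( X beta_k,  Z D_k Z' + sigma^2 I )
```

where `X` is a cubic and `Z` a quadratic polynomial basis on age mapped to
[−1, 1]: `beta_k` is the cluster's mean trajectory and `D_k` the covariance
of gene-specific trajectory deviations. The penalized objective

```
J = sum_i log sum_k pi_k f_k(y_i)  +  lambda * N * sum_k pi_k log pi_k
```

is maximized by a generalized EM that starts from `K_max` clusters and
removes superfluous ones (guarded annihilation and merging moves that never
decrease `J`), so the number of clusters is selected automatically. Because
both sexes are clustered in a single model, the male and female labels of
each gene are directly comparable: the male-by-female label
cross-tabulation splits the transcriptome into *concordant* (diagonal) and
*discordant* (off-diagonal) genes, which can then be screened for gene-set
overrepresentation (one-sided hypergeometric with BH correction).

A synthetic-data generator (`simulate_timecourse_study()`,
`simulate_compendium()`) reproduces exactly this generative structure —
cluster-level cubic curves, gene-level quadratic random effects, replicate
noise, a configurable sex-discordant fraction, and compendium datasets with
an embedded coordinately regulated signature — so the whole pipeline is
testable without any external download.

## Worked example

```r
library(epemix)

# a study with 4 temporal clusters and 30% sex-discordant genes
cfg <- sim_config(n_genes = 1000, discordant_fraction = 0.3, seed = 1)
sim <- simulate_timecourse_study(cfg)

profiles <- standardize_profiles(collapse_replicates(sim$matrix, sim$annotation))
fit <- epem(profiles, K_max = 10,
            control = epem_control(lambda = 0.3, n_restarts = 3), seed = 1)
print(fit)
#> Entropy-penalized mixture of polynomial mixed-effects models
#>   4 clusters fitted to 2000 temporal profiles over ages {3, 6, 9, 12, 18} months
#>   residual variance sigma^2 in [0.006672, 0.006672]; penalized objective = 6388.9839
#>   mixing proportions:
#> cluster_1 cluster_2 cluster_3 cluster_4
#>    0.2740    0.2480    0.2395    0.2385

part <- partition_genes(assign_labels(fit, profiles))
print(part)
#> concordance partition: 1000 genes (683 common, 317 discordant)
mean((part$labels$male_label != part$labels$female_label) ==
       sim$truth$discordant[match(part$labels$gene_id, sim$truth$gene_id)])
#> [1] 1
```

The fit recovers the four generating clusters from ten initial ones, the
mixing proportions match the uniform truth, and every gene's
concordant/discordant status agrees with the simulation truth (317/1000
discordant, close to the nominal 30%).

Cross-tabulations are summarized exactly:

```r
tab <- read_crosstab(system.file("extdata", "crosstab_9x9.tsv", package = "epemix"))
summarize_crosstab(tab)[c("diagonal_total", "offdiagonal_total", "grand_total")]
#> $diagonal_total    [1] 10919
#> $offdiagonal_total [1] 10306
#> $grand_total       [1] 21225
```

`run_pipeline()` drives simulate → de-screen → cluster → crosstab → enrich
→ sesame-scan from a single (YAML or list) configuration with one master
seed and writes a provenance manifest.

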