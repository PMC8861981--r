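---
title: "Models and methods behind epemix"
author: "epemix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epemix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(epemix)
```

This vignette documents the statistical models implemented in `epemix`,
the assumptions behind them, the tunable parameters and their defaults,
the numerical choices that matter, and what the synthetic-data generator
does and does not emulate. It states no empirical result beyond what the
package's test suite and `scripts/acceptance.R` themselves compute.

## The study design

`epemix` targets longitudinal two-sex bulk expression studies: both sexes
are profiled on a shared age grid (by default 3, 6, 9, 12 and 18 months)
with a small number of replicates per sex–age group (by default 4). The
input is a genes × samples matrix of normalized, linear-scale intensities
plus a sample annotation table (`sample_id`, `sex`, `age_months`,
`replicate`). Two questions are addressed:

1. **Quantitative dimorphism** — which genes differ in level between the
   sexes, pooling all ages?
2. **Temporal dimorphism** — which genes follow different *trajectories*
   over age in males and females?

## Quantitative track: the sex signature

`sex_ttest()` performs, per gene, a two-sided Student's two-sample t test
with pooled variance (equal-variance assumption, df = n~M~ + n~F~ − 2) of
male versus female samples across all ages, on non-log-transformed values;
a matrix flagged `log2` is exponentiated first. Time is deliberately
ignored: this screen asks about overall level differences, and a
stratified or interaction model is out of its scope. Multiplicity is
controlled by Benjamini–Hochberg step-up q-values (`benjamini_hochberg()`,
a validated wrapper over `stats::p.adjust`), with the FDR universe equal
to *all* genes in the matrix — filtering the universe is left to the
caller, since any filter changes q-values and silently baked-in filters
are a reproducibility hazard.

`extract_signature()` thresholds on q and tags each passing gene with the
sign of its sex difference (+1 higher in males). Male/female expression
ratios are reported on unlogged means; a gene with non-positive female
mean gets an `NA` ratio rather than an error, because normalized linear
intensities are occasionally non-positive after background subtraction.

### Signature-association scan

`sa_scores()` projects a signed signature onto an expression dataset:
every signature gene present (and non-constant) is z-scored across the
dataset's samples, and a sample's SA score is the unweighted mean of the
direction-signed z-scores. The unweighted mean keeps scores comparable
across signatures of different sizes; z-scoring makes the score invariant
to per-gene affine changes of scale, so datasets from different platforms
can be scanned without renormalization. Scores always average to zero
across a dataset's samples — the scan measures *coordinate regulation
within* a dataset, not absolute expression.

`scan_compendium()` pools |SA| over all samples of all datasets passing a
coverage filter (default: at least half the signature genes present), and
calls a sample "strong" when its |SA| reaches the pooled `strong_quantile`
(default 0.90). Each dataset is then tested with a two-sided Fisher exact
test on the 2 × 2 table (strong / not strong) × (this dataset / rest of
the compendium), with BH q-values across datasets. The pooled-quantile
definition of "strong" makes each dataset's table well-defined against
the rest of the compendium without any per-dataset tuning. Note that
Fisher's exact test is discrete and therefore conservative: under a pure
noise compendium, somewhat *fewer* than 5% of datasets fall below
p < 0.05 (the acceptance suite measures the realized rate at around 4%
for 20 datasets × 20 samples).

`fisher_exact_2x2()` implements the two-sided exact p directly as the sum
of hypergeometric probabilities not exceeding that of the observed table
(margins fixed, with the conventional 1 + 1e-7 relative tie tolerance);
the test suite cross-checks it against `stats::fisher.test` to 1e-12.

## Temporal track: the clustering model

### Profiles

`collapse_replicates()` averages replicates within each (gene, sex, age)
group, yielding one temporal profile per gene per sex on the observed age
grid. `standardize_profiles()` then centers each profile by its own mean
and scales by its own sample SD (denominator T − 1). Standardization makes
the clustering *shape-based*: two profiles differing only by an affine
transform become identical, which is what one wants when the biological
question is about temporal *pattern* rather than level. Profiles with SD
below `1e-8` carry no shape information and are removed (and reported in
the `excluded` field). The phrase "standardized by the gene-specific mean
and standard deviation" admits a second reading — moments pooled across
both sexes of a gene — which retains between-sex level differences;
`standardize_profiles(scope = "gene")` provides it, but the per-profile
variant is the default and the one exercised throughout, because a purely
shape-based clustering is the cleaner complement to the quantitative
t-test track, which already captures level differences.

### The mixture of polynomial mixed-effects models

Each standardized profile $y_i \in \mathbb{R}^T$ (a gene in one sex;
both sexes' profiles enter one model as distinct objects) is modeled as

$$ y_i \mid z_i = k \;\sim\; N\!\left(X\beta_k,\; Z D_k Z^\top + \sigma^2 I\right), $$

where $X$ is the cubic and $Z$ the quadratic polynomial basis on age
mapped linearly to $[-1, 1]$ (raw month powers up to $18^3$ are
numerically hostile; the affine map keeps the Gram matrices
well-conditioned and is shared between the simulator and the fitter).
$\beta_k$ is cluster $k$'s mean trajectory; $D_k$ is the covariance of
gene-specific quadratic deviations, capturing within-cluster
heterogeneity; $\sigma^2$ is the residual variance, shared across
clusters by default because five time points cannot reliably identify a
per-cluster residual variance alongside a full $3 \times 3$ $D_k$
(`epem_control(pooled_sigma2 = FALSE)` fits per-cluster variances for
data where clusters plainly carry unequal noise).

Joint clustering of both sexes is the crux: labels from two separate
per-sex clusterings would need an arbitrary remapping before they could
be compared, whereas a single model makes "same label in both sexes"
directly meaningful.

### The entropy-penalized objective

The number of clusters is selected automatically by maximizing

$$ J \;=\; \sum_i \log \sum_k \pi_k f_k(y_i) \;+\; \lambda N \sum_k \pi_k \log \pi_k , $$

a negative-entropy reward on the mixing proportions: superfluous clusters'
weights are driven toward zero and pruned. Fitting is a generalized EM
with, per iteration:

* **E-step** — responsibilities $r_{ik} \propto \pi_k f_k(y_i)$, computed
  with log-sum-exp.
* **M-step for $(\beta_k, D_k, \sigma^2)$** — the classical EM update for
  mixtures of linear mixed models: posterior random-effect moments at the
  current parameters, then closed-form updates from the weighted
  sufficient statistics. This is an exact EM step, so it never decreases
  the observed-data likelihood.
* **M-step for $\pi$** — a *safeguarded* update. Candidates are the
  previous $\pi$, the maximum-likelihood update $n_k/N$, the
  entropy-penalized fixed point
  $\pi_k \leftarrow n_k/N + \lambda \pi_k(\log \pi_k - \sum_j \pi_j \log \pi_j)$
  (clamped at zero), and "kill" candidates that zero out one of the three
  smallest clusters. The candidate with the best penalized objective is
  kept. Because the previous $\pi$ is always among the candidates, the
  recorded objective trace never decreases.
* **Merge moves** (every third iteration while $\lambda > 0$) — the two
  closest pairs of cluster mean curves are tentatively merged: the merged
  component is refitted on the summed responsibilities, the merged
  configuration is refined with a few plain EM iterations, and the merge
  is accepted only if the penalized objective does not decrease. Merging
  is what actually removes duplicate clusters created by an over-specified
  start: a pair of components tiling one true cluster loses almost no
  likelihood when replaced by a single component whose $D$ absorbs the
  spread, while the entropy reward favors the coarser model.
* **Pruning** — clusters whose effective size $\pi_k N$ falls below
  `prune_threshold` (default 1.0, i.e. less than one profile's worth of
  weight) are removed, again only if the objective does not decrease;
  otherwise they continue shrinking and are removed a few iterations
  later at negligible cost.

$\lambda$ is annealed linearly to zero over the first half of the
iterations: penalize early, so pruning and merging happen while the
penalty is active, and finish as pure maximum likelihood. Since the
penalty term $\lambda N \sum \pi_k \log \pi_k$ is non-positive and
$\lambda$ never increases, the trace stays monotone across the anneal as
well — a property the test suite asserts on every fit it runs.

Restarts (default 10) are compared by their final objective evaluated at
the *nominal* $\lambda$, not the annealed one: at $\lambda = 0$ a
solution with more clusters always has higher likelihood, so comparing
at the nominal penalty is what makes "best restart" mean "best tradeoff
of fit against complexity".

### Choosing $\lambda$

The default $\lambda = 0.1$ is appropriate for profiles that follow the
model as written. For **per-profile standardized** data a stronger
penalty, around 0.2–0.5, is advisable, and the package's own
study-scale validation uses 0.3. The reason is a structural
misspecification that standardization introduces: centering removes all
variance along the constant direction and amplitude-scaling removes it
along the profile's own mean-curve direction, so the within-cluster noise
becomes anisotropic in a cluster-specific way. An isotropic
$\sigma^2 I$ plus a quadratic-span $D_k$ cannot represent variance
deficits, and the shared $\sigma^2$ settles below the per-direction noise
of some clusters. The mixture can then gain roughly 0.1–0.2 nats per
profile by tiling such a cluster with two components displaced along a
direction outside the quadratic span — more than the $\lambda = 0.1$
entropy penalty (about $0.07$ nats per profile for an even split), and
the imbalance is scale-free in both the number of profiles and the noise
level. At $\lambda \approx 0.25$ the balance tips and the spurious splits
are merged away. The same consideration applies to real data: if a fit
on standardized profiles returns pairs of clusters with nearly identical
mean curves, raise $\lambda$ before believing the split.

### Other numerical choices

* **Variance floors** — $\sigma^2$ and the eigenvalues of each $D_k$ are
  floored at `variance_floor` (default 1e-6), which prevents likelihood
  blow-up on noise-free or duplicated profiles.
* **Initialization** — k-means on the profile rows with `K_max` centers
  (seeded; if fewer distinct rows than `K_max` exist, the start is
  reduced accordingly), $\beta_k$ from an OLS fit to each center,
  $D_k = 0.05\,I$, $\pi$ from the k-means partition sizes.
* **Convergence** — iteration stops once the objective changes by less
  than `tol * (1 + |J|)` (relative, default 1e-5, the convention of
  model-based-clustering packages) after the anneal has finished and no
  discrete move fired in the preceding iteration; `max_iter` (default
  400) caps each restart, and exhausting it sets a convergence warning
  rather than failing.
* **Canonical labels** — clusters are relabeled 1..K by decreasing
  membership, ties broken by the first fixed-effect coefficient, so
  reported label numbers are deterministic and permutation of the input
  rows permutes the assignments without changing the model.
* **Ties in hard assignment** — `assign_labels()` breaks responsibility
  ties toward the lowest cluster index.

### Concordance

`cross_tabulate()` counts, over genes labeled in both sexes, the
male-label × female-label pairs; `partition_genes()` calls a gene
*common* when both labels agree and *discordant* otherwise, excluding
(and reporting) genes labeled in only one sex. `gene_set_summary()`
reports each gene set's split over the two sides with integer-rounded
percentages for display and exact fractions for machine use.
`overrepresentation_test()` is the conventional one-sided upper-tail
hypergeometric ("modified Fisher exact") enrichment test against a
user-supplied background, BH-corrected across sets — enrichment only,
not depletion, matching how ontology tools use it.

## The synthetic-data generator

`simulate_timecourse_study()` draws data with exactly the structure the
clustering model assumes: per gene a male cluster from $\pi$; with
probability `discordant_fraction` a female cluster redrawn uniformly from
the remaining labels (so truth-discordance is label inequality by
construction); per gene × sex an independent random-effect draw
$b \sim N(0, D_k)$ — independent in the two sexes even for concordant
genes, because each sex's profile is a distinct object; i.i.d. Gaussian
replicate noise; and a per-gene affine map to expression scale with
lognormally distributed baselines (median `baseline_mean`, spread
`baseline_cv`; `baseline_cv = 0` gives a deterministic map, which the
moment-recovery tests use to work on the standardized scale directly).

Default conditions mirror the targeted design: 2 sexes × 5 ages
{3, 6, 9, 12, 18} months × 4 replicates, four cluster shapes (rising,
falling, mid-life peak, mid-life trough) with uniform mixing, replicate
noise variance 0.05, and a 30% discordant fraction. The default mean
curves are themselves standardized to mean 0 / SD 1 on the age grid —
the scale the clustering operates on — which also keeps the
post-standardization noise level comparable across clusters. No
published effect-size scale exists for the real sex differences, so
these values are chosen for testability: separations are several noise
standard deviations apart.

What the generator does **not** emulate: probe-level microarray noise,
batch effects and array failures, heavy-tailed or gene-correlated noise,
mean–variance coupling beyond the lognormal baseline spread, quantitative
sex shifts superimposed on the temporal structure, and cluster shapes
outside the cubic family. Passing tests therefore demonstrate
correctness of the machinery under the model's own assumptions — not
robustness to everything real arrays do.

`simulate_compendium()` builds the scan's test bed: standard-normal noise
datasets containing all signature genes plus decoys; embedded datasets
shift half their samples by `effect_delta` in each gene's signed
direction, emulating a series in which the signature is coordinately
regulated in a sample subgroup.

## Validation scales

The package validates itself at these problem sizes (chosen as
representative working scales for the method):

* cluster-count and membership recovery: 2,000 profiles from 4 clusters,
  $\sigma^2 = 0.05$, `K_max = 10`, 3 restarts, across 5 seeds;
* concordance recovery: a 1,000-gene study (2,000 profiles) through the
  full collapse → standardize → cluster → partition pipeline at
  $\lambda = 0.3$;
* EM ascent: 20 random mixtures at 120 profiles each; the profile
  log-likelihood against a dense multivariate-normal oracle on 100
  random parameter draws at tolerance 1e-10;
* screen calibration: 10,000 null genes for the t test; 200 seeded null
  compendium scans (20 datasets × 20 samples) and 5 seeded power scans
  with one embedded dataset at `effect_delta = 5`.

## Known limitations

* Five time points support at most a cubic mean and quadratic
  random-effect polynomial; the model cannot express sharper temporal
  features, and with $T = 5$ the likelihood surface for $(D_k, \sigma^2)$
  is flat enough that EM convergence is slow in its tail (hence the
  relative tolerance).
* Standardized profiles live on a lower-dimensional manifold than the
  Gaussian model assumes (see *Choosing $\lambda$*); a weak penalty can
  split genuine clusters on such data.
* The concordance partition depends on hard labels; genes with diffuse
  responsibilities near cluster boundaries are classified by their argmax
  even when the posterior is nearly flat. `assign_labels()` returns the
  full responsibility matrix so borderline calls can be filtered.
* The DE screen inherits the limitations of the unmoderated equal-variance
  t test on unlogged values: no variance shrinkage across genes and
  sensitivity to heteroscedasticity. Moderated alternatives exist in
  dedicated packages and are intentionally out of scope here.
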