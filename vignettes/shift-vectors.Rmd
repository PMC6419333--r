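---
title: "Differential-abundance shift vectors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential-abundance shift vectors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`otushift` characterizes experimental conditions in microbiome cohorts not
by the taxa present, but by how taxa *shift* with each condition. For every
numeric metadata variable it fits a univariate count model per taxon and
collects the resulting log2 fold changes into a per-rank *shift matrix* —
taxa in rows, conditions in columns. That matrix is then the object of
analysis: conditions can be compared to each other, to an external query
vector, to microbial trait annotations, and to alpha diversity, and the
input table itself can be checked for internal consistency with
permutation tests.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic benchmark cohort
does and does not establish.

# The differential-abundance model

For one metadata variable $x$ and one taxon $j$, counts are modelled as
negative binomial with mean $\mu_{ij}$ for sample $i$ and dispersion
$\phi_j$ (variance $\mu + \phi\mu^2$):

$$\log \mu_{ij} = \log(N_i f_i) + b_{0j} + b_{1j} x_i$$

where $N_i$ is the library size and $f_i$ a TMM scale factor, so that
$\log(N_i f_i)$ enters as a fixed offset. The reported effect is
$b_{1j}/\ln 2$: the log2 fold change per covariate unit. For a 0/1
covariate this is the usual between-group log2 ratio; for a recoded
frequency variable it is the change per additional daily event.
Significance comes from a likelihood-ratio test of $b_{1j} = 0$ against a
$\chi^2_1$ reference, with the intercept-only null fit on identical data,
offsets and dispersion.

Samples missing the variable are dropped listwise, per variable, and the
normalization factors are recomputed on the retained subset (so each
column of the shift matrix is self-contained). At least 8 non-missing
samples and 2 distinct covariate values are required; variables failing
this are skipped with a warning during shift-matrix assembly. P-values
are stored raw — downstream filters in this package follow the
"significant at p < 0.05" convention, and `p.adjust`-style corrections
are deliberately left to the consumer (a `fdr` flag exists where the
trait filter is applied).

## Fitting

Coefficients maximize the NB log-likelihood at fixed $\phi$ by
iteratively reweighted least squares with working weights
$\mu/(1+\phi\mu)$. Convergence is declared when the relative deviance
change falls below $10^{-8}$, with a cap of 100 iterations. The linear
predictor (net of offset) is clamped to $[-30, 30]$ to keep weights
finite on degenerate data; an all-zero count vector is rejected (such
taxa must be removed by `filter_taxa()` first), while a vector with a
single nonzero count still converges to finite coefficients.

## Dispersion estimation

The count model needs a per-taxon $\phi_j$, which a univariate
pipeline must estimate from the same data it tests. We use a profile
likelihood: for candidate $\phi$ values on a 21-point log-spaced grid in
$[10^{-6}, 10]$, the coefficients are re-fit and the log-likelihood
recorded. Per-taxon curves are then shrunk toward the cohort-wide
(common) curve with a prior weight equivalent to 10 observations: the
penalized curve is $\ell_j(\phi) + \tfrac{10}{n}\bar\ell(\phi)$, where
$\bar\ell$ is the across-taxa mean curve and $n$ the per-taxon sample
count. Because the grid alone is coarse (adjacent points differ by a
factor of about 2.2) the penalized maximizer is refined by a continuous
search inside its bracketing grid interval, interpolating the smooth
common curve with a spline. This refinement matters in practice: at the
grid resolution alone, a true $\phi = 0.5$ is estimated as the nearest
grid point (0.40), which inflates the likelihood-ratio statistic enough
to push the type-I error to the edge of its nominal band. With
refinement the null p-values are uniform (Kolmogorov–Smirnov p ≈ 0.4 at
2000 null tests) and the empirical type-I error sits at ≈ 0.05.

The floor of $10^{-6}$ makes the Poisson limit reachable; dispersions
are never allowed to be exactly zero so the NB likelihood stays defined.

## Normalization

`tmm_norm_factors()` implements the trimmed mean of M-values: log2
abundance ratios against a reference sample are trimmed 30% from each
tail, average log abundances 5% from each tail, and the surviving
M-values averaged with inverse delta-method variances. The reference is
the sample whose upper quartile of nonzero count proportions is closest
to the cohort mean. Factors are rescaled to geometric mean 1, so offsets
are identified. On two-sample, zero-free tables the result matches
edgeR's implementation to machine precision; with more samples the
reference choice and trim boundaries can differ in edge cases, and the
test suite checks agreement within a few percent. `--norm libsize`
(unit factors) is available as a fallback.

# Shift-matrix analyses

**Condition similarity** is the correlation of two conditions' log2FC
columns over the taxa finite in both, Spearman by default. Rank
correlation was chosen because low-abundance taxa produce heavy-tailed
fold-change estimates that dominate a Pearson statistic; Pearson is
available as an option. A pair sharing fewer than 3 finite taxa yields a
missing cell with a warning.

**Query ranking** applies the same similarity between a user-supplied
named log2FC vector and every condition, sorted descending with ties
broken by condition label. At least 3 overlapping taxa are required.

**Discriminative-taxon selection** reproduces the heatmap
feature-selection recipe: conditions are clustered into two groups by
average-linkage hierarchical clustering on correlation distance
(1 − similarity), and each taxon is scored by the one-way ANOVA
F-statistic of its log2FCs between the groups. Average linkage on rank
correlation distance is fixed here as the package's choice — any
hierarchical scheme could define the two clusters, and this one is
robust to the same heavy tails as the similarity itself. Rows with no
between-group variation score F = 0 and ties fall back to taxon label
order, making the output deterministic. `zscore_rows()` provides the
row-standardization used for heatmap display; constant rows become
all-zero with a warning rather than NaN.

# Diversity and traits

**ACE** (abundance-based coverage estimator) splits a sample's taxa at
abundance 10 into abundant and rare groups, estimates rare-group
coverage as $C = 1 - F_1/N_{rare}$, and returns
$S_{abund} + S_{rare}/C + (F_1/C)\,\gamma^2$ with $\gamma^2$ the clipped
rare-taxa coefficient of variation. When every rare taxon is a singleton
the coverage is zero and the estimator undefined; cohort-level analyses
flag such samples and drop them pairwise instead of aborting. The
implementation is checked against both a literal re-derivation of the
formula and vegan's `estimateR` to $10^{-9}$.

**Diversity–metadata correlation** is Spearman's rho (midrank ties)
between the per-sample ACE vector and each variable, with a two-sided
t-approximation p-value.

**Trait–shift correlation** matches taxa to a trait table by species
name (case-insensitive, underscores normalized to spaces, genus +
species extracted from lineage strings) and computes Pearson r between
each trait column and the log2FC vector. Pearson is used because trait
values are probabilities or 0/1 flags — for a binarized trait this is
the point-biserial correlation; Spearman is available. Traits passing
the p < 0.05 filter are returned sorted by |r|, with the unfiltered
table attached. Probability tables can be binarized at a cutoff
(default 0.9, inclusive: a value exactly at the cutoff becomes 1).

# Consistency checks

**Affinity matrices** over items (samples or conditions) default to
1 − Spearman correlation of item profiles, a rank-based construction
that is comparable across feature spaces of different scale and
dimension; Bray–Curtis (via vegan) is offered for raw counts.

**The Mantel test** correlates the strict upper triangles of two
distance matrices and assesses significance by simultaneous row/column
permutation of the second matrix, one-sided (greater), with the add-one
p-value $(b+1)/(n_{perm}+1)$. On up to 8 items all $n!$ relabelings can
be enumerated for an exact p-value; the permutation p is checked against
that enumeration in the tests. Note that the identity relabeling is part
of the permutation group, so for very small item sets the p-value of a
self-comparison is bounded well above $1/(n_{perm}+1)$ simply because
random permutations frequently reproduce the identity.

**Taxonomic coherence** asks whether species in the same genus (family,
order, ...) have more similar abundance profiles than random species
sets of the same sizes. Profiles are log(1+x)-transformed counts —
fixed here as the package's transform — and similarity is mean pairwise
Spearman within groups of ≥ 2 members. The null re-draws groups from a
table whose rows are independently permuted across samples, which
destroys inter-taxon correlation while preserving each taxon's marginal
distribution. The empirical p is add-one corrected, so it is never 0.

# The synthetic benchmark cohort

`simulate_dataset()` draws counts from exactly the model the engine
fits: $y_{ij} \sim NB(\mu_{ij}, \phi)$ with
$\log\mu_{ij} = \log N_i + a_j + \sum_k b_{jk}x_{ik}$. The default
parameters define the package's standard benchmark: 200 samples; a
3 phyla × 4 genera × 5 species taxonomy (60 species); log-normal
baseline abundances (sdlog 1.5) and library sizes (median 30,000 reads,
sdlog 0.3); dispersion $\phi = 0.5$, a typical 16S value; five metadata
variables (two Bernoulli(0.5) binary, three drawn from questionnaire
frequency categories and recoded to events/day); ten planted effects of
|log2FC| = 1.5 with alternating signs; and 2% missing metadata cells.
Planted taxa are drawn from species whose baseline relative abundance
is above its 25th percentile — fold changes of vanishingly rare taxa
are not stably estimable by any method, which is also why the real
pipeline filters low-abundance taxa before building shift vectors.
An optional per-genus latent factor (`genus_cor`) induces within-genus
profile correlation for the coherence benchmark, and
`simulate_traits()` adds a trait table in which linked traits track the
direction of the planted response: Beta(8, 2) probabilities on
positively shifted taxa, Beta(1, 9) on negatively shifted ones,
Beta(2, 8) background, with unlinked traits Beta(0.5, 0.5).

For the trait-calibration experiment the cohort concentrates all ten
planted effects on a single binary variable (5 up, 5 down). With the
effects spread over five variables only two taxa inform any one trait,
and a two-point linkage is statistically marginal by construction; ten
informative taxa of sixty make the planted linkage detectable while
leaving the 500 unlinked traits for the null-rate calibration.

What the generator does *not* emulate: compositional closure (counts
are drawn independently given $\mu$, so there is no sum constraint),
ecological interaction networks, zero inflation beyond what the NB
produces, phylogenetic signal in baseline abundances, and categorical
metadata that resists numeric coercion. Passing benchmarks therefore
demonstrate correctness of the statistical machinery under its own
model assumptions — not robustness to the full messiness of real 16S
surveys, where compositionality in particular (flagged as out of scope)
can distort fold changes when large shifts occupy much of the library.

## Problem sizes

The test and benchmark runs use sizes chosen to exercise every code
path while keeping a full run in the low minutes on a single core: the
200 × 60 benchmark cohort for recovery; a 200 × 100 cohort × 20 null
covariates (2000 tests) for calibration; 200 Mantel runs at 30 items ×
999 permutations for p-value uniformity; 100 query replicates; and
500 + 1 simulated traits.

# Degenerate inputs and tie-breaks

* Constant covariate, all-missing variable, too few samples → explicit
  errors (`E_DEGENERATE`, `E_SAMPLES`); during shift-matrix assembly
  these degrade to skipped columns with warnings.
* Taxa all-zero after listwise deletion are skipped for that variable
  and carry NA in its column.
* An empty taxon filter result warns and returns a 0-row matrix rather
  than erroring, since a downstream rank may still be analyzable.
* Collapsing pools taxa unassigned at the target rank into one
  `Unassigned` row so per-sample totals are conserved exactly (an
  invariant the tests enforce at every rank).
* Metadata coercion treats "", "NA", "NaN", "Unknown", "Unspecified"
  (case-insensitive) as missing; a non-numeric token never becomes 0.
* The frequency recoding anchors Daily = 1.0 and Never = 0.0;
  intermediate categories use midpoint-of-range per day (e.g.
  "Regularly (3-5 times/week)" → 4/7). Questionnaires differ, so the
  map is overridable (`--freq-map`).
* All stochastic stages take explicit seeds; the pipeline derives
  stage seeds from the run seed by fixed offsets, and repeated runs are
  checksum-identical.

# Known limitations

The model is univariate by design — no confounder adjustment, no
interactions. Fold changes are per covariate unit, so comparing shift
vectors across variables with different scales mixes units; the rank
correlation used for similarity absorbs monotone differences but not
sign structure. The dispersion shrinkage weight (10 observations) is a
fixed transparent choice, not an empirical-Bayes estimate. ACE is the
only diversity index; Bray–Curtis and Spearman distance the only
affinity constructions. BIOM/HDF5 input is out of scope: tables arrive
as TSV.
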