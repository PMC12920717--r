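---
title: "Estimating physiological blood age from somatic variant frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating physiological blood age from somatic variant frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloage)
```

## The model

An adult's hematopoietic stem cells (HSCs) descend from a set of lineages
that diversified during embryogenesis.  Through most of life each lineage
self-renews without branching, accumulating somatic single-nucleotide
alterations (SNAs) at a clock-like rate of roughly 17 per genome per year.
With age, clonal hematopoiesis (CH) sets in: some lineages expand into
clades of closely related cells, displacing other lineages and eroding the
phylogenetic diversity of the blood.

Reconstructing the HSC phylogeny to measure that erosion requires
colony-level sequencing of hundreds of single HSCs.  The observation this
package builds on is that the same signal is visible in the *variant
frequency spectrum* (VFS) obtainable from ordinary bulk sequencing: every
variant carried by an expanding clade's founding lineage rises to an
elevated, shared variant allele frequency (VAF).  A clade carrying a cell
fraction $f$ whose founding lineage bore $n$ variants removes diversity in
proportion to $f \times n$, and summing over clades,

$$\gamma = \sum_i f_i \, n_i ,$$

where the clusters $i$ come from subclonal structure inference on the VFS.
Because cluster frequency times cluster size is just the sum of the
members' VAFs, and every variant belongs to exactly one cluster, the sum
telescopes into a statistic that needs no clustering at all:

$$\lambda = \sum_k \mu_k ,$$

the sum of VAFs $\mu_k$ over all variants that survive the *tip-variant
filter*.  Variants private to a single sampled lineage (phylogenetic tips)
carry no expansion signal and sit at VAFs of roughly $1/(2 \cdot
\text{lineages sampled})$; a 1% VAF threshold removes them.  `phyloage`
implements both statistics; `gamma_metric()` on clusters whose frequencies
are exact member means reproduces `lambda_metric()` to machine precision,
which the test suite asserts.

In healthy cohorts $\lambda$ grows exponentially with age, so

$$\log \lambda = a + b \cdot \text{age}, \qquad
\text{phyloAge}^{*} = \frac{\log \lambda - a}{b}$$

defines a physiological blood age.  phyloAge\* above chronological age
indicates excess clonal expansion; below it, unusually preserved
diversity.

## Inputs

Two routes produce a VFS (`vfs()` objects):

* **Bulk sequencing** — alt/ref read depths from a VCF `AD` field
  (`read_vfs(..., format = "vcf")`) or the package's TSV layout.  The VAF
  is the raw alt-read fraction.
* **Colony sequencing** — a binary lineages-by-variants genotype matrix
  (`genotype_matrix_to_vfs()`).  Somatic variants are heterozygous, so the
  VAF is *half* the carrier cell fraction and is bounded by 0.5.

Bulk spectra without matched germline sequencing need germline removal
first; `cohort_germline_filter()` implements the recurrence rule (drop a
variant seen in two or more other somatic samples of the cohort) together
with a known-site blacklist.  `rescale_counts_to_depth()` provides the
deterministic down-scaling of colony counts to a nominal depth (e.g. 300
reads to 30 via divisor 10), used when building depth-matched reference
spectra.

## Tunable parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `threshold` (tip filter) | 0.01 | VAF | removes single-tip variants for spectra of 50+ sampled lineages; inclusive ($\ge$) |
| `k_max` (clusterer) | 20 | components | more subclones than this are not resolvable at desk-scale depths |
| `exclude_below` | 0.04 | VAF | subclone callers recover one large spurious cluster of rare (<4%) tip variants; the single largest cluster is flagged when its mean falls below this |
| `init_a`, `init_b` | 0.001, 0.3 | — | conventional optimizer starting values for the age-model fit |
| `mean_depth` | — | reads | target design depth for `simulate_depth()` |

## The age model fit

`fit_age_model()` maximizes a Gaussian likelihood on $\log \lambda$
(common variance, no per-individual weights), which coincides with least
squares on the log scale.  The optimizer (BFGS with analytic gradient)
runs from the stated initial values; the closed-form OLS solution is
computed as a cross-check, recorded in `fit_log`, and used only if the
optimizer stops above it.  The residual spread, standard errors and
provenance (threshold, depth profile, panel tag) are stored on the model
and serialized to JSON.

Choices worth spelling out:

* **Unweighted likelihood.**  A meta-regression framework would admit
  per-individual variances; none are specified for this problem, so the
  minimal unweighted Gaussian ML is used and surfaced in the model's
  `fit_log$likelihood` tag.
* **Natural logarithm.**  Any fixed base gives an internally consistent
  $(a, b)$ pair; natural log matches the likelihood machinery.
* **$\lambda = 0$.**  An individual with no retained variants is outside
  model support: dropped from training with a warning naming the sample,
  and an explicit error at prediction time rather than $-\infty$.
* **Negative predictions** (very small $\lambda$) are returned as-is with
  a `negative` attribute, not clipped — over-estimation for the young is a
  property of the model worth seeing.

`loo_evaluate()` refits per held-out individual and reports MAE/RMSE
overall, over the age bands 0–30, 31–45, 46–60, 61–75, 76–100 (implemented
as contiguous breaks so real-valued ages partition) plus an under/over-65
split, and a calibration regression of predictions on ages with seeded
bootstrap percentile intervals.

## Read-depth resampling and panels

`simulate_depth()` emulates re-sequencing a spectrum under a finite-depth
design: per variant, depth $r \sim \text{Poisson}(\bar r)$ and mutant
reads $m \sim \text{Binomial}(r, \text{VAF})$; variants with $r = 0$ are
unobserved and dropped, the rest take VAF $m/r$, and the tip filter is
re-applied.  Each variant draws from a substream derived from (seed,
variant id), so subsetting a spectrum never shifts the other variants'
draws.

One property deserves emphasis: since $E[m/r \mid r > 0]$ equals the input
VAF, resampling a tip-filtered spectrum preserves the *expected* $\lambda$
at any depth (at depths $\gtrsim 1/\text{threshold}$ the re-applied
threshold can reject low-$m$ draws and pushes the mean slightly down).
What depth changes is the dispersion of observed VAFs and *which* variants
are detected at all — in real pipelines, deeper sequencing lets the caller
report more low-frequency variants, which is why empirical $\lambda$
grows with depth.  The resampler operates on a fixed variant list and does
not emulate that detection effect.  The quantity that matters for
modelling is robust either way: training and predicting at the *same*
depth profile yields phyloAge\* estimates that track full-depth estimates
almost perfectly (the acceptance checks require $R^2 \ge 0.9$ at a mean
depth of 30; the measured value is ≈ 0.999).

`restrict_panel()` intersects a spectrum with BED regions (0-based
half-open, via rtracklayer) or a gene list, for building panel-matched
models.

## The synthetic cohort generator

`simulate_individual()` emulates the study design the method is meant for:

* `n_lineages = 300` sampled HSC tips (colony-seq studies sample a few
  hundred per person);
* embryonic diversification into those lineages within
  `embryonic_window = 0.1` years, emitted as a caterpillar of near-zero
  branches so trees stay strictly binary for newick portability;
* CH founding events as an inhomogeneous Poisson process with rate
  $n \cdot \texttt{ch\_rate} \cdot e^{\texttt{ch\_age\_coef}\, t}$
  (defaults $3\times10^{-5}$ per lineage-year and 0.05/yr).  The defaults
  give on the order of one event by age 30 and ~10 by age 80, and a
  realized $\log\lambda$–age slope in the 0.08–0.1/yr range — the same
  order as fits to healthy colony-seq cohorts;
* converted clade fractions drawn from Beta(1, 9) (right-skewed, mean
  10%, minimum two lineages), with sizes resampled and logged when they
  exceed the remaining primary lineages;
* instantaneous clade establishment: internal splits of a new clade are
  laid down within `expansion_window = 0.05` years of founding;
* mutations per branch as Poisson(17 × branch years).

Ground truth is exact by construction: `true_decay()` sums
$\tfrac{1}{2} f \times n$ over non-tip branches with carrier fraction
$f \ge 2\,\theta$, and equals `lambda_metric()` on the emitted noise-free
VFS to floating-point precision for every individual — the central
identity the test suite sweeps.

What the generator does **not** emulate: developmental (embryonic) shared
variants — embryonic branches carry zero mutations so that CH-free
individuals have purely tip-private spectra; per-driver selection
coefficients; nested expansions within an existing clade; copy-number
alterations; stem-cell exhaustion; and sequencing error.  Passing tests
therefore demonstrate the algebraic and statistical correctness of the
pipeline under the stated generative model, not calling accuracy on real
reads.

`calibrated_cohort()` bypasses trees entirely and draws $(\text{age},
\lambda)$ pairs from the exponential model with log-normal noise, for
fast, exactly-calibrated tests of the fitting machinery.

## Comparison statistics

For benchmarking against classical diversity measures the package computes
nucleotide diversity $\pi$ (from the VFS via carrier frequency $p = 2
\cdot \text{VAF}$ with the $n/(n-1)$ correction, or from a genotype matrix
as mean pairwise differences — the two routes agree exactly), Tajima's
$D$ and Fay & Wu's $H$ on the binary somatic alignment (reference allele
ancestral by construction; per-site pairwise deletion for missing calls),
Hill numbers of order 0/1/2 on inferred cluster frequencies, the largest
retained VAF, and a lineages-through-time Shannon diversity.

The LTT statistic cuts the phylogeny where embryonic diversification
plateaus.  The changepoint is the interior split event with the largest
*proportional* drop between incoming and outgoing slope of log lineage
count — raw second differences are dominated by the near-simultaneous
embryonic splits, whose curvature scales inversely with their spacing.
With no interior event the cut falls back to 2.5 years, the midpoint of
the typical 2–3-year plateau, clamped to half the tree height.  On
simulated trees the statistic reproduces the Shannon index of the known
clade decomposition exactly.

`cluster_vafs()` stands in for full Dirichlet-process subclone inference
with a one-dimensional binomial mixture over (mutant count, depth) pairs:
EM for 1..`k_max` components, k-means++-style seeding (deterministic given
`seed`), BIC selection with ties broken toward fewer components, hard
assignment by maximum posterior, and reported cluster frequencies equal to
exact member-mean VAFs.  It preserves the output contract (cluster size
and mean) at a desk-scale cost; it does not reproduce MCMC posterior
uncertainty or multi-sample joint clustering.

## Numerical choices and degenerate inputs

* Tip filtering keeps `vaf >= threshold` (inclusive), is idempotent, and
  composes: filtering at $\theta_1$ then $\theta_2 \ge \theta_1$ equals
  filtering at $\theta_2$.
* EM success probabilities are clamped to $[10^{-6}, 1-10^{-6}]$; BIC
  ties (within $10^{-8}$) resolve to fewer components; empty components
  after hard assignment are dropped and clusters renumbered by decreasing
  mean VAF.
* All-equal training ages, negative $\lambda$, fewer than 3 usable
  training points, fewer than 4 LOO individuals, zero age variance in
  calibration, matrices with no segregating sites, and trees with fewer
  than 2 tips are errors with specific messages, not silent NA.
* Seeded routines (`cluster_vafs`, `simulate_*`, `calibrated_cohort`,
  bootstrap CIs) restore the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script use: 100 random spectra for
the $\gamma \equiv \lambda$ identity; cohorts of 20 individuals aged 5–80
at 300 lineages for the simulator identity; 200 replicates of 40
individuals for noisy parameter recovery; a 40-individual cohort for
matched-depth modelling; and 200 random 4–8 lineage matrices for the
$D$/$H$/$\pi$ oracle sweep.  These sizes were chosen to exercise every
code path at interactive turnaround; all identities asserted are
size-independent.

## Known limitations

* The spurious-cluster exclusion defaults to flagging only the single
  largest cluster (when its mean VAF is below 4%); spectra with several
  distinct rare clusters may need `exclude = "all_below"`.
* $\pi$ from a bulk VFS assumes heterozygous carriers ($p = 2\,\text{VAF}$),
  which overstates carrier fractions under loss of heterozygosity or CNAs;
  no CNA adjustment is attempted anywhere.
* The depth resampler models sampling noise, not variant detection, as
  discussed above.
* Wide-panel VAFs from targeted assays are taken as-is, with no
  re-normalization.
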