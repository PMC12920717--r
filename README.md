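# phyloage

Physiological blood age from somatic variant frequency spectra.

## The problem

Hematopoietic stem cells (HSCs) diversify during embryogenesis and then
mostly self-renew for decades, each lineage accumulating somatic
single-nucleotide alterations at ~17 per genome per year.  With age,
clonal hematopoiesis (CH) expands some lineages into clades of
near-identical cells, eroding the phylogenetic diversity of the blood —
an erosion associated with blood-cancer risk.  Measuring it directly
requires colony-sequencing hundreds of single HSCs and rebuilding their
phylogeny, which is too expensive for routine use.

`phyloage` measures the same erosion from the **variant frequency
spectrum** (VFS) that ordinary bulk sequencing already provides.  Every
variant carried by an expanding clade's founding lineage shows up at an
elevated, shared variant allele frequency (VAF), so a clade converting a
cell fraction *f* whose founder carried *n* variants removes diversity in
proportion to *f* × *n*.  Summing over inferred subclonal clusters gives

    gamma = sum_i f_i * n_i

and, because cluster frequency times size is just the sum of member VAFs,
the cluster-free equivalent

    lambda = sum_k mu_k

— the sum of VAFs over all variants above a 1% tip-variant threshold
(variants private to a single sampled lineage carry no expansion signal).
In healthy cohorts log(lambda) rises linearly with age, so a two-constant
model converts lambda into a physiological blood age:

    log(lambda) = a + b * age        phyloAge* = (log(lambda) - a) / b

The package provides the VFS data structures and I/O (TSV, VCF allele
depths, colony genotype matrices), germline and tip-variant filtering,
the lambda/gamma metrics with a binomial-mixture VAF clusterer, the age
model with leave-one-out and calibration diagnostics, read-depth
resampling and panel restriction for matched-coverage models, classical
comparison statistics (pi, Tajima's D, Fay & Wu's H, Hill numbers, LTT
Shannon diversity), and a forward simulator of HSC phylogenies with known
ground truth.  A command-line front end lives in `exec/phyloage`.

## Worked example

Simulate a 62-year-old with age-dependent CH, compute lambda, and read
off the physiological age under a reference model:

```r
library(phyloage)

ind <- simulate_individual(age = 62, sim_params(), seed = 7)
ind
#> simulated individual: age 62 y, 300 lineages, 9 CH event(s), 216324 variant(s), true decay 175.1

lam <- lambda_metric(ind$vfs, threshold = 0.01)
round(lam, 3)
#> [1] 175.117

ref   <- calibrated_cohort(a = -1.65, b = 0.084, ages = seq(20, 80, 5))
model <- fit_age_model(ref)
model
#> phyloAge* model: log(lambda) = -1.65 + 0.084 * age
#>   n = 13, sigma(log) = 0, threshold = 0.01, depth = full, panel = all

predict_phyloage(model, lam)
#> [1] 81.1            # phyloAge*, years
residual_age(model, lam, age = 62)
#> [1] 19.1            # physiologically ~19 years older than chronological
```

The nine clonal expansions this individual accumulated push lambda to
175, i.e. a predicted blood age of 81 against a chronological age of 62.
On the noise-free spectrum lambda equals the simulator's ground-truth
decay (sum of clade fraction/2 × founder mutations) exactly — that
identity, along with brute-force oracles for every comparison statistic,
is what the test suite asserts.

For real data, start from `read_vfs()` (TSV or VCF with `AD` depths) or
`genotype_matrix_to_vfs()` for colony genotypes, apply
`cohort_germline_filter()` to bulk spectra without matched germline, and
fit on your reference cohort's `(age, lambda)` table.  Train and predict
at the same depth profile (`simulate_depth()`) and panel
(`restrict_panel()`) when the target data are shallower or targeted.

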