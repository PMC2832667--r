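---
title: "Estimating ancestry from pooled-DNA SNP arrays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ancestry from pooled-DNA SNP arrays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genome-wide genotyping of pooled DNA trades individual genotypes for a
per-SNP *estimate* of the pool's allele frequency, obtained from the
relative hybridization intensity of the two allelic probes. Two things
make these estimates usable for ancestry work despite their noise: the
enormous number of SNPs on a modern array, which lets regression average
the noise away when estimating admixture proportions; and an explicit
error model, which lets a case/control-style test be deflated so that
only differences exceeding the pooling noise are declared ancestry
informative markers (AIMs).

This vignette records the models `poolancestry` implements, the
parameters that matter, the numerical conventions chosen where the
underlying geometry is degenerate, and what the synthetic-data generator
does and does not emulate.

# Polar allele-frequency estimation

For each SNP, individuals genotyped on the same plate form three
bivariate clusters in (A-probe, B-probe) intensity space. The model
uses, per genotype class $g \in \{AA, AB, BB\}$, the cluster centroid
and $2\times 2$ covariance. The orientation of a cluster is the angle of
its covariance major axis,

$$\theta = \tfrac12\,\mathrm{atan2}\!\left(2C_{xy},\; C_{xx} - C_{yy}\right),$$

the canonical rotation angle of a Gaussian cloud. The lines through the
AA and BB centroids at angles $\theta_{AA}$ and $\theta_{BB}$ intersect
at the transform origin $O$; the unit directions from $O$ toward the AA
and BB centroids span an (in general oblique) coordinate frame
$(x', y')$.

A pooled replicate's intensity point $P$ is expressed in that frame and
its angle is corrected by the normalization factor
$NF = x'_{AB} / y'_{AB}$, computed from the heterozygote centroid, so
that unequal allelic probe brightness cancels:
$\varphi = \mathrm{atan2}(NF \cdot y'_P,\; x'_P)$. The allele frequency
for allele A is the linear interpolation $\mathrm{AF} = 1 - \varphi/90^\circ$.
This pins the three calibration points exactly — the AA direction maps
to 1, the AB centroid to 0.5 (by construction of $NF$), the BB direction
to 0 — and is monotone in angular position between the axes. The closed
form of the angle-to-frequency map beyond those three constraints is a
design choice of this package; linear interpolation in corrected angle
is the simplest map satisfying the calibration contract, and the
zero-noise round trip through the synthetic generator is exact to
machine precision under it (asserted in the tests, including under a
two-fold allelic-intensity imbalance).

Replicates of a pool are averaged; the squared standard error of the
mean is the pooling error variance $\mathrm{var}(e_p)$ carried into the
AIM test. Estimates are deliberately *not* clipped to $[0,1]$ at this
stage: values slightly outside are diagnostic of rare alleles or failed
hybridization and drive the negative-MAF exclusion downstream.

Degenerate geometry is flagged rather than silently repaired:

* near-parallel homozygous lines (angular separation below 0.5°) leave
  $O$ undefined — SNP flagged and excluded downstream;
* an isotropic homozygous covariance has no orientation — the
  convention $\theta_{AA}=0°$, $\theta_{BB}=90°$ is applied and the SNP
  flagged low-confidence;
* an AB centroid on or outside the $(x', y')$ axes (collapsed
  heterozygote cluster) leaves $NF$ undefined — flagged;
* a replicate point at $O$ has no angle — its AF is `NA`.

# Quality control

Pooled assays fail in ways individual genotyping does not, so four
SNP-level filters are applied before any inference:

| filter | score | default cut-off | rationale |
|---|---|---|---|
| FLD | minimum Fisher's-linear-discriminant separation over the adjacent cluster pairs, $\Delta\mu^\top (C_1+C_2)^{-1} \Delta\mu$ | ≥ 3.6 | collapsed or blended clusters make the polar transform meaningless |
| r | fraction of replicates with radius ratio $r/r' \ge$ 0.8 must be ≥ 80% | 0.8 / 0.8 | weak hybridization (small radius from $O$) yields unstable angles; the 0.8/80% operating point balances false positives against genome coverage with triplicate pools |
| MAF | panel-wide pooled minor allele frequency | ≥ 0.05 | AF estimation error is on the few-percent scale, so rare SNPs are indistinguishable from noise; estimates outside $[0,1]$ in any pool are hard-dropped |
| hist | variance across pools of (pooled − individual) AF | ≤ 1e-3 | requires a training panel typed both ways; verdicts are portable to other panels on the same array |

$r'$ — the radius expected for an average individual sample at the same
allele frequency — is the linear interpolation of the three centroid
radii in AF (BB at 0, AB at 0.5, AA at 1), with the AF clamped to
$[0,1]$ for interpolation only. The definition of the "average
individual" signal is not uniquely determined by the geometry; linear
interpolation of centroid radii is this package's choice.

The FLD and hist cut-offs have no universal value; they were fixed once
by running the packaged tuning utilities on the shipped synthetic study
conditions — `tune_cutoff_by_pfp()` (proportion of top-ranked pooled
tests that a training panel's individual genotypes call null) and
`tune_cutoff_by_lambda()` (genomic-control $\lambda$ of a null
pool-versus-pool comparison, usable without any individual genotypes) —
choosing the loosest cut-offs at which the corrupted-SNP modes of the
generator are removed while clean SNPs are retained. At these defaults
the combined filters remove ≥90% of deliberately corrupted SNPs while
retaining ≥80% of clean ones, and a null two-pool comparison is
calibrated ($\lambda \in [0.9, 1.1]$) after deflation; both properties
are asserted in the test suite, not assumed.

# Admixture regression

Across post-QC SNPs with reference call rate $> 0.8$ in every panel,
ordinary least squares fits

$$P_{ui} = c + \sum_j \beta_j P_{ji} + \varepsilon_i ,$$

where $P_{ui}$ is the pooled AF of the study population and $P_{ji}$ the
reference-panel frequencies, all oriented to allele A of the array
annotation. $\beta_j$ estimates the ancestry proportion from population
$j$. Three deliberate non-choices:

* no constraint $\beta_j \ge 0$ or $\sum_j \beta_j = 1$ — the shortfall
  $1-\sum\beta$ *is* the signal that the panels miss a component of
  ancestry;
* no variable transformation — plain OLS is the default; a logit or
  other proportion-regression would be a reasonable extension but is
  not what this implementation is calibrated around;
* OLS standard errors are reported as-is. Linkage disequilibrium between
  SNPs makes them optimistic; treat them as lower bounds, and thin SNPs
  by distance before refitting if honest uncertainty matters.

Because allele A is assigned independently of the minor allele, the
expected AF is ≈ 0.5 in every panel; `check_allele_orientation()` warns
when a panel's mean AF deviates from 0.5 by more than 0.05, since the
identity "unexplained ancestry ≈ 2 × intercept" (reported as the `two_c`
diagnostic) relies on it.

The pseudopopulation — the fitted combination
$\sum_j \beta_j P_{ji} + c$, clipped to $[0,1]$ with a logged count — is
assigned an effective size of 120 diploid individuals when two
HapMap-scale reference panels are used and 210 when three are (the
conventional panel sizes); any other configuration requires an explicit
size. Its pooling variance is 0 by construction.

# The deflated chi-square test

The naive test treats the estimated allele counts as observed and
computes the Pearson $\chi^2$ of the implied $2\times2$ allele-count
table (1 df). Pooling adds error variance the naive statistic ignores,
inflating it; the corrected statistic is

$$\chi^2_{\mathrm{corr}} = \chi^2_{\mathrm{naive}} \cdot
  \frac{V}{V + \mathrm{var}(e_{p,\mathrm{case}}) + \mathrm{var}(e_{p,\mathrm{control}})},
  \qquad
  V = \frac{p_c(1-p_c)}{2n_c} + \frac{p_t(1-p_t)}{2n_t}.$$

With several pools on one side, the combined AF is the pool-size
weighted mean and its error variance is $\sum_i w_i^2 SE_i^2$. The
ratio is computed before multiplying so that zero pooling variance
deflates by exactly 1. SNPs with an estimated AF outside $[0,1]$ in
either group cannot form a count table and are excluded with reason
`negative-MAF`.

Genomic control divides the corrected statistics by
$\lambda = \mathrm{median}(\chi^2)/0.4549$, floored at 1 so the
correction is never anti-conservative. The corrected statistic maps
back to the frequency scale as
$|\Delta\mathrm{AF}_{\mathrm{corr}}| = \sqrt{\chi^2_{\mathrm{corr}} \cdot V}$
with the sign of the raw difference — holding the pseudopopulation AF
fixed and moving the pooled AF the deflated distance. Near the null this
equals the raw difference when pooling variance is zero (asserted to
1e-6 on constructed inputs) and shrinks monotonically as pooling
variance grows.

## LD categorization, pruning and candidate lists

A real AIM should be supported by its neighborhood. SNPs within 20 Mb
(boundary inclusive) and genotype-dosage $r^2 > 0.5$ in a designated
reference panel count as LD neighbors; $r^2$ is the squared Pearson
correlation of unphased dosages, since haplotypes are not assumed
available. A SNP is *encouraging* if ≥1 neighbor has GC-corrected
$P<0.05$ and ≥ half have $P<0.1$; *discouraging* if none reach
$P<0.1$; otherwise *inconclusive* (which includes SNPs with no
neighbors). Non-discouraging SNPs are greedily pruned to ≥ 4 Mb
separation (strictly closer SNPs removed, best $P$ kept first); pruning
can be disabled to reuse already-genotyped SNPs at the cost of an
LD-independent panel.

Two candidate lists (default 25 each): the top SNPs by GC-corrected $P$
excluding those discouraging under either the filtered or unfiltered LD
set; and the SNPs with $P<10^{-3}$, ≥2 unfiltered LD neighbors and an
encouraging categorization under both sets, ranked by the count of
neighbors with $P<0.05$. Ties in that count break by smaller $P$, then
lexicographic SNP id — the rule is arbitrary but deterministic.

# What the generator emulates — and what it does not

`simulate_pool_study()` produces drifted reference panels
(Balding–Nichols: $\mathrm{AF}_j \mid p \sim
\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ around an ancestral $p$ uniform
on $[0.05, 0.95]$), pool cohorts drawn binomially at the
proportion-weighted mixture frequency (each allele copy independently
picks its source population — vectorised as one binomial draw, which is
identical in law), per-SNP cluster models with configurable allelic
imbalance, and replicate intensity points placed by inverting the polar
transform at the true AF plus angular (AF-scale) and radial noise.
Angular and radial noise are separate knobs because they stress
different filters (MAF/hist versus r).

Default study conditions: 82%/18% two-way admixture, drift $F = 0.15$
per reference panel (continental-scale divergence), pools of 250
individuals in triplicate, replicate AF noise SD 0.02, ancestral AF
uniform on $[0.05, 0.95]$. The noise magnitude is a calibration knob,
not a claim about any particular array: the intensity-noise process of
real arrays is not published, so the generator is calibrated on the
AF scale where its consequences are interpretable.

Three corruption modes exercise QC: `noisy` (replicate AF noise SD
0.15), `collapsed` (heterozygote cluster dragged onto AA with inflated
covariances) and `dim` (hybridization radius at 30% of expectation).

A *missing ancestry* component is simulated as an extra population with
its own drift **from an independent ancestral draw**, so it is
uncorrelated with the reference panels while keeping mean AF ≈ 0.5.
This choice makes the shortfall identity clean
($\sum\hat\beta \approx 1-w$, $\hat c \approx w/2$) and is the
qualitative phenomenon of interest; real missing ancestry is typically
*correlated* with the available panels, in which case part of it is
absorbed into the $\beta$'s and the shortfall understates it. Passing
the recovery tests therefore shows the regression machinery is correct,
not that real panels ever separate this cleanly.

Likewise the generator assigns SNPs to 22 chromosomes at even spacing
and simulates no linkage disequilibrium (block-correlated genotypes are
built directly in the LD tests); real data's LD both helps (neighbor
support) and hurts (optimistic regression SEs) in ways the synthetic
tests do not measure.

# Evaluation utilities

$F_{ST}$ defaults to the Hudson-style ratio of averages — per locus
$(p_1-p_2)^2$ minus the within-population finite-sample terms over
$p_1(1-p_2)+p_2(1-p_1)$, averaged before the ratio — with a naive
Wright $1-H_S/H_T$ option; the estimator behind any published pooled
$F_{ST}$ value is rarely stated, so both are exposed and the choice is
documented per result. Sample sizes may be omitted, in which case the
finite-sample correction vanishes (population frequencies). Tiny
negative estimates are clamped to 0.

PCA normalizes each SNP by $\sqrt{\hat p(1-\hat p)}$ after centering,
decomposes the individuals, and iteratively removes individuals more
than 6 SDs from the mean along any of the top 10 axes (at most 5
rounds) — the standard EIGENSTRAT operating point, used here as a
default rather than a fitted value. Axis correlation is reported as
$|r|$ because an eigenvector's sign is arbitrary.

The null maximum-deviation simulation draws each SNP's allele count as
$\mathrm{Binomial}(2n, p_{\mathrm{mix}})$ and reports the maximum
absolute deviation of sample AF from the mixture expectation — the
yardstick below which an apparent AF difference is explainable by
sampling alone (just under 0.08 at 382,000 SNPs and 521 individuals;
recomputed, not hard-coded, by `scripts/acceptance.R` and the test
suite).

# Problem sizes and numerical conventions

The test suite runs the full admixture-recovery property at $10^5$ SNPs
and the pipeline-level properties (null calibration, AIM power, QC
effectiveness) at $2\times10^4$ SNPs with 2–4 pools of 130–250
individuals in triplicate — sizes chosen so each property's Monte-Carlo
error is comfortably inside its assertion margin while the whole suite
runs in well under a minute. Distances are base pairs on 1-based
positions; the LD window is boundary-inclusive at 20 Mb and pruning
removes strictly-closer-than-4 Mb SNPs. All thresholds are `qc_config()`
/ function arguments, never hard-coded.

# Known limitations

* The angle-to-frequency map is pinned only at three points; any
  monotone map through them is admissible in principle, and real
  arrays' intermediate behavior may differ from linear-in-angle.
* OLS standard errors ignore LD; the reported `se` is optimistic on
  real genome-wide data.
* The hist-filter requires a training panel with individual genotypes;
  its portability across panels assumes a shared array and processing
  chain.
* The generator's missing-ancestry component is uncorrelated with the
  reference panels by construction (see above).
* Stage-1 replicate QC (plate-level intensity/call-rate screening) is
  out of scope; inputs are assumed to be replicate-screened upstream.
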