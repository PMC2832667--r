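# poolancestry

Ancestry estimation and ancestry-informative-marker (AIM) discovery from
**pooled-DNA SNP array data**.

Genotyping a DNA pool instead of its individual members cuts the cost of a
genome-wide scan by an order of magnitude, at the price of observing only
an *estimated* allele frequency per SNP — with extra, pooling-specific
error on top of binomial sampling. `poolancestry` implements the full
analysis chain that makes those noisy estimates useful for population
genetics:

1. **Polar allele-frequency estimation.** Each SNP's three genotype
   clusters (AA, AB, BB) in probe-intensity space define an origin *O*
   (the intersection of the lines through the homozygous centroids,
   angled at each cluster's own orientation
   θ = ½·atan2(2·C<sub>xy</sub>, C<sub>xx</sub> − C<sub>yy</sub>)).
   A pooled hybridization signal is expressed in the oblique frame
   spanned by the AA and BB directions from *O*; after a
   heterozygote-calibrated normalization factor
   NF = x′<sub>AB</sub>/y′<sub>AB</sub> (a k-correction for unequal
   allelic probe brightness), its corrected angle is interpolated
   linearly to an allele frequency with AA → 1, AB → 0.5, BB → 0.
   Replicates of a pool are averaged; their spread gives the pooling
   error variance var(e<sub>p</sub>).
2. **SNP quality control.** Four filters remove assays that genotype
   poorly in pools: cluster separation by Fisher's linear discriminant
   (FLD), the intensity-radius ratio r/r′ across replicates, the pooled
   minor allele frequency, and (given a training panel with individual
   genotypes) the variance across pools of the pooled-minus-individual
   AF difference ("hist" filter). Tuning utilities sweep cut-offs
   against the proportion of false positives and the genomic-control
   inflation factor λ.
3. **Admixture regression.** Across SNPs, the pooled allele frequency
   P<sub>u</sub> is regressed on reference-panel frequencies:
   P<sub>ui</sub> = Σ<sub>j</sub> β<sub>j</sub> P<sub>ji</sub> + c + ε.
   Each β<sub>j</sub> estimates the proportion of ancestry from
   reference population *j*; with mean allele frequencies ≈ 0.5, the
   unexplained ancestry ≈ 1 − Σβ ≈ 2c.
4. **Pseudopopulation and AIM scan.** A weighted reference panel with
   AF<sub>i</sub> = Σ<sub>j</sub> β<sub>j</sub>P<sub>ji</sub> + c is the
   null expectation; each SNP is tested with a Pearson allele-count χ²
   **deflated for pooling error**,
   χ²<sub>corr</sub> = χ²·V/(V + var(e<sub>case</sub>) + var(e<sub>control</sub>)),
   where V is the binomial sampling variance. Statistics are
   genomic-control corrected, SNPs categorized by the evidence at their
   LD neighbors (encouraging / inconclusive / discouraging), pruned to
   an independent panel (≥ 4 Mb apart), and distilled into two candidate
   AIM lists. The corrected AF difference √(χ²<sub>corr</sub>·V) maps
   the statistic back to the frequency scale.
5. **Evaluation.** Hudson- or Wright-style F<sub>ST</sub>, PCA with
   EIGENSTRAT-style iterative outlier removal, axis correlation between
   an AIM panel and genome-wide data, and a null simulation of the
   maximum AF deviation expected from sampling alone.

A first-class synthetic-data generator (Balding–Nichols drifted
reference panels, admixed cohorts, bivariate intensity clusters, noisy
and deliberately corrupted pool replicates) provides every input with
known ground truth, so the whole pipeline is testable without array
data.

## Worked example

```r
library(poolancestry)

cfg <- sim_config(n_snps = 50000, n_individuals = 250, n_pools = 2,
                  n_replicates = 3, admixture_proportions = c(0.82, 0.18),
                  drift_fst = 0.15, pool_noise_sd = 0.02,
                  corrupt_fraction = 0.05, seed = 1)
study <- simulate_pool_study(cfg)
res <- run_pipeline(study = study)
print(res)
print(res$admixture)
```

```
Pooled-ancestry pipeline result
  QC-passing SNPs: 41912
  regression SNPs: 41912
  admixture: ref1=0.819, ref2=0.180; intercept=0.00088
  GC lambda: 1; F_ST vs pseudopopulation: 0
Admixture-proportion fit (41912 SNPs)
       beta       se
ref1 0.8185 0.000361
ref2 0.1796 0.000351
intercept: 0.0008804 (se 0.000176)
summed proportion: 0.9981; unexplained ancestry: 0.0019; 2c diagnostic: 0.0018
```

The cohort was simulated with true ancestry proportions 0.82/0.18 and 5%
corrupted SNPs; QC removed most corrupted assays (41,912 of 50,000 SNPs
retained), and the regression recovers the admixture proportions to
three decimals with a near-zero intercept — i.e. essentially no
unexplained ancestry, as constructed. The F<sub>ST</sub> between the
pooled panel and its fitted pseudopopulation is ~0 and the
genomic-control λ of the AIM scan is at its floor of 1, both as expected
for a cohort fully described by its reference panels.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/poolancestry.R simulate --n-snps 10000 --seed 1 --out-dir study/
Rscript inst/cli/poolancestry.R run --config study/run.config
```

## Layout

- `R/` — synthetic data, intensity AF estimation, QC filters, admixture,
  AIM detection, population-genetic evaluation, I/O and pipeline.
- `vignettes/pooled-ancestry.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations).
- `inst/cli/poolancestry.R` — command-line front end.
- `tests/testthat/` — unit, property and acceptance tests; all fixtures
  are generated in code.
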