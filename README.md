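# hicpair

Comparative analysis of paired binned Hi-C contact maps in R.

`hicpair` is for researchers who have two binned genome-wide contact maps —
two cell types, two conditions, two developmental stages — and want to ask,
with the standard toolkit of the 3D-genomics field, *where and how* the two
genomes' spatial organization differs. It was built around the comparison of
mouse sperm (protamine-packaged, highly compacted) and fibroblast genomes at
1 Mb resolution, and implements that study design end-to-end:

* **Iterative correction** (symmetric Sinkhorn balancing) of raw count
  matrices, with zero-marginal and low-coverage masking, biases satisfying
  `corrected[i,j] = raw[i,j] / (b_i * b_j)`, and the shot-noise error model
  `sqrt(K)/K` for a contact supported by `K` reads.
* **A/B compartment tracks**: per-chromosome first eigenvector (E1) of the
  observed/expected Pearson correlation matrix; track comparison by
  perpendicular distance to the least-squares line through the
  `(E1_a, E1_b)` dots.
* **Regional differences** by three per-bin metrics — Euclidean distance
  `E_i = sqrt(sum_j (a_ij - b_ij)^2)` over cis partners, per-bin
  Pearson/Spearman correlation, and eigenvector distance — with a
  split-half *poor-bin* filter (`C_i < M - SD`, flanks excluded), top-100
  ranking, reference-based bias exclusion, and three-way intersection with
  its chance expectation `N_Eucl * N_P * N_E1 / N_T^2`.
* **Per-contact differential testing** under the uniform contact
  probability model `P = m / M` (mappable contacts = more than one read),
  normal-approximation gate `M*P*(1-P) > 9`, unpooled two-proportion
  z-test, Bonferroni q-values, and two-fold classification.
* **Distance scaling**: P(s) curves, log-log power-law fits (the study's
  sperm and fibroblast maps follow `P(s) ~ s^-1.07` and `P(s) ~ s^-1.27`),
  cis/trans ratios, interchromosomal enrichment, and the
  chromosome-length-difference correlation.
* **"Compression" normalization**: per-distance coefficients
  `K_j = target_j / source_j` (applied only when their relative error
  `sqrt(1/R_t + 1/R_s)` is at most 5%) rescale one map's P(s) onto the
  other's while preserving within-distance contact ratios and total mass —
  separating genome-wide packaging-density differences from locus-specific
  rewiring.
* A **synthetic map generator** with known ground truth (power-law decay,
  plaid compartments, TAD blocks, uniform trans background, per-bin
  visibility field, Poisson sampling, planted differences) that backs the
  entire test suite, plus a pipeline driver and CLI.

## Worked example

Two synthetic 300-bin maps that differ *only* in their distance-decay
exponent (1.07 vs 1.27), i.e. in packaging density, not in specific
contacts:

```r
library(hicpair)
spec <- preset_spec("compression", seed = 1)
pair <- generate_pair(spec)

corr_a <- iterative_correction(pair$map_a)
corr_b <- rescale_total(iterative_correction(pair$map_b), corr_a$total)

fit_power_law(ps_curve(corr_a))
#> PowerLawFit: P(s) ~ s^-1.079 (se 0.025, 99 points, 2e+06-1e+08 bp)
fit_power_law(ps_curve(corr_b))
#> PowerLawFit: P(s) ~ s^-1.278 (se 0.026, 99 points, 2e+06-1e+08 bp)

tests_pre <- test_contacts(corr_a, corr_b)
attr(tests_pre, "counts")
#>        untestable   not_significant       significant significant_2fold
#>             29980              8968               271                 1

coeffs <- compression_coefficients(corr_a, corr_b)
sum(coeffs$applied)
#> [1] 66
tests_post <- test_contacts(corr_a, apply_compression(corr_b, coeffs))
attr(tests_post, "counts")
#>        untestable   not_significant       significant significant_2fold
#>             27964             11256                 0                 0
```

Reading the output: the fitted exponents recover the generating values; the
naive contact test calls 272 contacts significantly different, but *all* of
them are explained by the global P(s) difference — after compressing map b
onto map a's distance scaling, none remain. On real sperm/fibroblast data
the analogous normalization explained roughly a quarter to a third of the
differences, the remainder being locus-specific.

The full pipeline (correction → compartments → regions → contacts →
scaling → compression → re-test) runs as one call and writes a
deterministic report bundle (TSV/BED/bedGraph tables plus `summary.json`):

```r
cfg <- run_config(synthetic = "compression", reference = "deep", seed = 1)
run_comparison(cfg, "out/")
```

or from the command line:

```sh
Rscript inst/cli/hicpair.R run-all --preset compression --out out/ --seed 1
Rscript inst/cli/hicpair.R simulate --spec regional --out sim/ --seed 1
```

## Documentation

The methods vignette (`vignettes/comparative-hic-methods.Rmd`) documents
the statistical models, every tunable threshold and its default, what the
synthetic generator does and does not emulate, and the numerical/design
choices made where the published description is ambiguous.
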