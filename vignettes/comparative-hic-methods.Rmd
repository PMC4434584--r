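---
title: "Comparing two genomes' 3D architecture from binned Hi-C maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two genomes' 3D architecture from binned Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicpair)
```

# The problem

Hi-C and its tethered variant (TCC) measure, genome-wide, how often every
pair of loci is found in spatial proximity. After binning read pairs at a
fixed resolution (1 Mb here) the data form a symmetric contact matrix per
sample. `hicpair` implements a complete comparative pipeline for two such
maps — motivated by the comparison of transcriptionally silent, protamine-
packaged sperm chromatin against a somatic cell type (fibroblasts), but
applicable to any pair:

1. **Normalization** — iterative correction (symmetric matrix balancing)
   removes multiplicative per-bin visibility biases.
2. **Compartments** — first-eigenvector (E1) tracks summarize the A/B
   plaid pattern; tracks are compared via distance to a regression line.
3. **Regional differences** — three per-bin metrics (Euclidean distance,
   Pearson correlation, eigenvector distance), bias-filtered against a
   split-half reference, ranked, and intersected.
4. **Individual contacts** — a two-proportion z-test under a uniform
   contact-probability model, Bonferroni-corrected.
5. **Distance scaling** — P(s) curves, power-law exponents, cis/trans and
   interchromosomal metrics.
6. **"Compression" normalization** — rescales one map's per-distance
   contact mass onto the other's P(s), separating global packaging-density
   differences from locus-specific rewiring.

Every stage is exercised end-to-end on synthetic maps with known ground
truth; the real sperm/fibroblast libraries are not required (and their
headline counts are not reproducible at desk scale).

# Models and estimators

## Balancing and the read-support error model

Iterative correction assumes observed counts factor as
$O_{ij} = b_i\,b_j\,T_{ij}$ with equal true visibility for all bins. We
balance by the symmetric Sinkhorn update until the maximum relative
deviation of unmasked row sums is below `tolerance` (default `1e-6`,
`max_iter = 200`), then rescale the matrix to the input total and fold the
factor into the biases so `corrected = raw / (b_i b_j)` holds exactly.
Convergence is checked *before* the final update, so the row-sum
coefficient of variation at exit is strictly below the tolerance.

Bins with zero marginal are always masked; `mask_percentile` masks an
additional bottom-coverage fraction. When two maps are compared we mask the
*union* via combined marginals (`mask_low_coverage()`): a bin masked in one
map only would otherwise masquerade as a dramatic regional difference.

The shot-noise error of a contact supported by $K$ reads is
$\sqrt{K}/K$. This is always evaluated on raw read counts, even when the
values being analyzed are corrected: the information content of a contact
is set by its reads, not by its rescaled value.

A contact is **mappable** when supported by more than one read ($K \ge 2$).

## Compartment eigenvectors

Per chromosome, the corrected cis matrix is turned into an
observed/expected matrix (expected = mean contact at each separation,
computed over the retained bins at their true genomic separations), then
into its Pearson correlation matrix; E1 is the leading eigenvector, scaled
to unit variance over non-missing bins. We use the cis-only, per-chromosome
construction; whether the original analysis used cis-only or trans-informed
decomposition is not documented, but compartment tracks are displayed per
chromosome, which the cis construction matches.

Eigenvector sign is arbitrary. With a `reference` track (generator truth in
tests; GC content would be the natural choice on real data) each
chromosome is oriented to correlate positively with it; otherwise a
deterministic skewness rule (`sum(v^3) >= 0`) is applied.

`compare_e1()` fits a least-squares line to the $(E1_a, E1_b)$ dots and
reports each bin's perpendicular distance to that line. The default is the
OLS line of *b* on *a*, which matches the documented worked example; it is
not exactly symmetric under exchanging the tracks, so a `line = "tls"`
mode (orthogonal regression) is provided and is symmetric to machine
precision. On strongly correlated E1 tracks the two are nearly identical.
Note that distance to a line cannot see anti-correlation (collinear dots
give zero distances at $r = -1$); the returned Pearson/Spearman summaries
do.

## Regional differences and the poor-bin filter

For bin $i$, restricted to intrachromosomal partners $j \ne i$:

* Euclidean distance $E_i = \sqrt{\sum_j (a_{ij} - b_{ij})^2}$,
* Pearson and Spearman correlations of the two contact vectors,
* eigenvector distance from `compare_e1()`.

Metrics are computed on corrected maps rescaled to equal totals (the
formula speaks of read counts, but heatmaps in this analysis tradition are
corrected, and equal totals make the metrics depth-comparable); raw-count
input is possible by passing raw maps. Pearson, not Spearman, feeds
candidate selection — Spearman's rank sensitivity at low signal-to-noise is
the stated reason in the original analysis.

**Poor bins.** The split halves of a *reference* map (binomial thinning,
`thin_split()`) are corrected and correlated per bin; bins with
$C_i < M - SD$ (median and standard deviation over all bins) are "poor"
and excluded together with one flanking bin on each side within the
chromosome. Two design points matter:

* The rule only separates poor bins from the good bulk when the $C_i$
  distribution has a genuine bad tail that inflates $SD$. The reference
  table therefore deliberately drops coverage masks. In a perfectly
  homogeneous synthetic world the rule would clip ~16% of good bins at
  random — this is a property of the published rule, not of this
  implementation.
* The reference should be a deep, independent dataset (the original
  analysis used a separate deep ES-cell library). For synthetic runs,
  `sample_reference_map()` draws a plant-free map at 4x depth; at map
  depth the split-half noise is comparable to the visibility tail and the
  filter excludes good bins by seed luck.

**Selection.** Per metric, bins are ranked most-different-first over
non-excluded bins (ties broken by bin index, which the source analysis
leaves unspecified), the top `n = 100` form candidate sets, bins also in
the reference's top `n` for the same metric are removed, and the three
sets are intersected. The expected chance overlap is
$N_{Eucl} N_P N_{E1} / N_T^2$.

## Individual contact testing

Under the uniform model the probability of contact $(i,j)$ is
$P = m/M$ with $m$ the (corrected) support of the pair and $M$ the total
support over mappable contacts. A contact is tested when mappable in both
datasets ("both" is our reading of the mappable-in-both phrasing; a union
mode exists) and when $M P (1-P) > 9$ in both (normal-approximation gate).
The statistic is the unpooled two-proportion
$z = (P_a - P_b)/\sqrt{P_a(1-P_a)/M_a + P_b(1-P_b)/M_b}$.

The source prints $p = 2\,\Phi(z) - 1$, which evaluates to 0 for identical
proportions — that is a confidence level, not a p-value, and would make
every equal pair maximally "significant" under a small-p rule. We
implement the conventional two-sided $p = 2(1 - \Phi(|z|))$, which is what
the downstream usage (small p ⇒ significant) requires, and keep the
printed form behind `as_printed = TRUE` for audit. q-values are Bonferroni
($q = \min(1, p \cdot n_{tests})$, $n_{tests}$ = gated contacts);
significance is $q < 0.05$, with a two-fold class when
$\max(P_a/P_b, P_b/P_a) > 2$.

## Distance scaling and interchromosomal structure

`ps_curve()` averages contact frequency over all locus pairs per
separation (per-diagonal by default; logarithmic bins of ratio 1.3 for
display). `fit_power_law()` is OLS of $\log_{10} P$ on $\log_{10} s$; the
default range drops the first diagonal and separations supported by fewer
than 100 locus pairs (falling back to all usable diagonals on maps too
small to ever reach 100 pairs). The fit is exact, with zero standard
error, on any noiseless power law.

The interchromosomal expectation is implemented as the symmetrized
$0.5\,(S_i S_j/(T{-}S_i) + S_i S_j/(T{-}S_j))$ — the printed formula
repeats $(T - S_i)$ in both terms, almost surely a typo; the as-printed
form is available for audit. Two caveats we discovered and preserve:
the formula is *not* normalized to 1 under a uniform trans background
(equal chromosomes give a common constant below 1), so null checks assert
flatness across chromosome pairs rather than unity; and its value is
scale-invariant, which is what the enrichment interpretation needs.

## Compression

`diagonal_sums()` aggregates intrachromosomal mass per separation across
chromosomes (cross-chromosome "diagonals" are meaningless and trans
entries are never rescaled). Coefficients $K_j = \text{target}_j /
\text{source}_j$ carry a relative error combining the $\sqrt{K}/K$ errors
of numerator and denominator raw supports in quadrature,
$\sqrt{1/R_t + 1/R_s}$ — the propagation rule is unstated in the source;
quadrature is the standard choice for independent ratios. Coefficients
with error above 5% are not applied (effective $K_j = 1$, keeping the
output complete). After rescaling the applied diagonals, the whole matrix
(trans included — the source does not say; uniform rescale preserves all
within-distance ratios) is scaled back to the source's original total.

# The synthetic world

`synthetic_spec()` states a stylized two-cell-type experiment:

| Parameter | Default / stated world | Rationale |
|---|---|---|
| decay exponent α | 1.07 / 1.27 for the scaling worlds | the two printed P(s) exponents |
| trans weight | 0.1 | >90% of interactions are intrachromosomal in these libraries |
| compartment profile | alternating 20-bin blocks, amplitude 0.6 | ~2:1 within/between O/E contrast, a realistic plaid strength at 1 Mb |
| planted differences | multiplicative, region x partner-set | folds compare directly to the two-fold classification |
| coverage bias | none, or a fixed lognormal field (sd 0.35 in log) | a genome's mappability landscape: fixed across experiments, continuously distributed |
| depth | 1e6-1e7 by world | desk-scale stand-ins for 150-400M read-pair libraries |

Design notes:

* Depth normalization uses the *unplanted* base expectation, so a planted
  fold is exactly the expectation ratio between the cell types at affected
  pairs; the expectation matrix sums to the requested depth exactly only
  for plant-free specs (both properties cannot hold at once).
* Each cell type's child seed derives from the master seed plus a hash of
  that cell type's own parameters: identical parameters give identical
  maps (a stated determinism contract), different parameters give
  independent draws.
* A planted *region x all-partners* gain is nearly a pure bias pattern and
  is absorbed by iterative correction — by design, balancing cannot
  distinguish it from visibility. Detectable regional differences must
  change the *shape* of a bin's contact profile; the regional world
  therefore plants a compartment-rewiring gain (a 5-bin A-region gaining
  10-fold contacts with distal B-blocks in one cell type).
* The generator does **not** model polymer structure, TADs by default,
  spatially correlated mappability, restriction-fragment artifacts, or
  copy-number differences. A green test establishes that the estimators
  recover the stated statistical structure at the stated depths — not that
  they would behave identically on any real library.

# Stochasticity of the regional-recovery check

The three-metric procedure ends with an exclusion of the reference's
top-100 bins per metric. In any world, the reference's eigen-distance
ranks among well-covered bins are close to a noise lottery (split halves
of one map converge to identical E1 as depth grows, leaving rank order to
residual noise), so each good bin carries a ~5-8% chance per seed of being
ejected from one candidate set. Full 5/5 recovery of a planted region is
therefore intrinsically a per-seed event with probability ~0.7-0.85, under
*any* faithful implementation of the published procedure. The acceptance
test runs the canonical package seed (1); the fold-monotonicity test
allows up to two lottery losses. The vignette records this rather than
weakening the procedure (e.g., skipping the exclusion step would make
recovery deterministic but unfaithful).

# Numerical choices

* Balancing: tolerance `1e-6` on row-sum deviation, `max_iter 200`,
  non-convergence is an error reporting the residual.
* E1: chromosomes need ≥ 4 unmasked bins; degenerate (constant)
  correlation matrices yield missing tracks with warnings.
* Ranks: ties broken by ascending bin index (stable, reproducible).
* Gates and thresholds: q `0.05`, fold `2`, candidate n `100`, compression
  error gate `0.05` — all analysis-scale defaults of the source; all
  configurable in `run_config()`.
* All RNG flows from one master seed; `visibility_field()` uses its own
  fixed seed and restores the caller's RNG state.

# Known limitations

* Dense in-memory matrices: comfortable to ~5,000 bins (a 1 Mb mammalian
  genome); not intended for 10-40 kb resolutions genome-wide.
* Bonferroni only (as in the source); no FDR alternatives.
* No TAD calling, 3D modeling, or annotation enrichment — out of scope.
* The per-contact test treats corrected values as pseudo-counts in a
  binomial approximation; this inherits the source's assumption and is
  anti-conservative when biases were large before correction.
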