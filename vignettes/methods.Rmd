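---
title: "Methods: ChIP-qPCR enrichment quantification and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ChIP-qPCR enrichment quantification and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Chromatin immunoprecipitation followed by quantitative PCR measures how
strongly a histone modification (here the activating marks H3K4me3 and
H3K27ac) decorates a set of candidate loci — in the motivating design, 15
transcription-start-site amplicons around liver metabolic genes in 41 wild
house mice falling into two social phenotypes (socialized nest-box males
versus ostracized free-roaming males). The scientific question is whether
the per-locus marking levels differ between the groups, and whether the
whole 14-to-15-dimensional marking profile separates them. Because group
sizes are modest and enrichment distributions are skewed, inference is by
label permutation rather than normal theory, with classical tests kept as
companions.

# From Ct values to enrichment

Every (mouse, locus, channel) combination is measured in triplicate;
channels are the input control (a fixed fraction *f* = 2% of the
pre-immunoprecipitation chromatin), one immunoprecipitate per marker, and a
rabbit IgG negative control. `aggregate_replicates()` averages the
determined replicates, flags cells whose replicate sd exceeds 0.5 cycles (a
plate-quality heuristic; the threshold is configurable and advisory), and
assigns the 40-cycle cap to all-undetermined cells so that downstream
enrichment becomes a detection floor instead of a missing value — per-sample
mean normalization needs complete rows, and a locus that never amplifies is
biologically "near zero", not "unknown".

Enrichment over input is the delta-Ct formula with a percent-input
correction:

$$\mathrm{enrichment} = E^{\,(Ct_\mathrm{input} - \log_E(1/f)) - Ct_\mathrm{IP}}$$

The correction term $\log_E(1/f)$ (5.644 cycles at $E=2$, $f=0.02$) shifts
the measured input Ct to its 100%-input equivalent. Whether the original
analyses applied this correction is unknowable from their outputs: it is a
per-mouse constant, and both normalizations divide it out — a property the
test suite verifies numerically. The amplification factor $E$ is fixed at
2.0 for analysis; `estimate_efficiency()` calibrates it from a 1:10
dilution series (20%, 2%, 0.2% of input) as $E = 10^{-1/b}$ with $b$ the
least-squares slope of Ct on $\log_{10}$(fraction), reducing to the
two-point formula when only two dilutions are usable. On noiseless series
the inversion is exact for any $E$; with 0.2-cycle replicate noise the
estimate stays within the conventional 1.9–2.1 acceptance window.

Quality control against non-specific pulldown computes, per locus, the mean
over mice of $E^{\,Ct_\mathrm{IgG} - Ct_\mathrm{IP}}$; loci below 2-fold
are flagged for exclusion from interpretation (strictly below — exactly
2-fold passes).

## Normalization and outlier samples

Two per-sample normalizations are provided: division by the reference locus
(*Gapdh* column becomes exactly 1) and division by the row mean over the
full panel (row mean becomes exactly 1). Both cancel chromatin-amount
differences between samples; the mean variant avoids trusting a single
control locus but makes the loci linearly dependent, which is why all
multivariate analyses run on 14 loci with one locus dropped per marker (the
near-zero *Cd36* for H3K4me3, the weakly marked *Gapdh* for H3K27ac).

Outlier samples are recognizable by values swinging between extreme low and
high across loci. `flag_high_variance_samples()` measures each mouse's
dispersion as the sd across loci of $\log_2(x_{ml}/\mathrm{median}_l)$ —
deviations from the per-locus median profile. Working on this scale matters:
locus baselines span two orders of magnitude, so the plain sd of normalized
values is dominated by the locus profile common to every mouse and dilutes
the contrast of a genuinely erratic sample (in simulations, detection of an
injected outlier rises from roughly 78% to essentially always). The
threshold is the median of the per-mouse sds plus $k = 3.5$ times their MAD
— median/MAD rather than mean/sd so the outlier itself does not inflate the
threshold. Flags are advisory; exclusion is a configuration choice
(`exclude_mice`), mirroring the practice of omitting flagged samples from
one marker's analysis while keeping them in the other's.

# Permutation inference

For two groups the test statistic is the absolute difference of group means
(for equality of variances, the absolute log ratio of sample variances).
The source analyses say only that group labels were shuffled; the raw mean
difference is the simplest statistic consistent with that, and a
studentized variant (`statistic = "t_stat"`) is provided for sensitivity
analysis. Each run draws `n_iterations` label shuffles and estimates

$$\hat p = \frac{\#\{T_\mathrm{perm} \ge T_\mathrm{obs}\} + 1}{N + 1},$$

never zero by construction (at the design's $N = 10^7$ the smallest
representable p is $10^{-7}$, below the smallest p the motivating study
reports). The reported p averages three runs. The runs consume successive
segments of one seeded RNG stream rather than explicitly separate seeds —
equivalent in distribution and simpler to log. Degenerate variances
(a constant group) push the statistic to $+\infty$; permutations are then
compared on that extended scale, and the fully degenerate case (both groups
constant) returns p = 1 with a flag.

The engine is ~40 lines of C++ (partial Fisher–Yates over the pooled
vector, statistics accumulated from running sums), driven by R's RNG so
`set.seed()` governs everything. An exhaustive-enumeration oracle
(`exact_permutation_p()`, bounded at $10^6$ assignments) exists purely so
tests can check the Monte-Carlo estimator against exact tail probabilities;
full-size designs ($\binom{39}{15} \approx 10^{10}$) are Monte-Carlo only.

Benjamini–Hochberg adjustment is applied separately per family — the 15
loci of one marker under one grouping, matching the per-column structure of
the original report; phenotype and weight groupings are not pooled. The
implementation delegates to `stats::p.adjust(method = "BH")` behind the
`bh_adjust()` surface and is tested against an independent hand-written
step-up computation.

# Multivariate analyses

All three run on the same centered and scaled matrix (`scale()` convention,
$n-1$ denominators).

**MANOVA.** One-way, two groups, Pillai's trace with the standard F
approximation (Wilks available; for two levels both coincide with
Hotelling's $T^2$, and the tests verify agreement with a hand-rolled
$T^2$ to $10^{-9}$). A single response column degenerates to the one-way
ANOVA F-test. The F approximation needs more mice than loci plus one; the
error message advises reducing the panel.

**PCA split tests.** `run_pca()` wraps the singular-value decomposition
with a deterministic sign convention (each component's largest-magnitude
loading is made positive) so score files reproduce byte-for-byte. A split
is either an axis (`PC_k = 0`) or a diagonal of slope ±1 through the origin
in a component-pair plane — the two usages seen in practice. Both reduce to
one signed coordinate per mouse (the score, or the signed perpendicular
distance to the line), on which the permutation mean test runs with labels
shuffled and the projection held fixed (it is label-independent, so this is
exact exchangeability). The choice of perpendicular distance over a
half-plane classification count keeps the statistic continuous and unifies
axis and diagonal modes; a two-sided statistic makes the test invariant to
sign flips of components or of the slope.

**Ward clustering.** Euclidean distances, `ward.D2` by default — the
textbook minimum-variance criterion, verified against brute-force
minimization of the within-cluster variance increase on small instances.
`ward.D` (the variant historical `method = "ward"` implementations applied
to unsquared distances) is exposed for parity with older analyses; the two
can produce different trees, and the variant is recorded on the result.
The deepest split is the 2-cluster cut at the root merge;
`deepest_split_test()` permutes a per-mouse variable (phenotype code or
body weight) across the fixed cluster memberships — under exchangeability
this is equivalent to permuting the memberships — and reports a Welch
t-test alongside, omitted with a flag when a cluster has fewer than two
mice or both clusters are constant.

# The synthetic-data generator

The generator inverts the enrichment formula so that every downstream stage
can be tested against known truth. Per (mouse, locus, marker) the true
log2 enrichment is

$$L = \mathrm{base} + \mathrm{effect} \cdot [\mathrm{group\ B}] +
\mathcal{N}(0, \sigma_\mathrm{bio}) \ (+\ \mathrm{outlier}),$$

and Cts are constructed so that the noiseless pipeline recovers $2^L$
exactly (the suite checks this to $10^{-9}$ relative). Defaults encode the
study conditions: 25 + 16 mice with body weights
$\mathcal{N}(22.7, 1.8^2)$ / $\mathcal{N}(25.4, 2.3^2)$ g truncated at the
13 g adult threshold; two preparation batches; a 15-locus panel whose
baselines echo the observed marking hierarchy and whose planted effects
follow the reported direction of change (H3K4me3: *Nr3c1*, *Sqle*, *Ppara*
up, *Cyp4a14*, *Pck1*, *Gapdh* down; H3K27ac: *Nr3c1* up, *Fasn*, *Plin5*
down; *Gapdh*'s direction is not printed anywhere, so down was chosen once).
Effects are 0.6 log2 units (−1.0 for *Cyp4a14*) against biological noise of
$\sigma_\mathrm{bio} = 0.3$ log2 — a strong-effect regime of roughly two
noise sds, consistent with headline p-values several orders of magnitude
below 0.05 at these group sizes. Replicate-level Ct jitter defaults to 0.15
cycles; no replicate dispersion is reported for the original data, so this
is a calibration choice, not a recovered fact. A per-mouse chromatin
scaling of $\mathcal{N}(0, 0.5)$ cycles shifts all channels of a mouse
equally — it cancels in the delta-Ct and lets tests verify that
cancellation. Optional outlier mice receive extra log2 noise of sd 1.5 with
sign alternating across loci, reproducing the low/high switching that makes
real outlier samples visible. One IgG channel is generated per (mouse,
locus), placed `igg_log2_offset` below the first marker's noiseless IP
signal; for the second marker the implied fold then shifts by the
difference in marker baselines, which reproduces the observation that the
IgG-fold ranking differs between markers. Cts beyond 40 cycles are written
as undetermined.

What the generator does **not** emulate: amplification-curve artifacts
(generation starts at Ct values), primer-specific efficiency differences
within a run, locus–locus correlation beyond what normalization induces,
and any genetic or nest structure among mice. Passing recovery tests
therefore demonstrates that the statistical machinery is correct and
calibrated — not that real ChIP-qPCR data meet the generator's independence
assumptions.

## Normalization leakage

Mean normalization couples the loci: strong planted effects at some loci
shift each mouse's row mean, so null loci acquire a small opposite-signed
apparent effect. With the default panel this leaks roughly a 2–3% group
difference into null loci — usually invisible, occasionally promoted to a
spurious BH-significant call (the recovery checks in the test suite
tolerate at most one such call per dataset, observed in about 5–10% of
seeds; a seed-7 example
appears in the README's worked output, where *Fasn* rides along). This is a
property of per-sample mean normalization itself, not of the
implementation; it is one reason the reference-locus normalization is kept
as an alternative.

# Numerical and design choices

- **Tie handling in tail counts:** permutation statistics are compared with
  a relative tolerance of $10^{-12}$ so floating-point ties (exact
  enumeration fixtures, mirrored assignments) count as "at least as
  extreme".
- **Descriptive rounding:** census fractions round half away from zero to 2
  decimals, weights to 1 decimal; undefined cells (empty denominators, sd
  of one animal) are `NA`. One printed census cell (nest D's adult sex
  ratio) disagrees with its own counts under any rounding convention and is
  treated as a typographical slip.
- **Seed namespacing:** the pipeline derives one sub-seed per stage
  (simulation, locus tests, PCA splits, cluster splits) from the master
  seed, logged with the iteration counts, so any stage can be reproduced in
  isolation and every reported p is traceable.
- **Weight groupings:** the two-group weight comparison takes the 16
  lightest versus 16 heaviest mice; the three-bin coloring convention
  (20.0–22.4 / 22.5–24.9 / 25.0–30.0 g) is retained for descriptive plots.
- **Problem sizes in the shipped checks:** the test suite and acceptance
  script run the permutation machinery at $10^4$–$10^6$ iterations and the
  calibration studies at 1000–2000 replicates — sizes chosen so the whole
  battery completes on a laptop while keeping Monte-Carlo error well inside
  the asserted bands. The analysis default remains $10^7 \times 3$ runs.

# Known limitations

- The permutation tests assume exchangeability under the null; batch
  effects violating it are tested as a grouping (`"batch"`) but not
  modeled.
- The deepest-split test conditions on the dendrogram: the tree is built
  from the same data being tested, so the p-value is for the association
  between the *given* 2-cluster structure and the variable, not for the
  existence of clusters.
- Only 2-cluster root splits are tested, matching the motivating analyses;
  there is no general k-cluster significance machinery.
- `estimate_efficiency()` fits a single efficiency per series; per-locus
  efficiency heterogeneity is handled by policy (fix 2.0, or calibrate per
  primer from its own series) rather than jointly modeled.
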