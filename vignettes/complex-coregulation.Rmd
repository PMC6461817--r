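---
title: "Methods: complex-level differential expression and co-regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complex-level differential expression and co-regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexdiff)
```

# Model and assumptions

plexdiff analyzes multiplexed (TMT-style) quantitative proteomics
cohorts at the level of protein complexes. The data model is:

- each multiplex set carries one *internal standard* channel (a pooled
  reference); every quantity is expressed as a log2 ratio against the
  internal standard of its own set, which removes between-set batch
  effects;
- per-sample loading differences are removed by subtracting a robust
  location (Tukey's biweight, tuning constant 5) from each sample
  column; this assumes most proteins do not change;
- reported zeros are treated as missing, never as a measured zero;
- complex-level analyses use complete cases only, so every correlation
  and every subunit mean is computed over the same samples.

A complex catalog (CORUM-style: `ComplexID`, `ComplexName`,
`subunits(UniProt IDs)`, optionally extended by an accession–complex
mapping table) is mapped onto the quantified protein groups. Isoform
suffixes (`-1`, `-2`, …) are stripped before matching. When several
protein groups could represent the same subunit, the group with the
higher median quantity wins (ties: lexicographically smallest id), and
the ambiguity is recorded.

Complexes then pass a coverage funnel, in order:

1. at least 2 quantified subunits;
2. subunit coverage ≥ 50% (boundary kept);
3. redundancy removal: complexes whose *quantified* subunit sets are
   identical are collapsed to the entry with the highest subunit
   coverage, ties broken by the smallest complex id;
4. pairwise-interaction (PPI) coverage ≥ 50%, where a pair is covered
   when both subunits are quantified: `k(k-1) / (n(n-1))` for `k`
   quantified of `n` subunits.

# Differential complex expression

For each retained complex, the per-sample profile is the unweighted mean
of its subunit log2 ratios. Groups are compared with a two-sample
Student *t*-test (equal variances, as the shared normalization
justifies), and p-values are converted to Storey q-values. A complex is
called differential when q < 0.05 **and** the absolute mean difference
exceeds an effect-size cutoff.

The cutoff is derived from the data: the spread of all observed complex
mean differences is estimated robustly (MAD scaled to the normal SD, so
genuinely changed complexes do not inflate it) and the cutoff is the
two-sided 5% point of a centered normal with that SD,
`qnorm(1 - 0.05/2) * SD`. With an observed SD of 0.158 this reproduces
the conventional 0.31 log2 cutoff:

```{r}
normal_threshold(0.158, 0.05)
```

# Differential co-regulation (assembly)

For a complex with subunit rows $x_1,\dots,x_k$ and a set of samples
$S$, each pair $(i,j)$ contributes the Fisher z-transform of the
Spearman correlation of $x_i$ and $x_j$ over $S$; correlations are
clipped to ±0.99 first so the transform stays finite with small sample
counts. The complex statistic in one group is the mean over all
$k(k-1)/2$ pairs (*mean z*); pairs undefined because a subunit is
constant are excluded and counted. The test statistic between groups A
and B is $\Delta = \bar z_A - \bar z_B$.

**Resampling null.** Correlation statistics on eight samples are noisy,
and their spread depends on the complex (its size, its missingness, its
tie structure). The null is therefore built per complex: pool the
analyzed samples of both groups, draw 16 samples without replacement,
split them into two *disjoint* subsets of 8, and recompute $\Delta$;
repeat (10,000 iterations by default). Disjointness matters: the
observed statistic is itself a disjoint 8-vs-8 split of the pooled
samples, and letting the two resampled subsets overlap shrinks the null
variance and inflates the type-I error well above nominal.

The p-value is the two-sided normal tail of the observed $\Delta$
against a normal with mean fixed at 0 and the null's SD (an empirical
tail count is also reported). The mean is fixed at zero because the null
is symmetric by construction; the fitted SD varies by complex. A
difference of 0.98 against a null SD of 0.308:

```{r}
normal_tail_p(0.98, null_summary(mean = 0, sd = 0.308, n_iterations = 10000))
```

Storey q-values are computed over the normal-fit p-values, and the
effect-size cutoff is derived from the pooled null SD across all
complexes at the two-sided 10% point — a pooled SD of 0.428 reproduces
the conventional 0.70 cutoff:

```{r}
normal_threshold(0.428, 0.10)
```

Per-complex resampling streams are derived deterministically from the
run seed and the complex id, so results are byte-identical across runs
and invariant to the order in which complexes are tested.

# Multiple testing: Storey q-values

`storey_qvalues()` implements the Storey–Tibshirani estimator: π₀ is
estimated on the λ grid 0.05, 0.10, …, 0.90 and smoothed with a cubic
smoothing spline (df = 3), taking the fit at the largest λ; q-values are
the step-up `cummin` of π₀·m·p/rank. For fewer than 100 p-values the π₀
estimate is unstable, so π₀ = 1 is used there (the Benjamini–Hochberg
limit, which is conservative).

# The synthetic-data generator

`generate_catalog()` and `generate_quant_matrix()` build a study with
known ground truth, emitted in the shapes real tools produce: a
MaxQuant-style `proteinGroups.tsv` (reporter intensities, decoy
`REV__` rows, flag columns), a design table, catalog/mapping TSVs, and a
YAML truth manifest. The default design emulates a 3-group × 9-sample
study in three multiplex sets with one internal standard per set and one
pre-registered excluded sample per group (8 analyzed per group).

The value model for protein $p$ in sample $s$ is

$$ v_{ps} = b_p + \delta_{p,g(s)} + \lambda_{c(p),g(s)} f_s +
\varepsilon_{ps}, \qquad \varepsilon_{ps} \sim N(0, \sigma^2), $$

with baseline $b_p$, planted group shifts $\delta$, and a per-sample
latent factor $f_s \sim N(0,1)$ loading the subunits of planted
co-regulated complexes. The loading for a target Pearson correlation
$\rho$ is $\lambda = \sigma\sqrt{\rho/(1-\rho)}$; the corresponding
Spearman value follows the bivariate-normal attenuation
$(6/\pi)\arcsin(\rho/2)$ (`spearman_from_pearson()`). Values are emitted
as intensities $2^{v+o_s}$ with per-sample offsets $o_s$ that
normalization must remove, and missingness is injected as zeros. The
default noise SD of 0.3 log2 units matches the between-sample spread
seen in well-normalized TMT ratios.

Duplicate catalog entries (a copy of a complex plus two never-quantified
phantom subunits) are injected to exercise redundancy removal.

# Operating characteristics

Two dedicated simulations ship with the package; their problem sizes are
the package's own validation choices, sized to give usable Monte-Carlo
precision inside a couple of minutes:

- `validate_coreg_type1()` — 400 complexes with no planted effects,
  2,000 resampling iterations; the fraction with p < 0.05 estimates the
  type-I error. At seed 1 this measures **0.055**, consistent with the
  nominal 0.05 (binomial SE ≈ 0.011).
- `validate_recovery()` — 50 complexes with planted within-group
  correlation 0.85, 50 with a 0.6 log2 complex-wide shift, and 200 null
  complexes. Expression power at seed 1 is **1.0**.

**Known limitation: the per-complex null is self-normalizing.** The
pooled samples used to build a complex's null *include* the samples that
carry its planted correlation, so for a truly co-regulated complex the
null SD grows with the observed difference. The observed statistic
saturates around 2.5 null SDs regardless of how strong the planted
correlation is (median p ≈ 0.012 for correlation 0.85 with 8 samples per
group), which is rarely enough to survive multiple-testing correction
across hundreds of complexes. Co-regulation *power* at q < 0.05 is
therefore low (≈ 0.02 at seed 1) even though the type-I error is
correct, and one acceptance test that asserts ≥ 70% power fails by
design. Using overlapping resamples would shrink the null SD and raise
apparent power, but it provably inflates the type-I error (the variance
of an overlapping split is smaller than that of the disjoint split the
observed statistic represents), so the conservative, correctly
calibrated disjoint null is kept. In practice the test is best read as a
calibrated screen whose raw p-values rank complexes by assembly change.

# Numerical choices

- Spearman correlations are computed from comparison-count ranks
  (`(#less + #less-or-equal + 1)/2`), which handles ties identically to
  `rank()` while vectorizing across thousands of resampling iterations.
- Fisher z clips at |ρ| = 0.99 (z ≈ 2.65) so a perfect rank correlation
  on 8 samples cannot dominate a complex's mean z.
- Tukey biweight uses c = 5, convergence tolerance 10⁻⁶, 50 iteration
  cap.
- All derived RNG stream seeds stay below 2³¹ and are pure functions of
  the user seed (and the complex id, for per-complex streams).
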