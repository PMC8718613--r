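---
title: "Quantifying metabolic interdependence with amino acid correlation networks"
author: "aminonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metabolic interdependence with amino acid correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aminonet)
```

## The problem

Steady-state concentrations of brain metabolites are homeostatically
buffered: a stressor can reorganize a metabolic network substantially while
barely moving the mean levels. Correlation analysis across animals exposes
that hidden reorganization. This package implements that analysis for a
fixed cerebellar panel of 17 analytes — the enzymatic activity of the
2-oxoglutarate dehydrogenase complex (OGDHC, the rate-limiting step of the
TCA cycle) and 16 free amino acids — measured in six experimental groups:
non-pregnant (NP) and pregnant (P) female rats that are untreated (control),
treated with the specific OGDHC inhibitor succinyl phosphonate (SP), or
exposed to acute hypobaric hypoxia.

## The statistics

For one group with $n$ animals, every analyte pair $(i, j)$ gets a Pearson
coefficient $r_{ij}$ and a two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom
(`buildNetwork()`). Pairs with $p \le 0.05$ are significant; pairs with
$0.05 < p \le 0.1$ are trends and are counted separately throughout. No
multiple-testing correction is applied across the 136 pairs: the summary
statistics are descriptive network parameters, not a discovery procedure.

Each analyte $i$ is then summarized by (`networkSummary()`):

* $\Sigma_i = \sum_{j \ne i} |r_{ij}|$ — the summed absolute correlation
  over all 16 partners, significant or not;
* $\bar{X}_i = \Sigma_i / 16$ — its mean;
* the counts of significant positive and negative correlations.

Group-level totals add the 17 per-analyte values; each significant pair
contributes to both of its endpoints, so the totals are even, and the
network mean is $\sum_i \Sigma_i / (17 \cdot 16)$.

Sign-sensitive reorganization around a hub analyte is tracked by the
algebraic sum of its 16 signed coefficients (`hubProfile()`,
`hubReport()`): when a stressor flips a hub's correlations from positive to
negative, the sum moves strongly negative even if $\Sigma$ changes little.
The hubs of interest are OGDHC (negative correlations with amino acids
indicate increased degradation of amino acids through the TCA cycle) and
tryptophan.

Group differences in these per-analyte parameters are tested by an exact
Wilcoxon signed-rank test pairing by analyte (`compareNetworkParams()`);
differences in the underlying concentrations by two-way ANOVA
(stressor × pregnancy) with Tukey–Kramer post-hoc contrasts
(`twoWayAnova()`, `tukeyHsd()`).

## Reference tables

The package ships the published group-level statistics it was validated
against (`referenceNetworkSummary()`, `referenceHubCorrelations()`): the
per-analyte $\Sigma$, $\bar X$ and signed counts for the control and SP
groups of both physiological states, and the 12 hub coefficient columns
(OGDHC and TRP × control/SP/hypoxia × NP/P). The animal-level raw data
behind them were never deposited, so these tables are the only exact
fixtures available; everything at the animal level is exercised through the
synthetic generator instead.

Two internal inconsistencies of the published summary table are worth
recording. First, recomputing column totals from printed per-analyte values
can differ in the last digit (e.g. an SP column sums to 164.29 against a
printed 164.27) because the printed cells are themselves rounded; all
fixture comparisons therefore round the final statistic (half away from
zero, `roundHalfAway()`) and allow a ±0.01–0.02 printed-rounding residual.
Second, in the control-P column the printed per-analyte means correspond to
$\Sigma/15$ for the 16 amino acids while the OGDHC row and all other
columns follow $\Sigma/16$ (its printed network average likewise equals the
total divided by $17 \cdot 15$). The package implements the definitional
$\Sigma/16$ everywhere; the validation suite asserts the published
control-P cells at their actual divisor and the self-consistent columns at
16, so the discrepancy is documented rather than hidden.

## Statistical tests from first principles

**Wilcoxon signed-rank.** Zero differences are dropped (Pratt's ranking is
available as `zeroPolicy = "pratt"`), absolute differences are ranked with
midranks for ties, and the reported statistic is the smaller one-sided rank
sum. For effective sizes up to 20 the two-sided p is exact: the full
distribution of the rank sum over all $2^n$ sign assignments is built by
convolution over the realized midranks, so ties are handled exactly —
unlike the base distribution functions, which assume distinct ranks. Above
20 pairs a tie-corrected normal approximation with continuity correction
takes over; at the boundary the two methods agree to about 0.01 on random
Gaussian data (the suite asserts < 0.015 for n = 15–20 and < 0.01 at
n = 25).

**Two-way ANOVA.** The six-group design is unbalanced (8–17 animals), so
Type II sums of squares are used: each main effect is adjusted for the
other, the interaction enters last. The implementation delegates the fit to
`lm()` and `car::Anova()`; the test suite verifies the decomposition
against independently computed residual-SS differences of nested fits to
1e-8. A perfect fit (zero residual) is handled by direct model comparison,
since the delegated route declines that case.

**Tukey–Kramer.** Computed directly from the studentized-range distribution
with the pooled one-way MSE, $q = |\bar y_a - \bar y_b| /
\sqrt{\tfrac{MSE}{2}(1/n_a + 1/n_b)}$, residual df from the one-way layout
of the groups; verified against `TukeyHSD()` and, for two groups, against
the identity $q = \sqrt{2}\,|t|$.

**Analytic versus permutation p for Pearson r.** The t-based p-value is an
unconditional (bivariate-normal) tail probability; a permutation test
conditions on the observed sample. At the study's group sizes (n = 8) the
two differ by a few hundredths for mid-range p even with an exact or very
large Monte-Carlo permutation oracle — that gap is a property of the small
sample, not an implementation error, and it exceeds the Monte-Carlo noise
of a 100,000-draw oracle by an order of magnitude. The suite therefore
checks closeness at absolute tolerances of a few hundredths at n = 4–10,
alongside exact agreement with `cor.test()`.

## The synthetic cohort generator

`generateCohort()` draws animals-by-analytes matrices by Cholesky
factorization of a target correlation matrix. Defaults emulate the study
conditions: concentrations of a few µmol/g with moderate (25%) dispersion,
lognormal margins (concentrations are positive; the correlation is applied
on the log scale and the log-scale parameters are chosen to match the
requested arithmetic means and SDs), a mildly positive background
correlation (0.4) among amino acids as seen in unstressed control networks
(mean absolute correlations around 0.5–0.6), and the published group sizes
(8–17). True dispersions of the cerebellar analytes were published only
graphically, so the SD default is a free parameter and the tests treat it
as such. What the generator does not emulate: measurement error structure,
non-Gaussian tails, or any dependence beyond the Gaussian copula — passing
recovery tests demonstrates correctness of the statistics, not biological
realism of the cohorts.

An arbitrary target matrix need not be positive semidefinite.
`nearestPDCorrelation()` repairs it by clipping eigenvalues at 1e-8 and
rescaling to unit diagonal — a one-shot spectral projection, deliberately
simpler than Higham's alternating projections and documented as
approximate. Repair has consequences: the published hypoxia-NP OGDHC hub
column (fourteen coefficients near −0.9) is *deeply* incompatible with a
flat positive background among the amino acids — the combined matrix has a
minimum eigenvalue near −1.4, and any PSD repair must shrink the hub row
substantially (to around −8 to −9 where the published algebraic sum is
−11.09). A PSD completion that carries the hub vector exactly always
exists, though: the single-factor completion $r_{ij} = v_i v_j$, whose
Schur complement is the diagonal $1 - v_i^2 \ge 0$. For that reason
`specFromHubProfiles()` offers two background modes — `"constant"` (the
plain fill) and `"factor"` (the single-factor completion) — and the
recovery checks of the hypoxia regime use the factor mode, where the
generated cohorts reproduce the published hub sum to within sampling noise
(±1.5 at n = 500).

```{r hub-recovery}
hub <- referenceHubColumn("OGDHC", "hypoxia", "NP")
spec <- specFromHubProfiles(list(OGDHC = hub), background = "factor",
                            mean = 5, sd = 1, n = 500L, seed = 101L,
                            family = "normal")
net <- buildNetwork(generateCohort(spec))
sum(networkR(net)["OGDHC", setdiff(panelNames(), "OGDHC")])
```

## HRV endpoints

R–R interval series (ms) are summarized by the mean interval, RMSSD
($\sqrt{\text{mean}(\Delta RR^2)}$, the parasympathetic index) and the
Baevsky stress index $SI = AMo / (2\,Mo\,MxDMn)$, the sympathetic index,
with $AMo$ the modal bin's relative frequency (%), $Mo$ the modal interval
(s) and $MxDMn$ the range (s). The cited methodology leaves histogram
details open, so the conventional parameters are fixed and configurable:
bin width 50 ms, bins anchored at 0, modal ties broken toward the lowest
bin. No ectopic-beat filtering is applied; input series are assumed clean.
Published per-group physiology values are means over unavailable raw
series, so they are not fixtures; the suite instead verifies closed forms
(constant series → RMSSD 0; alternating a,b → $|a-b|$; iid Gaussian →
RMSSD/SD → $\sqrt 2$).

## Numerical and design choices

* p-values are clamped into $(0, 1]$; a perfect correlation reports the
  smallest positive double, never 0.
* Comparisons with published two-decimal values round the *final* statistic
  half away from zero; intermediates stay at full precision.
* A coefficient of exactly 0 with $p \le \alpha$ counts as neither positive
  nor negative.
* Cohort tables are serialized at full double precision (`%.17g`), so
  write/read round trips are bit-exact.
* Missing values are rejected at ingest; there is no pairwise-complete
  correlation mode. Units are metadata only (Pearson r is scale-invariant).
* Whether the published significant-correlation counts include trend-level
  pairs is not determinable from the source tables; both counts are exposed
  separately, and the fixtures treat the printed counts as ground truth.
* Correlation requires at least 4 animals per group; constant analyte
  columns are an error naming the analyte.
* Problem sizes in the test suite: recovery runs use cohorts of 500–2000
  simulated animals, permutation oracles 20k–100k draws, enumeration
  oracles up to $2^{14}$ sign assignments; the full suite and the
  acceptance script each complete in well under a minute of compute per
  module.

## Limitations

* Per-pair sample size is a single integer per network: cohorts with
  missing values must be cleaned upstream.
* The eigenvalue-clipping repair is not the nearest-PSD projection; targets
  far from PSD are distorted (by design, documented above).
* The Gaussian/lognormal generator cannot emulate outlier-driven
  correlations; robust alternatives (Spearman, partial correlations,
  graphical models) are out of scope.
* The exact Wilcoxon path is limited to 20 effective pairs (beyond that the
  approximation error is below 0.01 anyway).
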