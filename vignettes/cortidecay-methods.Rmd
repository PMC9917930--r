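---
title: "Methods: temporal decay of corticosterone-responsive transcription"
author: "cortidecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal decay of corticosterone-responsive transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortidecay)
```

## The experiment being modelled

The package analyses a specific experimental design: mice receive
corticosterone in drinking water during their active (dark) phase, and
hippocampal transcriptomes are profiled at hours 1, 5 and 9 of the
following resting (light) phase, when blood corticosterone has returned
to baseline. Each two-color microarray co-hybridizes one control sample
(Cy3, green) with one treated sample (Cy5, red); eight biological
replicates per group and time point give 24 arrays. The scientific
question is not *whether* genes respond to the hormone, but *how long*
each response lasts once the hormone is gone — which motivates a
temporal taxonomy of effects rather than a single DE list.

## Preprocessing model

Raw spot intensities are modelled as additive normal background plus
exponential signal. `normexp_correct()` fits the three parameters
(`mu`, `sigma`, `alpha`) of the convolution by maximum likelihood on
the background-subtracted foreground and replaces each intensity by the
posterior expected signal `E[S | X]`, which is strictly positive. The
tests validate this conditional expectation against numerical
quadrature of the joint density.

Within each array, the log-ratio `M` is regressed on the average
log-intensity `A` by robustified loess (span 0.3, degree 1, 4
robustifying iterations — conventional settings for MA normalization)
and replaced by the residual, removing smooth intensity-dependent dye
bias. Between arrays, the decomposed single-channel log2 intensities
(`R = 2^(A + M/2)`, `G = 2^(A − M/2)`; the exact inverse of the M/A
transform at offset 0) of *all* channels are quantile-normalized
together, since the statistics that follow treat each channel as an
observation.

Two parallel datasets are produced: **offset 0** feeds fold changes and
the reported intensities; **offset 50** (a variance-stabilizing shift
for dim spots) feeds every test statistic. Both conventions are carried
through the pipeline rather than chosen once, because fold changes on
offset data are biased toward zero while test statistics on un-offset
data are dominated by dim-spot noise.

## Separate-channel inference

Each probe contributes two observations per array (one per dye). The
model is a group-cell means model over the six `group x timepoint`
cells, fitted by generalized least squares with a block-diagonal
correlation structure: the two channels of one spot are correlated, and
distinct spots are independent. The fit whitens each 2x2 block by its
Cholesky factor and solves ordinary least squares on the transformed
system; the tests verify exact agreement with explicit matrix-algebra
GLS and with the established two-color implementation.

**Intensity-dependent spot correlation.** The classical approach uses
one consensus correlation for all probes (per-probe estimates are far
too unstable at n = 8). During development we found that a single
consensus is measurably anti-conservative here: additive scanner
background noise is independent between channels, so the *effective*
within-spot correlation falls from ~0.7 for bright spots to ~0 for
spots near the background, and using the bright-spot consensus for dim
spots understates their standard errors (null p-values reached several
times the nominal far-tail rates, and the global-null BH procedure
produced spurious discoveries in ~20% of contrasts instead of ~5%).
`run_contrasts()` therefore defaults to an intensity-stratified
consensus: per-probe spot correlations are smoothed against `A` on the
variance-stabilized atanh scale (`intraspot_rho_curve()`), and probes
are fitted in ten intensity strata, each with its stratum consensus.
Passing a scalar `rho` restores the single-consensus behaviour exactly.
With stratification the global null is calibrated at all tail levels
under the generator's default conditions, dim spots included.

**Variance moderation.** Residual variances are shrunk toward a scaled
inverse-chi-square prior whose parameters are estimated by matching
moments of `log s^2`; the moderated variance is the df-weighted
average `(d0 s0^2 + df s^2)/(d0 + df)` and moderated t-statistics gain
`d0` degrees of freedom. Because residual variance of two-color data
still trends with intensity after the offset, the prior follows a
smooth trend in `A` by default (`trend = TRUE`); the scalar-prior
behaviour of `moderate_variances()` is retained when no covariate is
given, and the prior recovery test (simulated `d0 = 4`, `s0^2 = 1`)
exercises that path.

Six contrasts are tested: treated vs control at h1, h5 and h9, and the
within-control time contrasts (oriented later minus earlier, so a
positive estimate means higher expression later in the resting phase).
Fold changes come from the offset-0 fit, p-values from the offset-50
fit, and Benjamini–Hochberg adjustment is applied within each contrast
(the reported structure is per-comparison, not experiment-wide).

## Temporal taxonomy

Given the three treated-vs-control results of a probe at adjusted
p < 0.05, `classify_probes()` assigns exactly one category:

| category | h1 | h5 | h9 |
|---|---|---|---|
| LONG_LASTING | sig | sig, same sign | sig, same sign |
| INTERMEDIATE | sig | sig, same sign | ns |
| SHORT | sig | ns | ns |
| REVERSAL | sig | any later significant opposite sign | |
| SECONDARY | ns | sig at h5 and/or h9 | |
| COMPLEX | sig | ns | sig, same sign |
| NULL | ns | ns | ns |

Decisions made where the taxonomy leaves room: a reversal (opposite
sign at any later hour) takes precedence over the persistent
categories; the h1-and-h9-only same-sign cell has no named pattern and
goes to COMPLEX; the intermediate category *requires* non-significance
at h9 rather than filtering afterwards. Absolute fold changes are
binned at 0.32, 0.58 and 1.0 on the log2 scale (25%, 50%, 100%
differences; upper edges inclusive, so |log2FC| = 0.32 is still a
"small" change) at the category's reference time point — the latest
significant hour for persistent categories (h9 for long-lasting, h5
for intermediate), h1 for short-lasting and reversal, and the latest
significant hour for secondary effects. Probes whose mean normalized
single-channel intensity across all compared arrays falls below 50 are
flagged low-intensity; such calls are retained but marked, mirroring
the practice of rejecting them from headline gene lists.

Gene-level consolidation excludes probes annotated to more than one
gene or annotated inconsistently by the two sources, and keeps the full
category set per gene: probes of one gene legitimately disagree when
they bind different transcript variants, so the probe remains the unit
of inference.

## What the simulator emulates — and what it does not

`simulate_experiment()` plants the temporal patterns with a chosen
direction and effect size per probe and generates raw spot tables with:
normal additive background (mean 50, sd 10) under exponential-tailed
true signal; bivariate-normal biological noise with within-spot
correlation (default 0.7 — a typical consensus value for co-hybridized
channels; the design question is open, and the value is a free
parameter, not an empirical estimate); smooth cubic dye bias on M;
per-array log-scale offsets; and a configurable fraction of
low-intensity probes (default 0.3) whose signal sits below the
intensity cutoff. The treated (red) channel carries the full planted
effect; the control channel is the baseline, so within-control time
contrasts are truly null unless patterns are planted there.

Default planted fractions (6.5% long-lasting, 4.1% intermediate, 6.9%
short, 0.2% reversal, 11.4% secondary) mirror the share of each
category among all probes of the real platform; the default effect
size of 0.5 log2 sits in the middle of the observed magnitude
distribution, where half of real effects are below 0.32.

Not emulated: spatial/print-tip artifacts, circadian dynamics in
controls (the time contrasts are null by design unless planted),
gene–gene correlation, and any causal mechanism for secondary effects
(they are planted directly as null-at-h1 patterns, since the analysis
detects rather than models them).

Consequences for interpretation: passing recovery tests show that the
pipeline recovers what this generator plants under its noise model;
they do not certify behaviour under artifacts the generator omits,
most notably spatial structure and correlated probes.

## Benchmark designs and problem sizes

The recovery benchmark plants each pattern sparsely (2% of probes per
pattern, 1% reversal, 91% null) at effect size 2.0 log2 with n = 8
arrays per time point and 2,000–2,500 probes, and scores recall among
high-intensity probes — matching both the rejection of mean < 50
probes from headline lists and the fact that a spot dominated by
background carries little information regardless of the statistics.
Two known limitations are documented rather than hidden: (i) when a
*large* share of probes (tens of percent) carries ±2 log2 effects,
quantile normalization compresses the affected tails and recall
degrades — real effects of that size are rare (<1% of probes), so the
sparse design is the realistic one; (ii) the consensus correlation
over *all* probes, dim included, is attenuated (~0.55 at a planted
0.7), which is exactly the phenomenon that motivates the stratified
correlation above.

The null-calibration study uses 2,000-probe all-null experiments at
default generator settings; the acceptance run uses 200 seeds (50 in
the standalone script) and measures the per-contrast false-discovery
proportion `V / max(R, 1)`.

## Classical statistics

The Mann–Whitney U test uses midranks, the tie-corrected normal
approximation, and **no continuity correction** — the convention of the
classic commercial packages, and the one the printed values of interest
discriminate (U = 20 at n = 9, 10 gives p = 0.041 without the
correction and 0.046 with it). The variance-homogeneity battery runs
Cochran's C, Hartley's Fmax, Bartlett and mean-centered Levene tests;
Cochran critical values come from the closed form behind the published
tables, `C = (1 + (k−1)/F_{α/k}(ν, (k−1)ν))^{-1}` (it reproduces the
tabulated 0.6167 at k = 3, ν = 9), Hartley from a conservative
Bonferroni bound over pairwise variance ratios; both apply to equal
group sizes only and abstain otherwise. The decision route is:
pass → ANOVA; fail → square-root transform and retest; fail again →
Mann–Whitney. Two-way ANOVA uses Type II sums of squares (robust to
the mild 9-vs-10 imbalance), and Fisher's LSD is the unadjusted
pairwise t using the pooled MSE — equal to a pooled two-sample t-test
when only two cells exist.

qPCR efficiencies are the least-squares slope of mean Ct on log10
relative concentration over a five-fold dilution series
(`E = 10^(−1/slope)`); relative expression uses the
efficiency-corrected ratio `E_t^{ΔCt_t} / E_r^{ΔCt_r}` with
`ΔCt = mean control Ct − sample Ct`, so upregulation gives ratios
above 1, and technical triplicates are averaged on the Ct scale before
ratios. The reference gene is a configuration input (default *Tbp*);
selecting it is out of scope here.

## Numerical conventions

* Significance is a strict inequality (`adjusted p < alpha`).
* Magnitude bins are left-open/right-closed.
* atanh-transformed correlations are clamped to ±0.9999 before
  averaging; zero-residual probes (possible after quantile ties on dim
  spots) contribute a neutral 0 to the correlation smooth.
* Quantile normalization refuses missing values rather than imputing.
* `normexp_correct()` needs ≥ 10 spots and refuses constant input;
  `moderate_variances()` needs ≥ 100 probes; identical variances give
  `d0 = Inf` and no shrinkage, by convention.
* Determinism: every generator takes an explicit seed and the run
  manifest records a configuration hash, so a pipeline re-run is
  bit-identical.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 1,
                  sim = sim_config(n_probes = 2000, effect_size_log2 = 2,
                                   pattern_fractions = c(
                                     LONG_LASTING = 0.02, INTERMEDIATE = 0.02,
                                     SHORT = 0.02, REVERSAL = 0.01,
                                     SECONDARY = 0.02, "NULL" = 0.91)))
run <- run_pipeline(cfg)
print(run)                 # category counts, consensus rho, recall
run$recovery$confusion     # planted pattern vs called category
```
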