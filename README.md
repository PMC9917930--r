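# cortidecay

How long do transcriptomic responses to a glucocorticoid pulse last
once the hormone is gone? `cortidecay` implements, as a tested and
reusable R pipeline, the analysis of a mouse experiment addressing that
question: corticosterone is given in drinking water during the active
(dark) phase, and hippocampal expression is profiled on two-color
microarrays at hours 1, 5 and 9 of the following resting phase (blood
corticosterone is back to baseline from hour 5). The package is aimed
at analysts working with two-color time-course designs who need the
full chain from raw spot intensities to a temporal classification of
effects, plus the supporting classical statistics and qPCR validation
computations.

## What it computes

**Preprocessing.** normexp background correction (maximum-likelihood
fit of intensity = N(μ,σ²) background + Exp(α) signal, posterior
expected signal `E[S|X]`), within-array loess normalization of
M = log2(R/G) on A = ½log2(RG), channel decomposition
`R = 2^(A+M/2)`, `G = 2^(A−M/2)`, and between-array quantile
normalization of the pooled single channels. Two branches are kept:
offset 0 for fold changes, offset 50 for test statistics.

**Separate-channel inference.** Every dye channel is an observation;
a group×timepoint cell-means model is fitted by generalized least
squares with correlated within-spot channels. The consensus intra-spot
correlation is estimated from atanh-stabilized per-probe correlations
(and, by default, stratified by intensity, because background noise
decorrelates dim spots). Variances are moderated by empirical Bayes
(`s̃² = (d₀s₀² + df·s²)/(d₀+df)`), and six contrasts are tested with
Benjamini–Hochberg FDR control per contrast: treated vs control at h1,
h5, h9, and the within-control time contrasts.

**Temporal taxonomy.** Each probe's significant/sign triple maps to
one category — long-lasting, intermediate, short-lasting, reversal,
secondary, complex or null — with |log2FC| magnitude bins at 0.32,
0.58 and 1 (25%, 50%, 100% differences) and a low-intensity flag at
mean normalized intensity < 50. Probe calls consolidate to genes via
consensus annotation from two sources with synonym resolution.

**Support modules.** A synthetic-data generator that plants the
temporal patterns with known effect sizes (ground truth included, so
recovery is scorable); Mann–Whitney U with the tie-corrected normal
approximation (no continuity correction); a variance-homogeneity
battery (Cochran C, Hartley Fmax, Bartlett, mean-centered Levene) with
the sqrt-transform decision route; two-way Type-II ANOVA with Fisher
LSD; Pearson correlation; qPCR amplification efficiency from five-fold
dilution series (`E = 10^(−1/slope)`) and Pfaffl ratios
`E_t^{ΔCt_t}/E_r^{ΔCt_r}`; and overlap reports against referential
gene lists.

## A worked example

```r
library(cortidecay)

cfg <- run_config(seed = 1,
                  sim = sim_config(n_probes = 2000, effect_size_log2 = 2,
                                   pattern_fractions = c(
                                     LONG_LASTING = 0.02, INTERMEDIATE = 0.02,
                                     SHORT = 0.02, REVERSAL = 0.01,
                                     SECONDARY = 0.02, "NULL" = 0.91)))
run <- run_pipeline(cfg, quiet = TRUE)
print(run)
```

```
cortidecay pipeline run (seed 1)
  category counts:
    LONG_LASTING  35
    INTERMEDIATE  44
    SHORT         87
    REVERSAL      15
    SECONDARY     81
    COMPLEX       6
    NULL          1732
  intra-spot rho: 0.555
  recall: LONG_LASTING 0.72, INTERMEDIATE 0.72, SHORT 0.90, REVERSAL 0.75, SECONDARY 0.82, NULL 0.93
```

The category counts are the machine twin of the experiment's summary
bar data (40 of each persistent pattern and 20 reversals were planted
among 2000 probes), and the recall line scores the calls against the
generator's ground truth over *all* probes. Restricted to
high-intensity probes — the ones that survive the mean < 50 filter —
recall for this run is 1.00 for every planted pattern; dim probes are
where power is genuinely lost. The consensus intra-spot correlation
(0.56) is lower than the planted bright-spot value (0.7) because ~30%
of probes sit near the background, where the channels decorrelate —
see the methods vignette for why the default fit stratifies the
correlation by intensity.

Classical statistics mirror the measurement tables:

```r
mwu_p_from_U(2, 10, 10)    # 0.0002851 -> prints as 0.0003
f_tail(5.49, 2, 53)        # 0.0068    -> prints as 0.007
efficiency_from_dilution(data.frame(dilution = 5^(0:-4),
                                    ct = 22 - log(5^(0:-4))/log(2)))
# slope -3.32, E = 2, efficiency 100%
```

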