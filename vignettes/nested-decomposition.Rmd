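---
title: "Decomposing nested expression variance across two platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing nested expression variance across two platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestdecomp)
```

## The experimental design

`nestdecomp` analyses a balanced nested two-condition experiment: two
growth conditions (conventionally G and E), two biological replicates per
condition, two library/labelling preparations per biological replicate,
and each preparation measured on two chips (two-channel microarray) or
two lanes (RNA-seq), giving 16 profiles per platform from the same four
RNA samples. The condition and biological-replicate stages are shared
between the platforms; preparation and chip/lane are technology-specific.
The unit labels (`u1`, `u2`) denote the *physical* chip or lane, shared
across preparations, which is what makes per-unit fold-change contrasts
meaningful; all other levels nest as a tree, and `nested_design()`
enforces exactly this structure (a `relaxed` flag admits other balanced
binary layouts).

## The variance decomposition

For one gene's profile $y$ over the $n = 16$ samples we fit three nested
fixed-effects models — condition means ($p=2$), biological-replicate
means ($p=4$), preparation means ($p=8$) — and convert each fit's $R^2$
to the standard adjusted form
$\bar R^2 = 1 - (1 - R^2)\,(n-1)/(n-p)$.
Increments of $\bar R^2$ across the nested models estimate each stage's
fraction of variance; the chip/lane stage is deliberately *not*
parameterized (doing so would leave zero residual degrees of freedom) and
is read off as $1 - \bar R^2(M_3)$. Because adjusted increments can be
slightly negative under noise, components are clipped at zero and the
vector renormalized to sum to one; the clipping induces a small upward
bias on near-zero components (about +0.01 at the default study size),
which the parameter-recovery tolerance of ±0.05 comfortably absorbs.

Assumptions: fixed-effects group means describe the stage structure;
profiles are analysed on a log2 scale on which noise is approximately
additive; genes are analysed independently. This is a descriptive
partition, not a random-effects estimator — unbalanced or missing data
are out of scope, and REML-style variance components are deliberately not
offered.

Two numerical details are isolated behind single functions for easy
swapping: the adjusted-$R^2$ variant (the $(n-1)/(n-p)$ form) and the
count-data $R^2$. For counts, the same three models are fit as Poisson
log-linear models with a log library-size offset. Each such model has a
closed-form MLE (group rate = group count sum / group library-size sum),
so the implementation evaluates deviances directly rather than running a
GLM solver; `stats::glm` serves as the independent oracle in the tests.
Deviance $R^2 = 1 - D(\text{model})/D(\text{null})$ takes the same df
adjustment. Profiles with zero total variance (or zero null deviance —
e.g. exactly constant counts at equal library sizes) carry no
information; they are flagged degenerate, excluded from smoothing and
binning, and counted in the printed summary rather than aborting a
matrix.

## Intensity smoothing and the binned platform test

Per-gene fractions are smoothed against intensity *quantiles* (average
ranks scaled to (0,1]) by local quadratic regression. Span defaults to
0.75 — wide enough that 5000 noisy per-gene fractions yield a stable
track, while still resolving the low-intensity upturn; `surface =
"direct"` is used so local polynomial reproduction is exact rather than
interpolated. The 95% band comes from analytic local standard errors by
default, or a gene-resampling bootstrap (B = 200, seeded); bands are
clamped to contain the point estimate.

Cross-platform comparisons rank genes by the *minimum* of the two
platforms' intensity quantiles, so a gene must be well-measured on both
platforms to rank high. The binned test assigns genes to 10 equal-size
bins of that shared rank and runs a paired two-sided Wilcoxon signed-rank
test on the per-gene chip/lane fractions within each bin (the pairing
uses the same gene on both platforms, which cancels the shared condition
and biological structure). The signed-rank choice is this package's
concrete reading of an under-specified step; an unpaired rank-sum
alternative is available via `statistic = "rank_sum"`. BH adjustment is
applied across bins; bins under 10 genes are flagged, not tested.

## Normalization and differential expression

Two distinct sample layouts are used and never mixed:

* **Decomposition** uses the unpooled 16-sample matrices, because the
  later stages *are* the object of study.
* **Differential expression** first collapses technical stages — counts
  are summed and array log-ratios averaged within each biological
  replicate — because treating preparations or chips/lanes as replicates
  would be pseudoreplication that understates within-group variance.

Counts then get TMM (default), RLE, or no scaling, and the voom
transform: gene-wise trends of $\sqrt{\text{residual sd}}$ against mean
log2 count give each observation the weight
$(\text{predicted sd}^{1/2})^{-4}$, floored at $10^{-6}$. The trend span
is 0.5. TMM uses the published 30%/5% double trim with precision
weighting (via edgeR); RLE is implemented as median
count-to-geometric-mean ratios rescaled to geometric mean 1. Arrays are
quantile-normalized by default; the decomposition conclusions are
insensitive to the choice, which the normalization-robustness acceptance
test verifies under TMM, RLE and quantile.

Gene-wise weighted least squares on the 2-vs-2 biological replicates
leaves df = 2, so empirical-Bayes moderation is essential: a scaled
F-distribution fit to the residual variances yields a prior df $d_0$ and
prior variance $s_0^2$, posterior variances
$(d_0 s_0^2 + d\,s^2)/(d_0 + d)$, and moderated t on $d + d_0$ df. The
package warns whenever df < 3 that moderation dominates. FDR defaults to
Storey q-values with the smoother $\hat\pi_0$ (natural cubic smoothing
spline over $\lambda = 0.05, \dots, 0.95$, evaluated at 0.95, clamped to
(0,1]); forcing $\pi_0 = 1$ reproduces BH exactly, which the tests
assert. Genes with fewer than 16 pooled reads are not tested
(configurable `min_count`): at desk-scale depth such genes carry no
usable fold-change information. All tests are two-sided; direction is
reported separately.

## What the simulator emulates — and what it does not

`sim_params()` defines per-gene log2 baseline abundance
$a_g \sim N(4, 2^2)$, a condition effect $\beta_g$ (log2(G/E)) on a
`prop_de = 0.2` fraction of genes with $N(0,1)$ effects, and Gaussian
biological and preparation effects (sd 0.1 each, log2 scale) shared by
both platforms — the same RNA feeds both. Platform noise:

* **RNA-seq**: expected proportions $\propto 2^{\text{signal}}$ after a
  per-gene-per-lane lognormal overdispersion factor (sd 0.05, the knob
  between pure-Poisson and array-like behaviour), then independent
  Poisson counts at 200,000 reads per lane-sample (a desk-scale stand-in
  for the hundreds of millions of reads of a production run, chosen to
  preserve the intensity-dependence regime; a multinomial scheme is
  available and indistinguishable at these depths). Poisson sampling on
  the log2 scale contributes variance $\approx (\log_2 e)^2/\mu$, so lane
  noise falls with depth — the mechanism behind every intensity-dependent
  contrast in the package.
* **Microarray**: log2 ratios around a reference channel modelled as the
  midpoint of the two condition means plus small per-gene noise (sd
  0.05; it cancels from all contrasts), plus chip noise whose sd
  interpolates log-linearly from 0.22 at the bottom of the abundance
  range to 0.12 at the top. The mild decline mirrors the observed
  behaviour of array replicate noise; the high end is set at the
  sequencing noise floor of the top intensity decile
  ($\sqrt{\sigma_\text{lane}^2 + (\log_2 e)^2/\mu}$ at the top-decile
  mean count), so the two platforms converge at high intensity — the
  regime in which binned chip-vs-lane differences vanish above the 80th
  intensity percentile. These constants were fixed analytically from the
  default depth before any acceptance outcome was inspected.
* **qPCR**: Ct inversely linear in log2 abundance (one cycle = one log2
  unit), per-biological-sample plate offsets, three replicates per RNA
  sample, replicate sd 0.15 cycles. Biological effects are omitted by
  default so that the noiseless round trip recovers $\beta_g$ exactly
  for effect-balanced panels (the all-gene centring rule removes a
  panel-mean shift; correlations are unaffected either way).
* **Bias**: `bias_spec()` adds a fixed-magnitude, random-sign log2-FC
  offset to a chosen number of low-abundance genes on one platform,
  phenomenologically emulating cross-hybridization-style artifacts. The
  qPCR validation scenario injects 13 such genes (magnitude 1.5, bottom
  20% of abundance) into an experiment where every gene carries a real
  effect, so the "contested genes" have genuine fold changes to recover.
* **Gene sets**: `simulate_gene_sets()` draws members from a ±0.1 window
  of the abundance-quantile scale around a random centre, because real
  gene sets are expression-coherent — which is precisely what makes
  intensity a confounder for significance-ranked enrichment.

Not emulated: read-level artifacts (mapping, GC/length bias), probe
sequence effects (bias is injected phenomenologically, not mechanistic),
dye swaps, spatial array defects, and missing data. Passing tests
therefore demonstrate that the *pipeline* recovers known structure under
a plausible noise model, not that any particular real dataset behaves
this way.

## Enrichment and its intensity diagnostic

`enrich_all()` tests each set by a two-sided Mann-Whitney comparison of
in-set versus out-of-set per-gene statistics — either signed log2 fold
changes or unsigned DE p-values (ranking by significance is the
confounded choice the diagnostic is designed to expose). The exact null
is used when the smaller group has ≤ 8 members and no ties; otherwise
the normal approximation with tie and continuity correction. Direction
(sign of the median difference) and a rank-biserial effect size are
reported; BH across sets; minimum set size 5 after intersection with the
measured genes. `set_intensity_bins()` bins sets into five equal-count
bins of their members' median min-quantile, and
`binwise_pvalue_diagnostic()` reports per-bin p-value histograms with a
KS uniformity statistic. Under significance ranking, low-intensity sets'
genes occupy a narrow interior band of the overall p-value ranking, so
their rank-sum statistics are under-dispersed relative to the
permutation null and the enrichment p-values in the lowest bin shift
conservative; fold-change ranking largely escapes this. This is the
subtlest of the qualitative contrasts at desk scale, and the acceptance
test examines it at the default study size under a fixed seed.

## Problem sizes and runtime choices

The default study size is 5000 genes × 16 samples per platform at
200,000 reads per lane-sample; parameter-recovery calibration uses
$10^7$ reads so Poisson noise is negligible next to the specified flat
fractions. Decompositions are fully vectorized (group sums via matrix
products), so a full paired decomposition takes about a second. Rolling
correlations default to stride 1 (full overlap); the package's own
summary analyses use stride 50 with the 500-gene window, which changes
nothing visible in the tracks. Bootstrap bands use B = 200. These sizes
are the package's defaults, chosen so a complete analysis runs
comfortably on a laptop; all are configurable.

## Known limitations

* The decomposition is fixed-effects and purely descriptive; it does not
  propagate uncertainty from one stage to another.
* With 2 biological replicates per condition, DE inference leans heavily
  on variance moderation; the prior-df estimate itself is noisy.
* Storey's $\hat\pi_0$ smoother can be unstable for small gene counts;
  `fdr(..., "bh")` is the conservative fallback.
* The simulator's truth fractions for counts use the expected mean count
  in the Poisson term, an approximation that degrades for genes with
  expected counts near zero (those genes are typically flagged
  degenerate anyway).
* Gene identifiers are opaque strings; cross-platform matching is exact
  string equality, and genes absent from one platform are dropped (with
  a message) when shared rankings are built.
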