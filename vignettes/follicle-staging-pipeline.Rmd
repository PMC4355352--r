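---
title: "Staging dominant follicles from DNA-content cytometry, and the downstream expression pipeline"
author: "follistage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging dominant follicles from DNA-content cytometry, and the downstream expression pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follistage)
```

## The problem

Bovine dominant follicles (> 9 mm) pass through three physiological states —
active growth, a plateau, and atresia — that are not distinguishable by size:
mean diameters are indistinguishable across the three groups. What does
separate them is the apoptotic state of the mural granulosa cells. After
ethanol permeabilization, fragmented DNA leaks out of apoptotic cells, so in
a propidium-iodide (PI) DNA-content histogram those cells appear *below* the
G1 (2n) peak: the sub-G1 fraction is an apoptosis proxy. `follistage`
implements the full staging procedure from raw cytometer event tables, plus
the downstream analyses used to validate the staging on expression data:
loop-design two-color microarray differential expression, between-group
ordination, gene-set/regulon scoring and qPCR statistics. Every input can be
simulated with known ground truth, so the whole chain is testable without any
external data.

## Flow-cytometry model

### Gating

Two gates mirror standard acquisition practice (`gate_events()`):

* **debris** — events below the FSC or SSC thresholds (defaults 150/150
  channels) are removed;
* **doublets** — two cells crossing the laser together take longer, so their
  *integrated* fluorescence roughly doubles while *peak* fluorescence does
  not; events with peak/integrated ratio below `doublet_ratio_min`
  (default 0.6, a fixed and auditable threshold rather than a fitted
  discriminant) are removed.

When more than `target_events` (default 10,000) survive, a seeded uniform
subsample without replacement reproduces the fixed acquisition count.

### DNA-content deconvolution

`fit_dna_histogram()` replaces an interactive curve-fitting package with an
explicit mixture model on the binned integrated-fluorescence histogram
(256 bins by default):

* **G1**: Gaussian with mean $\mu$ and SD $\sigma$;
* **G2**: Gaussian constrained at $2\mu$ (PI fluorescence is linear in DNA
  content; the ratio is configurable within [1.8, 2.2]) with SD scaled by
  the same ratio;
* **S**: a uniform DNA-content plateau between $\mu$ and $2\mu$ convolved
  with the G1 width — a pragmatic substitute for polynomial S-phase models,
  adequate because only the four phase *proportions* are consumed
  downstream;
* **sub-G1**: all events below $\mu - k\sigma$ (default $k = 3$), with a
  left-truncated exponential component absorbing their histogram mass during
  fitting. The hard $k\sigma$ boundary makes "less than 2n DNA content"
  explicit and testable.

Component amplitudes are estimated by non-negativity-constrained least
squares at fixed $(\mu, \sigma)$, and $(\mu, \sigma)$ plus the sub-G1 decay
scale are refined by Nelder–Mead around the histogram mode. The optimizer is
constrained to a neighbourhood of the detected mode (0.75–1.3 × the mode,
CV between 1% and 15%) so the G1 peak cannot drift onto the sub-G1 shoulder
or the G2 peak under heavy atresia. Raw proportions are reported as percent
of gated events and may sum slightly away from 100; an optional rounding
mode (`round_proportions`) truncates each proportion to two decimals
independently, reproducing the drifting sums that capped-precision software
reports (observed sums between roughly 93% and 110% motivate the next step).

### Normalization and the x score

`normalize_proportions()` divides each phase by the sum of all four and
multiplies by 100 — idempotent and scale-invariant, mapping any raw profile
onto a true composition. The health score is

$$x = p_{G2} + p_S + p_{G1} - p_{subG1},$$

which on a normalized profile equals $100 - 2\,p_{subG1}$: ranking by
decreasing $x$ is exactly ranking by increasing apoptosis. `compute_x()`
refuses unnormalized profiles to avoid silent scale mixing (a flag allows
raw-profile scoring for sensitivity analysis).

### Stage assignment

`assign_stages()` excludes samples with RIN < 7 first, ranks the remainder
by $x$ (ties broken by sample id for reproducibility), and takes the top
*k* = 7 as growing, the bottom *k* as atretic, and *k* contiguous ranks as
plateau. The description of the plateau group as having "intermediate"
scores leaves the exact middle rule open; we center the plateau window on
the median of the post-extremes remainder, dropping the extra rank from the
growing side when the excess is odd — deterministic, and with 25 ranked
samples it leaves exactly four boundary exclusions. The procedure is a
partition: every sample receives exactly one label.

## Loop-design differential expression

Four samples per stage are hybridized pairwise around the loop
G–P, P–A, G–A, each slide with a dye-swap mate, giving 24 arrays and —
after channel extraction — eight single-channel data sets per stage.
Processing follows the standard two-color chain: background subtraction
with a floor of 0.5 (`background_correct()`; the subtraction flavour is
simple fg − bg since nothing finer is identifiable from intensity tables),
within-array loess of M on A (span 0.3), and between-array quantile
normalization (delegated to `limma::normalizeQuantiles`).

`fit_loop_model()` regresses each probe's M value on stage coefficients
(growing as reference) plus a single dye coefficient; the dye-swap mates
identify the dye term inside the model, preserving degrees of freedom
rather than pre-averaging mates. Residual variances are moderated by
moment matching on log variances (`squeeze_variances()`): prior df $d_0$
from the inverse trigamma of the excess log-variance spread, prior variance
$s_0^2$ from the mean, posterior
$(d_0 s_0^2 + d\,s^2)/(d_0 + d)$, moderated t on $d_0 + d$ df. Probes
pinned to a single rank by quantile normalization can have exactly zero
residual variance; they are offset to $10^{-5}\times$ the median variance
before fitting, and the implementation is cross-checked in the tests against
an independent reference implementation of the same moment-matching scheme.

DEG selection uses the strict symmetric fold-change rule
$|\log_2 FC| > \log_2 1.5$, strict $p < 0.05$ and inclusive average
intensity $A \ge 7$ (log2 scale); no multiple-testing correction is applied
in selection, mirroring the raw-p decision rule, but a Benjamini–Hochberg
FDR column is emitted for users. `partition_contrasts()` classifies genes
across the two transitions as continuous (same direction), reversal, or
transition-specific, and reports all pairwise intersections with the G-vs-A
list since "shared" counts admit more than one reading.

## Ordination

`between_group_analysis()` is a PCA-flavoured between-group analysis:
probe-centered data are reduced to group centroids weighted by group size,
principal axes are computed on the centroids (at most groups − 1 axes), and
every data set is projected onto them. Centroid projections equal the group
means of projected samples by construction. `separation_score()` summarizes
segregation as the mean silhouette width of the projected data sets under
their stage labels. The correspondence-analysis variant of BGA would also
have been defensible; the PCA flavour was chosen because the inputs are
already log-scale intensities.

## Enrichment

`fisher_enrichment()` is the one-sided hypergeometric over-representation
test with an explicit, user-supplied universe (the universe actually used by
knowledge-base tools is rarely stated, so it is a required argument here).
`activation_zscore()` scores a signed regulon as
$z = (n_{consistent} - n_{inconsistent})/\sqrt{n}$ with the conventional
activation calls at $z \ge 2$ / $z \le -2$; evidence weights are uniform
because literature-confidence weights are proprietary. Note that for small
regulons the $\pm 2$ rule is conservative relative to its nominal normal
approximation: for size 10 the exact null probability of $|z| \ge 2$ is
$22/2^{10} \approx 2.1\%$, not 4.6%.

## qPCR branch

Standard curves are least-squares fits of Cq on $\log_{10}$(input) over a
five-point decade-spaced series ($10^{-4}$–$10^{-8}$ ng by default);
efficiency is $10^{-1/slope} - 1$. Quantities invert the curve; undetected
wells propagate as explicit missing values, never zeros. geNORM
normalization divides each sample's quantities by the geometric mean of the
two reference genes (EIF2B2, SF3A1) and reports the pairwise-ratio
stability measure M for audit.

Contamination QC runs Bartlett's test on a theca marker (CYP17A1-like)
across stages; if variances differ, a sample is flagged when leave-one-out
removal restores homogeneity *and* its marker level exceeds its group median
by the configured multiple (default 5×) — both conditions together avoid
flagging benign variance drivers.

`stage_stats()` reproduces the validation battery per gene: Bartlett first;
if $p < 0.05$ the data are transformed by $Y = \log_{10}(y \cdot 10^{12})$
(the large factor keeps transformed values positive for quantities in ng)
and Bartlett is rerun — both p-values are reported, and the transform
decision is per gene (a per-contrast switch would also be defensible; per
gene matches how a set of data is transformed as a unit). Then: one-tailed
Welch t per contrast with the expected direction supplied externally (e.g.
from the microarray fold-change sign; by default the observed direction,
which halves the two-sided p), one-way ANOVA, a Student–Newman–Keuls
step-down post hoc at $\alpha = 0.05$ using studentized-range critical
values with harmonic-mean group sizes (letter groupings are maximal runs of
mutually non-significant ordered means), and a post-test for linear trend
(contrast $(-1, 0, 1)$ on the ordered stage means against the ANOVA error
term). Zero-variance genes are reported untestable rather than raising.

## What the generators emulate — and what they do not

* **Events** (`simulate_follicle_events()`): G1 at channel 200 of a
  1024-channel axis, CV 4%, G2 at exactly 2×, S as broadened uniform,
  sub-G1 as a truncated exponential decaying below $\mu - 3\sigma$
  (fragmented-DNA loss), doublets as the sum of two singlets' integrated
  fluorescence with the max of their peaks, debris at low scatter. Real
  cytometer quirks — compensation, carryover, drift, asymmetric CVs — are
  not modeled, so passing recovery tests shows correctness of the
  deconvolution under its own model family, not robustness to instrument
  artifacts.
* **Stage compositions**: no numeric per-stage phase ranges are published
  for this system; the defaults (sub-G1/G1/S/G2 = 2/77/12/9 growing,
  10/78/7/5 plateau, 30/60/5/5 atretic) were chosen once as a plausible
  apoptotic gradient with well-separated sub-G1 levels and are config
  overridable.
* **Arrays** (`simulate_loop_arrays()`): log2 base levels ~ Normal(9, 1.5)
  so the intensity-7 filter bites on both sides; additive background;
  gene-independent dye bias; technical noise SD 0.1. Per-sample biological
  deviations are kept small by default (SD 0.01) because the fixed-effects
  loop model — like the original analysis — treats a sample's arrays and
  dye-swap mates as independent; larger shared deviations are absorbed into
  the stage coefficients while escaping the residual variance, which breaks
  the nominal type-I calibration the generator is specified to satisfy.
  Spatial artifacts and amplification biases are out of scope. One known
  behaviour worth noting: strongly *asymmetric* differential expression
  biases the loess curve slightly (it assumes most genes are unchanged), so
  unidirectional injections are recovered with a few percent attenuation.
* **qPCR** (`simulate_qpcr()`): Cq from the log-linear amplification model
  with per-gene slope/intercept, log-normal biological scatter (CV 0.3),
  Cq noise SD 0.15, stage-independent references, optional contaminated
  sample with an elevated theca marker. Amplification-curve processing is
  out of scope; Cq values are the inputs.

All generators are pure functions of (configuration, seed).

## Problem sizes and numerical choices

The packaged analyses and tests run at 10,000 events per follicle, 27
follicles, 2,000 probes and 24 arrays — sizes at which the full chain
completes in seconds while leaving the statistical contracts (multinomial
recovery within binomial bounds, 3–7% null rejection, ±0.1 effect recovery)
meaningful. Histogram fitting uses 256 bins, Nelder–Mead with relative
tolerance 1e-8 and at most 200 iterations; loess uses span 0.3 with a
symmetric-family fit; quantile normalization averages ties; Newman–Keuls
uses exact studentized-range quantiles. Ties in the staging rank are broken
by sample id; degenerate cases (all-zero profiles, empty gates, zero-variance
genes, zero-overlap regulons) are rejected or flagged explicitly rather than
silently coerced.

## Limitations

* The staging rule is the pure rank procedure; any manual curation of the
  plateau group ("few mitoses, limited atresia") beyond ranks is not
  reproducible from the published description and is not attempted.
* Proportions are defined over gated events only; whether the original
  software's denominators included modeled-only events is unknowable from
  the outside.
* FCS container parsing is not included; event tables are consumed as
  delimited text with the four channel columns.
* The headline DEG counts and knowledge-base enrichment outputs of the
  motivating study depend on the real arrays and a proprietary database and
  are not desk-reproducible; the package validates the *procedures* on
  synthetic ground truth instead.
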