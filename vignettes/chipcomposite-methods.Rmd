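---
title: "Methods: differential expression and TSS-anchored ChIP composite profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression and TSS-anchored ChIP composite profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`chipcomposite` implements a two-part analysis linking transcriptional
changes between two genotypes (wild type and knockout, e.g. an
*Mbd2*-deficient dendritic-cell model) to histone H3K9/K14 acetylation
around transcription start sites (TSSs):

1. an array-style differential-expression (DE) chain — variance-stabilizing
   transformation, robust spline normalization, empirical-Bayes moderated
   t-statistics, fold-change/p-value filtering, and hypergeometric gene-set
   over-representation — and
2. a ChIP coverage profiler — depth normalization, 100-bp sliding-window
   per-base densities over a 6-kb interval centred on each TSS, and
   per-window median composite ("metagene") profiles stratified by DE call,
   with a paired WT-vs-KO test of TSS-proximal signal.

A synthetic-data generator with known ground truth makes every stage
verifiable by parameter recovery, with no external downloads.

# The DE model

Let $x_{gs}$ be transformed, normalized log2 intensities for gene $g$ in
sample $s$, with $n_{WT}$ and $n_{KO}$ replicates per genotype (3 and 3 by
default). The per-gene statistic is a two-group moderated t:

* residual variance $s_g^2$ with $d_g = n_{WT} + n_{KO} - 2$ degrees of
  freedom;
* a scaled inverse-chi-square prior on true variances with hyperparameters
  $(d_0, s_0^2)$, estimated by moment matching on
  $e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$: the excess of
  $\mathrm{var}(e)$ over $\psi'(d_g/2)$ equals $\psi'(d_0/2)$, solved by
  bisection on a geometrically widened bracket to $10^{-10}$; then
  $s_0^2 = \exp\{\overline{e} + \psi(d_0/2) - \log(d_0/2)\}$;
* posterior variance
  $\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, statistic
  $\tilde t_g = \mathrm{log2FC}_g / (\tilde s_g \sqrt{1/n_{WT} + 1/n_{KO}})$
  on $d_0 + d_g$ degrees of freedom (standard normal when $d_0 = \infty$;
  $d_0 = 0$ recovers the ordinary pooled t);
* Benjamini–Hochberg adjustment across genes.

When $\mathrm{var}(e) \le \psi'(d_g/2)$ there is no detectable spread in
true variances; $d_0$ is reported as the `Inf` sentinel and $s_0^2$ as the
plain geometric mean of the $s_g^2$ (so that identical input variances are
returned exactly — the bias-corrected alternative $\exp(\overline e)$ would
not have that property).

Calls: a gene is `down` iff $\mathrm{log2FC} \le -\log_2(\mathrm{fc})$
(boundary inclusive, default fc = 2) *and* its p-value (raw by default;
`adjusted` selectable) is strictly below 0.05; `up` symmetrically. Raw-p is
the default because the source convention ("P < 0.05, moderated t-test"
alongside FDR control) is ambiguous; both p-values are always reported, and
reproducing published signature counts on real arrays should record which
mode (and whether probe-level or gene-collapsed features) reproduces them.

## Variance-stabilizing transform

The VST is a fitted generalized log: per-gene variance is modelled as
$v = a + b\,\mu^2$ (additive + multiplicative components) and the transform
is $g(x) = \log_2(x + \sqrt{x^2 + \lambda}) - 1$ with $\lambda = a/b$.
Plain least squares of $v$ on $\mu^2$ is dominated by a handful of bright,
high-variance genes and is unstable (occasionally producing enormous
$\lambda$ that crushes low-intensity fold changes); the trend is therefore
fitted on the rescaled form $v/\mu^2 = b + a(1/\mu^2)$, which weights genes
evenly, with two rounds of 3-sigma residual trimming. If the multiplicative
component is non-positive the transform falls back to plain log2 with a
warning. Exact published array-specific VST variants are out of scope; the
contract downstream stages need is monotonicity plus variance flattening,
which the tests verify directly (Spearman correlation between gene mean and
variance drops from above 0.6 to below 0.2 on an
additive-plus-multiplicative fixture).

## Robust spline normalization

Each array is mapped through a monotone smooth function onto the quantiles
of a reference pseudo-sample (the per-gene mean array): sample and
reference quantiles at 101 probability points are interpolated with a
monotone (Hyman-filtered) cubic spline, falling back to monotone linear
interpolation if reference knots tie. Ranks are preserved exactly within
each sample. One consequence shared with all quantile-anchored methods: the
sample-wise extremes map to the reference extremes, so the globally dimmest
gene can become constant across arrays; the moderation fit excludes
zero-variance genes with a warning.

# The ChIP profiler

Tracks are scaled to a common total (`mean(total)/total` per track),
mirroring normalization by average mapped bases per sample. Windows of 100
bp advance in 20-bp steps across a 6-kb interval centred on the TSS — 296
windows, anchored at the interval start, reported at window centres — and
each window's density is the arithmetic mean of per-base signal ("average
number of hits per base"), not a window sum. Composites are per-window
medians across genes (even counts: mean of the two central order
statistics). Design choices the source leaves open:

* minus-strand profiles are flipped to gene orientation by default
  (`strand_flip = FALSE` reproduces unstranded behaviour);
* genes whose 6-kb interval crosses a chromosome end are excluded and
  reported, not zero-padded (padding biases edge windows toward zero);
* ChIP and input are profiled separately; no input subtraction or ratio.

## The paired comparison

The source displays stratified composite profiles without a printed test;
the quantification here is this package's addition. Each gene's
TSS-proximal statistic is its mean windowed density over window centres
within ±500 bp (chosen to straddle the acetylation peak; configurable).
The effect is the median paired difference (WT − KO) and the p-value a
two-sided Wilcoxon signed-rank across genes — exact for ≤ 25 non-zero
differences, normal approximation with continuity correction above. With
one library per genotype, inference pairs genes, not samples; the manifest
states this to prevent over-interpretation. BH adjustment is applied across
the assay × stratum comparison family.

Two numerical conventions matter here:

* **Difference quantization.** Differences are snapped to a grid of 1% of
  the median non-zero |difference| before ranking; sub-resolution
  differences count as zeros and equal-magnitude differences tie (midranks).
  Without this, depth normalization — which scales WT and KO by slightly
  different factors — turns gene pairs with identical underlying counts
  into minute *coherently signed* differences, and deterministically breaks
  magnitude ties between +1-count and −1-count pairs. Both effects bias the
  signed-rank statistic with sparse integer coverage even when no biological
  difference exists. Distinctions below 1% of a typical difference are far
  below anything the profiler can resolve, so discarding them costs no real
  power.
* **Composition bias.** Totals-based normalization (equivalently,
  sequencing a fixed number of reads) means that genuinely attenuating
  peaks at one gene class slightly inflates everything else in that
  library. The effect scales with the attenuated peaks' share of total
  signal, which is why the simulator defaults to a mouse-scale genome
  (below): on a toy megabase genome the planted peaks dominate the totals
  and this artefact, not biology, would drive the unchanged-stratum test.

# The synthetic world

The generator's defaults describe one fixed study design:

* **Expression:** 2000 genes, 3 replicates per genotype; baseline log2
  intensities Normal(8, 1.5²) (typical array dynamic range); gene variances
  scaled inverse-chi-square with $d_{0,true} = 4$, $s^2_{0,true} = 0.05$
  (a heavy-tailed, array-like variance prior that makes moderated-t
  hyperparameter recovery a meaningful test); 3% of genes planted down and
  3% up at |log2FC| = 1.5 (≈2.8-fold, comfortably past the twofold filter;
  the source reports ~119 changed genes, and 6% of 2000 keeps strata large
  enough for stable medians while staying a small minority). Raw intensity
  is $2^{\log_2 x}$, so a log2 transform recovers exactly Normal data.
* **Genome and ChIP:** 20 chromosomes of 125 Mb (mouse-scale, 2.5 Gb
  total); Gaussian acetylation peaks of amplitude 1 and SD 350 bp at each
  TSS over a uniform background of 0.02 expected signal per base, sampled
  at a depth factor of 0.05 — about 2.6 million events per library, a
  plausible early-HiSeq ChIP library with ~50-fold promoter enrichment
  over background. Knockout peaks at down-class genes are attenuated by
  $\rho = 0.5$; up and unchanged classes keep wild-type amplitude; input
  is background only. Peaks may be made asymmetric
  (`peak_sd_downstream`) to exercise strand handling; by default they are
  symmetric so strand-flip tests are exact.
* **Sampling:** coverage is drawn by Poisson superposition — a Poisson
  event count per component with positions from the component's normalized
  rate — which is exactly equivalent to independent per-base Poisson
  counts (peaks truncated at 5 SD, relative mass < 6e-7) and makes a
  2.5-Gb genome desk-cheap.

What a green test does and does not establish: the generator matches the
statistical *structure* the analysis assumes (Normal log intensities,
inverse-chi-square variances, Poisson coverage, symmetric peaks, one
amplitude per class). Real arrays have probe effects, background, and
batch structure; real acetylation is asymmetric, gene-to-gene variable,
and correlated with expression level; real libraries have mapping and
duplication artefacts. Recovery on this world validates the computations,
not the biology of any particular dataset.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; WIG's 1-based
  convention converted at the I/O boundary.
* Coverage is run-length encoded; bedGraph/WIG assembly is positional (no
  accumulation arithmetic), so writer/reader round trips are bit-exact.
  Values are emitted with `%.17g`.
* Overlapping bedGraph intervals, negative values, unknown chromosomes and
  out-of-bounds coordinates are errors (a permissive flag downgrades
  unknown chromosomes to a warning).
* Trigamma inversion: bisection, 200 iterations max, tolerance 1e-10.
* A gene with zero posterior standard error gets $\tilde t = 0$, $p = 1$,
  and a flag.
* All-zero-difference comparisons return effect 0, $p = 1$, flagged.
* Pipeline manifests carry no timestamps, so fixed config + seed reruns
  are byte-identical.
* `run_pipeline` config is a flat key-value set (JSON on disk); every
  default is echoed into the manifest, so no silent defaults exist.

# Known limitations

* Only two-group designs; no multi-factor contrasts.
* Probe-to-gene collapsing for real arrays keeps the probe with the
  highest mean intensity; the synthetic world is 1:1.
* Gene sets are flat (no GO graph propagation); collections are
  user-supplied GMT files.
* Read mapping, peak calling, input-ratio tracks and heat-map rendering
  are out of scope; the pipeline starts from mapped coverage tracks.
* Reproducing accession-scale published signature counts requires the
  deposited arrays and is deliberately outside the offline test suite; the
  recipe is: VST → robust spline normalization → moderated t → twofold &
  P < 0.05, trying raw vs adjusted p and probe vs gene features, and
  recording which combination reproduces the printed counts.
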