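# chipcomposite

Links differential gene expression between two genotypes to histone
H3K9/K14 acetylation around transcription start sites (TSSs). The package
is aimed at analysts working with array-style expression matrices plus
ChIP-seq coverage tracks (e.g. wild-type vs knockout immune-cell models,
such as Mbd2-deficient dendritic cells) who want a tested, reproducible
version of the classic two-part analysis:

1. **Differential expression** — variance-stabilizing transformation,
   robust spline normalization across arrays, empirical-Bayes moderated
   t-statistics, twofold/p-value filtering, and hypergeometric gene-set
   over-representation.
2. **TSS composite profiling** — depth normalization of coverage tracks to
   a common total, per-base densities in 100-bp windows sliding by 20 bp
   across a 6-kb interval centred on each TSS (296 windows), per-window
   **median** composite profiles stratified by DE call (down / up /
   unchanged), and a paired WT-vs-KO Wilcoxon signed-rank test of
   TSS-proximal signal per stratum and assay.

At its statistical core is the moderated t with a scaled
inverse-chi-square variance prior: with gene residual variances *s²_g* on
*d_g* degrees of freedom, hyperparameters *(d₀, s₀²)* are estimated by
log-scale moment matching (digamma/trigamma equations), the posterior
variance is *s̃²_g = (d₀s₀² + d_g s²_g)/(d₀ + d_g)*, and
*t̃_g = log2FC_g / (s̃_g √(1/n_WT + 1/n_KO))* is referred to a t
distribution on *d₀ + d_g* df with Benjamini–Hochberg FDR control.

A first-class synthetic-data generator (mouse-scale genome, Gaussian
acetylation peaks over Poisson background, planted fold changes and
knockout peak attenuation, heavy-tailed gene variances) provides ground
truth so every stage is verified by parameter recovery — no downloads
needed. See `vignettes/chipcomposite-methods.Rmd` for the model, the
synthetic world, and the numerical conventions.

## Worked example

```r
library(chipcomposite)

# Simulate a complete experiment and run the full chain:
# VST -> spline normalization -> moderated t -> twofold & p<0.05 calls ->
# TSS stratification -> depth normalization -> composites -> comparisons.
res <- run_pipeline(pipeline_config(), out_dir = "report", seed = 1)

res$de
#> DEResult: 2000 genes (56 down, 62 up)
res$de$fit
#> ModerationFit: d0 = 4.348093, s0sq = 0.048504, residual df = 4
res$strata
#> StratifiedSets: 56 down, 62 up, 1882 unchanged (0 dropped)
print(res$comparison_table, digits = 3)
#>     stratum assay    n effect_wt_minus_ko  p_value    p_adj
#> 1      down  H3ac   56           1.92e-02 8.16e-11 4.89e-10
#> 2        up  H3ac   62           1.49e-03 4.45e-01 6.35e-01
#> 3 unchanged  H3ac 1882          -1.80e-04 4.33e-01 6.35e-01
#> 4      down input   56           8.10e-07 1.69e-01 5.08e-01
#> 5        up input   62           0.00e+00 5.29e-01 6.35e-01
#> 6 unchanged input 1882           8.10e-07 7.97e-01 7.97e-01
```

Reading the output: the simulator planted 60 down- and 60 up-regulated
genes (3% each of 2000) at |log2FC| = 1.5, and attenuated knockout
acetylation peaks by half at down-regulated genes only. The DE chain
recovers 56/62 calls; the moderation fit recovers the generative prior
(d₀ = 4, s₀² = 0.05) closely. In the comparison table, only the
down-stratum ChIP comparison is significant — reduced acetylation in the
knockout (positive WT − KO effect, p ≈ 8e-11) — while up/unchanged strata
and all input-track comparisons behave as nulls. The down-stratum KO
composite lies below the WT composite at every window centre within
±500 bp of the TSS (e.g. medians 0.049 vs 0.020 at offset −30). This is
exactly the planted picture: expression loss accompanied by promoter
deacetylation at down-regulated genes.

The report directory contains `de_table.tsv`, down/up gene lists,
per-track × per-stratum composite TSVs (offset, median, n), a comparison
table, optional enrichment tables, and a machine-readable `manifest.json`
(package version, seed, every parameter, exclusion counts) sufficient to
reproduce the run byte-for-byte.

## Command-line use

A thin CLI over the same functions ships in `inst/cli`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/chipcomposite.R", package="chipcomposite"))')
Rscript $CLI simulate --config sim.json --seed 3 --out simdir
Rscript $CLI de --expression expr.tsv --metadata meta.tsv --out dedir
Rscript $CLI profile --coverage H3ac_WT.bedgraph --anchors genes.bed --out prof.tsv
Rscript $CLI locus --coverage H3ac_WT.bedgraph --anchors genes.bed \
        --gene g00001 --flank 3000 --out locus.bedgraph
Rscript $CLI enrich --genes down.txt --universe universe.txt --gmt sets.gmt --out enrich.tsv
Rscript $CLI pipeline --config pipeline.json --seed 1 --out report
```

Supported formats: WIG (fixedStep/variableStep with span), bedGraph, BED6,
GFF3, TSV matrices, GMT gene sets, UCSC chrom.sizes.

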