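#' Simulation configuration
#'
#' Defaults describe the emulated study design: two genotypes (WT vs KO) with
#' three array replicates each, a planted twofold-or-greater differential
#' subset, gene-wise variances from a scaled inverse-chi-square prior (the
#' prior the moderated-t machinery assumes, so hyperparameter recovery is a
#' meaningful test), and one ChIP plus one input coverage sample per genotype
#' with Gaussian acetylation peaks at TSSs over a Poisson background. In the
#' knockout, peaks of downregulated genes are attenuated by
#' `ko_down_attenuation`; upregulated and unchanged genes keep the wild-type
#' amplitude.
#'
#' The default genome is deliberately mouse-scale (20 chromosomes of 125 Mb)
#' with modelled peaks at only 2000 TSSs, so that planted peaks are a small
#' share of each library's total signal, as in a real experiment. This
#' matters: totals-based depth normalization transfers any genotype
#' difference in aggregate peak signal onto all other bases (composition
#' bias), and a dense toy genome would make that artefact dominate.
#' Coverage is sampled by Poisson superposition (event counts plus
#' positions), which is exactly equivalent to independent per-base Poisson
#' draws and keeps a 2.5-Gb genome cheap to simulate.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_chroms Number of chromosomes the genes are spread over.
#' @param chrom_length Chromosome length in bp.
#' @param replicates Array replicates per genotype (default 3).
#' @param de_frac_down,de_frac_up Fractions of genes planted down/up.
#' @param delta Planted |log2 fold change| for DE genes (default 1.5, i.e.
#'   ~2.8-fold, comfortably past the twofold filter).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of gene-level
#'   baseline log2 intensities.
#' @param d0_true,s0sq_true Variance-prior degrees of freedom and scale:
#'   gene variances are drawn as `s0sq_true * d0_true / rchisq(d0_true)`.
#' @param background_rate ChIP background rate, expected signal per base.
#' @param peak_amplitude Added expected signal per base at the peak summit.
#' @param peak_sd Gaussian peak standard deviation in bp.
#' @param peak_sd_downstream Optional downstream (3', in gene orientation)
#'   peak standard deviation; when set, peaks are asymmetric around the TSS
#'   (upstream side uses `peak_sd`), exercising strand handling.
#' @param ko_down_attenuation Multiplier (rho, in \[0,1\]) applied to KO peak
#'   amplitudes of down-class genes.
#' @param depth Per-sample sequencing depth factor (scalar; expected counts
#'   are `depth * rate`).
#' @param chip_replicates ChIP-style samples per genotype/assay (default 1,
#'   matching a one-library-per-condition design).
#' @param min_tss_spacing Minimum distance between consecutive TSSs (bp).
#' @param seed Integer seed; all `simulate_*` operations are deterministic
#'   given the config seed (or an explicit `seed` argument).
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 2000, n_chroms = 20, chrom_length = 1.25e8,
                       replicates = 3,
                       de_frac_down = 0.03, de_frac_up = 0.03, delta = 1.5,
                       baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                       d0_true = 4, s0sq_true = 0.05,
                       background_rate = 0.02, peak_amplitude = 1,
                       peak_sd = 350, peak_sd_downstream = NULL,
                       ko_down_attenuation = 0.5, depth = 0.05,
                       chip_replicates = 1,
                       min_tss_spacing = 6000, seed = 1) {
  cfg <- structure(as.list(environment()), class = "SimConfig")
  if (cfg$de_frac_down + cfg$de_frac_up >= 1)
    stop2("de_frac_down + de_frac_up must be < 1")
  if (cfg$ko_down_attenuation < 0 || cfg$ko_down_attenuation > 1)
    stop2("ko_down_attenuation must be in [0, 1]")
  pos <- c("chrom_length", "replicates", "d0_true", "s0sq_true",
           "background_rate", "peak_sd", "depth", "chip_replicates")
  for (p in pos) if (cfg[[p]] <= 0) stop2(p, " must be positive")
  if (cfg$peak_amplitude < 0) stop2("peak_amplitude must be nonnegative")
  if (cfg$delta < 0) stop2("delta must be nonnegative")
  if (cfg$n_genes < 0) stop2("n_genes must be nonnegative")
  cfg
}

# Profiling uses a 6-kb interval centred on the TSS, so simulated TSSs keep
# span/2 = 3 kb clearance from chromosome ends.
SIM_CLEARANCE <- 3000

#' Simulate a genome annotation
#'
#' Places `n_genes` TSSs across `n_chroms` chromosomes with at least
#' `min_tss_spacing` between consecutive TSSs and 3-kb clearance from
#' chromosome ends (so the default 6-kb profiling interval always fits).
#' Strands are Bernoulli(0.5). Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed`.
#' @return A [genome_annotation()] object.
#' @export
simulate_annotation <- function(config, seed = config$seed) {
  set.seed(seed + 11L)
  L <- config$chrom_length
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  lens <- setNames(rep(L, config$n_chroms), chroms)
  n <- config$n_genes
  if (n == 0)
    return(genome_annotation(lens, NULL))
  per <- diff(floor(seq(0, n, length.out = config$n_chroms + 1)))
  s <- config$min_tss_spacing
  need <- (max(per) - 1) * s + 2 * SIM_CLEARANCE + 1
  if (need > L)
    stop2("chromosome too short: need at least ", need, " bp for ",
          max(per), " genes at ", s, " bp spacing with ", SIM_CLEARANCE,
          " bp end clearance")
  genes <- list()
  idx <- 0L
  for (k in seq_along(chroms)) {
    m <- per[k]
    if (m == 0) next
    slack <- (L - 2 * SIM_CLEARANCE - 1) - (m - 1) * s
    tss <- SIM_CLEARANCE + floor(sort(runif(m, 0, slack + 1))) +
      (seq_len(m) - 1) * s
    ids <- sprintf("g%05d", idx + seq_len(m))
    genes[[k]] <- data.frame(gene_id = ids, chrom = chroms[k], tss = tss,
                             strand = c("+", "-")[rbinom(m, 1, 0.5) + 1],
                             stringsAsFactors = FALSE)
    idx <- idx + m
  }
  genome_annotation(lens, do.call(rbind, genes))
}

#' Simulate a two-group expression matrix with known truth
#'
#' Gene baselines are `Normal(baseline_log2_mean, baseline_log2_sd^2)`;
#' gene variances are scaled inverse-chi-square `(d0_true, s0sq_true)`;
#' a planted fraction of genes receives a log2 fold change of `-delta`
#' (down) or `+delta` (up), split evenly between group means
#' (`mu -/+ delta/2`); log2 intensities are Normal and raw intensities are
#' `2^log2`, so a plain log2 transform recovers exactly Normal data.
#'
#' @param annotation A [genome_annotation()] supplying the gene ids.
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed`.
#' @return A list with `matrix` (raw-scale `ExpressionMatrix`) and `truth`
#'   (`data.frame`: `gene_id`, `class` in down/up/null, `log2fc_true`,
#'   `var_true`, `amp_wt`, `amp_ko`).
#' @export
simulate_expression <- function(annotation, config, seed = config$seed) {
  set.seed(seed + 22L)
  ids <- annotation$genes$gene_id
  n <- length(ids)
  n_down <- round(n * config$de_frac_down)
  n_up <- round(n * config$de_frac_up)
  cls <- rep("null", n)
  pick <- sample.int(n, n_down + n_up)
  cls[pick[seq_len(n_down)]] <- "down"
  cls[pick[n_down + seq_len(n_up)]] <- "up"
  lfc <- ifelse(cls == "down", -config$delta,
                ifelse(cls == "up", config$delta, 0))
  sigma2 <- config$s0sq_true * config$d0_true / rchisq(n, config$d0_true)
  mu <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  r <- config$replicates
  samples <- data.frame(
    sample_id = c(sprintf("WT_%d", seq_len(r)), sprintf("KO_%d", seq_len(r))),
    genotype = rep(c("WT", "KO"), each = r),
    replicate = rep(seq_len(r), 2), stringsAsFactors = FALSE)
  means <- cbind(matrix(mu - lfc / 2, n, r), matrix(mu + lfc / 2, n, r))
  x <- means + matrix(rnorm(n * 2 * r, 0, sqrt(sigma2)), n, 2 * r)
  dimnames(x) <- list(ids, samples$sample_id)
  rho <- config$ko_down_attenuation
  truth <- data.frame(gene_id = ids, class = cls, log2fc_true = lfc,
                      var_true = sigma2,
                      amp_wt = config$peak_amplitude,
                      amp_ko = config$peak_amplitude *
                        ifelse(cls == "down", rho, 1),
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(2^x, samples, scale = "raw-intensity"),
       truth = truth)
}

# Expected per-base rate vector for one chromosome and one genotype:
# background + sum over genes of Gaussian bumps (truncated at 5 sd).
# Dense reference form; the sampler below draws from the same rates by
# Poisson superposition. Kept exported-internal as the analytic oracle.
chip_lambda_chrom <- function(L, tss, amp, strand, config) {
  lam <- rep(config$background_rate, L)
  for (i in seq_along(tss)) {
    w <- peak_weights(L, tss[i], strand[i], config)
    lam[w$base + 1] <- lam[w$base + 1] + amp[i] * w$weight
  }
  lam
}

# Gaussian peak weights over the truncated (+/- 5 sd) support of one gene.
# Upstream/downstream are in gene orientation; the genomic left side of a
# "-" gene is its downstream side.
peak_weights <- function(L, tss, strand, config) {
  sd5 <- config$peak_sd
  sd3 <- config$peak_sd_downstream %||% config$peak_sd
  sdl <- if (strand == "+") sd5 else sd3
  sdr <- if (strand == "+") sd3 else sd5
  lo <- max(0, floor(tss - 5 * sdl))
  hi <- min(L - 1, ceiling(tss + 5 * sdr))
  b <- lo:hi
  sd_b <- ifelse(b < tss, sdl, sdr)
  list(base = b, weight = exp(-(b - tss)^2 / (2 * sd_b^2)))
}

# Assemble a per-base Rle from 0-based event positions (with multiplicity).
events_to_rle <- function(pos, L) {
  if (!length(pos)) return(S4Vectors::Rle(0, L))
  r <- rle(sort(pos))
  at <- r$values; cnt <- r$lengths
  gap <- c(at[1], diff(at) - 1L)
  rl <- c(rbind(gap, 1L), L - at[length(at)] - 1L)
  rv <- c(rbind(0, cnt), 0)
  keep <- rl > 0L
  S4Vectors::Rle(rv[keep], rl[keep])
}

#' Simulate ChIP and input coverage tracks
#'
#' Expected signal at base `b` is
#' `lambda(b) = background_rate + sum_g A_g * exp(-(b - tss_g)^2 / (2 sd^2))`
#' for ChIP tracks (with `A_g` the genotype- and class-dependent amplitude
#' from `truth`) and `background_rate` alone for input tracks; observed
#' per-base counts are Poisson with mean `depth * lambda(b)`. Sampling is by
#' Poisson superposition: a Poisson number of events per component
#' (background, each peak) with positions drawn from the component's
#' normalized rate, which yields exactly independent per-base Poisson counts
#' while scaling to chromosomes of hundreds of megabases (peaks are
#' truncated at 5 standard deviations, relative mass < 6e-7). Deterministic
#' given the seed.
#'
#' @param annotation A [genome_annotation()].
#' @param truth Truth table from [simulate_expression()].
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed`.
#' @return Named list of `CoverageTrack`s: `H3ac_WT`, `H3ac_KO`, `input_WT`,
#'   `input_KO` (with `_repN` suffixes when `chip_replicates > 1`).
#' @export
simulate_chip_coverage <- function(annotation, truth, config,
                                   seed = config$seed) {
  set.seed(seed + 33L)
  g <- annotation$genes
  if (nrow(g) && !identical(g$gene_id, truth$gene_id))
    truth <- truth[match(g$gene_id, truth$gene_id), ]
  lens <- annotation$chrom_lengths
  tracks <- list()
  for (genotype in c("WT", "KO")) {
    amp <- if (genotype == "WT") truth$amp_wt else truth$amp_ko
    for (assay in c("H3ac", "input")) {
      for (rep_i in seq_len(config$chip_replicates)) {
        sig <- lapply(names(lens), function(ch) {
          L <- lens[[ch]]
          pos <- list(sample.int(L, rpois(1, config$depth *
                                            config$background_rate * L),
                                 replace = TRUE) - 1L)
          if (assay == "H3ac") {
            for (i in which(g$chrom == ch)) {
              w <- peak_weights(L, g$tss[i], g$strand[i], config)
              k <- rpois(1, config$depth * amp[i] * sum(w$weight))
              if (k > 0)
                pos[[length(pos) + 1L]] <- sample(w$base, k, replace = TRUE,
                                                  prob = w$weight)
            }
          }
          events_to_rle(unlist(pos, use.names = FALSE), L)
        })
        names(sig) <- names(lens)
        id <- paste0(assay, "_", genotype)
        if (config$chip_replicates > 1) id <- sprintf("%s_rep%d", id, rep_i)
        tracks[[id]] <- coverage_track(sig, sample_id = id, assay = assay,
                                       genotype = genotype,
                                       chrom_lengths = lens)
      }
    }
  }
  tracks
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_annotation()],
#' [simulate_expression()] and [simulate_chip_coverage()] with one config.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed`.
#' @return List with `annotation`, `expression` (`ExpressionMatrix`),
#'   `truth`, `tracks`, and the `config` used.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  ann <- simulate_annotation(config, seed = seed)
  ex <- simulate_expression(ann, config, seed = seed)
  tracks <- simulate_chip_coverage(ann, ex$truth, config, seed = seed)
  list(annotation = ann, expression = ex$matrix, truth = ex$truth,
       tracks = tracks, config = config, seed = seed)
}

#' Write a simulated dataset to a directory
#'
#' Emits annotation (BED6), expression (TSV), truth (TSV), one bedGraph per
#' coverage track, and a JSON manifest of config, seed and file names.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- sim$seed
  write_annotation_bed(sim$annotation, file.path(dir, "annotation.bed"),
                       seed = seed)
  write_chrom_sizes(sim$annotation, file.path(dir, "chrom.sizes"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"),
                   seed = seed)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(annotation = "annotation.bed", chrom_sizes = "chrom.sizes",
             expression = "expression.tsv", truth = "truth.tsv")
  for (id in names(sim$tracks)) {
    f <- paste0(id, ".bedgraph")
    write_coverage(sim$tracks[[id]], file.path(dir, f),
                   dialect = "bedgraph", seed = seed)
    files[[id]] <- f
  }
  cfg <- sim$config
  cfg$peak_sd_downstream <- cfg$peak_sd_downstream %||% NA
  manifest <- list(tool = "chipcomposite",
                   version = as.character(
                     utils::packageVersion("chipcomposite")),
                   seed = seed, config = unclass(cfg),
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
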