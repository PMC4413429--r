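# Shared fixture builders. Everything is generated in code; no stored data.

tiny_annotation <- function(lengths = c(chr1 = 1000, chr2 = 800),
                            genes = NULL) {
  if (is.null(genes))
    genes <- data.frame(
      gene_id = c("gA", "gB", "gC"),
      chrom = c("chr1", "chr1", "chr2"),
      tss = c(300, 650, 400),
      strand = c("+", "-", "+"),
      stringsAsFactors = FALSE)
  genome_annotation(lengths, genes)
}

# Random sparse track with plenty of equal-value runs and zeros.
random_track <- function(lengths = c(chr1 = 400, chr2 = 250),
                         sample_id = "rnd", values = c(0, 0, 1, 2, 2.5)) {
  sig <- lapply(lengths, function(L)
    sample(values, L, replace = TRUE))
  names(sig) <- names(lengths)
  coverage_track(sig, sample_id = sample_id, chrom_lengths = lengths)
}

# Dense per-base vector of a track chromosome (test-side decoding).
dense_signal <- function(track, chrom) {
  as.numeric(track$signal[[chrom]])
}

# Brute-force per-base window averaging: the independent profiling oracle.
brute_force_density <- function(dense, tss, strand, span, window, slide,
                                strand_flip = TRUE) {
  n <- (span - window) / slide + 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- tss - span / 2 + (i - 1) * slide   # 0-based window start
    acc <- 0
    for (b in s:(s + window - 1)) acc <- acc + dense[b + 1]
    out[i] <- acc / window
  }
  if (strand_flip && strand == "-") out <- rev(out)
  out
}

# Independent moment-equation solver for the variance-prior fit
# (uniroot-based; the package uses hand-rolled bisection).
oracle_fit_moments <- function(s2, dg) {
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  evar <- stats::var(e) - trigamma(dg / 2)
  if (evar <= 0) return(list(d0 = Inf, s0sq = exp(mean(log(s2)))))
  half <- stats::uniroot(function(x) trigamma(x) - evar,
                         lower = 1e-6, upper = 1e6, tol = 1e-12)$root
  list(d0 = 2 * half, s0sq = exp(mean(e) + digamma(half) - log(half)))
}

# A 3 vs 3 raw-intensity matrix with fixed values (positive).
fixed_expression <- function(values) {
  samples <- data.frame(
    sample_id = c("WT_1", "WT_2", "WT_3", "KO_1", "KO_2", "KO_3"),
    genotype = rep(c("WT", "KO"), each = 3),
    replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  colnames(values) <- samples$sample_id
  expression_matrix(values, samples, scale = "raw-intensity")
}

# Small simulation config on a desk-scale genome for unit tests.
small_sim_config <- function(...) {
  do.call(sim_config, utils::modifyList(
    list(n_genes = 200, n_chroms = 2, chrom_length = 2e6,
         background_rate = 0.05, depth = 1), list(...)))
}
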