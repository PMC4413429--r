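#' Sliding-window grid centred on an anchor
#'
#' Defines the window layout for TSS-centred density computation: windows of
#' `window` bp advancing by `slide` bp across a `span`-bp interval centred
#' on the anchor. The first window begins at `-span/2`; reported offsets are
#' window centres. Defaults (6 kb span, 100-bp windows, 20-bp slide) give
#' 296 windows.
#'
#' @param span Interval width in bp (default 6000), must be even.
#' @param window Window width in bp (default 100).
#' @param slide Step between window starts in bp (default 20);
#'   `(span - window)` must be divisible by `slide`.
#' @return An object of class `WindowGrid` with fields `span`, `window`,
#'   `slide`, `n_windows`, and `offsets` (window-centre positions relative
#'   to the anchor).
#' @export
window_grid <- function(span = 6000, window = 100, slide = 20) {
  if (window > span) stop2("window must not exceed span")
  if (span %% 2 != 0) stop2("span must be even")
  if ((span - window) %% slide != 0)
    stop2("(span - window) must be divisible by slide")
  n <- (span - window) / slide + 1
  structure(list(span = span, window = window, slide = slide,
                 n_windows = n,
                 offsets = -span / 2 + window / 2 + slide * (seq_len(n) - 1)),
            class = "WindowGrid")
}

#' @export
print.WindowGrid <- function(x, ...) {
  cat(sprintf("WindowGrid: span %d bp, %d-bp windows, %d-bp slide (%d windows)\n",
              x$span, x$window, x$slide, x$n_windows))
  invisible(x)
}

#' Scale coverage tracks to a common total signal
#'
#' Normalizes for variable sequencing depth: each track is scaled by
#' `mean(total_signal) / total_signal`, so every post-normalization total
#' equals the pre-normalization mean.
#'
#' @param tracks List of `CoverageTrack`s.
#' @return List of scaled `CoverageTrack`s (same names and order).
#' @export
depth_normalize <- function(tracks) {
  if (!length(tracks)) stop2("need at least one track")
  totals <- vapply(tracks, function(t) t$total_signal, numeric(1))
  zero <- totals == 0
  if (any(zero))
    stop2("zero-signal track(s): ",
          paste(vapply(tracks[zero], function(t) t$sample_id, character(1)),
                collapse = ", "))
  target <- mean(totals)
  lapply(tracks, function(t) track_scale(t, target / t$total_signal))
}

#' Per-window density around one anchor
#'
#' Window `i` covers genomic interval
#' `[tss - span/2 + (i-1)*slide, tss - span/2 + (i-1)*slide + window)`;
#' its density is the arithmetic mean of per-base signal over the window.
#' For minus-strand anchors the vector is reversed (unless
#' `strand_flip = FALSE`) so offsets read 5' to 3' along the gene.
#'
#' @param track A `CoverageTrack`.
#' @param chrom Chromosome name.
#' @param tss 0-based anchor coordinate.
#' @param strand `"+"` or `"-"`.
#' @param grid A [window_grid()].
#' @param strand_flip Reverse minus-strand profiles (default `TRUE`).
#' @return Numeric vector of length `grid$n_windows`, named by offset.
#' @export
windowed_density <- function(track, chrom, tss, strand = "+",
                             grid = window_grid(), strand_flip = TRUE) {
  half <- grid$span / 2
  lo <- tss - half; hi <- tss + half
  if (!chrom %in% names(track$chrom_lengths))
    stop2("chromosome not in track: ", chrom)
  L <- track$chrom_lengths[[chrom]]
  if (lo < 0 || hi > L)
    stop2("interval [", lo, ", ", hi, ") out of bounds on ", chrom,
          " (length ", L, ")")
  sl <- track_slice(track, chrom, lo, hi)
  cs <- c(0, cumsum(sl))
  starts <- grid$slide * (seq_len(grid$n_windows) - 1)
  dens <- (cs[starts + grid$window + 1] - cs[starts + 1]) / grid$window
  if (strand_flip && strand == "-") dens <- rev(dens)
  names(dens) <- grid$offsets
  dens
}

#' TSS-centred composite (metagene) profile
#'
#' Computes [windowed_density()] for every requested gene and summarizes
#' each window by the median across genes (for an even number of genes, the
#' mean of the two central order statistics). Genes whose interval extends
#' beyond chromosome bounds are excluded and reported, not zero-padded.
#'
#' @param track A (depth-normalized) `CoverageTrack`.
#' @param annotation A [genome_annotation()].
#' @param gene_ids Gene ids to include (must exist in the annotation).
#' @param grid A [window_grid()].
#' @param gene_set_id Label stored in the result.
#' @param strand_flip Passed to [windowed_density()].
#' @return An object of class `CompositeProfile`: list with `grid`,
#'   `track_id`, `gene_set_id`, `per_gene_matrix` (gene x window),
#'   `median_profile`, `n_genes`, `excluded` (gene ids dropped at bounds).
#' @export
composite_profile <- function(track, annotation, gene_ids,
                              grid = window_grid(), gene_set_id = "set",
                              strand_flip = TRUE) {
  g <- annotation$genes
  missing_ids <- setdiff(gene_ids, g$gene_id)
  if (length(missing_ids)) stop2("gene id(s) not in annotation: ",
                                 paste(missing_ids, collapse = ", "))
  g <- g[match(gene_ids, g$gene_id), , drop = FALSE]
  half <- grid$span / 2
  len <- annotation$chrom_lengths[g$chrom]
  ok <- g$tss - half >= 0 & g$tss + half <= len
  excluded <- g$gene_id[!ok]
  g <- g[ok, , drop = FALSE]
  if (!nrow(g)) stop2("no genes left after boundary exclusion")
  mat <- t(vapply(seq_len(nrow(g)), function(i)
    windowed_density(track, g$chrom[i], g$tss[i], g$strand[i], grid,
                     strand_flip = strand_flip),
    numeric(grid$n_windows)))
  rownames(mat) <- g$gene_id
  med <- apply(mat, 2, median)
  structure(list(grid = grid, track_id = track$sample_id,
                 gene_set_id = gene_set_id, per_gene_matrix = mat,
                 median_profile = med, n_genes = nrow(g),
                 excluded = excluded),
            class = "CompositeProfile")
}

#' @export
print.CompositeProfile <- function(x, ...) {
  cat(sprintf(
    "CompositeProfile '%s' x '%s': %d genes, %d windows (%d excluded)\n",
    x$track_id, x$gene_set_id, x$n_genes, x$grid$n_windows,
    length(x$excluded)))
  invisible(x)
}

#' Write a composite profile as TSV (offset, median, n_genes)
#' @param profile A `CompositeProfile`.
#' @param path Output path.
#' @param per_gene Also write the per-gene matrix to
#'   `<path>.per_gene.tsv` (default `FALSE`).
#' @export
write_composite <- function(profile, path, per_gene = FALSE) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(tool_header(), con)
  writeLines(sprintf("# track=%s gene_set=%s n_genes=%d",
                     profile$track_id, profile$gene_set_id,
                     profile$n_genes), con)
  writeLines("offset\tmedian\tn_genes", con)
  writeLines(sprintf("%d\t%.17g\t%d", as.integer(profile$grid$offsets),
                     profile$median_profile, profile$n_genes), con)
  if (per_gene) {
    m <- profile$per_gene_matrix
    pg <- paste0(path, ".per_gene.tsv")
    con2 <- file(pg, "w"); on.exit(close(con2), add = TRUE)
    writeLines(paste(c("gene_id", profile$grid$offsets), collapse = "\t"),
               con2)
    writeLines(paste(rownames(m),
                     apply(m, 1, function(v)
                       paste(sprintf("%.17g", v), collapse = "\t")),
                     sep = "\t"), con2)
  }
  invisible(path)
}

#' Extract a per-base signal slice around one gene's TSS
#'
#' Returns the `[tss - flank, tss + flank)` slice for browser-style locus
#' rendering; out-of-bounds flanks are truncated with a warning.
#'
#' @param track A `CoverageTrack`.
#' @param annotation A [genome_annotation()].
#' @param gene_id Gene identifier.
#' @param flank Flank size in bp (`>= 0`).
#' @return An object of class `LocusSlice`: list with `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open), and `signal` (per-base values).
#' @export
locus_extract <- function(track, annotation, gene_id, flank) {
  if (flank < 0) stop2("flank must be >= 0")
  g <- annotation$genes
  i <- match(gene_id, g$gene_id)
  if (is.na(i)) stop2("gene not in annotation: ", gene_id)
  L <- annotation$chrom_lengths[[g$chrom[i]]]
  lo <- g$tss[i] - flank; hi <- g$tss[i] + flank
  if (lo < 0 || hi > L) {
    warning("flank truncated at chromosome bounds for ", gene_id)
    lo <- max(0, lo); hi <- min(L, hi)
  }
  structure(list(gene_id = gene_id, chrom = g$chrom[i], start = lo,
                 end = hi,
                 signal = track_slice(track, g$chrom[i], lo, hi)),
            class = "LocusSlice")
}

#' Write a locus slice as bedGraph
#' @param slice A `LocusSlice` from [locus_extract()].
#' @param path Output path.
#' @export
write_locus <- function(slice, path) {
  lens <- setNames(slice$end, slice$chrom)
  sig <- setNames(list(c(S4Vectors::Rle(0, slice$start),
                         S4Vectors::Rle(slice$signal))), slice$chrom)
  tr <- coverage_track(sig, sample_id = slice$gene_id,
                       chrom_lengths = lens)
  write_coverage(tr, path, dialect = "bedgraph")
}
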