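#' Per-base genome coverage track for one sample
#'
#' Signal is stored run-length encoded (one [S4Vectors::Rle] per chromosome);
#' dense vectors are materialized only inside window computations. All
#' coordinates are 0-based, half-open internally.
#'
#' @param signal Named list of numeric vectors or `Rle` objects, one per
#'   chromosome, each of length equal to the chromosome.
#' @param sample_id Sample identifier.
#' @param assay `"H3ac"` (ChIP) or `"input"` (control), or `NA`.
#' @param genotype `"WT"` or `"KO"`, or `NA`.
#' @param chrom_lengths Optional named lengths; defaults to the signal
#'   lengths. Signal vectors shorter than the declared length are zero-padded.
#' @return An object of class `CoverageTrack` with fields `sample_id`,
#'   `assay`, `genotype`, `signal` (list of `Rle`), `chrom_lengths`, and
#'   `total_signal` (sum of per-base signal).
#' @export
coverage_track <- function(signal, sample_id = "sample",
                           assay = NA_character_, genotype = NA_character_,
                           chrom_lengths = NULL) {
  if (is.null(names(signal)) || any(names(signal) == ""))
    stop2("signal must be a named list (one element per chromosome)")
  sig <- lapply(signal, function(v) {
    r <- if (methods::is(v, "Rle")) v else S4Vectors::Rle(as.numeric(v))
    if (any(S4Vectors::runValue(r) < 0)) stop2("negative signal values")
    r
  })
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(sig, length, numeric(1))
  } else {
    bad <- !(names(sig) %in% names(chrom_lengths))
    if (any(bad)) stop2("signal chromosome(s) not in chrom_lengths: ",
                        paste(names(sig)[bad], collapse = ", "))
    for (ch in names(sig)) {
      L <- chrom_lengths[[ch]]
      if (length(sig[[ch]]) > L)
        stop2("signal on ", ch, " longer than chromosome (", L, " bp)")
      if (length(sig[[ch]]) < L)
        sig[[ch]] <- c(sig[[ch]], S4Vectors::Rle(0, L - length(sig[[ch]])))
    }
    # carry zero-only chromosomes so tracks over one annotation are congruent
    for (ch in setdiff(names(chrom_lengths), names(sig)))
      sig[[ch]] <- S4Vectors::Rle(0, chrom_lengths[[ch]])
    sig <- sig[names(chrom_lengths)]
  }
  if (!is.na(assay) && !assay %in% c("H3ac", "input"))
    stop2("assay must be 'H3ac' or 'input'")
  if (!is.na(genotype) && !genotype %in% c("WT", "KO"))
    stop2("genotype must be 'WT' or 'KO'")
  structure(list(sample_id = sample_id, assay = assay, genotype = genotype,
                 signal = sig,
                 chrom_lengths = setNames(as.numeric(chrom_lengths[names(sig)]),
                                          names(sig)),
                 total_signal = sum(vapply(sig, function(r) sum(as.numeric(
                   S4Vectors::runValue(r)) * S4Vectors::runLength(r)),
                   numeric(1)))),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf(
    "CoverageTrack '%s' (assay=%s, genotype=%s): %d chromosome(s), total signal %.6g\n",
    x$sample_id, x$assay, x$genotype, length(x$signal), x$total_signal))
  invisible(x)
}

#' Recompute the total signal of a track from its run-length encoding
#' @param track A `CoverageTrack`.
#' @return The sum of per-base signal.
#' @export
track_total <- function(track) {
  sum(vapply(track$signal, function(r)
    sum(as.numeric(S4Vectors::runValue(r)) * S4Vectors::runLength(r)),
    numeric(1)))
}

#' Multiply a track by a positive scalar
#' @param track A `CoverageTrack`.
#' @param factor Positive scale factor.
#' @return The scaled `CoverageTrack`.
#' @export
track_scale <- function(track, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0)
    stop2("factor must be a nonnegative scalar")
  # scaling by a positive factor preserves run boundaries, so rebuild each
  # Rle from its runs directly instead of going through Ops dispatch
  track$signal <- lapply(track$signal, function(r) {
    S4Vectors::runValue(r) <- as.numeric(S4Vectors::runValue(r)) * factor
    r
  })
  track$total_signal <- track$total_signal * factor
  track
}

# Dense numeric slice [start, end) of one chromosome, 0-based half-open.
track_slice <- function(track, chrom, start, end) {
  r <- track$signal[[chrom]]
  if (is.null(r)) stop2("chromosome not in track: ", chrom)
  if (start < 0 || end > length(r) || end < start)
    stop2("slice [", start, ", ", end, ") out of bounds on ", chrom)
  if (end == start) return(numeric(0))
  as.numeric(S4Vectors::window(r, start + 1L, end))
}

#' Read a coverage track from WIG or bedGraph
#'
#' Parsing is delegated to [rtracklayer::import()] (fixedStep and
#' variableStep WIG with `span`, and 0-based half-open bedGraph are all
#' supported); validation and assembly into per-base run-length signal happen
#' here. Bases not covered by any declaration are 0.
#'
#' @param path Path to the file.
#' @param dialect `"wig"` or `"bedgraph"`.
#' @param annotation Optional [genome_annotation()]; when given, unknown
#'   chromosomes or intervals beyond chromosome ends are errors (set
#'   `permissive = TRUE` to drop unknown chromosomes with a warning instead).
#' @param sample_id,assay,genotype Track metadata (see [coverage_track()]).
#' @param permissive Drop intervals on unknown chromosomes instead of
#'   erroring (only relevant with `annotation`).
#' @return A `CoverageTrack`.
#' @export
read_coverage <- function(path, dialect = c("wig", "bedgraph"),
                          annotation = NULL,
                          sample_id = tools::file_path_sans_ext(basename(path)),
                          assay = NA_character_, genotype = NA_character_,
                          permissive = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("file not found: ", path)
  fmt <- if (dialect == "wig") "wig" else "bedGraph"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop2("malformed ", dialect, " file ",
                                           path, ": ", conditionMessage(e)))
  gr <- methods::as(gr, "GRanges")
  if (length(gr) && any(gr$score < 0)) {
    i <- which(gr$score < 0)[1]
    stop2("negative value ", gr$score[i], " at ",
          as.character(GenomicRanges::seqnames(gr)[i]), ":",
          GenomicRanges::start(gr)[i] - 1, " in ", path)
  }
  hit <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                     drop.redundant = TRUE)
  if (length(hit)) {
    i <- S4Vectors::queryHits(hit)[1]; j <- S4Vectors::subjectHits(hit)[1]
    stop2("overlapping intervals in ", path, ": ",
          as.character(GenomicRanges::seqnames(gr)[i]), ":",
          GenomicRanges::start(gr)[i] - 1, "-", GenomicRanges::end(gr)[i],
          " overlaps ",
          GenomicRanges::start(gr)[j] - 1, "-", GenomicRanges::end(gr)[j])
  }
  chroms <- as.character(GenomicRanges::seqnames(gr))
  if (!is.null(annotation)) {
    lens <- annotation$chrom_lengths
    unknown <- !(chroms %in% names(lens))
    if (any(unknown)) {
      if (permissive) {
        warning("dropping ", sum(unknown),
                " interval(s) on unknown chromosome(s): ",
                paste(unique(chroms[unknown]), collapse = ", "))
        gr <- gr[!unknown]
        chroms <- chroms[!unknown]
      } else {
        stop2("unknown chromosome(s) in ", path, ": ",
              paste(unique(chroms[unknown]), collapse = ", "))
      }
    }
    if (length(gr) && any(GenomicRanges::end(gr) > lens[chroms]))
      stop2("interval beyond chromosome length in ", path)
    widths <- lens
  } else {
    if (!length(gr)) stop2("no data lines in ", path,
                           " and no annotation to define chromosomes")
    widths <- tapply(GenomicRanges::end(gr), chroms, max)
    widths <- setNames(as.numeric(widths), names(widths))
  }
  # intervals are validated disjoint, so the run-length encoding can be
  # assembled positionally (coverage(weight=) would accumulate floating-
  # point residue in zero regions)
  sig <- lapply(names(widths), function(ch) {
    sel <- gr[chroms == ch]
    if (!length(sel)) return(S4Vectors::Rle(0, widths[[ch]]))
    o <- order(GenomicRanges::start(sel))
    s0 <- GenomicRanges::start(sel)[o] - 1   # 0-based starts
    e0 <- GenomicRanges::end(sel)[o]         # 0-based half-open ends
    gap <- s0 - c(0, e0[-length(e0)])
    rl <- c(rbind(gap, e0 - s0), widths[[ch]] - e0[length(e0)])
    rv <- c(rbind(0, as.numeric(sel$score)[o]), 0)
    keep <- rl > 0
    S4Vectors::Rle(rv[keep], rl[keep])
  })
  names(sig) <- names(widths)
  coverage_track(sig, sample_id = sample_id, assay = assay,
                 genotype = genotype, chrom_lengths = widths)
}

#' Write a coverage track as bedGraph or WIG
#'
#' bedGraph output merges runs of equal value and omits zero runs (zeros are
#' implicit); WIG output emits one `fixedStep` block per nonzero run with
#' `step` and `span` equal to the run length. Both re-read to an identical
#' track. A comment header records tool version and optional seed.
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @param dialect `"bedgraph"` or `"wig"`.
#' @param seed Optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path, dialect = c("bedgraph", "wig"),
                           seed = NULL) {
  dialect <- match.arg(dialect)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop2("cannot write ", path))
  on.exit(close(con))
  writeLines(tool_header(seed = seed), con)
  if (dialect == "bedgraph")
    writeLines("track type=bedGraph", con)
  for (ch in names(track$signal)) {
    r <- track$signal[[ch]]
    rl <- S4Vectors::runLength(r)
    rv <- as.numeric(S4Vectors::runValue(r))
    ends <- cumsum(rl)            # 0-based half-open run ends
    starts <- ends - rl           # 0-based run starts
    nz <- rv != 0
    if (!any(nz)) next
    if (dialect == "bedgraph") {
      writeLines(sprintf("%s\t%s\t%s\t%s", ch,
                         format(starts[nz], scientific = FALSE, trim = TRUE),
                         format(ends[nz], scientific = FALSE, trim = TRUE),
                         sprintf("%.17g", rv[nz])), con)
    } else {
      # WIG is 1-based: run starting at 0-based b begins at base b + 1
      writeLines(sprintf(
        "fixedStep chrom=%s start=%s step=%s span=%s\n%s", ch,
        format(starts[nz] + 1, scientific = FALSE, trim = TRUE),
        format(rl[nz], scientific = FALSE, trim = TRUE),
        format(rl[nz], scientific = FALSE, trim = TRUE),
        sprintf("%.17g", rv[nz])), con)
    }
  }
  invisible(path)
}
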