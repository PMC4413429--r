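#' Genome annotation: chromosome lengths and TSS-bearing gene records
#'
#' The anchor set for all TSS-centred profiling. Internally every coordinate
#' is 0-based, half-open; the transcription start site (`tss`) of a gene is a
#' single 0-based base position.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param genes A `data.frame` with columns `gene_id`, `chrom`, `tss`,
#'   `strand` (`"+"` or `"-"`) and optionally `name` (display label; defaults
#'   to `gene_id`).
#' @return An object of class `GenomeAnnotation`: a list with elements
#'   `chrom_lengths` and `genes`.
#' @examples
#' ann <- genome_annotation(
#'   c(chr1 = 1e4),
#'   data.frame(gene_id = "g1", chrom = "chr1", tss = 5000, strand = "+")
#' )
#' @export
genome_annotation <- function(chrom_lengths, genes) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths)) ||
      any(names(chrom_lengths) == ""))
    stop2("chrom_lengths must be a named vector of chromosome lengths")
  if (anyDuplicated(names(chrom_lengths)))
    stop2("duplicate chromosome names in chrom_lengths")
  if (any(chrom_lengths <= 0)) stop2("chromosome lengths must be positive")
  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        tss = integer(), strand = character(),
                        name = character(), stringsAsFactors = FALSE)
  } else {
    genes <- as.data.frame(genes, stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "tss", "strand")
    miss <- setdiff(req, names(genes))
    if (length(miss)) stop2("genes is missing columns: ",
                            paste(miss, collapse = ", "))
    if (!"name" %in% names(genes)) genes$name <- genes$gene_id
    genes <- genes[, c("gene_id", "chrom", "tss", "strand", "name")]
    genes$tss <- as.numeric(genes$tss)
    dup <- genes$gene_id[duplicated(genes$gene_id)]
    if (length(dup)) stop2("duplicate gene_id: ",
                           paste(unique(dup), collapse = ", "))
    if (!all(genes$strand %in% c("+", "-")))
      stop2("strand must be '+' or '-'")
    bad <- !(genes$chrom %in% names(chrom_lengths))
    if (any(bad)) stop2("gene chrom not in chrom_lengths: ",
                        paste(unique(genes$chrom[bad]), collapse = ", "))
    len <- chrom_lengths[genes$chrom]
    if (any(genes$tss < 0 | genes$tss >= len))
      stop2("tss outside chromosome bounds for gene(s): ",
            paste(genes$gene_id[genes$tss < 0 | genes$tss >= len],
                  collapse = ", "))
  }
  rownames(genes) <- NULL
  structure(list(chrom_lengths = chrom_lengths, genes = genes),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d chromosome(s), %d gene(s)\n",
              length(x$chrom_lengths), nrow(x$genes)))
  invisible(x)
}

#' Read a gene/TSS annotation from BED6 or GFF3
#'
#' TSS conventions (0-based internal coordinates):
#' * BED6: `tss = chromStart` for `+` strand, `chromEnd - 1` for `-`.
#' * GFF3 (1-based, inclusive): `tss = start - 1` for `+`, `end - 1` for `-`.
#'
#' Chromosome lengths are taken from `chrom_lengths` when supplied, otherwise
#' inferred from the right-most feature end per chromosome.
#'
#' @param path Path to the annotation file.
#' @param dialect `"bed6"` or `"gff3"`.
#' @param feature_type For GFF3, the feature type to anchor on
#'   (default `"gene"`).
#' @param chrom_lengths Optional named vector of chromosome lengths; features
#'   beyond these bounds are an error.
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(path, dialect = c("bed6", "gff3"),
                            feature_type = "gene", chrom_lengths = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop2("file not found: ", path)
  if (dialect == "bed6") {
    g <- parse_bed6(path)
  } else {
    g <- parse_gff3_genes(path, feature_type)
  }
  if (is.null(chrom_lengths)) {
    if (nrow(g)) {
      chrom_lengths <- tapply(g$end, g$chrom, max)
      chrom_lengths <- setNames(as.numeric(chrom_lengths),
                                names(chrom_lengths))
    } else {
      stop2("empty annotation file and no chrom_lengths supplied: ", path)
    }
  } else {
    bad <- !(g$chrom %in% names(chrom_lengths))
    if (any(bad)) stop2("unknown chromosome(s) in ", path, ": ",
                        paste(unique(g$chrom[bad]), collapse = ", "))
    if (any(g$end > chrom_lengths[g$chrom]))
      stop2("feature end beyond chromosome length in ", path)
  }
  tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  genome_annotation(chrom_lengths,
                    data.frame(gene_id = g$gene_id, chrom = g$chrom,
                               tss = tss, strand = g$strand, name = g$name,
                               stringsAsFactors = FALSE))
}

# BED6 parsed in-package: the format is six whitespace-separated fields and
# hand parsing lets malformed-line errors carry a line number.
parse_bed6 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) &
    nzchar(trimws(lines))
  idx <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "[ \t]+")
  n <- lengths(rows)
  if (any(n < 6)) stop2("malformed BED6 line ", idx[which(n < 6)[1]],
                        " in ", path, ": fewer than 6 fields")
  m <- do.call(rbind, lapply(rows, `[`, 1:6))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- is.na(start) | is.na(end) | start < 0 | end <= start |
    !(m[, 6] %in% c("+", "-"))
  if (any(bad)) stop2("malformed BED6 line ", idx[which(bad)[1]],
                      " in ", path)
  data.frame(chrom = m[, 1], start = start, end = end,
             gene_id = m[, 4], name = m[, 4], strand = m[, 6],
             stringsAsFactors = FALSE)
}

parse_gff3_genes <- function(path, feature_type) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop2("malformed GFF3 in ", path, ": ",
                                           conditionMessage(e)))
  gr <- gr[gr$type == feature_type]
  if (!length(gr)) stop2("no '", feature_type, "' features in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop2("feature(s) without '+'/'-' strand in ", path)
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  if (anyNA(ids)) stop2("GFF3 '", feature_type,
                        "' feature without an ID attribute in ", path)
  nm <- if (!is.null(gr$Name)) as.character(gr$Name) else ids
  nm[is.na(nm)] <- ids[is.na(nm)]
  # GFF3 is 1-based inclusive; convert to the package's 0-based half-open
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             gene_id = ids, name = nm, strand = strand,
             stringsAsFactors = FALSE)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  f <- strsplit(lines, "[ \t]+")
  len <- suppressWarnings(vapply(f, function(x) as.numeric(x[2]), numeric(1)))
  if (anyNA(len)) stop2("malformed chrom.sizes line ", which(is.na(len))[1],
                        " in ", path)
  setNames(len, vapply(f, `[`, character(1), 1))
}

#' Write a chrom.sizes file for an annotation
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @export
write_chrom_sizes <- function(annotation, path) {
  writeLines(sprintf("%s\t%s", names(annotation$chrom_lengths),
                     format(annotation$chrom_lengths, scientific = FALSE,
                            trim = TRUE)), path)
  invisible(path)
}

#' Write an annotation as BED6
#'
#' Each gene is emitted as a 1-bp feature at its TSS (the only interval the
#' annotation retains), preserving the BED TSS conventions used by
#' [read_annotation()].
#'
#' @param annotation A [genome_annotation()] object.
#' @param path Output path.
#' @param seed Optional integer recorded in the comment header.
#' @export
write_annotation_bed <- function(annotation, path, seed = NULL) {
  g <- annotation$genes
  # For "-" strand read_annotation takes chromEnd - 1, so a 1-bp interval
  # [tss, tss + 1) round-trips on both strands.
  lines <- c(tool_header(seed = seed),
             if (nrow(g)) sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom,
                                  as.integer(g$tss), as.integer(g$tss) + 1L,
                                  g$gene_id, g$strand))
  writeLines(lines, path)
  invisible(path)
}
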