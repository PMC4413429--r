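#' Probe/gene-by-sample intensity matrix with genotype metadata
#'
#' @param values Numeric matrix (features in rows, samples in columns) with
#'   feature ids as row names and sample ids as column names.
#' @param samples `data.frame` with columns `sample_id`, `genotype`
#'   (`"WT"`/`"KO"`) and `replicate` (integer), one row per column of
#'   `values`, in column order.
#' @param scale `"raw-intensity"` (strictly positive values) or
#'   `"transformed"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, samples,
                              scale = c("raw-intensity", "transformed")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values))
    stop2("values must be numeric with no missing cells")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop2("values must have unique feature ids as row names")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "genotype", "replicate")
  if (!all(req %in% names(samples)))
    stop2("samples must have columns: ", paste(req, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop2("samples has ", nrow(samples), " rows but values has ",
          ncol(values), " columns")
  if (!all(samples$genotype %in% c("WT", "KO")))
    stop2("genotype must be 'WT' or 'KO'")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop2("column names of values must match samples$sample_id in order")
  if (scale == "raw-intensity" && any(values <= 0))
    stop2("raw-intensity values must be strictly positive (offending ",
          "feature: ", rownames(values)[which(values <= 0,
                                              arr.ind = TRUE)[1, 1]], ")")
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' Read an intensity matrix from TSV
#'
#' The file must have a header row of sample ids and feature ids in the first
#' column; every body cell must be numeric.
#'
#' @param path TSV path.
#' @param metadata `data.frame` with `sample_id`, `genotype`, `replicate`
#'   covering every column of the file (extra rows are an error).
#' @param scale Passed to [expression_matrix()].
#' @return An `ExpressionMatrix` with columns ordered as in the file.
#' @export
read_expression <- function(path, metadata,
                            scale = c("raw-intensity", "transformed")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop2("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "#",
                          colClasses = "character")
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(df)), nrow = nrow(df),
           dimnames = dimnames(df)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop2("non-numeric cell at feature '", rownames(vals)[bad[1]],
          "', sample '", colnames(vals)[bad[2]], "' in ", path)
  }
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  miss <- setdiff(colnames(vals), metadata$sample_id)
  if (length(miss)) stop2("missing metadata for sample(s): ",
                          paste(miss, collapse = ", "))
  meta <- metadata[match(colnames(vals), metadata$sample_id), , drop = FALSE]
  expression_matrix(vals, meta, scale = scale)
}

#' Write an expression matrix as TSV
#' @param matrix An `ExpressionMatrix`.
#' @param path Output path.
#' @param seed Optional integer recorded in the comment header.
#' @export
write_expression <- function(matrix, path, seed = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(tool_header(seed = seed), con)
  writeLines(paste(c("feature_id", colnames(matrix$values)),
                   collapse = "\t"), con)
  body <- apply(matrix$values, 1, function(v)
    paste(sprintf("%.17g", v), collapse = "\t"))
  writeLines(paste(rownames(matrix$values), body, sep = "\t"), con)
  invisible(path)
}

#' Gene-set collection (GMT)
#'
#' @param terms Named list; each element a list with `description` (string)
#'   and `members` (character vector of gene ids, non-empty, no duplicates).
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(terms) {
  if (is.null(names(terms)) || any(names(terms) == ""))
    stop2("terms must be a named list")
  if (anyDuplicated(names(terms))) stop2("duplicate term ids")
  for (id in names(terms)) {
    m <- terms[[id]]$members
    if (!length(m)) stop2("empty member list for term '", id, "'")
    if (anyDuplicated(m)) stop2("duplicate members in term '", id, "'")
  }
  structure(list(terms = terms), class = "GeneSetCollection")
}

#' Read a GMT gene-set file
#'
#' Lines are tab-separated: term id, description, then one or more members.
#'
#' @param path GMT path.
#' @return A [gene_set_collection()] object.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop2("no terms in GMT file ", path)
  terms <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3)
      stop2("GMT line ", i, " has no members (term '", f[1] %||% "?", "')")
    terms[[f[1]]] <- list(description = f[2], members = unique(f[-(1:2)]))
  }
  gene_set_collection(terms)
}
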