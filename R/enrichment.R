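#' Hypergeometric gene-set over-representation test
#'
#' For each term, members are intersected with the universe; with `N` the
#' universe size, `K` the intersected term size, `n` the query size and `k`
#' the query/term overlap, the upper-tail hypergeometric p-value
#' `P(X >= k)` is computed and Benjamini-Hochberg adjusted across all tested
#' terms. Terms with `K = 0` are skipped.
#'
#' @param query Character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of gene ids defining the background.
#' @param collection A [gene_set_collection()].
#' @return An object of class `EnrichmentResult`: a `data.frame` with
#'   `term_id`, `description`, `k`, `K`, `n`, `N`, `p_value`, `p_adj`,
#'   ordered by `p_value`.
#' @export
enrichment_test <- function(query, universe, collection) {
  query <- unique(query); universe <- unique(universe)
  out <- setdiff(query, universe)
  if (length(out)) stop2("query gene(s) not in universe: ",
                         paste(out, collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection$terms), function(id) {
    term <- collection$terms[[id]]
    members <- intersect(term$members, universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, query))
    data.frame(term_id = id, description = term$description,
               k = k, K = K, n = n, N = N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(structure(data.frame(term_id = character(),
                                description = character(), k = integer(),
                                K = integer(), n = integer(), N = integer(),
                                p_value = numeric(), p_adj = numeric()),
                     class = c("EnrichmentResult", "data.frame")))
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  structure(res, class = c("EnrichmentResult", "data.frame"))
}
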