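#' @importFrom stats median pnorm pt p.adjust quantile rnorm rpois rbinom
#'   rchisq runif var wilcox.test splinefun lm coef setNames phyper
#' @importFrom utils read.delim write.table packageVersion
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

#' Header comment lines for emitted files
#'
#' All writers stamp a short comment header so artifacts are traceable to a
#' package version and, where applicable, a generation seed.
#' @noRd
tool_header <- function(prefix = "#", seed = NULL) {
  h <- sprintf("%s chipcomposite %s", prefix,
               as.character(utils::packageVersion("chipcomposite")))
  if (!is.null(seed)) h <- c(h, sprintf("%s seed=%d", prefix, as.integer(seed)))
  h
}
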