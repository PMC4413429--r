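#' Variance-stabilizing transformation
#'
#' Fits the per-gene variance as an additive-plus-multiplicative function of
#' the per-gene mean, `var ~ a + b * mean^2`, and applies the generalized
#' log `g(x) = log2(x + sqrt(x^2 + lambda)) - 1` with `lambda = a/b` (the
#' ratio of the additive to the multiplicative variance component). For
#' large `x`, `g(x) -> log2(x)`; the transform is strictly monotone for any
#' `lambda >= 0`. The trend is fitted on the rescaled form
#' `var/mean^2 ~ b + a/mean^2` (which weights genes evenly across the
#' intensity range) with two rounds of 3-sigma residual trimming, since
#' plain least squares on `var ~ mean^2` is dominated by a handful of
#' high-intensity, high-variance genes. When the fit fails (non-positive
#' multiplicative component), the function falls back to plain `log2` with
#' a warning; `method = "log2"` requests that directly.
#'
#' @param matrix A raw-scale `ExpressionMatrix` (strictly positive values).
#' @param method `"vst"` (default) or `"log2"`.
#' @return A transformed `ExpressionMatrix`; the fitted `lambda` is attached
#'   as attribute `"vst_lambda"` (`0` for plain log2).
#' @export
vst_transform <- function(matrix, method = c("vst", "log2")) {
  method <- match.arg(method)
  if (matrix$scale != "raw-intensity")
    stop2("vst_transform expects a raw-intensity matrix")
  x <- matrix$values
  if (any(x <= 0)) stop2("non-positive intensities")
  lambda <- 0
  if (method == "vst") {
    if (nrow(x) < 8) stop2("need >= 8 genes to fit the mean-variance trend")
    mu <- rowMeans(x)
    v <- apply(x, 1, var)
    fit <- fit_meanvar_trend(mu, v)
    if (is.null(fit)) {
      warning("mean-variance trend fit failed; falling back to log2")
    } else {
      lambda <- max(fit["a"], 0) / fit["b"]
    }
  }
  out <- if (lambda > 0) log2(x + sqrt(x^2 + lambda)) - 1 else log2(x)
  res <- expression_matrix(out, matrix$samples, scale = "transformed")
  attr(res, "vst_lambda") <- lambda
  res
}

# Trimmed least-squares fit of var = a + b * mean^2, performed on the
# rescaled response var/mean^2 against 1/mean^2 so every gene carries
# comparable weight. Returns c(a=, b=) or NULL on failure.
fit_meanvar_trend <- function(mu, v, trim_sd = 3, rounds = 2) {
  y <- v / mu^2
  x <- 1 / mu^2
  keep <- is.finite(y) & is.finite(x)
  for (i in seq_len(rounds + 1)) {
    fit <- tryCatch(lm(y ~ x, subset = keep), error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(coef(fit)))) return(NULL)
    if (i > rounds) break
    res <- y - coef(fit)[1] - coef(fit)[2] * x
    keep <- keep & abs(res - median(res[keep])) <=
      trim_sd * stats::mad(res[keep])
  }
  cf <- coef(fit)
  if (cf[1] <= 0) return(NULL)
  c(a = unname(cf[2]), b = unname(cf[1]))
}

#' Robust spline normalization across samples
#'
#' Maps each sample through a monotone smooth function onto the quantiles of
#' a reference pseudo-sample (the per-gene mean array): at a grid of
#' probability points, sample quantiles are matched to reference quantiles
#' and a monotone cubic (Hyman-filtered) spline interpolates between them.
#' Within-sample ranks are preserved exactly; after normalization the
#' per-sample quantile curves agree up to spline smoothing error.
#'
#' @param matrix A transformed `ExpressionMatrix` with >= 2 samples.
#' @param n_knots Number of quantile knots for the spline (default 101,
#'   capped at the number of genes).
#' @return The normalized `ExpressionMatrix`.
#' @export
rsn_normalize <- function(matrix, n_knots = 101) {
  x <- matrix$values
  if (ncol(x) < 2) stop2("need >= 2 samples to normalize")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop2("constant sample (zero variance): ",
          paste(colnames(x)[sds == 0], collapse = ", "))
  ref <- rowMeans(x)
  p <- seq(0, 1, length.out = min(n_knots, nrow(x)))
  yq <- quantile(ref, p, names = FALSE, type = 7)
  out <- x
  for (j in seq_len(ncol(x))) {
    xq <- quantile(x[, j], p, names = FALSE, type = 7)
    # collapse tied knots so the interpolant's abscissae strictly increase
    keep <- !duplicated(xq)
    xk <- xq[keep]
    yk <- vapply(split(yq, cumsum(keep)), mean, numeric(1))
    if (length(xk) < 2) stop2("degenerate quantile grid for sample ",
                              colnames(x)[j])
    # hyman needs strictly monotone ordinates; fall back to monotone linear
    # interpolation when reference knots tie
    f <- if (all(diff(yk) > 0)) splinefun(xk, yk, method = "hyman")
         else stats::approxfun(xk, yk, rule = 2, ties = "ordered")
    out[, j] <- f(x[, j])
  }
  expression_matrix(out, matrix$samples, scale = "transformed")
}
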