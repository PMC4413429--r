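#' Estimate empirical-Bayes variance-moderation hyperparameters
#'
#' Under the standard hierarchical model, gene-wise residual variances
#' `s2_g` given the true variance follow a scaled chi-square with `d_g`
#' degrees of freedom, and true variances follow a scaled inverse-chi-square
#' prior with `d0` degrees of freedom and scale `s0sq`. The hyperparameters
#' are estimated by moment matching on the log scale: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`,
#' `var(e)` exceeds `trigamma(d_g/2)` by `trigamma(d0/2)`, so `d0` solves
#' `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))` (monotone
#' root-finding: bisection on a geometrically widened bracket, tolerance
#' 1e-10) and `s0sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the
#' excess is non-positive there is no detectable spread in the true
#' variances: `d0` is the `Inf` sentinel and `s0sq` is the geometric mean of
#' the `s2_g`.
#'
#' @param matrix A transformed `ExpressionMatrix`.
#' @param design Optional character vector of genotypes per sample; defaults
#'   to `matrix$samples$genotype`.
#' @return An object of class `ModerationFit`: list with `d0`, `s0sq`,
#'   `df_residual` (common per-gene residual df), `converged`.
#' @export
fit_moderation <- function(matrix, design = NULL) {
  design <- design %||% matrix$samples$genotype
  x <- matrix$values
  if (nrow(x) < 8) stop2("need >= 8 genes for stable moment estimates")
  groups <- unique(design)
  if (length(groups) != 2) stop2("design must have exactly 2 groups")
  n1 <- sum(design == groups[1]); n2 <- sum(design == groups[2])
  if (n1 < 2 || n2 < 2) stop2("need >= 2 samples per group")
  s2 <- gene_residual_var(x, design, groups)
  dg <- n1 + n2 - 2
  ok <- s2 > 0
  if (!all(ok)) warning(sum(!ok), " gene(s) with zero residual variance ",
                        "excluded from hyperparameter estimation")
  fit <- fit_fdist_moments(s2[ok], dg)
  structure(list(d0 = fit$d0, s0sq = fit$s0sq, df_residual = dg,
                 converged = fit$converged),
            class = "ModerationFit")
}

# Per-gene pooled residual variance for the two-group design.
gene_residual_var <- function(x, design, groups) {
  i1 <- design == groups[1]; i2 <- design == groups[2]
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  ss <- rowSums((x[, i1, drop = FALSE] - m1)^2) +
    rowSums((x[, i2, drop = FALSE] - m2)^2)
  ss / (n1 + n2 - 2)
}

# Moment estimator for the variance prior; dg is the common residual df.
fit_fdist_moments <- function(s2, dg) {
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  evar <- var(e) - trigamma(dg / 2)
  if (!is.finite(evar) || evar <= 0) {
    # no excess spread: point-mass prior (d0 = Inf); geometric mean scale
    return(list(d0 = Inf, s0sq = exp(mean(log(s2))), converged = TRUE))
  }
  half_d0 <- trigamma_inverse(evar)
  d0 <- 2 * half_d0
  list(d0 = d0, s0sq = exp(mean(e) + digamma(half_d0) - log(half_d0)),
       converged = TRUE)
}

# Solve trigamma(x) = y for x > 0 by bisection on a geometrically widened
# bracket; trigamma is strictly decreasing. Tolerance 1e-10 on x.
trigamma_inverse <- function(y) {
  lo <- 1e-8; hi <- 1
  while (trigamma(hi) > y) hi <- hi * 2
  while (trigamma(lo) < y) lo <- lo / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  (lo + hi) / 2
}

#' @export
print.ModerationFit <- function(x, ...) {
  cat(sprintf("ModerationFit: d0 = %s, s0sq = %.6g, residual df = %d\n",
              format(x$d0), x$s0sq, x$df_residual))
  invisible(x)
}

#' Moderated two-group t-test
#'
#' For each gene, the posterior variance shrinks the observed residual
#' variance toward the prior scale,
#' `s2_post = (d0 * s0sq + d_g * s2_g) / (d0 + d_g)`, and the moderated
#' statistic is `t = log2FC / sqrt(s2_post * (1/n_WT + 1/n_KO))` with
#' two-sided p-values from a t distribution on `d0 + d_g` degrees of freedom
#' (standard normal when `d0 = Inf`; `d0 = 0` reduces to the ordinary
#' pooled-variance t). Benjamini-Hochberg adjustment is applied across all
#' genes in the comparison. The log2 fold change is KO minus WT on the
#' transformed scale.
#'
#' @param matrix A transformed `ExpressionMatrix`.
#' @param fit A `ModerationFit` (or `NULL` to fit one first).
#' @param design Optional genotype vector; defaults to sample metadata.
#' @return An object of class `DEResult`: list with `table` (a `data.frame`
#'   with `gene_id`, `log2fc`, `mean_expr`, `s2`, `s2_post`, `t_mod`, `df`,
#'   `p_value`, `p_adj`, `flagged`), `fit`, and `thresholds` (empty until
#'   [filter_de()] is applied).
#' @export
moderated_t_test <- function(matrix, fit = NULL, design = NULL) {
  design <- design %||% matrix$samples$genotype
  if (is.null(fit)) fit <- fit_moderation(matrix, design)
  x <- matrix$values
  iw <- design == "WT"; ik <- design == "KO"
  if (!any(iw) || !any(ik)) stop2("design must contain both WT and KO")
  n1 <- sum(iw); n2 <- sum(ik)
  mw <- rowMeans(x[, iw, drop = FALSE]); mk <- rowMeans(x[, ik, drop = FALSE])
  lfc <- mk - mw
  s2 <- gene_residual_var(x, design, c("WT", "KO"))
  dg <- n1 + n2 - 2
  d0 <- fit$d0
  s2_post <- if (is.infinite(d0)) rep(fit$s0sq, length(s2)) else
    (d0 * fit$s0sq + dg * s2) / (d0 + dg)
  v <- 1 / n1 + 1 / n2
  se <- sqrt(s2_post * v)
  flagged <- se == 0
  tmod <- ifelse(flagged, 0, lfc / ifelse(se == 0, 1, se))
  df_total <- d0 + dg
  p <- if (is.infinite(d0)) 2 * pnorm(-abs(tmod)) else
    2 * pt(-abs(tmod), df = df_total)
  p[flagged] <- 1
  tab <- data.frame(gene_id = rownames(x), log2fc = lfc,
                    mean_expr = (mw * n1 + mk * n2) / (n1 + n2),
                    s2 = s2, s2_post = s2_post, t_mod = tmod,
                    df = df_total, p_value = p,
                    p_adj = p.adjust(p, method = "BH"),
                    flagged = flagged, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, fit = fit, thresholds = NULL),
            class = "DEResult")
}

#' @export
print.DEResult <- function(x, ...) {
  cat(sprintf("DEResult: %d genes", nrow(x$table)))
  if (!is.null(x$table$call))
    cat(sprintf(" (%d down, %d up)", sum(x$table$call == "down"),
                sum(x$table$call == "up")))
  cat("\n")
  invisible(x)
}

#' Fold-change and p-value filtering of DE results
#'
#' A gene is called `down` iff `log2fc <= -log2(fc_threshold)` (boundary
#' inclusive) and its p-value (raw or BH-adjusted per `p_mode`) is strictly
#' below `p_threshold`; `up` symmetrically; otherwise `unchanged`.
#'
#' @param result A `DEResult` from [moderated_t_test()].
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 2, i.e. twofold).
#' @param p_threshold P-value threshold (default 0.05, exclusive).
#' @param p_mode `"raw"` (default) or `"adjusted"`.
#' @return The `DEResult` with a `call` column and recorded `thresholds`.
#' @export
filter_de <- function(result, fc_threshold = 2, p_threshold = 0.05,
                      p_mode = c("raw", "adjusted")) {
  p_mode <- match.arg(p_mode)
  if (fc_threshold <= 0 || p_threshold <= 0) stop2("thresholds must be > 0")
  tab <- result$table
  p <- if (p_mode == "raw") tab$p_value else tab$p_adj
  lfc_cut <- log2(fc_threshold)
  call <- rep("unchanged", nrow(tab))
  call[tab$log2fc <= -lfc_cut & p < p_threshold] <- "down"
  call[tab$log2fc >= lfc_cut & p < p_threshold] <- "up"
  tab$call <- call
  result$table <- tab
  result$thresholds <- list(fc_threshold = fc_threshold,
                            p_threshold = p_threshold, p_mode = p_mode)
  result
}
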