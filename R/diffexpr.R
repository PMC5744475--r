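#' Remove control probesets from an expression matrix
#'
#' Drops rows whose id starts with the control prefix (case-sensitive),
#' preserving the order of the remaining rows.
#'
#' @param matrix Numeric matrix with gene ids as rownames.
#' @param control_prefix Prefix marking control rows (default "AFFX").
#' @return The matrix without control rows.
#' @export
remove_controls <- function(matrix, control_prefix = "AFFX") {
  if (!nzchar(control_prefix)) stopf("control_prefix must be non-empty")
  keep <- !startsWith(rownames(matrix), control_prefix)
  if (!any(keep)) stopf("removing controls would drop every row")
  matrix[keep, , drop = FALSE]
}

#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample onto a common distribution: each column's sorted
#' values are replaced by the across-sample mean of sorted values; within-
#' sample ranks are preserved, and tied values receive the mean of the tied
#' target positions.
#'
#' @param matrix Numeric matrix, genes in rows, samples in columns (>= 2).
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2L) stopf("quantile normalization needs >= 2 samples")
  if (any(is.na(matrix))) stopf("matrix contains NA/NaN values")
  target <- rowMeans(apply(matrix, 2L, sort))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    x <- matrix[, j]
    assigned <- numeric(length(x))
    assigned[order(x)] <- target
    out[, j] <- stats::ave(assigned, x, FUN = mean)
  }
  out
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; used for moment-matching the variance prior.
trigamma_inverse <- function(x) {
  out <- x
  pos <- is.finite(x) & x > 0
  out[!pos & !is.na(x)] <- Inf
  y <- 0.5 + 1 / x[pos]
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x[pos]) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  out[pos] <- y
  out
}

# Moment-match a scaled-F distribution to observed sample variances with df
# residual degrees of freedom, returning the prior df d0 and prior variance
# s0^2. Follows the classic empirical-Bayes log-variance moment equations.
fit_variance_prior <- function(s2, df, prior_df = NULL) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stopf("all gene variances are zero; cannot fit a prior")
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  if (!is.null(prior_df)) {
    d0 <- prior_df
    s02 <- if (is.infinite(d0)) exp(emean)
           else if (d0 > 0) exp(emean + digamma(d0 / 2) - log(d0 / 2))
           else NA_real_
    return(list(df_prior = d0, var_prior = s02))
  }
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    list(df_prior = Inf, var_prior = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    list(df_prior = d0, var_prior = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Empirical-Bayes moderated t-test for a two-group contrast
#'
#' Per-gene log2 fold change (group A minus group B: "up in AvsB" means up-
#' regulated in A) tested with a variance-shrunk t-statistic. The pooled
#' per-gene variance \eqn{s_g^2} (with \eqn{d_g = n_A + n_B - 2} df) is
#' shrunk toward a prior: \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2) /
#' (d_0 + d_g)}, with \eqn{d_0, s_0^2} estimated by moment matching of the
#' scaled-F distribution of sample variances unless supplied. P-values come
#' from the t distribution with \eqn{d_g + d_0} degrees of freedom and are
#' Benjamini-Hochberg adjusted.
#'
#' @param matrix Numeric log2 matrix, genes in rows.
#' @param metadata data.frame with columns \code{sample} and \code{group}
#'   matching the matrix columns.
#' @param group_a,group_b Group labels to contrast (logFC = A - B).
#' @param prior_df Prior degrees of freedom \eqn{d_0}: \code{NULL} (default)
#'   to estimate, \code{0} for the ordinary pooled t-test, \code{Inf} for a
#'   fully shared variance.
#' @param alpha FDR threshold for the significance flag (default 0.05).
#' @return A \code{de_result} data.frame with columns gene_id, logFC, t, p,
#'   p_adj, significant; the estimated \code{df_prior} and \code{var_prior}
#'   are attached as attributes.
#' @export
moderated_t_contrast <- function(matrix, metadata, group_a, group_b,
                                 prior_df = NULL, alpha = 0.05) {
  if (group_a == group_b) stopf("contrast groups must differ")
  idx <- match(colnames(matrix), metadata$sample)
  if (anyNA(idx)) stopf("matrix columns missing from metadata")
  grp <- metadata$group[idx]
  a <- which(grp == group_a)
  b <- which(grp == group_b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("each contrast group needs >= 2 replicates (got %d and %d)",
          length(a), length(b))
  na <- length(a); nb <- length(b)
  ma <- rowMeans(matrix[, a, drop = FALSE])
  mb <- rowMeans(matrix[, b, drop = FALSE])
  va <- apply(matrix[, a, drop = FALSE], 1L, stats::var)
  vb <- apply(matrix[, b, drop = FALSE], 1L, stats::var)
  s2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  if (all(s2 == 0)) stopf("zero variance for every gene")
  dg <- na + nb - 2
  prior <- fit_variance_prior(s2, dg, prior_df)
  d0 <- prior$df_prior
  s2_tilde <- if (is.infinite(d0)) rep(prior$var_prior, length(s2))
              else if (d0 == 0) s2
              else (d0 * prior$var_prior + dg * s2) / (d0 + dg)
  logfc <- ma - mb
  tstat <- logfc / sqrt(s2_tilde * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(tstat), df = dg + d0)
  p_adj <- adjust_bh(p)
  res <- data.frame(gene_id = rownames(matrix), logFC = logfc, t = tstat,
                    p = p, p_adj = p_adj, significant = p_adj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(res, contrast = paste0(group_a, "vs", group_b),
            df_prior = d0, var_prior = prior$var_prior,
            df_residual = dg, alpha = alpha,
            class = c("de_result", "data.frame"))
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Moderated-t contrast %s: %d genes, %d significant at FDR %g\n",
              attr(x, "contrast"), nrow(x), sum(x$significant),
              attr(x, "alpha")))
  cat(sprintf("  prior df = %.3g, prior variance = %.4g\n",
              attr(x, "df_prior"), attr(x, "var_prior")))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  sets <- classify_de(object)
  out <- list(contrast = attr(object, "contrast"),
              n_genes = nrow(object),
              n_up = length(sets$up), n_down = length(sets$down),
              skewness_all = skewness_g1(object$logFC),
              df_prior = attr(object, "df_prior"),
              alpha = attr(object, "alpha"))
  sig <- object$logFC[object$significant]
  out$skewness_significant <- if (length(sig) >= 3L && stats::sd(sig) > 0)
    skewness_g1(sig) else NA_real_
  class(out) <- "summary.de_result"
  out
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("Contrast %s: %d up / %d down of %d genes (FDR < %g)\n",
              x$contrast, x$n_up, x$n_down, x$n_genes, x$alpha))
  cat(sprintf("  logFC skewness G1: all genes %.3f, significant %.3f\n",
              x$skewness_all, x$skewness_significant))
  invisible(x)
}

#' MA-style plot of a contrast
#'
#' @param x A \code{de_result}.
#' @param ... Passed to \code{plot}.
#' @export
plot.de_result <- function(x, ...) {
  graphics::plot(x$logFC, -log10(x$p), pch = 20, cex = 0.4,
                 col = ifelse(x$significant, "darkorange", "grey60"),
                 xlab = "log2 fold change (A - B)", ylab = "-log10 p",
                 main = attr(x, "contrast"), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; values are validated to lie in [0, 1].
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_bh <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Split a contrast into up- and down-regulated gene sets
#'
#' @param result A \code{de_result}.
#' @param alpha FDR threshold (default 0.05).
#' @return A \code{\link{gene_set_pair}}; significant genes with logFC
#'   exactly 0 (if any) are excluded with a message.
#' @export
classify_de <- function(result, alpha = 0.05) {
  sig <- result$p_adj < alpha
  zero <- sig & result$logFC == 0
  if (any(zero))
    message(sum(zero), " significant gene(s) with logFC = 0 excluded")
  gene_set_pair(up = result$gene_id[sig & result$logFC > 0],
                down = result$gene_id[sig & result$logFC < 0])
}

#' Adjusted Fisher-Pearson standardized moment coefficient of skewness
#'
#' \eqn{G_1 = \frac{n}{(n-1)(n-2)} \sum_i ((x_i - \bar x)/s)^3} with the
#' sample (n-1) standard deviation. Negative values indicate a distribution
#' skewed toward down-regulation when applied to logFC vectors.
#'
#' @param logfcs Numeric vector, length >= 3, with positive spread.
#' @return The G1 skewness coefficient.
#' @export
skewness_g1 <- function(logfcs) {
  n <- length(logfcs)
  if (n < 3L) stopf("skewness needs at least 3 values")
  s <- stats::sd(logfcs)
  if (!is.finite(s) || s == 0) stopf("skewness undefined for zero variance")
  n / ((n - 1) * (n - 2)) * sum(((logfcs - mean(logfcs)) / s)^3)
}
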