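#' Screen qPCR amplification efficiencies
#'
#' Efficiency is derived from the dilution-curve slope as
#' \eqn{E = 10^{-1/slope} - 1} (slope of Ct against log10 template amount;
#' -3.32 corresponds to perfect doubling, E = 1). A gene fails if its
#' efficiency deviates from 100\% by more than 10 percentage points, and the
#' whole panel fails the spread check if the efficiencies are not within 10
#' points of each other.
#'
#' @param curves Named list, one entry per gene: either a single numeric
#'   slope, or a data.frame with columns \code{dilution} (relative template
#'   amount) and \code{ct} from which the slope is fit by least squares
#'   (>= 3 points).
#' @param tol Allowed deviation and spread (default 0.10).
#' @return Data.frame with columns gene, slope, efficiency, pass_individual,
#'   pass_spread, pass.
#' @export
check_efficiencies <- function(curves, tol = 0.10) {
  slopes <- vapply(names(curves), function(g) {
    cv <- curves[[g]]
    if (is.numeric(cv) && length(cv) == 1L) return(as.numeric(cv))
    if (!is.data.frame(cv) || nrow(cv) < 3L)
      stopf("dilution curve for %s needs >= 3 points", g)
    x <- log10(cv$dilution)
    if (stats::sd(x) == 0) stopf("singular dilution curve for %s", g)
    unname(stats::coef(stats::lm(cv$ct ~ x))[2L])
  }, numeric(1L))
  eff <- 10^(-1 / slopes) - 1
  pass_ind <- abs(eff - 1) <= tol
  pass_spread <- (max(eff) - min(eff)) <= tol
  data.frame(gene = names(curves), slope = slopes, efficiency = eff,
             pass_individual = pass_ind, pass_spread = pass_spread,
             pass = pass_ind & pass_spread,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Delta-delta-Ct relative quantification
#'
#' Per replicate sample, \eqn{\Delta Ct = Ct_{target} - Ct_{reference}};
#' \eqn{\Delta\Delta Ct} subtracts the calibrator condition's mean
#' \eqn{\Delta Ct}, and the relative quantity is \eqn{RQ = 2^{-\Delta\Delta
#' Ct}} (amplification efficiency taken as exactly 2, justified by the
#' efficiency screen). Condition means are computed on the
#' \eqn{\Delta\Delta Ct} scale, so the calibrator's mean RQ is exactly 1.
#'
#' @param table A \code{\link{ct_table}}.
#' @param target Target gene id (must differ from the reference gene).
#' @return A \code{relative_expression} data.frame with columns condition,
#'   rq_mean, rq_sd, n; per-replicate RQs are attached as the
#'   \code{"replicates"} attribute (named list by condition).
#' @export
delta_delta_ct <- function(table, target) {
  stopifnot(inherits(table, "ct_table"))
  ref <- attr(table, "reference_gene")
  cal <- attr(table, "calibrator")
  if (target == ref) stopf("target must differ from the reference gene")
  tg <- table[table$gene == target, , drop = FALSE]
  if (!nrow(tg)) stopf("target gene '%s' absent from Ct table", target)
  rf <- table[table$gene == ref, , drop = FALSE]
  ref_ct <- rf$ct[match(tg$sample, rf$sample)]
  if (anyNA(ref_ct))
    stopf("reference Ct missing for sample(s): %s",
          paste(unique(tg$sample[is.na(ref_ct)]), collapse = ", "))
  d_ct <- tg$ct - ref_ct
  cal_mean <- mean(d_ct[tg$condition == cal])
  dd_ct <- d_ct - cal_mean
  rq <- 2^(-dd_ct)
  conds <- unique(tg$condition)
  reps <- split(rq, factor(tg$condition, levels = conds))
  out <- data.frame(
    condition = conds,
    rq_mean = vapply(split(dd_ct, factor(tg$condition, levels = conds)),
                     function(v) 2^(-mean(v)), numeric(1L)),
    rq_sd = vapply(reps, stats::sd, numeric(1L)),
    n = vapply(reps, length, integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, target = target, reference_gene = ref, calibrator = cal,
            replicates = reps,
            class = c("relative_expression", "data.frame"))
}

#' @export
print.relative_expression <- function(x, ...) {
  cat(sprintf("ddCt relative expression of %s (reference %s, calibrator %s)\n",
              attr(x, "target"), attr(x, "reference_gene"),
              attr(x, "calibrator")))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Pairwise Welch t-tests with Holm correction
#'
#' All pairwise comparisons between condition groups of RQ replicates, using
#' Welch's two-sample t-test and Bonferroni-Holm step-down adjustment.
#'
#' @param groups Named list of numeric replicate vectors (>= 2 each), or a
#'   \code{relative_expression} object (its per-replicate RQs are used).
#' @param alpha Significance threshold on adjusted p (default 0.07).
#' @return Data.frame with columns group1, group2, p, p_adj, significant.
#' @export
pairwise_holm <- function(groups, alpha = 0.07) {
  if (inherits(groups, "relative_expression"))
    groups <- attr(groups, "replicates")
  if (any(vapply(groups, length, 1L) < 2L))
    stopf("every condition needs >= 2 replicates")
  nms <- names(groups)
  pairs <- utils::combn(nms, 2L)
  p <- apply(pairs, 2L, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      stopf("degenerate (zero) variance in both groups %s and %s",
            pr[1], pr[2])
    stats::t.test(x, y)$p.value
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p = p,
             p_adj = stats::p.adjust(p, method = "holm"),
             significant = stats::p.adjust(p, method = "holm") < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
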