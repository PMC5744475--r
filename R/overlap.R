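#' Construct an up/down gene-set pair
#'
#' @param up,down Character vectors of gene ids; must be disjoint.
#' @return A \code{gene_set_pair}.
#' @export
gene_set_pair <- function(up = character(0), down = character(0)) {
  up <- unique(as.character(up)); down <- unique(as.character(down))
  if (length(intersect(up, down)))
    stopf("up and down sets must be disjoint")
  structure(list(up = up, down = down), class = "gene_set_pair")
}

#' @export
print.gene_set_pair <- function(x, ...) {
  cat(sprintf("Gene set pair: %d up, %d down\n",
              length(x$up), length(x$down)))
  invisible(x)
}

#' Direction-aware overlap between two regulated datasets
#'
#' Shared genes must agree in direction; genes regulated in opposite
#' directions are reported as discordant. Percentages are relative to dataset
#' A's direction totals and rounded half-away-from-zero to integers.
#'
#' @param a,b \code{\link{gene_set_pair}} objects.
#' @return An \code{overlap_result} list with \code{shared_up},
#'   \code{shared_down}, \code{discordant}, \code{frac_up_a},
#'   \code{frac_down_a}.
#' @export
directional_overlap <- function(a, b) {
  stopifnot(inherits(a, "gene_set_pair"), inherits(b, "gene_set_pair"))
  shared_up <- intersect(a$up, b$up)
  shared_down <- intersect(a$down, b$down)
  discordant <- union(intersect(a$up, b$down), intersect(a$down, b$up))
  pct <- function(k, n) if (n == 0L) 0 else round_half_away(100 * k / n)
  structure(list(shared_up = shared_up, shared_down = shared_down,
                 discordant = discordant,
                 frac_up_a = pct(length(shared_up), length(a$up)),
                 frac_down_a = pct(length(shared_down), length(a$down))),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Directional overlap: %d shared up (%d%% of A-up), %d shared down (%d%% of A-down), %d discordant\n",
    length(x$shared_up), x$frac_up_a, length(x$shared_down), x$frac_down_a,
    length(x$discordant)))
  invisible(x)
}

half_life_vector <- function(table) {
  if (is.data.frame(table)) {
    stats::setNames(as.numeric(table$half_life_h), table$gene_id)
  } else {
    table
  }
}

bin_labels <- function(edges) {
  lo <- c(0, edges[-length(edges)])
  sprintf("%g-%g h", lo, edges)
}

#' Bin genes by mRNA half-life
#'
#' Bins are left-closed/right-open except the last, which is closed:
#' with the default edges, [0,1), [1,3), [3,6), [6,12), [12,24] hours.
#' Half-lives above the top edge map to the top bin; genes absent from the
#' table get "no score".
#'
#' @param genes Character vector of gene ids.
#' @param table Half-life table: named numeric vector (hours) or data.frame
#'   with columns gene_id, half_life_h.
#' @param edges Strictly increasing positive bin edges (default
#'   \code{c(1, 3, 6, 12, 24)}).
#' @return Named character vector: bin label or "no score" per gene.
#' @export
bin_half_lives <- function(genes, table, edges = c(1, 3, 6, 12, 24)) {
  if (any(edges <= 0) || is.unsorted(edges, strictly = TRUE))
    stopf("edges must be strictly increasing and positive")
  h <- half_life_vector(table)[genes]
  labels <- bin_labels(edges)
  idx <- findInterval(h, c(0, edges))         # [0,e1), [e1,e2), ...
  idx <- pmin(idx, length(edges))             # closed top bin; >max -> top
  out <- ifelse(is.na(h), "no score", labels[idx])
  stats::setNames(out, genes)
}

#' Association between mRNA stability and regulation direction
#'
#' For each half-life bin, the fraction of scored up- and down-regulated
#' genes; under decay-driven regulation, up-fractions rise with stability.
#' Coverage records the fraction of queried genes that carry a score.
#'
#' @param sets A \code{\link{gene_set_pair}}.
#' @param table Half-life table (see \code{\link{bin_half_lives}}).
#' @param edges Bin edges in hours.
#' @return A \code{stability_association} data.frame with columns bin, n_up,
#'   n_down, up_fraction, down_fraction; coverage is attached as an
#'   attribute.
#' @export
stability_association <- function(sets, table, edges = c(1, 3, 6, 12, 24)) {
  stopifnot(inherits(sets, "gene_set_pair"))
  up_bin <- bin_half_lives(sets$up, table, edges)
  down_bin <- bin_half_lives(sets$down, table, edges)
  labels <- bin_labels(edges)
  n_up <- as.integer(table(factor(up_bin, levels = labels)))
  n_down <- as.integer(table(factor(down_bin, levels = labels)))
  scored <- sum(n_up) + sum(n_down)
  if (scored == 0L) stopf("no queried gene has a half-life score")
  tot <- n_up + n_down
  out <- data.frame(bin = labels, n_up = n_up, n_down = n_down,
                    up_fraction = ifelse(tot > 0, n_up / tot, NA_real_),
                    down_fraction = ifelse(tot > 0, n_down / tot, NA_real_),
                    stringsAsFactors = FALSE)
  structure(out,
            coverage = scored / (length(sets$up) + length(sets$down)),
            class = c("stability_association", "data.frame"))
}

#' Order genes by decreasing mRNA half-life
#'
#' The heatmap ordering: scored genes sorted from most to least stable, ties
#' broken by id (lexicographic), unscored genes appended in input order.
#'
#' @param genes Character vector of gene ids.
#' @param table Half-life table (see \code{\link{bin_half_lives}}).
#' @return Reordered character vector of the same ids.
#' @export
order_by_half_life <- function(genes, table) {
  h <- half_life_vector(table)[genes]
  scored <- !is.na(h)
  ord <- order(-h[scored], genes[scored])
  c(genes[scored][ord], genes[!scored])
}
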