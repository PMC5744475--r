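#' Term overrepresentation by one-sided Fisher/hypergeometric test
#'
#' For each term, tests whether the query gene set contains more term members
#' than expected from a uniform draw out of the genome: the p-value is the
#' hypergeometric upper tail of the observed-or-more overlap (equivalent to a
#' one-sided Fisher exact test on the 2x2 table). Expected counts are
#' \eqn{|geneset| \cdot |term| / |genome|}; p-values are Benjamini-Hochberg
#' adjusted across terms.
#'
#' @param genes Query gene ids; must be a subset of \code{genome}.
#' @param terms Named list: term id -> member gene ids. Term descriptions may
#'   ride along in a \code{"descriptions"} attribute (as from
#'   \code{\link{read_gmt}}).
#' @param genome Background gene ids (the tested universe).
#' @param p_cut Adjusted-p cutoff for the significance flag (default 0.01).
#' @return An \code{enrichment_result} data.frame with columns term, name,
#'   observed, expected, p, p_adj, significant, ordered by p.
#' @export
fisher_enrichment <- function(genes, terms, genome, p_cut = 0.01) {
  genome <- unique(as.character(genome))
  genes <- unique(as.character(genes))
  if (length(genome) < 2L) stopf("genome must contain >= 2 genes")
  stray <- setdiff(genes, genome)
  if (length(stray))
    stopf("query genes absent from genome: %s",
          paste(utils::head(stray, 5L), collapse = ", "))
  if (!length(terms)) stopf("empty term database")
  desc <- attr(terms, "descriptions") %||%
    stats::setNames(rep("", length(terms)), names(terms))
  N <- length(genome); n <- length(genes)
  rows <- lapply(names(terms), function(tm) {
    members <- intersect(unique(terms[[tm]]), genome)
    if (!length(members))
      stopf("term '%s' has no members in the genome", tm)
    K <- length(members)
    obs <- length(intersect(genes, members))
    data.frame(term = tm, name = unname(desc[tm]), observed = obs,
               expected = n * K / N, p = hypergeom_tail(obs, K, N, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p)
  out$significant <- out$p_adj < p_cut
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, genome_size = N, query_size = n, p_cut = p_cut,
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Overrepresentation: %d terms tested, %d significant (adj p < %g); query %d of %d genes\n",
              nrow(x), sum(x$significant), attr(x, "p_cut"),
              attr(x, "query_size"), attr(x, "genome_size")))
  print.data.frame(utils::head(as.data.frame(x), 8L), digits = 3)
  invisible(x)
}
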