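#' Construct a transcription-factor database
#'
#' @param df data.frame with columns \code{gene_id}, \code{family},
#'   \code{source}.
#' @return A \code{tf_database} data.frame (one row per gene_id x source).
#' @export
tf_database <- function(df) {
  need <- c("gene_id", "family", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("TF database missing column(s): %s",
                          paste(miss, collapse = ", "))
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            class = c("tf_database", "data.frame"))
}

#' Merge transcription-factor databases
#'
#' Takes the union over gene ids (each source contributes some unique
#' entries). When sources disagree on the family label, every label is
#' retained with provenance and the primary label is the one from the
#' highest-priority (earliest-listed) source. Records with missing or empty
#' ids are skipped with a warning.
#'
#' @param sources List of \code{\link{tf_database}} objects, in priority
#'   order.
#' @return A merged \code{tf_database} with columns gene_id, family (primary),
#'   families (all, ";"-joined) and sources (";"-joined).
#' @export
merge_tf_databases <- function(sources) {
  if (!length(sources)) stopf("need at least one source database")
  all_df <- do.call(rbind, lapply(seq_along(sources), function(i) {
    df <- sources[[i]]
    data.frame(gene_id = as.character(df$gene_id),
               family = as.character(df$family),
               source = as.character(df$source),
               priority = i, stringsAsFactors = FALSE)
  }))
  bad <- is.na(all_df$gene_id) | !nzchar(all_df$gene_id)
  if (any(bad)) {
    warning(sum(bad), " record(s) with malformed ids skipped")
    all_df <- all_df[!bad, , drop = FALSE]
  }
  all_df <- all_df[order(all_df$priority), , drop = FALSE]
  merged <- do.call(rbind, lapply(split(all_df, all_df$gene_id), function(d) {
    fams <- unique(d$family)
    data.frame(gene_id = d$gene_id[1L], family = d$family[1L],
               families = paste(fams, collapse = ";"),
               sources = paste(unique(d$source), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  structure(merged[order(merged$gene_id), , drop = FALSE],
            class = c("tf_database", "data.frame"))
}

#' Count transcription-factor families in a gene list (countTFs)
#'
#' Counts the query genes per primary TF family; query genes absent from the
#' database are reported as a residual (non-TF) count, so family counts plus
#' the residual always total the query size.
#'
#' @param genes Character vector of query gene ids.
#' @param db A \code{\link{tf_database}} (merged: one row per id).
#' @return List with \code{counts} (data.frame family, count, decreasing) and
#'   \code{n_non_tf}.
#' @export
count_tf_families <- function(genes, db) {
  genes <- unique(as.character(genes))
  fam <- db$family[match(genes, db$gene_id)]
  hit <- !is.na(fam)
  tab <- sort(table(fam[hit]), decreasing = TRUE)
  counts <- data.frame(family = names(tab), count = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(counts = counts, n_non_tf = sum(!hit))
}

#' Construct TF target sets
#'
#' @param sets Named list (one element per TF) of lists with components
#'   \code{confirmed} and \code{unconfirmed} (character vectors of target
#'   ids); the "all" level is their union.
#' @return A \code{tf_target_sets} object.
#' @export
tf_target_sets <- function(sets) {
  out <- lapply(sets, function(s) {
    conf <- unique(as.character(s$confirmed %||% character(0)))
    unconf <- unique(as.character(s$unconfirmed %||% character(0)))
    list(confirmed = conf, unconfirmed = unconf,
         all = union(conf, unconf))
  })
  structure(out, class = "tf_target_sets")
}

#' TF-target enrichment with minimum-hit cutoff and Yekutieli correction
#'
#' For each transcription factor whose known targets overlap the query in at
#' least \code{min_hits} genes, a one-sided Fisher/hypergeometric
#' overrepresentation p-value is computed and adjusted by the
#' Benjamini-Yekutieli (FDR under dependency) procedure. The hit cutoff
#' guards against spuriously high enrichment for factors with few known
#' targets.
#'
#' @param genes Query gene ids (subset of \code{genome}).
#' @param targets A \code{\link{tf_target_sets}} object.
#' @param genome Background gene ids.
#' @param level Target confidence level: "all", "confirmed" or "unconfirmed".
#' @param min_hits Minimum query-overlap to test a factor (default 5).
#' @param alpha Adjusted-p threshold for the significance flag (default 0.05).
#' @return Data.frame with columns tf, n_targets, hits, expected, p, p_adj,
#'   significant (one row per tested factor, ordered by p).
#' @export
tft_enrichment <- function(genes, targets, genome,
                           level = c("all", "confirmed", "unconfirmed"),
                           min_hits = 5L, alpha = 0.05) {
  level <- match.arg(level)
  stopifnot(inherits(targets, "tf_target_sets"))
  genome <- unique(as.character(genome))
  genes <- unique(as.character(genes))
  stray <- setdiff(genes, genome)
  if (length(stray))
    stopf("query genes absent from genome: %s",
          paste(utils::head(stray, 5L), collapse = ", "))
  N <- length(genome); n <- length(genes)
  rows <- list()
  for (tf in names(targets)) {
    tset <- targets[[tf]][[level]]
    if (length(tset) > N)
      stopf("target set of %s larger than the genome", tf)
    members <- intersect(tset, genome)
    hits <- length(intersect(genes, members))
    if (hits < min_hits) next
    K <- length(members)
    rows[[tf]] <- data.frame(tf = tf, n_targets = K, hits = hits,
                             expected = n * K / N,
                             p = hypergeom_tail(hits, K, N, n),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(tf = character(0), n_targets = integer(0),
                      hits = integer(0), expected = numeric(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BY")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}
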