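#' Read a log2 expression matrix from TSV
#'
#' The first column holds gene identifiers; every remaining column is one
#' sample of log2 intensities. Duplicate gene ids are rejected.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with gene ids as rownames and sample ids as colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stopf("duplicate gene ids in %s", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stopf("non-finite expression values in %s", path)
  rownames(m) <- ids
  m
}

#' Write a log2 expression matrix to TSV
#'
#' @param matrix Numeric matrix, genes in rows.
#' @param path Output path.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns \code{sample}, \code{group}, \code{replicate} and
#' optionally \code{storage_h} (hours of dry storage).
#'
#' @param path Path to a tab-separated file.
#' @return data.frame of sample metadata.
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("metadata missing column(s): %s", paste(miss, collapse = ", "))
  df
}

#' Read a GMT gene-set file
#'
#' Standard GMT layout: one set per line, tab-separated as
#' set name, description, then member ids.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; set descriptions are kept in the
#'   \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stopf("malformed GMT line(s) in %s", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||% rep("", length(sets))
  }
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(nm, d, members) {
    paste(c(nm, d, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a per-transcript half-life table
#'
#' Expects columns \code{gene_id} and \code{half_life_h} (hours). Genes absent
#' from the table have no stability score.
#'
#' @param path Path to a tab-separated file.
#' @return Named numeric vector of half-lives in hours.
#' @export
read_half_life_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "half_life_h") %in% names(df)))
    stopf("half-life table needs columns gene_id, half_life_h")
  h <- stats::setNames(as.numeric(df$half_life_h), df$gene_id)
  if (any(!is.finite(h)) || any(h <= 0)) stopf("half-lives must be positive and finite")
  h
}

#' Read a qPCR Ct table
#'
#' Expects columns \code{sample}, \code{condition}, \code{gene}, \code{ct}.
#'
#' @param path Path to a tab-separated file.
#' @param reference_gene Id of the reference (normalizer) gene.
#' @param calibrator Condition label used as the calibrator.
#' @return A \code{ct_table} data.frame.
#' @export
read_ct_tsv <- function(path, reference_gene, calibrator) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  ct_table(df, reference_gene = reference_gene, calibrator = calibrator)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
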