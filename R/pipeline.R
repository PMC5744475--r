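#' Pipeline configuration
#'
#' Collects the file paths, contrasts and thresholds needed for a full run.
#' All referenced files must exist; thresholds must lie in (0, 1].
#'
#' @param matrix,metadata,annotation Paths to the expression TSV, sample
#'   metadata TSV and annotation TSV.
#' @param taggit_gmt,taggit_keywords Paths to the TAGGIT map (GMT + keyword
#'   sidecar TSV).
#' @param tf_db Path to the TF database TSV (gene_id, family, source).
#' @param tf_targets_gmt Path to TF target sets in GMT; set names carry a
#'   \code{|confirmed} or \code{|unconfirmed} suffix.
#' @param terms_gmt Path to the term database GMT.
#' @param half_life Path to the half-life TSV.
#' @param contrasts Named list of \code{c(group_a, group_b)} pairs.
#' @param de_alpha,enrich_p,tft_alpha Thresholds (defaults 0.05, 0.01, 0.05).
#' @param min_hits TFT minimum-hit cutoff (default 5).
#' @param seed Integer RNG seed, logged and recorded in the report.
#' @param out_dir Output directory (created if missing).
#' @return A \code{pipeline_config}.
#' @export
pipeline_config <- function(matrix, metadata, annotation, taggit_gmt,
                            taggit_keywords, tf_db, tf_targets_gmt, terms_gmt,
                            half_life, contrasts,
                            de_alpha = 0.05, enrich_p = 0.01,
                            tft_alpha = 0.05, min_hits = 5L, seed = 1L,
                            out_dir = tempfile("dryseedr_run_")) {
  paths <- list(matrix = matrix, metadata = metadata, annotation = annotation,
                taggit_gmt = taggit_gmt, taggit_keywords = taggit_keywords,
                tf_db = tf_db, tf_targets_gmt = tf_targets_gmt,
                terms_gmt = terms_gmt, half_life = half_life)
  missing <- names(paths)[!vapply(paths, file.exists, TRUE)]
  if (length(missing))
    stopf("input file(s) missing: %s", paste(missing, collapse = ", "))
  for (th in c(de_alpha, enrich_p, tft_alpha)) {
    if (th <= 0 || th > 1) stopf("thresholds must lie in (0, 1]")
  }
  cfg <- c(paths, list(contrasts = contrasts, de_alpha = de_alpha,
                       enrich_p = enrich_p, tft_alpha = tft_alpha,
                       min_hits = as.integer(min_hits),
                       seed = as.integer(seed), out_dir = out_dir))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds the same fields as \code{\link{pipeline_config}};
#' \code{contrasts} is a mapping from contrast name to a two-element list
#' \code{[group_a, group_b]}. Relative input paths are resolved against the
#' YAML file's directory.
#'
#' @param path Path to a YAML configuration file.
#' @return A \code{\link{pipeline_config}}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(p)
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  file_fields <- c("matrix", "metadata", "annotation", "taggit_gmt",
                   "taggit_keywords", "tf_db", "tf_targets_gmt", "terms_gmt",
                   "half_life")
  args <- lapply(file_fields, function(f) resolve(y[[f]]))
  names(args) <- file_fields
  args$contrasts <- lapply(y$contrasts, function(ct) as.character(unlist(ct)))
  for (f in c("de_alpha", "enrich_p", "tft_alpha", "min_hits", "seed")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$out_dir)) args$out_dir <- resolve(y$out_dir)
  do.call(pipeline_config, args)
}

#' Write a complete synthetic input bundle
#'
#' Generates annotation, expression, gene-set, half-life and Ct inputs from a
#' \code{\link{simulation_config}} and writes them to \code{dir} in the
#' pipeline's file formats. The planted truth is written alongside for
#' recovery checks.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param dir Output directory (created if missing).
#' @return A \code{\link{pipeline_config}} pointing at the written files; the
#'   truth table is attached as the \code{"truth"} attribute.
#' @export
write_synthetic_inputs <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  expr <- generate_expression(config, ann$truth)
  gs <- generate_genesets(config, ann$truth)
  ct <- generate_ct_table(config, ann$truth)

  p <- function(f) file.path(dir, f)
  write_expression_tsv(expr$matrix, p("expression.tsv"))
  write_tsv(expr$metadata, p("metadata.tsv"))
  write_tsv(ann$annotation, p("annotation.tsv"))
  write_taggit_map(gs$taggit_map, p("taggit.gmt"), p("taggit_keywords.tsv"))
  write_tsv(gs$tf_db, p("tf_db.tsv"))
  tft_flat <- list()
  for (tf in names(gs$tf_targets)) {
    tft_flat[[paste0(tf, "|confirmed")]] <- gs$tf_targets[[tf]]$confirmed
    tft_flat[[paste0(tf, "|unconfirmed")]] <- gs$tf_targets[[tf]]$unconfirmed
  }
  write_gmt(tft_flat, p("tf_targets.gmt"),
            descriptions = rep("TF target set", length(tft_flat)))
  write_gmt(gs$term_db, p("terms.gmt"),
            descriptions = names(gs$term_db))
  write_tsv(data.frame(gene_id = names(gs$half_life),
                       half_life_h = unname(gs$half_life),
                       stringsAsFactors = FALSE),
            p("half_life.tsv"))
  write_tsv(as.data.frame(ct), p("ct.tsv"))
  truth_df <- ann$truth
  attr(truth_df, "taggit_route") <- NULL
  write_tsv(truth_df, p("truth.tsv"))

  pc <- pipeline_config(
    matrix = p("expression.tsv"), metadata = p("metadata.tsv"),
    annotation = p("annotation.tsv"), taggit_gmt = p("taggit.gmt"),
    taggit_keywords = p("taggit_keywords.tsv"), tf_db = p("tf_db.tsv"),
    tf_targets_gmt = p("tf_targets.gmt"), terms_gmt = p("terms.gmt"),
    half_life = p("half_life.tsv"), contrasts = config$contrasts,
    seed = config$rng_seed, out_dir = file.path(dir, "out"))
  attr(pc, "truth") <- ann$truth
  attr(pc, "ct_table") <- ct
  pc
}

# Read TF target GMT with |confirmed / |unconfirmed suffixes back into a
# tf_target_sets object.
read_tf_targets_gmt <- function(path) {
  flat <- read_gmt(path)
  base <- sub("\\|(confirmed|unconfirmed)$", "", names(flat))
  level <- ifelse(grepl("\\|confirmed$", names(flat)), "confirmed",
                  ifelse(grepl("\\|unconfirmed$", names(flat)),
                         "unconfirmed", "confirmed"))
  sets <- list()
  for (i in seq_along(flat)) {
    tf <- base[i]
    if (is.null(sets[[tf]])) sets[[tf]] <- list(confirmed = character(0),
                                                unconfirmed = character(0))
    sets[[tf]][[level[i]]] <- union(sets[[tf]][[level[i]]], flat[[i]])
  }
  tf_target_sets(sets)
}

#' Parse a per-timepoint logFC table
#'
#' Reads a tab-separated table whose first column is the gene id, optional
#' second non-numeric column a gene symbol/description, and remaining columns
#' log2 fold changes per timepoint. Missing values are marked by a dash
#' (en-dash or hyphen), "NA" or an empty cell. Each timepoint yields the
#' up- (positive) and down- (negative) regulated gene lists.
#'
#' @param path Path to the TSV.
#' @return Named list (one per timepoint) of \code{\link{gene_set_pair}}
#'   objects; the number of distinct regulated genes across timepoints is
#'   attached as attribute \code{"n_distinct"}.
#' @export
parse_logfc_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  ids <- df[[1L]]
  value_cols <- names(df)[-1L]
  # Drop a leading annotation column (no parsable numbers at all).
  is_missing <- function(x) is.na(x) | x %in% c("–", "-", "NA", "")
  parse_col <- function(x) {
    x <- trimws(x)
    x[is_missing(x)] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  parsed <- lapply(df[value_cols], parse_col)
  numericish <- vapply(seq_along(value_cols), function(j) {
    any(!is.na(parsed[[j]]))
  }, TRUE)
  if (length(value_cols) >= 2L && !numericish[1L] &&
      all(is.na(parsed[[1L]]))) {
    # second column is a symbol column only if nothing in it parses
    raw <- trimws(df[[value_cols[1L]]])
    if (any(!is_missing(raw))) {
      value_cols <- value_cols[-1L]
      parsed <- parsed[value_cols]
    }
  }
  out <- list()
  used <- character(0)
  for (tp in value_cols) {
    raw <- trimws(df[[tp]])
    vals <- parsed[[tp]]
    bad <- is.na(vals) & !is_missing(raw)
    if (any(bad))
      stopf("unparseable value '%s' in column '%s', row %d (gene %s)",
            raw[which(bad)[1L]], tp, which(bad)[1L], ids[which(bad)[1L]])
    out[[tp]] <- gene_set_pair(up = ids[!is.na(vals) & vals > 0],
                               down = ids[!is.na(vals) & vals < 0])
    used <- union(used, ids[!is.na(vals)])
  }
  attr(out, "n_distinct") <- length(used)
  out
}

#' Run the full dry-seed analysis pipeline
#'
#' Preprocess (control-probe removal, quantile normalization), fit every
#' configured contrast with the moderated t-test, derive up/down gene sets
#' and logFC skewness, profile the sets over TAGGIT categories, count TF
#' families, test TF-target and term overrepresentation, compute the
#' direction-aware overlap between the first two contrasts and the
#' half-life/stability association, and write all stage outputs plus a JSON
#' report. Reruns with an identical configuration are bitwise identical.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param verbose Log stage progress?
#' @return A \code{dryseed_report} (invisibly the same list written as JSON).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]

  say("reading inputs")
  mat <- read_expression_tsv(config$matrix)
  meta <- read_metadata_tsv(config$metadata)
  ann <- utils::read.delim(config$annotation, stringsAsFactors = FALSE)
  map <- read_taggit_map(config$taggit_gmt, config$taggit_keywords)
  tfdb <- tf_database(utils::read.delim(config$tf_db,
                                        stringsAsFactors = FALSE))
  tft <- read_tf_targets_gmt(config$tf_targets_gmt)
  terms <- read_gmt(config$terms_gmt)
  half_life <- read_half_life_tsv(config$half_life)

  say("preprocessing")
  mat <- remove_controls(mat)
  mat <- quantile_normalize(mat)
  genome <- rownames(mat)

  per_contrast <- list()
  set_pairs <- list()
  for (nm in names(config$contrasts)) {
    ct <- config$contrasts[[nm]]
    say("contrast %s", nm)
    de <- moderated_t_contrast(mat, meta, ct[1], ct[2],
                               alpha = config$de_alpha)
    write_tsv(as.data.frame(de), file.path(config$out_dir,
                                           paste0("de_", nm, ".tsv")))
    sets <- classify_de(de, config$de_alpha)
    set_pairs[[nm]] <- sets
    prof <- taggit_profile(sets, ann, map)
    write_tsv(as.data.frame(prof),
              file.path(config$out_dir, paste0("taggit_", nm, ".tsv")))
    tf_up <- count_tf_families(sets$up, tfdb)
    tf_down <- count_tf_families(sets$down, tfdb)

    enr <- list()
    tft_res <- list()
    for (dir_nm in c("up", "down")) {
      gset <- sets[[dir_nm]]
      if (!length(gset)) next
      enr[[dir_nm]] <- fisher_enrichment(gset, terms, genome,
                                         p_cut = config$enrich_p)
      write_tsv(as.data.frame(enr[[dir_nm]]),
                file.path(config$out_dir,
                          sprintf("enrichment_%s_%s.tsv", nm, dir_nm)))
      tft_res[[dir_nm]] <- tft_enrichment(gset, tft, genome,
                                          min_hits = config$min_hits,
                                          alpha = config$tft_alpha)
      write_tsv(tft_res[[dir_nm]],
                file.path(config$out_dir,
                          sprintf("tft_%s_%s.tsv", nm, dir_nm)))
    }

    stab <- tryCatch(stability_association(sets, half_life),
                     error = function(e) NULL)
    sig <- de$logFC[de$significant]
    per_contrast[[nm]] <- list(
      n_up = length(sets$up), n_down = length(sets$down),
      skewness_all = skewness_g1(de$logFC),
      skewness_significant = if (length(sig) >= 3L && stats::sd(sig) > 0)
        skewness_g1(sig) else NA_real_,
      taggit = as.data.frame(prof),
      tf_up = tf_up, tf_down = tf_down,
      enrichment_significant = vapply(enr, function(e)
        sum(e$significant), integer(1L)),
      tft_significant = vapply(tft_res, function(e)
        sum(e$significant), integer(1L)),
      stability = if (!is.null(stab))
        list(table = as.data.frame(stab),
             coverage = attr(stab, "coverage")) else NULL)
  }

  overlap <- NULL
  if (length(set_pairs) >= 2L) {
    ov <- directional_overlap(set_pairs[[1L]], set_pairs[[2L]])
    overlap <- list(
      contrasts = names(set_pairs)[1:2],
      n_shared_up = length(ov$shared_up),
      n_shared_down = length(ov$shared_down),
      n_discordant = length(ov$discordant),
      frac_up_a = ov$frac_up_a, frac_down_a = ov$frac_down_a)
  }

  # hash the analytic parameters only, so identical analyses hash equal
  # regardless of where the input files live
  cfg_for_hash <- list(contrasts = config$contrasts,
                       de_alpha = config$de_alpha,
                       enrich_p = config$enrich_p,
                       tft_alpha = config$tft_alpha,
                       min_hits = config$min_hits, seed = config$seed)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_for_hash, tmp, auto_unbox = TRUE)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  report <- list(
    provenance = list(package = "dryseedr",
                      version = as.character(utils::packageVersion("dryseedr")),
                      seed = config$seed, config_hash = cfg_hash),
    n_genes = nrow(mat),
    contrasts = per_contrast,
    overlap = overlap)
  class(report) <- "dryseed_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  say("done in %.1f s", proc.time()[["elapsed"]] - t0)
  report
}

#' @export
print.dryseed_report <- function(x, ...) {
  cat(sprintf("dryseedr pipeline report (seed %d, %d genes)\n",
              x$provenance$seed, x$n_genes))
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat(sprintf("  %s: %d up / %d down, G1(all) = %.3f\n",
                nm, ct$n_up, ct$n_down, ct$skewness_all))
  }
  if (!is.null(x$overlap))
    cat(sprintf("  overlap %s vs %s: %d up (%d%%), %d down (%d%%)\n",
                x$overlap$contrasts[1], x$overlap$contrasts[2],
                x$overlap$n_shared_up, x$overlap$frac_up_a,
                x$overlap$n_shared_down, x$overlap$frac_down_a))
  invisible(x)
}
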