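#' Construct a TAGGIT category map
#'
#' The TAGGIT scheme assigns genes to 26 seed-dormancy/germination categories
#' by AGI id lists combined with description-keyword search. The map carries,
#' per category, the member id list and the lowercase keyword patterns.
#'
#' @param id_lists Named list of 26 character vectors (AGI ids per category).
#' @param keywords Named list of character vectors (keywords per category);
#'   names must match \code{id_lists}.
#' @return A \code{taggit_map}.
#' @export
taggit_map <- function(id_lists, keywords) {
  if (length(id_lists) != 26L)
    stopf("a TAGGIT map must have exactly 26 categories (got %d)",
          length(id_lists))
  nms <- names(id_lists)
  if (is.null(nms) || anyDuplicated(nms))
    stopf("category names must be present and unique")
  if (!setequal(nms, names(keywords)))
    stopf("keyword list must cover the same 26 categories")
  map <- lapply(nms, function(nm) list(
    ids = unique(as.character(id_lists[[nm]])),
    keywords = tolower(as.character(keywords[[nm]]))))
  names(map) <- nms
  structure(map, class = "taggit_map")
}

#' Read a TAGGIT map from GMT plus keyword sidecar
#'
#' @param gmt_path GMT file of the 26 id lists.
#' @param keywords_path TSV with columns \code{category}, \code{keyword}
#'   (one row per keyword).
#' @return A \code{taggit_map}.
#' @export
read_taggit_map <- function(gmt_path, keywords_path) {
  ids <- read_gmt(gmt_path)
  kw <- utils::read.delim(keywords_path, stringsAsFactors = FALSE)
  if (!all(c("category", "keyword") %in% names(kw)))
    stopf("keyword sidecar needs columns category, keyword")
  kw_list <- split(kw$keyword, kw$category)[names(ids)]
  names(kw_list) <- names(ids)
  kw_list[vapply(kw_list, is.null, TRUE)] <- list(character(0))
  taggit_map(ids, kw_list)
}

#' Write a TAGGIT map to GMT plus keyword sidecar
#'
#' @param map A \code{taggit_map}.
#' @param gmt_path,keywords_path Output paths.
#' @export
write_taggit_map <- function(map, gmt_path, keywords_path) {
  write_gmt(lapply(map, `[[`, "ids"), gmt_path,
            descriptions = rep("TAGGIT category", length(map)))
  kw <- do.call(rbind, lapply(names(map), function(nm) {
    k <- map[[nm]]$keywords
    if (!length(k)) return(NULL)
    data.frame(category = nm, keyword = k, stringsAsFactors = FALSE)
  }))
  write_tsv(kw, keywords_path)
  invisible(gmt_path)
}

#' Assign TAGGIT categories to genes
#'
#' A gene receives every category whose id list contains it OR whose keyword
#' occurs (case-insensitive substring; optionally word-bounded) in its
#' annotation description. Genes matching nothing are left with an empty
#' category set ("unclassified"); queried ids missing from the annotation are
#' reported with a message, not an error.
#'
#' @param genes Character vector of gene ids.
#' @param annotation data.frame with columns \code{gene_id},
#'   \code{description}.
#' @param map A \code{\link{taggit_map}}.
#' @param word_boundary Require keyword matches at word boundaries?
#' @return Named list: per gene, the character vector of matched categories.
#' @export
taggit_categorize <- function(genes, annotation, map, word_boundary = FALSE) {
  if (!inherits(map, "taggit_map") || !length(map)) stopf("empty TAGGIT map")
  genes <- unique(as.character(genes))
  desc <- tolower(annotation$description[match(genes, annotation$gene_id)])
  missing <- genes[is.na(desc)]
  if (length(missing))
    message(length(missing), " queried id(s) absent from annotation")
  desc[is.na(desc)] <- ""
  out <- stats::setNames(vector("list", length(genes)), genes)
  for (i in seq_along(genes)) out[[i]] <- character(0)
  for (nm in names(map)) {
    hit <- genes %in% map[[nm]]$ids
    for (k in map[[nm]]$keywords) {
      pat <- if (word_boundary) paste0("\\b", k, "\\b") else k
      hit <- hit | grepl(pat, desc, fixed = !word_boundary)
    }
    for (i in which(hit)) out[[i]] <- union(out[[i]], nm)
  }
  out
}

#' Profile up- and down-regulated gene sets over TAGGIT categories
#'
#' Per category and direction, the count and the percentage of that
#' direction's total gene count (the full direction size, including
#' unclassified genes, is the denominator). Multi-category genes contribute
#' to every matched category.
#'
#' @param sets A \code{\link{gene_set_pair}}.
#' @param annotation Annotation data.frame (gene_id, description).
#' @param map A \code{\link{taggit_map}}.
#' @param word_boundary Passed to \code{\link{taggit_categorize}}.
#' @return A \code{taggit_profile} data.frame with columns category,
#'   up_count, up_pct, down_count, down_pct. Percentages for an empty
#'   direction are NA.
#' @export
taggit_profile <- function(sets, annotation, map, word_boundary = FALSE) {
  stopifnot(inherits(sets, "gene_set_pair"))
  count_dir <- function(genes) {
    cats <- taggit_categorize(genes, annotation, map, word_boundary)
    tab <- table(factor(unlist(cats), levels = names(map)))
    as.integer(tab)
  }
  up_n <- count_dir(sets$up)
  down_n <- count_dir(sets$down)
  prof <- data.frame(
    category = names(map),
    up_count = up_n,
    up_pct = if (length(sets$up)) 100 * up_n / length(sets$up) else NA_real_,
    down_count = down_n,
    down_pct = if (length(sets$down)) 100 * down_n / length(sets$down)
               else NA_real_,
    stringsAsFactors = FALSE)
  structure(prof, n_up = length(sets$up), n_down = length(sets$down),
            class = c("taggit_profile", "data.frame"))
}

#' Horizontal bar plot of a TAGGIT profile
#'
#' @param x A \code{taggit_profile}.
#' @param ... Passed to \code{barplot}.
#' @export
plot.taggit_profile <- function(x, ...) {
  vals <- rbind(up = x$up_pct, down = -x$down_pct)
  graphics::barplot(vals, beside = TRUE, horiz = TRUE,
                    names.arg = x$category, las = 1, cex.names = 0.55,
                    col = c("firebrick", "steelblue"),
                    xlab = "% of direction total", ...)
  invisible(x)
}

#' TAGGIT profile of random gene sets (negative control)
#'
#' Draws disjoint uniform random "up" and "down" sets from the genome and
#' profiles them, checking that category enrichments observed for real
#' datasets could not arise from an unbiased random draw. Defaults mirror
#' the 330-up / 430-down control design.
#'
#' @param n_up,n_down Sizes of the random up and down sets.
#' @param genome Character vector of candidate gene ids.
#' @param map A \code{\link{taggit_map}}.
#' @param annotation Annotation data.frame.
#' @param seed Integer seed for the draw.
#' @return A \code{taggit_profile}.
#' @export
random_control_profile <- function(n_up = 330L, n_down = 430L, genome, map,
                                   annotation, seed = 1L) {
  if (n_up + n_down > length(genome))
    stopf("genome too small for disjoint sets of %d + %d", n_up, n_down)
  with_seed(seed, {
    pick <- sample(genome, n_up + n_down)
    sets <- gene_set_pair(up = pick[seq_len(n_up)],
                          down = pick[n_up + seq_len(n_down)])
    taggit_profile(sets, annotation, map)
  })
}

#' Summarize repeated random-control draws
#'
#' Repeats \code{\link{random_control_profile}} over seeded draws and reports
#' the mean and maximum per-category absolute difference between up- and
#' down-percentages, the quantity that should stay small for an unbiased
#' categorization.
#'
#' @inheritParams random_control_profile
#' @param n_draws Number of draws.
#' @param seed Base seed; draw k uses \code{seed + k - 1}.
#' @return List with \code{mean_abs_diff}, \code{max_abs_diff} (scalars,
#'   percentage points) and the per-draw matrix of |up% - down%|.
#' @export
random_control_summary <- function(n_up = 330L, n_down = 430L, genome, map,
                                   annotation, n_draws = 100L, seed = 1L) {
  diffs <- vapply(seq_len(n_draws), function(k) {
    p <- random_control_profile(n_up, n_down, genome, map, annotation,
                                seed = seed + k - 1L)
    abs(p$up_pct - p$down_pct)
  }, numeric(26L))
  list(mean_abs_diff = mean(diffs), max_abs_diff = max(diffs),
       per_draw = t(diffs))
}
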