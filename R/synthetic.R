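#' Default TAGGIT category names
#'
#' The 26 seed-dormancy/germination categories used by the TAGGIT ontology
#' profiling module, covering the hormone, storage-reserve, translation,
#' transcription and cell-biology themes that dominate dry-seed transcriptomes.
#'
#' @return Character vector of 26 category names.
#' @export
taggit_category_names <- function() {
  c("ABA", "GA", "auxin", "ethylene", "cytokinin", "brassinosteroid",
    "jasmonate", "LEAs", "seed storage proteins", "heat shock proteins",
    "dormancy", "germination", "translation", "transcription",
    "protein degradation", "inhibition of protein degradation",
    "cell wall", "cell cycle", "cytoskeleton", "photosynthesis",
    "respiration", "oxidative stress", "sugar metabolism",
    "lipid metabolism", "secondary metabolism", "signaling")
}

# One indicative description keyword per category; keyword matching is
# case-insensitive substring on description text.
taggit_default_keywords <- function() {
  stats::setNames(list(
    "abscisic acid", "gibberellin", "auxin-responsive", "ethylene-responsive",
    "cytokinin", "brassinosteroid", "jasmonate",
    "late embryogenesis abundant", "seed storage", "heat shock",
    "dormancy-associated", "germination-related", "ribosomal",
    "transcriptional regulator", "ubiquitin-proteasome", "protease inhibitor",
    "cell wall", "cell cycle", "tubulin", "chlorophyll a/b binding",
    "respiratory chain", "oxidative stress", "sucrose metabolic",
    "lipid transfer", "flavonoid biosynthesis", "receptor kinase"),
    taggit_category_names())
}

#' Simulation configuration for an ATH1-like dry-seed experiment
#'
#' Defaults mirror the study design the package targets: a 22,810-row
#' ATH1-style array (22,746 genes plus 64 control probesets), four dry-seed
#' sample groups (wild type, dormant mutant, long after-ripened mutant, and a
#' GID1b-overexpression rescue line) in triplicate, and three contrasts
#' (DvsWT, ARvsD, GIDvsD) with planted differential abundance whose per-
#' contrast fractions and sign imbalances match the published dataset sizes
#' (794, 770 and 7 regulated genes with 65\%, 56\% and 29\% down-regulated).
#'
#' @param n_genes Number of non-control genes.
#' @param groups Named integer vector: replicates per group; the first group
#'   is the baseline with zero expression effect.
#' @param contrasts Named list of \code{c(group_a, group_b)} pairs; logFC is
#'   reported as A minus B ("up in AvsB" = up in A).
#' @param frac_de_per_contrast Fraction of genes planted as differentially
#'   abundant, one value per contrast (recycled).
#' @param pi_down Fraction of planted DE genes that are down-regulated, per
#'   contrast (recycled).
#' @param de_logfc_mean,de_logfc_sd Mean and sd (log2) of planted effect-size
#'   magnitudes; magnitudes are truncated below at 0.25.
#' @param replicate_noise_sd Gaussian replicate noise sd on the log2 scale.
#' @param n_control_probes Number of "AFFX"-prefixed control rows.
#' @param half_life_meanlog,half_life_sdlog Log-normal parameters of mRNA
#'   half-life (hours).
#' @param half_life_coupling Log-scale shift applied to half-lives of genes
#'   planted up (+) or down (-) in the after-ripening contrast, emulating the
#'   stability/regulation association of dry storage.
#' @param half_life_frac_scored Fraction of genes with a half-life score
#'   (external stability studies do not cover every transcript).
#' @param storage_times_h Named numeric vector: hours of dry storage per group.
#' @param tf_frac Fraction of genes encoding transcription (co)factors.
#' @param tf_families Family labels to draw from.
#' @param taggit_prevalence Per-category membership probability.
#' @param n_qpcr_genes Number of target genes in the synthetic Ct table.
#' @param ct_noise_sd Gaussian Ct noise sd (cycles).
#' @param ct_calibrator Condition used as ddCt calibrator.
#' @param rng_seed Integer seed; identical configs give identical outputs.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_genes = 22746L,
                              groups = c(WT = 3L, D = 3L, AR = 3L, GID = 3L),
                              contrasts = list(DvsWT = c("D", "WT"),
                                               ARvsD  = c("AR", "D"),
                                               GIDvsD = c("GID", "D")),
                              frac_de_per_contrast = c(DvsWT = 794, ARvsD = 770,
                                                       GIDvsD = 7) / 22810,
                              pi_down = c(DvsWT = 517 / 794, ARvsD = 430 / 770,
                                          GIDvsD = 2 / 7),
                              de_logfc_mean = 1.5,
                              de_logfc_sd = 0.5,
                              replicate_noise_sd = 0.25,
                              n_control_probes = 64L,
                              half_life_meanlog = log(4),
                              half_life_sdlog = 0.8,
                              half_life_coupling = 0.5,
                              half_life_frac_scored = 0.7,
                              storage_times_h = c(WT = 336, D = 336,
                                                  AR = 13870, GID = 336),
                              tf_frac = 0.06,
                              tf_families = c("AP2-EREBP", "ARF", "bHLH",
                                              "bZIP", "C2H2", "C3H", "GRAS",
                                              "HB", "MADS", "MYB",
                                              "MYB-related", "NAC", "WRKY",
                                              "HSF", "CO-like"),
                              taggit_prevalence = 0.01,
                              n_qpcr_genes = 6L,
                              ct_noise_sd = 0.05,
                              ct_calibrator = "D",
                              rng_seed = 1L) {
  if (length(n_genes) != 1L || !is.finite(n_genes) || n_genes <= 0)
    stopf("n_genes must be a positive count")
  if (is.null(names(groups)) || any(groups < 1))
    stopf("groups must be a named vector of positive replicate counts")
  fr <- rep_len(frac_de_per_contrast, length(contrasts))
  pd <- rep_len(pi_down, length(contrasts))
  if (any(fr < 0 | fr > 1) || any(pd < 0 | pd > 1))
    stopf("fractions must lie in [0, 1]")
  for (ct in contrasts) {
    if (length(ct) != 2L || ct[1] == ct[2] || !all(ct %in% names(groups)))
      stopf("each contrast must name two distinct groups present in 'groups'")
  }
  if (any(storage_times_h < 0)) stopf("storage times must be non-negative")
  cfg <- list(n_genes = as.integer(n_genes), groups = groups,
              contrasts = contrasts,
              frac_de_per_contrast = stats::setNames(fr, names(contrasts)),
              pi_down = stats::setNames(pd, names(contrasts)),
              de_logfc_mean = de_logfc_mean, de_logfc_sd = de_logfc_sd,
              replicate_noise_sd = replicate_noise_sd,
              n_control_probes = as.integer(n_control_probes),
              half_life_meanlog = half_life_meanlog,
              half_life_sdlog = half_life_sdlog,
              half_life_coupling = half_life_coupling,
              half_life_frac_scored = half_life_frac_scored,
              storage_times_h = storage_times_h,
              tf_frac = tf_frac, tf_families = tf_families,
              taggit_prevalence = taggit_prevalence,
              n_qpcr_genes = as.integer(n_qpcr_genes),
              ct_noise_sd = ct_noise_sd, ct_calibrator = ct_calibrator,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "simulation_config"
  cfg
}

# Synthetic AGI-style ids on the reserved chromosome digit 0 so they cannot
# collide with real Arabidopsis loci (At1g-At5g, AtMg, AtCg).
synthetic_gene_ids <- function(n) sprintf("At0g%05d", seq_len(n))
synthetic_control_ids <- function(n) {
  if (n == 0L) character(0) else sprintf("AFFX-Ctrl-%03d", seq_len(n))
}

#' Generate synthetic gene annotation and ground truth
#'
#' Produces an annotation table (AGI-style ids, symbols, description text,
#' control flags) together with an aligned truth table recording, per gene,
#' the planted log2 fold change for every contrast, transcription-factor
#' family, TAGGIT category memberships and mRNA half-life. Category members
#' are wired to be discoverable by the TAGGIT rules: each member is either
#' listed by id in the category map, carries the category keyword in its
#' description, or both.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with elements \code{annotation} (one row per gene plus one per
#'   control probe) and \code{truth} (one row per gene).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  with_seed(config$rng_seed, {
    ids <- synthetic_gene_ids(n)
    cats <- taggit_category_names()
    kw <- taggit_default_keywords()

    # Planted effects per contrast; group effects are chained from these.
    lfc <- matrix(0, n, length(config$contrasts),
                  dimnames = list(ids, names(config$contrasts)))
    for (j in seq_along(config$contrasts)) {
      nm <- names(config$contrasts)[j]
      n_de <- round(config$frac_de_per_contrast[[nm]] * n)
      idx <- sample.int(n, n_de)
      mag <- pmax(0.25, stats::rnorm(n_de, config$de_logfc_mean,
                                     config$de_logfc_sd))
      sign <- ifelse(stats::runif(n_de) < config$pi_down[[nm]], -1, 1)
      lfc[idx, j] <- sign * mag
    }

    # TF family labels.
    tf_family <- rep(NA_character_, n)
    tf_idx <- which(stats::runif(n) < config$tf_frac)
    tf_family[tf_idx] <- sample(config$tf_families, length(tf_idx),
                                replace = TRUE)

    # TAGGIT memberships: independent per category; route decides whether the
    # gene is id-listed, keyword-tagged, or both.
    member <- matrix(stats::runif(n * 26L) < config$taggit_prevalence, n, 26L,
                     dimnames = list(ids, cats))
    route <- matrix(sample(c("id", "keyword", "both"), n * 26L, replace = TRUE,
                           prob = c(0.6, 0.2, 0.2)), n, 26L)
    route[!member] <- ""

    # Half-lives: log-normal hours, shifted by the sign of the planted
    # after-ripening effect when an AR-style contrast exists.
    mu <- rep(config$half_life_meanlog, n)
    ar <- grep("^AR", names(config$contrasts))[1]
    if (!is.na(ar)) mu <- mu + config$half_life_coupling * sign(lfc[, ar])
    half_life <- stats::rlnorm(n, mu, config$half_life_sdlog)
    scored <- stats::runif(n) < config$half_life_frac_scored

    base_desc <- sample(c("expressed protein", "hypothetical protein",
                          "unknown function protein"), n, replace = TRUE)
    desc <- base_desc
    for (j in seq_len(26L)) {
      tag <- route[, j] %in% c("keyword", "both")
      if (any(tag)) desc[tag] <- paste(desc[tag], kw[[j]], sep = "; ")
    }
    is_tf <- !is.na(tf_family)
    desc[is_tf] <- paste(desc[is_tf],
                         sprintf("%s family transcription factor",
                                 tf_family[is_tf]), sep = "; ")

    taggit_categories <- apply(member, 1L, function(m)
      paste(cats[m], collapse = ";"))

    annotation <- data.frame(
      gene_id = c(ids, synthetic_control_ids(config$n_control_probes)),
      symbol = c(sprintf("SYN%05d", seq_len(n)),
                 rep("control", config$n_control_probes)),
      description = c(desc, rep("spike-in control probeset",
                                config$n_control_probes)),
      is_control = rep(c(FALSE, TRUE), c(n, config$n_control_probes)),
      stringsAsFactors = FALSE)

    truth <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
    for (nm in colnames(lfc)) {
      truth[[paste0("logfc_", nm)]] <- lfc[, nm]
      truth[[paste0("is_de_", nm)]] <- lfc[, nm] != 0
    }
    truth$tf_family <- tf_family
    truth$taggit_categories <- taggit_categories
    truth$half_life_h <- half_life
    truth$half_life_scored <- scored
    attr(truth, "taggit_route") <- route
    list(annotation = annotation, truth = truth)
  })
}

# Chain planted contrast effects into additive per-group effects, anchored at
# the first-listed group.
group_effects <- function(config, truth) {
  groups <- names(config$groups)
  n <- nrow(truth)
  eff <- matrix(NA_real_, n, length(groups),
                dimnames = list(truth$gene_id, groups))
  eff[, groups[1]] <- 0
  pending <- config$contrasts
  repeat {
    progressed <- FALSE
    for (nm in names(pending)) {
      a <- pending[[nm]][1]; b <- pending[[nm]][2]
      if (!anyNA(eff[, b]) && anyNA(eff[, a])) {
        eff[, a] <- eff[, b] + truth[[paste0("logfc_", nm)]]
        pending[[nm]] <- NULL
        progressed <- TRUE
      } else if (!anyNA(eff[, b]) && !anyNA(eff[, a])) {
        pending[[nm]] <- NULL
        progressed <- TRUE
      }
    }
    if (!length(pending)) break
    if (!progressed)
      stopf("contrasts do not connect all groups to the baseline group")
  }
  eff
}

#' Generate a synthetic log2 expression matrix
#'
#' Per-gene log2 values are baseline + group effect + i.i.d. Gaussian
#' replicate noise; group effects realize the planted contrast logFCs exactly
#' in the zero-noise limit. Control probes carry baseline and noise only.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param truth Truth table from \code{\link{generate_annotation}}.
#' @return List with \code{matrix} (log2, rows = genes then controls) and
#'   \code{metadata} (sample, group, replicate, storage_h).
#' @export
generate_expression <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(truth) != config$n_genes)
    stopf("truth has %d rows but config expects %d genes",
          nrow(truth), config$n_genes)
  with_seed(config$rng_seed + 1L, {
    eff <- group_effects(config, truth)
    n <- config$n_genes
    nc <- config$n_control_probes
    baseline <- stats::rnorm(n + nc, mean = 7, sd = 1.5)
    samples <- data.frame(
      sample = unlist(lapply(names(config$groups), function(g)
        paste0(g, "_", seq_len(config$groups[[g]])))),
      group = rep(names(config$groups), config$groups),
      replicate = unlist(lapply(config$groups, seq_len)),
      stringsAsFactors = FALSE)
    samples$storage_h <- unname(config$storage_times_h[samples$group])
    m <- matrix(0, n + nc, nrow(samples),
                dimnames = list(c(truth$gene_id, synthetic_control_ids(nc)),
                                samples$sample))
    for (j in seq_len(nrow(samples))) {
      g <- samples$group[j]
      m[, j] <- baseline + c(eff[, g], rep(0, nc)) +
        stats::rnorm(n + nc, 0, config$replicate_noise_sd)
    }
    list(matrix = m, metadata = samples)
  })
}

#' Simulate first-order mRNA decay during dry storage
#'
#' Each transcript decays exponentially with its own half-life:
#' \eqn{N_i(t) = N_i(0) \cdot 2^{-t/h_i}}. With \code{renormalize = TRUE} the
#' decayed abundances are rescaled to the initial total, emulating profiling
#' of apparently equal RNA amounts, under which slowly decaying transcripts
#' appear up-regulated and fast-decaying transcripts down-regulated.
#'
#' @param abundance0 Linear-scale starting abundances (non-negative).
#' @param half_lives Half-lives in hours, one per transcript, all positive.
#' @param t Storage time in hours, non-negative scalar.
#' @param renormalize Rescale so total abundance is conserved?
#' @return Linear-scale abundances after \code{t} hours.
#' @export
simulate_dry_storage_decay <- function(abundance0, half_lives, t,
                                       renormalize = FALSE) {
  if (length(half_lives) != length(abundance0))
    stopf("abundance0 and half_lives must have equal length")
  if (any(!is.finite(half_lives)) || any(half_lives <= 0))
    stopf("all half-lives must be positive")
  if (length(t) != 1L || !is.finite(t) || t < 0)
    stopf("t must be a single non-negative time in hours")
  if (any(abundance0 < 0)) stopf("abundances must be non-negative")
  decayed <- abundance0 * 2^(-t / half_lives)
  if (renormalize && sum(decayed) > 0)
    decayed <- decayed * sum(abundance0) / sum(decayed)
  decayed
}

#' Construct a qPCR Ct table
#'
#' @param df data.frame with columns sample, condition, gene, ct.
#' @param reference_gene Reference (normalizer) gene id.
#' @param calibrator Calibrator condition label.
#' @return A \code{ct_table} data.frame.
#' @export
ct_table <- function(df, reference_gene, calibrator) {
  need <- c("sample", "condition", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("Ct table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(df$ct <= 0)) stopf("Ct values must be positive")
  if (!calibrator %in% df$condition)
    stopf("calibrator condition '%s' absent from Ct table", calibrator)
  if (!reference_gene %in% df$gene)
    stopf("reference gene '%s' absent from Ct table", reference_gene)
  structure(df, reference_gene = reference_gene, calibrator = calibrator,
            class = c("ct_table", "data.frame"))
}

#' Generate a synthetic qPCR Ct table with planted fold changes
#'
#' Target genes are the strongest planted effects of the after-ripening
#' contrast (falling back to the first contrast); the reference gene is a
#' planted non-regulated gene measured in every sample. The target Ct shifts
#' by \eqn{-\log_2(\mathrm{fold})} per planted fold change relative to the
#' calibrator condition, with three replicates per condition.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param truth Truth table from \code{\link{generate_annotation}}.
#' @return A \code{ct_table}; planted per-condition folds for each target are
#'   kept in the \code{"planted_fold"} attribute.
#' @export
generate_ct_table <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$rng_seed + 2L, {
    eff <- group_effects(config, truth)
    ar <- grep("^AR", names(config$contrasts))[1]
    if (is.na(ar)) ar <- 1L
    key <- truth[[paste0("logfc_", names(config$contrasts)[ar])]]
    targets <- truth$gene_id[order(-abs(key))][seq_len(config$n_qpcr_genes)]
    lfc_cols <- grep("^logfc_", names(truth))
    ref <- truth$gene_id[rowSums(abs(truth[, lfc_cols, drop = FALSE])) == 0][1]
    if (is.na(ref)) stopf("no non-regulated gene available as reference")
    conds <- names(config$groups)
    cal <- config$ct_calibrator
    if (!cal %in% conds) cal <- conds[1]
    rows <- list()
    for (g in conds) {
      for (r in 1:3) {
        sample_id <- sprintf("%s_r%d", g, r)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sample_id, condition = g, gene = ref,
          ct = 20 + stats::rnorm(1, 0, config$ct_noise_sd),
          stringsAsFactors = FALSE)
        for (tg in targets) {
          shift <- eff[tg, g] - eff[tg, cal]   # log2 fold vs calibrator
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, condition = g, gene = tg,
            ct = 24 - shift + stats::rnorm(1, 0, config$ct_noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    tab <- ct_table(do.call(rbind, rows), reference_gene = ref,
                    calibrator = cal)
    folds <- 2^(eff[targets, conds, drop = FALSE] -
                  eff[targets, cal])
    attr(tab, "planted_fold") <- folds
    tab
  })
}

#' Generate gene-set resources consistent with the synthetic truth
#'
#' Builds the TAGGIT category map (id lists plus keywords), a merged-style TF
#' database, TF target sets (one planted to be enriched among the first
#' contrast's down-regulated genes, mirroring a master-regulator signal),
#' a term database for overrepresentation testing, and the half-life table
#' restricted to scored genes.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param truth Truth table from \code{\link{generate_annotation}}.
#' @return List with \code{taggit_map}, \code{tf_db}, \code{tf_targets},
#'   \code{term_db}, \code{half_life}.
#' @export
generate_genesets <- function(config, truth) {
  stopifnot(inherits(config, "simulation_config"))
  route <- attr(truth, "taggit_route")
  if (is.null(route)) stopf("truth lacks the taggit_route attribute")
  with_seed(config$rng_seed + 3L, {
    cats <- taggit_category_names()
    ids <- lapply(seq_len(26L), function(j)
      truth$gene_id[route[, j] %in% c("id", "both")])
    map <- taggit_map(stats::setNames(ids, cats), taggit_default_keywords())

    is_tf <- !is.na(truth$tf_family)
    tf_db <- data.frame(gene_id = truth$gene_id[is_tf],
                        family = truth$tf_family[is_tf],
                        source = "synthTFDB",
                        stringsAsFactors = FALSE)

    # TF target sets: ~8 regulators with random targets; the first one is
    # planted to prefer the first contrast's down-regulated genes.
    tf_ids <- utils::head(tf_db$gene_id, 8L)
    down1 <- truth$gene_id[truth[[paste0("logfc_",
                                         names(config$contrasts)[1])]] < 0]
    sets <- list()
    for (i in seq_along(tf_ids)) {
      size <- min(sample(40:120, 1L), max(10L, config$n_genes %/% 4L))
      if (i == 1L && length(down1) >= 20L) {
        n_sig <- min(length(down1), round(0.5 * size))
        rest <- setdiff(truth$gene_id, down1)
        members <- c(sample(down1, n_sig),
                     sample(rest, min(size - n_sig, length(rest))))
      } else {
        members <- sample(truth$gene_id, size)
      }
      conf <- stats::runif(length(members)) < 0.5
      sets[[tf_ids[i]]] <- list(confirmed = members[conf],
                                unconfirmed = members[!conf])
    }
    targets <- tf_target_sets(sets)

    # Term database: each TAGGIT category doubles as a flat term, plus a few
    # random terms.
    term_members <- lapply(seq_len(26L), function(j)
      truth$gene_id[route[, j] != ""])
    names(term_members) <- paste0("TERM:", gsub(" ", "_", cats))
    for (k in 1:4) {
      term_members[[sprintf("TERM:random_%d", k)]] <-
        sample(truth$gene_id, min(sample(50:200, 1L), config$n_genes %/% 2L))
    }
    term_members <- term_members[vapply(term_members, length, 1L) > 0L]

    half_life <- stats::setNames(truth$half_life_h, truth$gene_id)
    half_life <- half_life[truth$half_life_scored]

    list(taggit_map = map, tf_db = tf_db, tf_targets = targets,
         term_db = term_members, half_life = half_life)
  })
}
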