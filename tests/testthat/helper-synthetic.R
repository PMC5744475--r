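# Small simulation configs used across tests.
small_config <- function(n_genes = 500L, seed = 11L, ...) {
  simulation_config(n_genes = n_genes, n_control_probes = 5L,
                    frac_de_per_contrast = c(DvsWT = 0.08, ARvsD = 0.08,
                                             GIDvsD = 0.01),
                    rng_seed = seed, ...)
}

# Two-group matrix with planted shifts for contrast tests.
two_group_matrix <- function(n_genes = 200L, n_de = 10L, lfc = 2,
                             sigma = 0.2, n_rep = 3L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 2 * n_rep, 8, sigma), n_genes, 2 * n_rep,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              paste0("s", seq_len(2 * n_rep))))
  if (n_de > 0) m[seq_len(n_de), seq_len(n_rep)] <-
      m[seq_len(n_de), seq_len(n_rep)] + lfc
  meta <- data.frame(sample = colnames(m),
                     group = rep(c("A", "B"), each = n_rep),
                     replicate = rep(seq_len(n_rep), 2))
  list(matrix = m, metadata = meta, de = rownames(m)[seq_len(n_de)])
}

# Minimal annotation / map pair for TAGGIT unit tests.
tiny_taggit_map <- function() {
  cats <- taggit_category_names()
  ids <- setNames(vector("list", 26), cats)
  ids[] <- list(character(0))
  ids[["ABA"]] <- c("At0g00001", "At0g00002")
  ids[["translation"]] <- "At0g00003"
  kw <- setNames(as.list(rep("", 26)), cats)
  kw[] <- lapply(cats, function(x) character(0))
  kw[["LEAs"]] <- "late embryogenesis abundant"
  kw[["translation"]] <- "ribosomal"
  taggit_map(ids, kw)
}

tiny_annotation <- function() {
  data.frame(
    gene_id = sprintf("At0g%05d", 1:6),
    description = c("expressed protein", "hypothetical protein",
                    "60S ribosomal protein L10",
                    "late embryogenesis abundant protein",
                    "unknown function protein", "expressed protein"),
    stringsAsFactors = FALSE)
}
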