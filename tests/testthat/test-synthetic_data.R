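test_that("annotation honours configured counts, control flags and keywords", {
  cfg <- simulation_config(n_genes = 10L, n_control_probes = 2L,
                           rng_seed = 5L)
  out <- generate_annotation(cfg)
  expect_equal(nrow(out$annotation), 12L)
  expect_equal(sum(out$annotation$is_control), 2L)
  expect_true(all(startsWith(
    out$annotation$gene_id[out$annotation$is_control], "AFFX")))
  expect_equal(nrow(out$truth), 10L)

  # any LEA-category member carries the LEA keyword or is id-listed
  cfg2 <- small_config(n_genes = 400L, seed = 9L,
                       taggit_prevalence = 0.05)
  out2 <- generate_annotation(cfg2)
  gs <- generate_genesets(cfg2, out2$truth)
  members <- grepl("\\bLEAs\\b", out2$truth$taggit_categories)
  expect_gt(sum(members), 0L)
  kw_hit <- grepl("late embryogenesis abundant",
                  out2$annotation$description[seq_len(400)][members])
  id_hit <- out2$truth$gene_id[members] %in% gs$taggit_map[["LEAs"]]$ids
  expect_true(all(kw_hit | id_hit))

  expect_error(simulation_config(n_genes = 0), "positive")
})

test_that("identical configs give identical outputs (determinism)", {
  cfg <- small_config(seed = 21L)
  a1 <- generate_annotation(cfg); a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  e1 <- generate_expression(cfg, a1$truth)
  e2 <- generate_expression(cfg, a2$truth)
  expect_identical(e1, e2)
  expect_identical(generate_ct_table(cfg, a1$truth),
                   generate_ct_table(cfg, a2$truth))
  expect_identical(generate_genesets(cfg, a1$truth),
                   generate_genesets(cfg, a2$truth))
})

test_that("zero-noise expression reproduces planted logFCs exactly", {
  cfg <- small_config(n_genes = 300L, seed = 2L, replicate_noise_sd = 0)
  out <- generate_annotation(cfg)
  expr <- generate_expression(cfg, out$truth)
  m <- expr$matrix[seq_len(300L), ]
  grp <- expr$metadata$group[match(colnames(m), expr$metadata$sample)]
  obs <- rowMeans(m[, grp == "AR"]) - rowMeans(m[, grp == "D"])
  expect_equal(unname(obs), out$truth$logfc_ARvsD, tolerance = 1e-12)
})

test_that("planted DE counts and sign imbalance follow the config", {
  cfg <- simulation_config(n_genes = 1000L, n_control_probes = 0L,
                           frac_de_per_contrast = 0.05,
                           pi_down = 0.65, rng_seed = 3L)
  truth <- generate_annotation(cfg)$truth
  expect_equal(sum(truth$is_de_DvsWT), 50L)
  signs <- sign(truth$logfc_DvsWT[truth$is_de_DvsWT])
  expect_equal(mean(signs < 0), 0.65, tolerance = 0.12)
  expect_true(all(truth$is_de_DvsWT == (truth$logfc_DvsWT != 0)))
})

test_that("decay follows the half-life law and conserves mass on renormalization", {
  expect_equal(simulate_dry_storage_decay(10, half_lives = 4, t = 4), 5)
  x <- c(3, 7, 2)
  expect_identical(simulate_dry_storage_decay(x, c(1, 5, 24), t = 0), x)

  h <- 1:24
  n0 <- rep(1, 24)
  dec <- simulate_dry_storage_decay(n0, h, t = 12, renormalize = TRUE)
  expect_equal(sum(dec), sum(n0), tolerance = 1e-12)
  ratio <- log2(dec / n0)
  expect_true(all(diff(ratio) > 0))       # strictly increasing in half-life
  expect_gt(ratio[24], 0)                 # most stable transcript appears up

  expect_error(simulate_dry_storage_decay(1, 0, 1), "positive")
  expect_error(simulate_dry_storage_decay(1, 2, -1), "non-negative")
})

test_that("Ct table plants fold changes recoverable by the ddCt pipeline", {
  cfg <- small_config(n_genes = 300L, seed = 13L, ct_noise_sd = 0)
  truth <- generate_annotation(cfg)$truth
  tab <- generate_ct_table(cfg, truth)
  planted <- attr(tab, "planted_fold")
  tg <- rownames(planted)[1]
  rq <- delta_delta_ct(tab, tg)
  expect_equal(rq$rq_mean[rq$condition == attr(tab, "calibrator")], 1)
  got <- setNames(rq$rq_mean, rq$condition)
  expect_equal(got[colnames(planted)], planted[tg, ], tolerance = 1e-9)

  # with noise, recovery within 2x the Ct noise sd on the log2 scale
  cfg2 <- small_config(n_genes = 300L, seed = 13L, ct_noise_sd = 0.05)
  tab2 <- generate_ct_table(cfg2, generate_annotation(cfg2)$truth)
  rq2 <- delta_delta_ct(tab2, tg)
  got2 <- setNames(rq2$rq_mean, rq2$condition)
  expect_equal(log2(got2[colnames(planted)]), log2(planted[tg, ]),
               tolerance = 0.2)
})

test_that("generated gene sets are consistent with the truth labels", {
  cfg <- small_config(n_genes = 400L, seed = 17L)
  truth <- generate_annotation(cfg)$truth
  gs <- generate_genesets(cfg, truth)

  expect_length(gs$taggit_map, 26L)
  myb <- truth$gene_id[!is.na(truth$tf_family) & truth$tf_family == "MYB"]
  expect_true(all(myb %in% gs$tf_db$gene_id[gs$tf_db$family == "MYB"]))
  expect_equal(length(gs$half_life), sum(truth$half_life_scored))
  expect_true(all(gs$half_life > 0))
  for (tf in names(gs$tf_targets)) {
    s <- gs$tf_targets[[tf]]
    expect_setequal(s$all, union(s$confirmed, s$unconfirmed))
  }
})
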