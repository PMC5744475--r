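test_that("control-probe removal is prefix-based and case-sensitive", {
  m <- matrix(1:20, 10, 2,
              dimnames = list(c(sprintf("At0g%05d", 1:7), "AFFX-1", "AFFX-2",
                                "affx-3"), c("s1", "s2")))
  out <- remove_controls(m)
  expect_equal(nrow(out), 8L)
  expect_true("affx-3" %in% rownames(out))     # lowercase retained
  expect_identical(remove_controls(out), out)  # no controls -> identity
  m2 <- m[8:9, , drop = FALSE]
  expect_error(remove_controls(m2), "every row")
})

test_that("quantile normalization matches the rank-mean rule", {
  m <- matrix(c(1, 5, 3, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- quantile_normalize(m)
  expect_equal(unname(out), matrix(c(2, 6, 2, 6), 2, 2))

  set.seed(4)
  m3 <- matrix(rnorm(600), 100, 6)
  rownames(m3) <- sprintf("g%03d", 1:100)
  out3 <- quantile_normalize(m3)
  sorted <- apply(out3, 2, sort)
  for (j in 2:6) expect_equal(sorted[, j], sorted[, 1])   # identical dists
  expect_equal(apply(out3, 2, rank), apply(m3, 2, rank))  # ranks preserved

  expect_error(quantile_normalize(matrix(c(1, NA, 2, 3), 2, 2)), "NA")
})

test_that("quantile normalization agrees with limma's implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  m <- matrix(rnorm(500), 100, 5)
  m[7, 2] <- m[9, 2]  # plant a within-sample tie
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("moderated t reduces to the pooled t-test at prior_df = 0", {
  d <- two_group_matrix(n_genes = 50, n_de = 5, seed = 6)
  res <- moderated_t_contrast(d$matrix, d$metadata, "A", "B", prior_df = 0)
  ref_t <- apply(d$matrix, 1, function(x) {
    stats::t.test(x[1:3], x[4:6], var.equal = TRUE)$statistic
  })
  ref_p <- apply(d$matrix, 1, function(x) {
    stats::t.test(x[1:3], x[4:6], var.equal = TRUE)$p.value
  })
  expect_equal(res$t, unname(ref_t), tolerance = 1e-12)
  expect_equal(res$p, unname(ref_p), tolerance = 1e-12)
})

test_that("infinite prior df pools every gene to a shared variance", {
  d <- two_group_matrix(n_genes = 40, seed = 7)
  res <- moderated_t_contrast(d$matrix, d$metadata, "A", "B", prior_df = Inf)
  # t / logFC constant across genes when the variance is shared
  scale <- res$t / res$logFC
  expect_equal(max(scale) - min(scale), 0, tolerance = 1e-10)
})

test_that("moderated t agrees with limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(3)
  n <- 400
  sds <- sqrt(0.05 * 4 / stats::rchisq(n, 4))
  m <- matrix(rnorm(n * 6, 8, rep(sds, 6)), n, 6,
              dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:6)))
  meta <- data.frame(sample = paste0("s", 1:6),
                     group = rep(c("A", "B"), each = 3),
                     replicate = rep(1:3, 2))
  mine <- moderated_t_contrast(m, meta, "A", "B")
  design <- stats::model.matrix(~ 0 + factor(rep(c("A", "B"), each = 3)))
  colnames(design) <- c("A", "B")
  fit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(m, design),
    limma::makeContrasts(A - B, levels = design)))
  expect_equal(attr(mine, "df_prior"), fit$df.prior, tolerance = 1e-9)
  expect_equal(attr(mine, "var_prior"), fit$s2.prior, tolerance = 1e-9)
  expect_equal(mine$t, unname(fit$t[, 1]), tolerance = 1e-9)
  expect_equal(mine$p, unname(fit$p.value[, 1]), tolerance = 1e-9)
})

test_that("planted effects are detected with high sensitivity", {
  d <- two_group_matrix(n_genes = 1000, n_de = 50, lfc = 2, sigma = 0.2,
                        seed = 12)
  res <- moderated_t_contrast(d$matrix, d$metadata, "A", "B")
  called <- res$gene_id[res$significant & res$logFC > 0]
  sensitivity <- length(intersect(called, d$de)) / length(d$de)
  expect_gte(sensitivity, 0.9)
})

test_that("moderated t validates its inputs", {
  d <- two_group_matrix(n_genes = 20, seed = 1)
  meta1 <- d$metadata
  meta1$group[meta1$group == "B"] <- c("B", "C", "C")
  expect_error(moderated_t_contrast(d$matrix, meta1, "A", "B"),
               ">= 2 replicates")
  m0 <- matrix(5, 10, 6, dimnames = list(sprintf("g%02d", 1:10),
                                         d$metadata$sample))
  expect_error(moderated_t_contrast(m0, d$metadata, "A", "B"),
               "zero variance")
})

test_that("BH adjustment matches the hand-worked step-up rule", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(adjust_bh(0.004), 0.004)
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("classification splits by sign and keeps sets disjoint", {
  fixture <- system.file("extdata", "gid1b_oe_vs_dormant_logfc.tsv",
                         package = "dryseedr")
  tab <- parse_logfc_table(fixture)
  expect_equal(length(tab$dry$up), 5L)
  expect_equal(length(tab$dry$down), 2L)

  res <- structure(data.frame(gene_id = c("a", "b", "c"),
                              logFC = c(1, -1, 2),
                              t = c(5, -5, 6), p = c(0.001, 0.001, 0.9),
                              p_adj = c(0.003, 0.003, 0.9),
                              significant = c(TRUE, TRUE, FALSE)),
                   class = c("de_result", "data.frame"))
  sets <- classify_de(res)
  expect_setequal(sets$up, "a")
  expect_setequal(sets$down, "b")
  expect_length(intersect(sets$up, sets$down), 0L)

  res$p_adj <- rep(0.9, 3)
  empty <- classify_de(res)
  expect_length(empty$up, 0L)
  expect_length(empty$down, 0L)
})

test_that("G1 skewness is exact, antisymmetric and zero on symmetric input", {
  expect_equal(skewness_g1(c(-1, 0, 1)), 0)
  # frozen value from direct evaluation of the adjusted moment formula
  expect_equal(skewness_g1(c(1, 2, 3, 4, 10)), 1.697056274847714,
               tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:50, 1))
    expect_equal(skewness_g1(-x), -skewness_g1(x), tolerance = 1e-12)
  }
  expect_error(skewness_g1(c(1, 2)), "at least 3")
  expect_error(skewness_g1(c(2, 2, 2)), "zero variance")
})

test_that("down-biased planted effects give negative genome-wide skewness", {
  # pi_down = 0.65 over the full per-gene logFC vector (nulls mass near 0)
  hits <- vapply(1:60, function(s) {
    cfg <- simulation_config(n_genes = 800L, n_control_probes = 0L,
                             frac_de_per_contrast = 0.15, pi_down = 0.65,
                             rng_seed = 1000L + s)
    truth <- generate_annotation(cfg)$truth
    expr <- generate_expression(cfg, truth)
    res <- moderated_t_contrast(expr$matrix, expr$metadata, "D", "WT")
    skewness_g1(res$logFC) < 0
  }, TRUE)
  expect_true(all(hits))
})
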