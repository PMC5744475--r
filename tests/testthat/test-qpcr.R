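make_ct <- function(shifts, noise = 0, seed = 1, calibrator = "D") {
  # shifts: named per-condition log2 fold of the target vs calibrator
  set.seed(seed)
  rows <- do.call(rbind, lapply(names(shifts), function(cond) {
    do.call(rbind, lapply(1:3, function(r) {
      s <- sprintf("%s_r%d", cond, r)
      data.frame(sample = s, condition = cond,
                 gene = c("REF", "TGT"),
                 ct = c(20, 24 - shifts[[cond]]) + rnorm(2, 0, noise),
                 stringsAsFactors = FALSE)
    }))
  }))
  ct_table(rows, reference_gene = "REF", calibrator = calibrator)
}

test_that("efficiency screening applies both the 100% and spread rules", {
  res <- check_efficiencies(list(a = -3.3219, b = -3.32))
  expect_equal(res$efficiency, c(1, 1), tolerance = 1e-3)
  expect_true(all(res$pass))

  # E = 0.85 -> individual fail
  slope_085 <- -1 / log10(1.85)
  res2 <- check_efficiencies(list(a = slope_085))
  expect_false(res2$pass_individual)

  # E = 0.95 and 1.07: each within 10% of 100%, spread 0.12 -> pairwise fail
  res3 <- check_efficiencies(list(a = -1 / log10(1.95), b = -1 / log10(2.07)))
  expect_true(all(res3$pass_individual))
  expect_false(any(res3$pass_spread))

  # slope from a dilution series
  dil <- data.frame(dilution = c(1, 0.1, 0.01), ct = c(20, 23.3219, 26.6439))
  res4 <- check_efficiencies(list(g = dil))
  expect_equal(res4$efficiency, 1, tolerance = 1e-3)
  expect_error(check_efficiencies(list(g = data.frame(
    dilution = c(1, 1, 1), ct = c(20, 21, 22)))), "singular")
})

test_that("ddCt identities hold on noiseless tables", {
  # target parallel to reference in every sample -> RQ = 1 everywhere
  flat <- make_ct(c(D = 0, AR = 0))
  rq <- delta_delta_ct(flat, "TGT")
  expect_equal(rq$rq_mean, c(1, 1))

  # planted 4-fold: Ct shift -2 cycles, RQ = 4; ddCt = -1 -> RQ = 2
  tab <- make_ct(c(D = 0, AR = 2, WT = 1))
  rq2 <- delta_delta_ct(tab, "TGT")
  got <- setNames(rq2$rq_mean, rq2$condition)
  expect_equal(unname(got["D"]), 1)
  expect_equal(unname(got["AR"]), 4, tolerance = 1e-12)
  expect_equal(unname(got["WT"]), 2, tolerance = 1e-12)

  expect_error(delta_delta_ct(tab, "REF"), "differ")
  bad <- tab[!(tab$gene == "REF" & tab$sample == "AR_r1"), ]
  bad <- ct_table(bad, "REF", "D")
  expect_error(delta_delta_ct(bad, "TGT"), "AR_r1")
})

test_that("RQ is invariant to per-sample plate shifts", {
  tab <- make_ct(c(D = 0, AR = 1.5), noise = 0.05, seed = 4)
  rq1 <- delta_delta_ct(tab, "TGT")
  shifted <- tab
  for (s in unique(tab$sample)) {
    d <- runif(1, -3, 3)
    shifted$ct[shifted$sample == s] <- shifted$ct[shifted$sample == s] + d
  }
  shifted <- ct_table(shifted, "REF", "D")
  rq2 <- delta_delta_ct(shifted, "TGT")
  expect_equal(rq1$rq_mean, rq2$rq_mean, tolerance = 1e-12)
})

test_that("planted folds are recovered within 10% at 0.05-cycle noise", {
  folds <- c(0.5, 1, 2, 8)
  for (i in seq_along(folds)) {
    tab <- make_ct(c(D = 0, AR = log2(folds[i])), noise = 0.05,
                   seed = 100 + i)
    rq <- delta_delta_ct(tab, "TGT")
    got <- rq$rq_mean[rq$condition == "AR"]
    expect_lt(abs(got - folds[i]) / folds[i], 0.10)
  }
})

test_that("Holm adjustment and pairwise testing behave as specified", {
  # hand-worked step-down vector
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))

  set.seed(9)
  g <- list(a = rnorm(3, 1, 0.1), b = rnorm(3, 1, 0.1), c = rnorm(3, 2, 0.1))
  res <- pairwise_holm(g)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$p_adj >= res$p - 1e-15))
  ab <- res[res$group1 == "a" & res$group2 == "b", ]
  expect_false(ab$significant)
  ac <- res[res$group1 == "a" & res$group2 == "c", ]
  expect_true(ac$significant)

  # single comparison: Holm equals the raw p
  res1 <- pairwise_holm(g[c("a", "c")])
  expect_equal(res1$p_adj, res1$p)

  expect_error(pairwise_holm(list(a = c(1, 1, 1), b = c(1, 1, 1))),
               "degenerate")
  expect_error(pairwise_holm(list(a = 1, b = c(1, 2))), ">= 2 replicates")
})
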