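test_that("the map constructor enforces the 26-category schema", {
  expect_length(taggit_category_names(), 26L)
  expect_error(taggit_map(list(a = "x"), list(a = "k")), "26")
  map <- tiny_taggit_map()
  expect_s3_class(map, "taggit_map")
  expect_length(map, 26L)
})

test_that("categorization follows the id-list OR keyword rule", {
  map <- tiny_taggit_map()
  ann <- tiny_annotation()
  cats <- taggit_categorize(c("At0g00001", "At0g00003", "At0g00004",
                              "At0g00005"), ann, map)
  expect_equal(cats[["At0g00001"]], "ABA")            # id-list route
  expect_equal(cats[["At0g00004"]], "LEAs")           # keyword route
  # id-listed AND keyword-matched in the same category: counted once
  expect_equal(cats[["At0g00003"]], "translation")
  expect_length(cats[["At0g00005"]], 0L)              # unclassified

  # idempotent and order-independent
  rev_cats <- taggit_categorize(rev(names(cats)), ann, map)
  expect_identical(cats[sort(names(cats))], rev_cats[sort(names(rev_cats))])
  expect_error(taggit_categorize("x", ann, structure(list(),
                                                     class = "taggit_map")),
               "empty")
})

test_that("profiles report percentages of the direction totals", {
  map <- tiny_taggit_map()
  ann <- tiny_annotation()
  sets <- gene_set_pair(up = c("At0g00003", "At0g00005", "At0g00006",
                               "At0g00002"),
                        down = c("At0g00001", "At0g00004"))
  prof <- taggit_profile(sets, ann, map)
  expect_equal(prof$up_pct[prof$category == "translation"], 25)
  expect_equal(prof$up_pct[prof$category == "ABA"], 25)
  expect_equal(prof$down_pct[prof$category == "ABA"], 50)
  expect_equal(prof$down_pct[prof$category == "LEAs"], 50)

  none <- gene_set_pair(up = "At0g00005", down = "At0g00006")
  p0 <- taggit_profile(none, ann, map)
  expect_true(all(p0$up_count == 0L) && all(p0$down_count == 0L))
})

test_that("planted category fractions are recovered exactly", {
  cfg <- small_config(n_genes = 400L, seed = 31L)
  out <- generate_annotation(cfg)
  gs <- generate_genesets(cfg, out$truth)
  members <- out$truth$gene_id[
    grepl("\\btranslation\\b", out$truth$taggit_categories)]
  others <- setdiff(out$truth$gene_id, members)
  # build an up-set with exactly 25% planted translation members
  up <- c(members[1:3], others[1:9])
  down <- others[10:29]
  prof <- taggit_profile(gene_set_pair(up, down), out$annotation,
                         gs$taggit_map)
  expect_equal(prof$up_pct[prof$category == "translation"], 25)
})

test_that("random control draws are deterministic, disjoint and unbiased", {
  cfg <- small_config(n_genes = 900L, seed = 41L, taggit_prevalence = 0.03)
  out <- generate_annotation(cfg)
  gs <- generate_genesets(cfg, out$truth)
  genome <- out$truth$gene_id

  p1 <- random_control_profile(genome = genome, map = gs$taggit_map,
                               annotation = out$annotation, seed = 99L)
  p2 <- random_control_profile(genome = genome, map = gs$taggit_map,
                               annotation = out$annotation, seed = 99L)
  expect_identical(p1, p2)
  expect_equal(attr(p1, "n_up"), 330L)      # default control design
  expect_equal(attr(p1, "n_down"), 430L)

  # genome with no category signal -> all-zero profile
  blank_ann <- data.frame(gene_id = sprintf("x%03d", 1:800),
                          description = "expressed protein",
                          stringsAsFactors = FALSE)
  blank_map <- taggit_map(
    setNames(rep(list(character(0)), 26), taggit_category_names()),
    setNames(rep(list(character(0)), 26), taggit_category_names()))
  p0 <- random_control_profile(genome = blank_ann$gene_id, map = blank_map,
                               annotation = blank_ann, seed = 1L)
  expect_true(all(p0$up_count == 0L) && all(p0$down_count == 0L))

  expect_error(random_control_profile(500, 500, genome = genome[1:100],
                                      map = gs$taggit_map,
                                      annotation = out$annotation),
               "too small")
})
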