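test_that("copy-number normalization divides, inverts, and validates", {
  ft <- tiny_otu_table()
  gcm <- tiny_gcm()
  norm <- normalize_by_copy_number(ft, gcm)
  expect_equal(norm$values["OTU_1", "s1"], 10 / 2)
  expect_equal(norm$values["OTU_3", "s2"], 8 / 4)

  # copy number 1 everywhere is the identity
  ones <- gene_content_matrix(gcm$content,
                              stats::setNames(rep(1, 3), gcm$otu_ids))
  expect_equal(normalize_by_copy_number(ft, ones)$values, ft$values)

  # inverse property on a random 50 x 6 table
  big <- random_count_table(50, 6, seed = 9)
  bgcm <- random_gcm(big$feature_ids, 4, seed = 10)
  rec <- normalize_by_copy_number(big, bgcm)$values *
    bgcm$copy_number[big$feature_ids]
  expect_equal(rec, big$values)

  missing <- ft_subset(ft, features = c("OTU_1", "OTU_2"))
  small_gcm <- gene_content_matrix(gcm$content["OTU_1", , drop = FALSE],
                                   gcm$copy_number["OTU_1"])
  expect_error(normalize_by_copy_number(missing, small_gcm), "OTU_2")
  expect_error(normalize_by_copy_number(
    feature_table(ft$values, scale = "log2"), gcm), "counts")
})

test_that("metagenome prediction is the content-weighted sum with exact contributions", {
  # one OTU, normalized abundance 5, content 3 -> KO abundance 15
  one <- feature_table(matrix(5, 1, 1, dimnames = list("OTU_1", "s1")),
                       scale = "counts")
  g1 <- gene_content_matrix(matrix(3, 1, 1, dimnames = list("OTU_1", "K00001")),
                            c(OTU_1 = 1))
  pm1 <- predict_metagenome(one, g1)
  expect_equal(pm1$ko_table$values["K00001", "s1"], 15)

  # two OTUs: 5*3 + 1*2 = 17, contributions 15 and 2
  two <- feature_table(matrix(c(5, 1), 2, 1,
                              dimnames = list(c("OTU_1", "OTU_2"), "s1")),
                       scale = "counts")
  g2 <- gene_content_matrix(matrix(c(3, 2), 2, 1,
                                   dimnames = list(c("OTU_1", "OTU_2"), "K00001")),
                            c(OTU_1 = 1, OTU_2 = 1))
  pm2 <- predict_metagenome(two, g2)
  expect_equal(pm2$ko_table$values["K00001", "s1"], 17)
  expect_equal(sort(pm2$contributions$contribution), c(2, 15))
})

test_that("prediction matches the triple-loop oracle and conserves contributions", {
  for (seed in c(21, 22)) {
    tab <- random_count_table(30, 5, seed = seed)
    gcm <- random_gcm(tab$feature_ids, 8, seed = seed + 100)
    norm <- normalize_by_copy_number(tab, gcm)
    pm <- suppressMessages(predict_metagenome(norm, gcm))
    oracle <- predict_oracle(norm, gcm)
    oracle <- oracle[rowSums(oracle) > 0, , drop = FALSE]
    expect_equal(pm$ko_table$values, oracle, tolerance = 1e-12)

    # per (ko, sample) contribution sums reconstruct the prediction
    agg <- tapply(pm$contributions$contribution,
                  list(pm$contributions$ko_id, pm$contributions$sample_id),
                  sum, default = 0)
    agg <- agg[rownames(pm$ko_table$values), colnames(pm$ko_table$values)]
    rel <- abs(agg - pm$ko_table$values) / pmax(pm$ko_table$values, 1e-300)
    rel[pm$ko_table$values == 0] <- abs(agg[pm$ko_table$values == 0])
    expect_lt(max(rel), 1e-9)
    expect_true(all(pm$contributions$contribution > 0))
  }
})

test_that("prediction is linear in the input table", {
  tab1 <- random_count_table(20, 4, seed = 31)
  tab2 <- random_count_table(20, 4, seed = 32)
  gcm <- random_gcm(tab1$feature_ids, 6, seed = 33)
  mix <- feature_table(2 * tab1$values + 3 * tab2$values, scale = "counts")
  p <- function(t) suppressMessages(
    predict_metagenome(normalize_by_copy_number(t, gcm), gcm))$ko_table$values
  expect_equal(p(mix), 2 * p(tab1) + 3 * p(tab2), tolerance = 1e-12)
})

test_that("pathway collapse sums member KOs, duplicating multi-membership", {
  kt <- feature_table(matrix(c(3, 4, 10), 3, 1,
                             dimnames = list(c("K1", "K2", "K3"), "s1")),
                      scale = "counts")
  db <- pathway_db(list(P1 = c("K1", "K2"), P2 = c("K2", "K3"), P3 = "K9"))
  pt <- suppressMessages(collapse_to_pathways(kt, db))
  expect_equal(pt$values["P1", "s1"], 7)
  expect_equal(pt$values["P2", "s1"], 14)   # K2 counted in both pathways
  expect_false("P3" %in% pt$feature_ids)    # no measured KO -> dropped

  # random instance vs brute-force per-pathway summation
  set.seed(44)
  kt2 <- feature_table(matrix(rpois(60, 5), 12, 5,
                              dimnames = list(sprintf("K%02d", 1:12),
                                              paste0("s", 1:5))),
                       scale = "counts")
  members <- lapply(1:6, function(i) sample(kt2$feature_ids, sample(2:5, 1)))
  names(members) <- paste0("P", 1:6)
  db2 <- pathway_db(members)
  pt2 <- suppressMessages(collapse_to_pathways(kt2, db2))
  for (p in pt2$feature_ids) {
    brute <- colSums(kt2$values[sort(unique(members[[p]])), , drop = FALSE])
    expect_equal(pt2$values[p, ], brute)
  }
})

test_that("genus aggregation follows taxonomy, the unclassified policy, and conservation", {
  ft <- tiny_otu_table()
  m <- matrix(c(3, 9, 1, 2, 4, 7), 3, 2,
              dimnames = list(ft$feature_ids, ft$sample_ids))
  ft2 <- feature_table(m, feature_meta = ft$feature_meta, scale = "counts")
  gen <- aggregate_to_genus(ft2)
  expect_equal(gen$values["Prevotella", "s1"], 3 + 9)
  expect_true("unclassified_S24-7" %in% gen$feature_ids)
  expect_equal(colSums(gen$values), colSums(ft2$values))

  no_meta <- feature_table(m, scale = "counts")
  expect_error(aggregate_to_genus(no_meta), "taxonomy")
})
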