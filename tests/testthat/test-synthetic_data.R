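test_that("generators are fully deterministic under a fixed seed", {
  a <- generate_community(n_otus = 80, n_per_group = 3, n_planted = 8, seed = 5)
  b <- generate_community(n_otus = 80, n_per_group = 3, n_planted = 8, seed = 5)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    a$table$values,
    generate_community(n_otus = 80, n_per_group = 3, n_planted = 8,
                       seed = 6)$table$values))

  s1 <- generate_study(study_config(n_otus = 60, n_kos = 50, n_genes = 40,
                                    n_pathways = 8, pathway_size = 4,
                                    cassette_otus = 3,
                                    n_planted_pathways = 2), seed = 9)
  s2 <- generate_study(study_config(n_otus = 60, n_kos = 50, n_genes = 40,
                                    n_pathways = 8, pathway_size = 4,
                                    cassette_otus = 3,
                                    n_planted_pathways = 2), seed = 9)
  expect_identical(s1$otu_table$values, s2$otu_table$values)
  expect_identical(s1$gcm$content, s2$gcm$content)
  expect_identical(s1$expression$values, s2$expression$values)
  expect_identical(s1$truth, s2$truth)

  # byte-identical files on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("zero effect plants nothing and generator validates its inputs", {
  nullcom <- generate_community(n_otus = 50, n_per_group = 3, n_planted = 10,
                                effect_log2 = 0, seed = 2)
  expect_equal(nrow(nullcom$truth), 0L)
  expect_error(generate_community(n_otus = 5, n_planted = 10, seed = 1),
               "n_planted")
  expect_error(generate_gene_content(paste0("OTU_", 1:5), 10, sparsity = 1),
               "sparsity")
  expect_error(generate_study(study_config(n_kos = 10, pathway_size = 12,
                                           n_planted_pathways = 3), seed = 1),
               "KOs")
})

test_that("planted OTUs realize their fold change in the group means", {
  # Monte-Carlo over 100 seeds, frozen from a pre-build tabulation:
  # fraction of planted OTUs (effect 2, dispersion 0.1, n = 5/group) whose
  # realized |log2 group-mean ratio| >= 1 averaged 0.9755
  frac <- vapply(1:100, function(s) {
    cm <- generate_community(n_otus = 200, n_per_group = 5, n_planted = 20,
                             effect_log2 = 2, dispersion = 0.1, depth = 15000,
                             seed = s)
    grp <- cm$design$groups[cm$table$sample_ids]
    ok <- vapply(seq_len(nrow(cm$truth)), function(i) {
      ab <- strsplit(cm$truth$contrast[i], "-", fixed = TRUE)[[1]]
      r <- log2(mean(cm$table$values[cm$truth$id[i], grp == ab[1]]) /
                  mean(cm$table$values[cm$truth$id[i], grp == ab[2]]))
      is.finite(r) && abs(r) >= 1
    }, logical(1))
    mean(ok)
  }, numeric(1))
  expect_equal(mean(frac), 0.9755, tolerance = 1e-8)
  expect_gte(mean(frac), 0.9)
})

test_that("planted genes are recovered by the differential gate at the design power", {
  # Monte-Carlo oracle frozen before the build: mean recovery 0.9996667 over
  # 100 seeds at n = 5/group, effect 2, noise SD 0.5
  grps <- c("NOCIA", "CIA", "MS", "MTXMS")
  ctr <- c("CIA-NOCIA", "MS-CIA", "MTXMS-CIA", "MS-MTXMS")
  pow <- vapply(1:100, function(s) {
    ex <- generate_expression(n_genes = 300, n_per_group = 5, n_planted = 30,
                              effect_log2 = 2, noise_sd = 0.5, seed = s)
    des <- study_design(stats::setNames(rep(grps, each = 5),
                                        colnames(ex$table$values)),
                        contrasts = ctr)
    d <- run_differential(ex$table, des, use_voom = FALSE)
    hit <- vapply(seq_len(nrow(ex$truth)), function(i) {
      row <- d[d$feature == ex$truth$id[i] & d$contrast == ex$truth$contrast[i], ]
      (ex$truth$effect[i] > 0 && row$direction == "up") ||
        (ex$truth$effect[i] < 0 && row$direction == "down")
    }, logical(1))
    mean(hit)
  }, numeric(1))
  expect_equal(mean(pow), 0.9996667, tolerance = 1e-6)
  expect_gte(min(pow), 0.9)
})

test_that("null expression p-values are uniform (KS) per seed batch", {
  for (s in 1:3) {
    ex <- generate_expression(n_genes = 2000, n_per_group = 5, n_planted = 0,
                              effect_log2 = 0, noise_sd = 0.5, seed = s)
    des <- study_design(stats::setNames(
      rep(c("NOCIA", "CIA", "MS", "MTXMS"), each = 5),
      colnames(ex$table$values)), contrasts = "MS-CIA")
    d <- run_differential(ex$table, des, use_voom = FALSE)
    expect_gt(suppressWarnings(stats::ks.test(d$p_raw, "punif"))$p.value, 0.01)
  }
})

test_that("study bundles reload cleanly and the manifest ids all exist", {
  dir <- withr::local_tempdir()
  b <- generate_study(study_config(n_otus = 80, n_kos = 60, n_genes = 50,
                                   n_pathways = 10, pathway_size = 5,
                                   cassette_otus = 3, n_planted_pathways = 2,
                                   planted_genes_per_pathway = 2),
                      seed = 3, out_dir = dir)
  r <- read_study(dir)
  expect_equal(r$otu_table$values, b$otu_table$values)
  expect_equal(r$gcm$content, b$gcm$content)
  expect_equal(r$expression$values, b$expression$values)
  expect_setequal(names(r$pathway_db$members), names(b$pathway_db$members))

  tr <- b$truth
  expect_true(all(tr$id[tr$kind == "otu"] %in% b$otu_table$feature_ids))
  expect_true(all(tr$id[tr$kind == "gene"] %in% b$expression$feature_ids))
  expect_true(all(tr$id[tr$kind == "pathway"] %in% names(b$pathway_db$members)))
  expect_true(all(tr$contrast %in% b$design$contrasts$label))
})

test_that("pathway cassettes make their OTUs the sole contributors", {
  b <- generate_study(study_config(n_otus = 80, n_kos = 60, n_genes = 50,
                                   n_pathways = 10, pathway_size = 5,
                                   cassette_otus = 3, n_planted_pathways = 2,
                                   planted_genes_per_pathway = 2), seed = 4)
  pm <- suppressMessages(predict_metagenome(
    normalize_by_copy_number(b$otu_table, b$gcm), b$gcm))
  planted <- b$truth[b$truth$kind == "pathway", ]
  for (pid in planted$id) {
    kos <- b$pathway_db$members[[pid]]
    cas_otus <- b$gcm$otu_ids[rowSums(b$gcm$content[, kos, drop = FALSE]) > 0]
    contrib_otus <- unique(pm$contributions$otu_id[pm$contributions$ko_id %in% kos])
    expect_setequal(contrib_otus, cas_otus)
    expect_lte(length(cas_otus), 3L)
  }
})
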