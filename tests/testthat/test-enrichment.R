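test_that("EASE score penalizes the overlap and matches tail enumeration", {
  # a single hit (or none) can never score
  expect_equal(ease_score(0, 10, 20, 200), 1)
  expect_equal(ease_score(1, 10, 20, 200), 1)
  expect_equal(ease_score(c(0, 1), c(5, 5), c(5, 5), c(10, 10)), c(1, 1))

  # spec-style instance: tail of the penalized table (2, 7, 17, 174)
  expect_equal(ease_score(3, 10, 20, 200), ease_enum_oracle(3, 10, 20, 200),
               tolerance = 1e-14)
  expect_gte(ease_score(3, 10, 20, 200),
             ease_score(3, 10, 20, 200, variant = "fisher"))

  # complete overlap, penalized: still computed from the reduced margins
  expect_equal(ease_score(7, 7, 7, 7), ease_enum_oracle(7, 7, 7, 7))
  expect_equal(ease_score(7, 7, 7, 7), 1)  # K-1 of N-1 drawn n-1: certain

  # monotone: p non-increasing in k at fixed margins
  ps <- ease_score(0:10, 15, 30, 300)
  expect_true(all(diff(ps) <= 1e-15))

  expect_error(ease_score(5, 4, 10, 100), "margins")
  expect_error(ease_score(2, 5, 10, 8), "margins")
})

test_that("enrichment ranks a planted pathway first and stars the thresholds", {
  set.seed(12)
  universe <- paste0("K", 1:400)
  planted_kos <- paste0("K", 1:12)
  lst <- c(planted_kos, paste0("K", 301:308))  # 20-KO list, 12 in the pathway
  members <- c(list(PLANTED = planted_kos),
               lapply(1:9, function(i) sample(universe, 12)))
  names(members) <- c("PLANTED", paste0("BG", 1:9))
  db <- pathway_db(members)
  prov <- stats::setNames(rep(list("microbiome"), length(lst)), lst)
  ks <- ko_set("MS-CIA", "UP", lst, prov)
  enr <- enrich(ks, db, universe)
  expect_equal(enr$pathway[1], "PLANTED")
  expect_equal(enr$k[1], 12)
  expect_equal(enr$p_ease[1], ease_enum_oracle(12, 20, 12, 400),
               tolerance = 1e-12)

  # fully disjoint pathway: p = 1
  disj <- enr[enr$pathway != "PLANTED" & enr$k <= 1, ]
  expect_true(all(disj$p_ease == 1))

  expect_equal(star_labels <- komix:::star_label(c(0.0005, 0.005, 0.05, 0.06)),
               c("***", "**", "*", ""))
  expect_error(enrich(ks, db, character()), "empty")
  small <- ko_set("MS-CIA", "UP", "K999", stats::setNames(list("microbiome"), "K999"))
  expect_warning(enrich(small, db, universe), "outside the universe")
})

test_that("pathways below the minimum measured size are not tested", {
  db <- pathway_db(list(BIG = paste0("K", 1:5), TINY = c("K1", "K99")))
  universe <- paste0("K", 1:10)  # TINY has one measured KO
  prov <- stats::setNames(list("microbiome"), "K1")
  enr <- enrich(ko_set("X-Y", "ALL", "K1", prov), db, universe)
  expect_equal(enr$pathway, "BIG")
})

test_that("deconvolution recovers cassette taxa, directions, and shares", {
  enr <- data.frame(pathway = "PW1", pathway_name = "Sphingolipid metabolism",
                    comparison = "MS-MTXMS", direction = "ALL",
                    k = 3, K = 3, n = 5, N = 50, p_ease = 1e-4, stars = "***",
                    hit_kos = "K1,K2,K3", stringsAsFactors = FALSE)
  contributions <- data.frame(
    otu_id = c("OTU_1", "OTU_1", "OTU_2", "OTU_3", "OTU_3"),
    ko_id = c("K1", "K2", "K1", "K2", "K3"),
    sample_id = "s1",
    contribution = c(6, 2, 3, 0.5, 0.5),
    stringsAsFactors = FALSE)
  prov <- list(K1 = c("B4galt6", "microbiome"), K2 = "microbiome",
               K3 = c("Sptlc1", "microbiome"))
  dec <- deconvolute_contributors(
    enr, contributions, prov,
    gene_sets = list(up = c("B4galt6", "Sptlc1"), down = character()),
    otu_genus = c(OTU_1 = "Akkermansia", OTU_2 = "Prevotella", OTU_3 = "Lactobacillus"),
    genus_sets = list(up = c("Akkermansia", "Lactobacillus"), down = "Prevotella"))

  expect_equal(sum(dec$taxa$share), 1, tolerance = 1e-9)
  # ordered by contribution share, descending
  expect_equal(dec$taxa$genus, c("Akkermansia", "Prevotella", "Lactobacillus"))
  expect_equal(dec$taxa$genus_direction, c("up", "down", "up"))
  expect_setequal(dec$genes$gene, c("B4galt6", "Sptlc1"))
  expect_equal(unique(dec$genes$gene_direction), "up")

  # report row: pathway | genes | microbes | comparison_direction
  expect_equal(dec$summary$pathway, "Sphingolipid metabolism")
  expect_equal(dec$summary$comparison, "MS-MTXMS_ALL")
  expect_match(dec$summary$genes, "B4galt6\\(up\\), Sptlc1\\(up\\)")
  expect_match(dec$summary$microbes,
               "Akkermansia\\(up\\), Prevotella\\(down\\), Lactobacillus\\(up\\)")

  # missing contribution records for a microbial hit KO is an error
  expect_error(deconvolute_contributors(
    enr, contributions[contributions$ko_id != "K3", ], prov),
    "K3")
})
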