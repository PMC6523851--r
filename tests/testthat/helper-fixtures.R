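# In-code fixtures and independent oracles shared across the suite.

two_group_design <- function(n_per_group = 4, groups = c("A", "B")) {
  ids <- paste0(rep(groups, each = n_per_group), "_", seq_len(n_per_group))
  study_design(stats::setNames(rep(groups, each = n_per_group), ids),
               contrasts = paste0(groups[1], "-", groups[2]))
}

tiny_otu_table <- function() {
  m <- matrix(c(10, 0, 3,
                5, 2, 8),
              nrow = 3,
              dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), c("s1", "s2")))
  tax <- c("k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Prevotellaceae;g__Prevotella;s__",
           "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Prevotellaceae;g__Prevotella;s__copri",
           "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__S24-7;g__;s__")
  feature_table(m, feature_meta = data.frame(taxonomy = tax), scale = "counts")
}

tiny_gcm <- function() {
  content <- matrix(c(3, 2,
                      0, 1,
                      1, 0),
                    nrow = 3, byrow = TRUE,
                    dimnames = list(c("OTU_1", "OTU_2", "OTU_3"),
                                    c("K00001", "K00002")))
  gene_content_matrix(content, c(OTU_1 = 2, OTU_2 = 1, OTU_3 = 4))
}

random_count_table <- function(n_feat, n_samp, seed, max_count = 50) {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, max_count / 2), n_feat, n_samp,
              dimnames = list(sprintf("OTU_%04d", seq_len(n_feat)),
                              sprintf("s%02d", seq_len(n_samp))))
  feature_table(m, scale = "counts")
}

random_gcm <- function(otu_ids, n_kos, seed) {
  set.seed(seed)
  content <- matrix(rpois(length(otu_ids) * n_kos, 1), length(otu_ids), n_kos,
                    dimnames = list(otu_ids, sprintf("K%05d", seq_len(n_kos))))
  gene_content_matrix(content, stats::setNames(sample(1:5, length(otu_ids),
                                                      replace = TRUE), otu_ids))
}

# Triple-loop metagenome prediction oracle: ko(k, s) = sum_o norm(o,s)*content(o,k)
predict_oracle <- function(norm_table, gcm) {
  otus <- norm_table$feature_ids
  kos <- gcm$ko_ids
  samples <- norm_table$sample_ids
  out <- matrix(0, length(kos), length(samples), dimnames = list(kos, samples))
  for (k in kos) for (s in samples) {
    acc <- 0
    for (o in otus) acc <- acc + norm_table$values[o, s] * gcm$content[o, k]
    out[k, s] <- acc
  }
  out
}

# EASE oracle by explicit term-wise enumeration of the penalized table's
# upper tail, in log space (exact for moderate N).
ease_enum_oracle <- function(k, n, K, N) {
  if (k <= 1) return(1)
  kk <- k - 1; nn <- n - 1; KK <- K - 1; NN <- N - 1
  j <- kk:min(KK, nn)
  sum(exp(lchoose(KK, j) + lchoose(NN - KK, nn - j) - lchoose(NN, nn)))
}

# Same tail, summed from hypergeometric pmf terms (precise at large N).
ease_dhyper_oracle <- function(k, n, K, N) {
  if (k <= 1) return(1)
  j <- (k - 1):min(K - 1, n - 1)
  sum(stats::dhyper(j, K - 1, N - K, n - 1))
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
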