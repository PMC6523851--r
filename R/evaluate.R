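# Benchmark evaluation of a study analysis against the planted ground truth
# of its synthetic bundle.

#' Score planted-pathway recovery of an analysis
#'
#' For every planted pathway in the bundle's truth manifest, checks whether
#' the joint enrichment reports it at `p <= p_cut` in the planted comparison
#' and direction, and how completely the deconvolution recovered its
#' cassette genera and planted genes. Cassette OTUs are identified from the
#' gene-content construction (they are the only OTUs with content for the
#' pathway's KOs) and planted genes from the truth manifest restricted to
#' genes mapping into the pathway.
#'
#' @param bundle a `study_bundle` with a truth manifest.
#' @param analysis the matching `study_analysis`.
#' @param p_cut EASE p threshold defining recovery.
#' @return data.frame, one row per planted pathway: `pathway`, `contrast`,
#'   `direction`, `p_ease` (best matching joint row), `recovered`,
#'   `genus_recall`, `gene_recall`.
#' @export
planted_pathway_recovery <- function(bundle, analysis, p_cut = 0.05) {
  truth <- bundle$truth
  tp <- truth[truth$kind == "pathway", , drop = FALSE]
  if (!nrow(tp)) {
    return(data.frame(pathway = character(), contrast = character(),
                      direction = character(), p_ease = numeric(),
                      recovered = logical(), genus_recall = numeric(),
                      gene_recall = numeric(), stringsAsFactors = FALSE))
  }
  enr <- analysis$enrichment
  otu_genus <- stats::setNames(genus_of(bundle$otu_table),
                               bundle$otu_table$feature_ids)
  rows <- lapply(seq_len(nrow(tp)), function(i) {
    pid <- tp$id[i]
    dir <- if (tp$effect[i] > 0) "UP" else "DOWN"
    hit <- enr[enr$pathway == pid & enr$omic == "JOINT" &
                 enr$comparison == tp$contrast[i] & enr$direction == dir, ,
               drop = FALSE]
    p <- if (nrow(hit)) min(hit$p_ease) else NA_real_
    recovered <- isTRUE(p <= p_cut)
    kos <- bundle$pathway_db$members[[pid]]
    cas_otus <- bundle$gcm$otu_ids[
      rowSums(bundle$gcm$content[, intersect(kos, bundle$gcm$ko_ids),
                                 drop = FALSE]) > 0]
    cas_genera <- unique(otu_genus[cas_otus])
    genes <- intersect(
      truth$id[truth$kind == "gene" & truth$contrast == tp$contrast[i]],
      bundle$gene_ko_map$gene_id[bundle$gene_ko_map$ko_id %in% kos])
    dec <- analysis$deconvolution
    dtaxa <- dec$taxa[dec$taxa$pathway == pid &
                        dec$taxa$comparison == tp$contrast[i], , drop = FALSE]
    dgenes <- dec$genes[dec$genes$pathway == pid &
                          dec$genes$comparison == tp$contrast[i], , drop = FALSE]
    data.frame(pathway = pid, contrast = tp$contrast[i], direction = dir,
               p_ease = p, recovered = recovered,
               genus_recall = if (length(cas_genera))
                 mean(cas_genera %in% dtaxa$genus) else NA_real_,
               gene_recall = if (length(genes))
                 mean(genes %in% dgenes$gene) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
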