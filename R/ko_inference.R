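# Metagenome inference from 16S profiles: copy-number normalization,
# gene-content projection into KO space with per-OTU contribution
# accounting, pathway collapse, and genus aggregation.

#' Normalize an OTU table by 16S rRNA gene copy numbers
#'
#' Divides each OTU's counts by its genome's 16S copy number, converting read
#' abundance into an approximation of organism abundance. Output stays on the
#' counts scale but is no longer integer.
#'
#' @param otu_table a `feature_table` with `scale = "counts"`.
#' @param gcm a [gene_content_matrix()] covering every OTU in the table.
#' @return a `feature_table` of normalized abundances.
#' @export
normalize_by_copy_number <- function(otu_table, gcm) {
  stopifnot(inherits(otu_table, "feature_table"), inherits(gcm, "gene_content_matrix"))
  if (otu_table$scale != "counts") komix_stop("copy-number normalization needs scale=counts")
  missing <- setdiff(otu_table$feature_ids, gcm$otu_ids)
  if (length(missing)) {
    komix_stop("OTUs absent from gene-content matrix: %s", id_list(missing))
  }
  cn <- gcm$copy_number[otu_table$feature_ids]
  feature_table(otu_table$values / cn, otu_table$feature_ids, otu_table$sample_ids,
                feature_meta = otu_table$feature_meta, scale = "counts")
}

#' Predict KO (metagenome) abundances from a normalized OTU table
#'
#' For each sample, KO abundance is the gene-content-weighted sum over OTUs:
#' `ko(k, s) = sum_o norm(o, s) * content(o, k)`. The per-OTU summands are
#' returned as a contribution table so enriched pathways can later be
#' deconvoluted into the taxa that drive them. KO rows that are zero in all
#' samples are dropped with a logged count.
#'
#' @param norm_table copy-number-normalized OTU `feature_table`.
#' @param gcm a [gene_content_matrix()].
#' @param contributions if `FALSE`, skip building the (large) contribution
#'   records and return `NULL` in their place.
#' @param round_predictions legacy-parity flag: round predicted abundances to
#'   integers (off by default; rounding discards information the downstream
#'   differential stage can use). Contributions are always unrounded.
#' @return list with `ko_table` (a `feature_table` of KOs x samples) and
#'   `contributions` (data.frame `otu_id, ko_id, sample_id, contribution`
#'   with zero contributions omitted, or `NULL`).
#' @export
predict_metagenome <- function(norm_table, gcm, contributions = TRUE,
                               round_predictions = FALSE) {
  stopifnot(inherits(norm_table, "feature_table"), inherits(gcm, "gene_content_matrix"))
  missing <- setdiff(norm_table$feature_ids, gcm$otu_ids)
  if (length(missing)) {
    komix_stop("OTUs absent from gene-content matrix: %s", id_list(missing))
  }
  content <- gcm$content[norm_table$feature_ids, , drop = FALSE]
  ko_vals <- crossprod(content, norm_table$values)  # KOs x samples
  keep <- rowSums(ko_vals) > 0
  n_drop <- sum(!keep)
  if (n_drop > 0L) komix_log("predict_metagenome: dropped %d all-zero KO row(s)", n_drop)
  ko_vals <- ko_vals[keep, , drop = FALSE]
  contrib <- NULL
  if (contributions) {
    contrib <- build_contributions(norm_table, content, rownames(ko_vals))
  }
  if (round_predictions) ko_vals <- round(ko_vals)
  list(ko_table = feature_table(ko_vals, rownames(ko_vals), colnames(ko_vals),
                                scale = "counts"),
       contributions = contrib)
}

# Long-format (otu, ko, sample, contribution) records for KOs kept in the
# prediction; zero products omitted.
build_contributions <- function(norm_table, content, kept_kos) {
  content <- content[, kept_kos, drop = FALSE]
  nz <- which(content > 0, arr.ind = TRUE)
  if (!nrow(nz)) {
    return(data.frame(otu_id = character(), ko_id = character(),
                      sample_id = character(), contribution = numeric(),
                      stringsAsFactors = FALSE))
  }
  n_samp <- ncol(norm_table$values)
  otu_idx <- rep(nz[, 1L], each = n_samp)
  ko_idx <- rep(nz[, 2L], each = n_samp)
  samp_idx <- rep.int(seq_len(n_samp), nrow(nz))
  val <- norm_table$values[cbind(otu_idx, samp_idx)] * content[cbind(otu_idx, ko_idx)]
  keep <- val > 0
  data.frame(otu_id = rownames(content)[otu_idx[keep]],
             ko_id = colnames(content)[ko_idx[keep]],
             sample_id = norm_table$sample_ids[samp_idx[keep]],
             contribution = val[keep],
             stringsAsFactors = FALSE)
}

#' Collapse a KO table into KEGG pathway abundances
#'
#' Pathway abundance is the sum of its member KOs' abundances; a KO belonging
#' to several pathways contributes its full abundance to each of them (the
#' PICRUSt `categorize_by_function` convention). Pathways with no measured
#' member KO are dropped with a logged count.
#'
#' @param ko_table a `feature_table` of KO abundances.
#' @param db a [pathway_db()].
#' @return a `feature_table` of pathways x samples.
#' @export
collapse_to_pathways <- function(ko_table, db) {
  stopifnot(inherits(ko_table, "feature_table"), inherits(db, "pathway_db"))
  measured <- lapply(db$members, intersect, x = ko_table$feature_ids)
  keep <- lengths(measured) > 0L
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    komix_log("collapse_to_pathways: dropped %d pathway(s) with no measured KO", n_drop)
  }
  measured <- measured[keep]
  if (!length(measured)) komix_stop("no pathway has any measured KO")
  vals <- matrix(0, length(measured), ncol(ko_table$values),
                 dimnames = list(names(measured), ko_table$sample_ids))
  for (i in seq_along(measured)) {
    vals[i, ] <- colSums(ko_table$values[measured[[i]], , drop = FALSE])
  }
  feature_table(vals, names(measured), ko_table$sample_ids, scale = "counts")
}

#' Aggregate an OTU table to genus level
#'
#' Sums counts over OTUs sharing the genus field of their taxonomy string
#' (see [genus_of()] for the unclassified policy). Column sums are preserved.
#'
#' @param otu_table a `feature_table` with taxonomy metadata.
#' @return a `feature_table` of genera x samples.
#' @export
aggregate_to_genus <- function(otu_table) {
  stopifnot(inherits(otu_table, "feature_table"))
  genera <- genus_of(otu_table)  # errors if taxonomy metadata is missing
  agg <- rowsum(otu_table$values, group = genera, reorder = TRUE)
  feature_table(agg, rownames(agg), otu_table$sample_ids, scale = otu_table$scale)
}
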