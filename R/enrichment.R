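# EASE-score (modified Fisher) KEGG-pathway enrichment and deconvolution of
# enriched pathways into the transcripts and taxa that drive them.

#' EASE score: conservative one-sided Fisher enrichment p-value
#'
#' The EASE variant removes one hit from the overlap before testing: the
#' 2x2 table becomes `(k-1, n-k, K-k, N-K-n+k)`, i.e. every margin shrinks
#' by one, and the p-value is the upper hypergeometric tail of that reduced
#' table. A list with one or zero hits can never score: `k <= 1` gives
#' `p = 1`. The penalty makes single-hit pathways unrankable and is always
#' at least as large as the unpenalized Fisher p. All four arguments are
#' vectorized.
#'
#' @param k hits: differential KOs in the pathway.
#' @param n list size: differential KOs in the universe.
#' @param K measured pathway size: pathway KOs in the universe.
#' @param N universe size.
#' @param variant `"ease"` (default) or `"fisher"` (no penalty).
#' @return p-value(s) in (0, 1].
#' @examples
#' ease_score(3, 10, 20, 200)
#' ease_score(1, 10, 20, 200)  # 1: a single hit never scores
#' @export
ease_score <- function(k, n, K, N, variant = c("ease", "fisher")) {
  variant <- match.arg(variant)
  m <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(as.numeric(k), m); n <- rep_len(as.numeric(n), m)
  K <- rep_len(as.numeric(K), m); N <- rep_len(as.numeric(N), m)
  bad <- k < 0 | n < 0 | K < 0 | N < 0 | k > pmin(n, K) | n > N | K > N
  if (any(bad)) {
    i <- which(bad)[1L]
    komix_stop("inconsistent enrichment margins: k=%g, n=%g, K=%g, N=%g",
               k[i], n[i], K[i], N[i])
  }
  p <- rep(1, m)
  if (variant == "fisher") {
    i <- k >= 1
    p[i] <- stats::phyper(k[i] - 1, K[i], N[i] - K[i], n[i], lower.tail = FALSE)
  } else {
    # upper tail P(X >= k-1) for X ~ Hypergeom(N-1; K-1 marked; n-1 drawn)
    i <- k > 1
    p[i] <- stats::phyper(k[i] - 2, K[i] - 1, N[i] - K[i], n[i] - 1,
                          lower.tail = FALSE)
  }
  pmin(p, 1)
}

star_label <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' Pathway enrichment of a KO set against a measured universe
#'
#' One EASE test per pathway. The universe (background) is the set of KOs
#' measured in the relevant dataset and annotated to at least one pathway;
#' pathway sizes `K` are counted inside that universe and pathways with
#' fewer than `min_size` measured KOs are skipped. List members outside the
#' universe are dropped with a warning. No multiple-testing correction is
#' applied (raw EASE p-values are reported, with star annotations at
#' 0.05 / 0.01 / 0.001).
#'
#' @param koset a [ko_set()].
#' @param db a [pathway_db()].
#' @param universe character vector of measured, pathway-annotated KO ids.
#' @param min_size minimum measured pathway size to test.
#' @param variant EASE variant, see [ease_score()].
#' @return an `enrichment_result` data.frame sorted by p: `pathway`,
#'   `pathway_name`, `comparison`, `direction`, `k`, `K`, `n`, `N`,
#'   `p_ease`, `stars`, `hit_kos` (comma-joined).
#' @export
enrich <- function(koset, db, universe, min_size = 3L, variant = "ease") {
  stopifnot(inherits(koset, "ko_set"), inherits(db, "pathway_db"))
  universe <- unique(as.character(universe))
  if (!length(universe)) komix_stop("enrichment universe is empty")
  outside <- setdiff(koset$kos, universe)
  if (length(outside)) {
    warning(sprintf("%d KO(s) outside the universe dropped from the %s_%s list",
                    length(outside), koset$comparison, koset$direction))
  }
  hits_all <- intersect(koset$kos, universe)
  n <- length(hits_all)
  N <- length(universe)
  measured <- lapply(db$members, intersect, x = universe)
  measured <- measured[lengths(measured) >= min_size]
  rows <- lapply(names(measured), function(pid) {
    pk <- measured[[pid]]
    hit <- intersect(hits_all, pk)
    data.frame(pathway = pid,
               pathway_name = unname(db$pathway_names[pid]),
               comparison = koset$comparison,
               direction = koset$direction,
               k = length(hit), K = length(pk), n = n, N = N,
               p_ease = ease_score(length(hit), n, length(pk), N, variant = variant),
               hit_kos = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(), pathway_name = character(),
                      comparison = character(), direction = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      p_ease = numeric(), hit_kos = character(),
                      stringsAsFactors = FALSE)
  }
  out$stars <- star_label(out$p_ease)
  out <- out[order(out$p_ease, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("pathway", "pathway_name", "comparison", "direction",
                 "k", "K", "n", "N", "p_ease", "stars", "hit_kos")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Deconvolute enriched pathways into contributing genes and taxa
#'
#' For each enrichment row, hit KOs are traced back to their sources: host
#' genes via the KO set's provenance (annotated with their own differential
#' direction), and microbial taxa via the per-OTU contribution records of
#' the metagenome prediction. Taxa are reported at genus level, annotated
#' with the genus-level differential direction, and ordered by their share
#' of the total contribution to the pathway's hit KOs (shares sum to 1 per
#' pathway).
#'
#' @param enr an `enrichment_result` (typically the significant rows).
#' @param contributions contribution records from [predict_metagenome()].
#' @param provenance named list KO -> sources, from the enriched [ko_set()].
#' @param gene_sets list with `up`/`down` character vectors of differential
#'   genes (direction lookup for contributing genes).
#' @param otu_genus named character vector OTU id -> genus label.
#' @param genus_sets list with `up`/`down` character vectors of differential
#'   genera.
#' @return list of class `deconvolution`: `summary` (one row per enrichment
#'   row: `pathway`, `genes`, `microbes`, `comparison` in the
#'   `<comparison>_<direction>` form), `genes` and `taxa` (long form with
#'   per-genus `share`).
#' @export
deconvolute_contributors <- function(enr, contributions, provenance,
                                     gene_sets = list(up = character(), down = character()),
                                     otu_genus = character(),
                                     genus_sets = list(up = character(), down = character())) {
  stopifnot(is.data.frame(enr))
  gene_rows <- list(); taxa_rows <- list(); summary_rows <- list()
  for (i in seq_len(nrow(enr))) {
    row <- enr[i, ]
    hit <- strsplit(row$hit_kos, ",", fixed = TRUE)[[1L]]
    hit <- hit[nzchar(hit)]
    label <- paste0(row$comparison, "_", row$direction)
    src <- provenance[hit]
    genes <- sort(unique(unlist(src)[unlist(src) != "microbiome"]))
    gdir <- ifelse(genes %in% gene_sets$up, "up",
                   ifelse(genes %in% gene_sets$down, "down", "ns"))
    mic_kos <- hit[vapply(src, function(s) "microbiome" %in% s, logical(1L))]
    taxa <- NULL
    if (length(mic_kos)) {
      sub <- contributions[contributions$ko_id %in% mic_kos, , drop = FALSE]
      uncovered <- setdiff(mic_kos, unique(sub$ko_id))
      if (length(uncovered)) {
        komix_stop("no contribution records for microbial hit KO(s): %s",
                   id_list(uncovered))
      }
      per_otu <- tapply(sub$contribution, sub$otu_id, sum)
      genus <- otu_genus[names(per_otu)]
      genus[is.na(genus)] <- "unclassified_unknown"
      per_genus <- tapply(as.numeric(per_otu), genus, sum)
      share <- as.numeric(per_genus) / sum(per_genus)
      taxa <- data.frame(pathway = row$pathway, comparison = row$comparison,
                         direction = row$direction, genus = names(per_genus),
                         share = share, stringsAsFactors = FALSE)
      taxa$genus_direction <- ifelse(taxa$genus %in% genus_sets$up, "up",
                                     ifelse(taxa$genus %in% genus_sets$down, "down", "ns"))
      taxa <- taxa[order(-taxa$share, taxa$genus), , drop = FALSE]
    }
    if (length(genes)) {
      gene_rows[[length(gene_rows) + 1L]] <-
        data.frame(pathway = row$pathway, comparison = row$comparison,
                   direction = row$direction, gene = genes,
                   gene_direction = gdir, stringsAsFactors = FALSE)
    }
    if (!is.null(taxa)) taxa_rows[[length(taxa_rows) + 1L]] <- taxa
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      pathway = if (nzchar(row$pathway_name %||% "")) row$pathway_name else row$pathway,
      genes = paste(annotate_direction(genes, gdir), collapse = ", "),
      microbes = if (is.null(taxa)) "" else
        paste(annotate_direction(taxa$genus, taxa$genus_direction), collapse = ", "),
      comparison = label, stringsAsFactors = FALSE)
  }
  structure(list(
    summary = bind_or_empty(summary_rows,
                            c("pathway", "genes", "microbes", "comparison")),
    genes = bind_or_empty(gene_rows,
                          c("pathway", "comparison", "direction", "gene", "gene_direction")),
    taxa = bind_or_empty(taxa_rows,
                         c("pathway", "comparison", "direction", "genus", "share",
                           "genus_direction"))
  ), class = "deconvolution")
}

annotate_direction <- function(ids, dirs) {
  if (!length(ids)) return(character())
  paste0(ids, ifelse(dirs == "ns", "", paste0("(", dirs, ")")))
}

bind_or_empty <- function(rows, cols) {
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  out <- as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols),
                       stringsAsFactors = FALSE)
  out
}

#' Write an enrichment result to TSV
#'
#' @param enr an `enrichment_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enr, path) {
  utils::write.table(format_numeric_df(as.data.frame(enr)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
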