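# Synthetic study generator: complete input bundles (OTU counts,
# gene-content, expression, gene->KO map, pathway memberships, design) with
# planted differential features and planted enriched pathways plus a
# ground-truth manifest, so the whole pipeline can be validated end-to-end
# with no external data.

default_groups <- function() c("NOCIA", "CIA", "MS", "MTXMS")

# Study-arm contrasts, Fig-3 order: disease vs healthy baseline, each
# therapy vs disease, and therapy vs therapy.
default_contrasts <- function() c("CIA-NOCIA", "MS-CIA", "MTXMS-CIA", "MS-MTXMS")

genus_pool <- function() {
  c("Prevotella", "Lactobacillus", "Turicibacter", "Allobaculum", "Akkermansia",
    "Parabacteroides", "Moryella", "Oscillospira", "Blautia", "Coprococcus",
    "Odoribacter", "Bacteroides", "Ruminococcus", "Clostridium",
    "Faecalibacterium", "Roseburia", "Dorea", "Sutterella", "Desulfovibrio",
    "Bifidobacterium")
}

make_sample_ids <- function(groups, n_per_group) {
  unlist(lapply(groups, function(g) sprintf("%s_%d", g, seq_len(n_per_group))))
}

make_group_vector <- function(groups, n_per_group) {
  ids <- make_sample_ids(groups, n_per_group)
  stats::setNames(rep(groups, each = n_per_group), ids)
}

# Draw negative-binomial counts with variance mu + dispersion * mu^2;
# dispersion 0 degenerates to Poisson.
rnb <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate an OTU count community with planted group effects
#'
#' Baseline relative abundances are log-normal; counts are negative-binomial
#' with variance `mu + dispersion * mu^2` around per-sample means scaled to
#' the target sequencing depth. A planted OTU has the mean of the first
#' (focal) group of its contrast multiplied by `2^(signed effect)`, so its
#' expected log2 fold change in that contrast equals the planted effect.
#' Taxonomy strings follow the 7-rank Greengenes convention with several
#' OTUs per genus (exercising genus aggregation) and a small fraction of
#' genus-unclassified OTUs.
#'
#' @param n_otus number of OTUs.
#' @param groups group labels.
#' @param n_per_group samples per group.
#' @param n_planted number of planted differential OTUs (ignored when a
#'   `planted` frame is supplied; forced to 0 when `effect_log2 = 0`).
#' @param effect_log2 planted |log2 fold change|; >= 1 recommended so
#'   planted features clear the fold-change gate.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param depth target reads per sample.
#' @param seed integer seed; fully determines the output.
#' @param contrasts contrast labels planted effects refer to.
#' @param planted optional data.frame `(otu_id, contrast, effect)` taking
#'   full control of the planting (ids must be `OTU_%04d` within range).
#' @return list: `table` (a counts `feature_table` with taxonomy),
#'   `truth` (data.frame `kind, id, contrast, effect`), `design`.
#' @export
generate_community <- function(n_otus = 300, groups = default_groups(),
                               n_per_group = 5, n_planted = 30,
                               effect_log2 = 2, dispersion = 0.1,
                               depth = 15000, seed = 1,
                               contrasts = default_contrasts(),
                               planted = NULL) {
  stopifnot(length(groups) >= 2, n_per_group >= 2)
  if (is.null(planted) && n_planted > n_otus) {
    komix_stop("n_planted (%d) exceeds n_otus (%d)", n_planted, n_otus)
  }
  contrasts <- normalize_contrasts(contrasts)
  otu_ids <- sprintf("OTU_%04d", seq_len(n_otus))
  with_seed(seed, {
    if (is.null(planted)) {
      planted <- if (effect_log2 > 0 && n_planted > 0) {
        data.frame(
          otu_id = sample(otu_ids, n_planted),
          contrast = contrasts$label[rep_len(seq_len(nrow(contrasts)), n_planted)],
          effect = effect_log2 * rep_len(c(1, -1), n_planted),
          stringsAsFactors = FALSE)
      } else {
        data.frame(otu_id = character(), contrast = character(),
                   effect = numeric(), stringsAsFactors = FALSE)
      }
    }
    base <- stats::rlnorm(n_otus, meanlog = 0, sdlog = 1.5)
    rel <- base / sum(base)
    grp <- make_group_vector(groups, n_per_group)
    mu <- matrix(rel * depth, n_otus, length(grp),
                 dimnames = list(otu_ids, names(grp)))
    if (nrow(planted)) {
      focal <- vapply(strsplit(planted$contrast, "-", fixed = TRUE), `[`, "", 1L)
      for (i in seq_len(nrow(planted))) {
        cols <- grp == focal[i]
        mu[planted$otu_id[i], cols] <- mu[planted$otu_id[i], cols] * 2^planted$effect[i]
      }
    }
    counts <- matrix(rnb(mu, dispersion), n_otus, ncol(mu), dimnames = dimnames(mu))
    pool <- genus_pool()
    gidx <- sample(rep_len(seq_along(pool), n_otus))
    genus <- pool[gidx]
    # ~5% of OTUs lack a genus call and fall back to a named family
    n_unc <- max(0L, round(0.05 * n_otus))
    unc <- if (n_unc > 0) sample.int(n_otus, n_unc) else integer()
    fam <- sprintf("Family%02d", (seq_len(n_otus) %% 7L) + 1L)
    tax <- sprintf("k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__%s;g__%s;s__",
                   fam, genus)
    tax[unc] <- sprintf("k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__%s;g__;s__",
                        fam[unc])
    table <- feature_table(counts, otu_ids, names(grp),
                           feature_meta = data.frame(taxonomy = tax,
                                                     stringsAsFactors = FALSE),
                           scale = "counts")
    truth <- if (nrow(planted)) {
      data.frame(kind = "otu", id = planted$otu_id, contrast = planted$contrast,
                 effect = planted$effect, stringsAsFactors = FALSE)
    } else {
      data.frame(kind = character(), id = character(), contrast = character(),
                 effect = numeric(), stringsAsFactors = FALSE)
    }
    list(table = table, truth = truth,
         design = study_design(grp, contrasts = contrasts))
  })
}

#' Simulate an OTU x KO gene-content matrix with 16S copy numbers
#'
#' Integer gene copies with a controlled fraction of exact zeros; 16S copy
#' numbers uniform integers in `copy_number_range`. A "pathway cassette"
#' gives a chosen KO set gene content only in chosen OTUs, which makes those
#' OTUs the sole contributors of the cassette KOs downstream — the planted
#' ground truth for deconvolution.
#'
#' @param otu_ids OTU identifiers.
#' @param n_kos number of KOs (ids `K%05d`).
#' @param sparsity fraction of zero cells in the background content, in
#'   `[0, 1)`.
#' @param copy_number_range integer range for 16S copy numbers.
#' @param seed integer seed.
#' @param cassettes optional list of `list(kos=, otus=)`: each cassette's
#'   KO columns are zeroed outside its OTUs and set positive inside.
#' @return a [gene_content_matrix()].
#' @export
generate_gene_content <- function(otu_ids, n_kos = 400, sparsity = 0.9,
                                  copy_number_range = c(1, 5), seed = 1,
                                  cassettes = NULL) {
  if (sparsity < 0 || sparsity >= 1) komix_stop("sparsity must be in [0, 1)")
  ko_ids <- sprintf("K%05d", seq_len(n_kos))
  with_seed(seed, {
    n <- length(otu_ids) * n_kos
    content <- matrix((stats::rpois(n, 1) + 1) * (stats::runif(n) >= sparsity),
                      length(otu_ids), n_kos, dimnames = list(otu_ids, ko_ids))
    for (cas in cassettes %||% list()) {
      stopifnot(all(cas$kos %in% ko_ids), all(cas$otus %in% otu_ids))
      content[, cas$kos] <- 0
      content[cas$otus, cas$kos] <-
        matrix(sample(1:3, length(cas$otus) * length(cas$kos), replace = TRUE),
               length(cas$otus), length(cas$kos))
    }
    cn <- sample(seq(copy_number_range[1L], copy_number_range[2L]),
                 length(otu_ids), replace = TRUE)
    gene_content_matrix(content, stats::setNames(as.numeric(cn), otu_ids))
  })
}

#' Simulate a log2 expression matrix with planted differential genes
#'
#' Gaussian log2 expression around per-gene baselines; a planted gene's mean
#' is shifted by the signed effect in the focal group of its contrast. A
#' many-to-many gene-to-KO map is drawn with a configurable fraction of
#' genes pointing at microbially measured KOs (so the joint KO-space
#' analysis is non-trivial); the rest map to host-only KOs.
#'
#' @param n_genes number of genes (ids `Gene%04d`).
#' @param groups,n_per_group,contrasts as in [generate_community()].
#' @param n_planted planted differential genes (0 when `effect_log2 = 0`).
#' @param effect_log2 planted |log2 shift|.
#' @param noise_sd residual SD of log2 expression.
#' @param seed integer seed.
#' @param ko_pool character vector of microbially measured KO ids a gene may
#'   map to.
#' @param shared_fraction fraction of mapping records that target `ko_pool`
#'   rather than host-only KOs.
#' @param planted optional data.frame `(gene_id, contrast, effect)`.
#' @param planted_map optional data.frame `(gene_id, ko_id)` overriding the
#'   mapping of those genes (used to wire planted genes to planted pathway
#'   KOs).
#' @return list: `table` (log2 `feature_table`), `map` ([gene_ko_map()]),
#'   `truth` (data.frame `kind, id, contrast, effect`).
#' @export
generate_expression <- function(n_genes = 600, groups = default_groups(),
                                n_per_group = 5, n_planted = 30,
                                effect_log2 = 2, noise_sd = 0.5, seed = 1,
                                contrasts = default_contrasts(),
                                ko_pool = character(), shared_fraction = 0.3,
                                planted = NULL, planted_map = NULL) {
  contrasts <- normalize_contrasts(contrasts)
  gene_ids <- sprintf("Gene%04d", seq_len(n_genes))
  with_seed(seed, {
    if (is.null(planted)) {
      planted <- if (effect_log2 > 0 && n_planted > 0) {
        data.frame(
          gene_id = sample(gene_ids, min(n_planted, n_genes)),
          contrast = contrasts$label[rep_len(seq_len(nrow(contrasts)),
                                             min(n_planted, n_genes))],
          effect = effect_log2 * rep_len(c(1, -1), min(n_planted, n_genes)),
          stringsAsFactors = FALSE)
      } else {
        data.frame(gene_id = character(), contrast = character(),
                   effect = numeric(), stringsAsFactors = FALSE)
      }
    }
    grp <- make_group_vector(groups, n_per_group)
    base <- stats::rnorm(n_genes, 8, 1.5)
    mu <- matrix(base, n_genes, length(grp), dimnames = list(gene_ids, names(grp)))
    if (nrow(planted)) {
      focal <- vapply(strsplit(planted$contrast, "-", fixed = TRUE), `[`, "", 1L)
      for (i in seq_len(nrow(planted))) {
        cols <- grp == focal[i]
        mu[planted$gene_id[i], cols] <- mu[planted$gene_id[i], cols] + planted$effect[i]
      }
    }
    y <- mu + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu), ncol(mu))
    dimnames(y) <- dimnames(mu)
    host_kos <- sprintf("KH%05d", seq_len(max(20L, round(n_genes / 3))))
    n_map <- sample(1:2, n_genes, replace = TRUE)
    map_gene <- rep(gene_ids, n_map)
    use_shared <- length(ko_pool) > 0 & stats::runif(length(map_gene)) < shared_fraction
    map_ko <- character(length(map_gene))
    if (any(use_shared)) map_ko[use_shared] <- sample(ko_pool, sum(use_shared), replace = TRUE)
    map_ko[!use_shared] <- sample(host_kos, sum(!use_shared), replace = TRUE)
    if (!is.null(planted_map) && nrow(planted_map)) {
      keep <- !(map_gene %in% planted_map$gene_id)
      map_gene <- c(map_gene[keep], planted_map$gene_id)
      map_ko <- c(map_ko[keep], planted_map$ko_id)
    }
    ord <- order(map_gene, map_ko)
    truth <- if (nrow(planted)) {
      data.frame(kind = "gene", id = planted$gene_id, contrast = planted$contrast,
                 effect = planted$effect, stringsAsFactors = FALSE)
    } else {
      data.frame(kind = character(), id = character(), contrast = character(),
                 effect = numeric(), stringsAsFactors = FALSE)
    }
    list(table = feature_table(y, gene_ids, names(grp), scale = "log2"),
         map = gene_ko_map(map_gene[ord], map_ko[ord]),
         truth = truth)
  })
}

#' Default synthetic-study configuration
#'
#' The generator's defaults define the study conditions every synthetic run
#' emulates: four arms of 5 samples sequenced at 15,000 reads, 300 OTUs with
#' negative-binomial dispersion 0.1, 400 microbial KOs at 90% content
#' sparsity, 600 host genes with residual SD 0.5, 40 pathways of 12 KOs, and
#' 3 planted pathways realized as 6-OTU cassettes plus 4 planted genes each,
#' all at |log2FC| = 2.
#'
#' @param ... overrides merged over the defaults.
#' @return named list of generator parameters.
#' @export
study_config <- function(...) {
  cfg <- list(
    groups = default_groups(), contrasts = default_contrasts(),
    n_per_group = 5,
    n_otus = 300, depth = 15000, dispersion = 0.1,
    n_kos = 400, sparsity = 0.9, copy_number_range = c(1, 5),
    n_genes = 600, noise_sd = 0.5, shared_fraction = 0.3,
    n_pathways = 40, pathway_size = 12,
    n_planted_pathways = 3, cassette_otus = 6, planted_genes_per_pathway = 4,
    n_extra_planted_otus = 10, n_extra_planted_genes = 10,
    effect_log2 = 2)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) over <- over[[1L]]
  cfg[names(over)] <- over
  cfg
}

#' Generate a complete synthetic study with planted enriched pathways
#'
#' Builds every input the pipeline consumes. Planted pathways are realized
#' as cassettes: each planted pathway's KOs receive gene content only from a
#' dedicated set of OTUs that are themselves planted differential in the
#' pathway's contrast and direction, and a few planted host genes are wired
#' to the same KOs through the gene-to-KO map. The truth manifest records
#' every planted OTU, gene and pathway with its contrast and signed effect.
#' With `effect_log2 = 0` nothing is planted (a global-null study).
#'
#' @param config a [study_config()] (or override list).
#' @param seed integer master seed; per-stage substreams are derived from it
#'   and the output is fully determined by it.
#' @param out_dir if non-NULL, the bundle is written there as the TSV files
#'   the readers consume (plus `truth.tsv`).
#' @return list of class `study_bundle`: `otu_table`, `gcm`, `expression`,
#'   `gene_ko_map`, `pathway_db`, `design`, `truth`, `config`, and (if
#'   written) `paths`.
#' @export
generate_study <- function(config = study_config(), seed = 1, out_dir = NULL) {
  cfg <- study_config(config)
  if (cfg$n_planted_pathways > 0 && cfg$effect_log2 > 0 &&
      cfg$pathway_size < 3) {
    komix_stop("planted pathway size %d is below the minimum testable size", cfg$pathway_size)
  }
  if (cfg$n_planted_pathways * cfg$pathway_size > cfg$n_kos) {
    komix_stop("planted pathways need %d KOs but only %d exist",
               cfg$n_planted_pathways * cfg$pathway_size, cfg$n_kos)
  }
  seeds <- derive_seeds(seed, 6L)
  contrasts <- normalize_contrasts(cfg$contrasts)
  otu_ids <- sprintf("OTU_%04d", seq_len(cfg$n_otus))
  ko_ids <- sprintf("K%05d", seq_len(cfg$n_kos))
  plant <- cfg$effect_log2 > 0 & cfg$n_planted_pathways > 0

  # --- choose planted structure -------------------------------------------
  planted_paths <- data.frame(kind = character(), id = character(),
                              contrast = character(), effect = numeric(),
                              stringsAsFactors = FALSE)
  cassettes <- list()
  planted_otus <- NULL
  planted_genes <- NULL
  planted_map <- NULL
  path_ids <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  if (plant) {
    sel <- with_seed(seeds[1L], {
      pp <- sample(path_ids, cfg$n_planted_pathways)
      need_otus <- cfg$n_planted_pathways * cfg$cassette_otus
      need_genes <- cfg$n_planted_pathways * cfg$planted_genes_per_pathway
      list(pp = pp,
           cas_otus = sample(otu_ids, need_otus),
           cas_kos = sample(ko_ids, cfg$n_planted_pathways * cfg$pathway_size),
           genes = sprintf("Gene%04d",
                           sample(cfg$n_genes, need_genes + cfg$n_extra_planted_genes)))
    })
    dirs <- rep_len(c(1, -1), cfg$n_planted_pathways)
    ctr <- contrasts$label[rep_len(seq_len(nrow(contrasts)), cfg$n_planted_pathways)]
    planted_otus_rows <- list(); gene_rows <- list(); map_rows <- list()
    for (j in seq_len(cfg$n_planted_pathways)) {
      kos_j <- sel$cas_kos[((j - 1L) * cfg$pathway_size + 1L):(j * cfg$pathway_size)]
      otus_j <- sel$cas_otus[((j - 1L) * cfg$cassette_otus + 1L):(j * cfg$cassette_otus)]
      genes_j <- sel$genes[((j - 1L) * cfg$planted_genes_per_pathway + 1L):
                             (j * cfg$planted_genes_per_pathway)]
      cassettes[[sel$pp[j]]] <- list(kos = kos_j, otus = otus_j)
      planted_otus_rows[[j]] <- data.frame(otu_id = otus_j, contrast = ctr[j],
                                           effect = dirs[j] * cfg$effect_log2,
                                           stringsAsFactors = FALSE)
      gene_rows[[j]] <- data.frame(gene_id = genes_j, contrast = ctr[j],
                                   effect = dirs[j] * cfg$effect_log2,
                                   stringsAsFactors = FALSE)
      map_rows[[j]] <- data.frame(gene_id = genes_j,
                                  ko_id = kos_j[seq_along(genes_j)],
                                  stringsAsFactors = FALSE)
    }
    planted_otus <- do.call(rbind, planted_otus_rows)
    planted_genes <- do.call(rbind, gene_rows)
    planted_map <- do.call(rbind, map_rows)
    planted_paths <- data.frame(kind = "pathway", id = sel$pp, contrast = ctr,
                                effect = dirs * cfg$effect_log2,
                                stringsAsFactors = FALSE)
    # extra planted features outside the cassettes (background signal)
    free_otus <- setdiff(otu_ids, planted_otus$otu_id)
    free_genes <- setdiff(sprintf("Gene%04d", seq_len(cfg$n_genes)),
                          planted_genes$gene_id)
    extra <- with_seed(seeds[2L], list(
      otus = sample(free_otus, min(cfg$n_extra_planted_otus, length(free_otus))),
      genes = sample(free_genes, min(cfg$n_extra_planted_genes, length(free_genes)))))
    if (length(extra$otus)) {
      planted_otus <- rbind(planted_otus, data.frame(
        otu_id = extra$otus,
        contrast = contrasts$label[rep_len(seq_len(nrow(contrasts)), length(extra$otus))],
        effect = cfg$effect_log2 * rep_len(c(1, -1), length(extra$otus)),
        stringsAsFactors = FALSE))
    }
    if (length(extra$genes)) {
      planted_genes <- rbind(planted_genes, data.frame(
        gene_id = extra$genes,
        contrast = contrasts$label[rep_len(seq_len(nrow(contrasts)), length(extra$genes))],
        effect = cfg$effect_log2 * rep_len(c(1, -1), length(extra$genes)),
        stringsAsFactors = FALSE))
    }
  }

  # --- emit the tables -----------------------------------------------------
  comm <- generate_community(cfg$n_otus, cfg$groups, cfg$n_per_group,
                             n_planted = 0, effect_log2 = cfg$effect_log2,
                             dispersion = cfg$dispersion, depth = cfg$depth,
                             seed = seeds[3L], contrasts = contrasts,
                             planted = planted_otus)
  gcm <- generate_gene_content(otu_ids, cfg$n_kos, cfg$sparsity,
                               cfg$copy_number_range, seed = seeds[4L],
                               cassettes = cassettes)
  expr <- generate_expression(cfg$n_genes, cfg$groups, cfg$n_per_group,
                              n_planted = 0, effect_log2 = cfg$effect_log2,
                              noise_sd = cfg$noise_sd, seed = seeds[5L],
                              contrasts = contrasts,
                              ko_pool = setdiff(ko_ids, unlist(lapply(cassettes, `[[`, "kos"))),
                              shared_fraction = cfg$shared_fraction,
                              planted = planted_genes, planted_map = planted_map)

  # pathway memberships: planted pathways are exactly their cassette KOs;
  # background pathways sample from the remaining microbial + host KOs
  host_kos <- setdiff(unique(expr$map$ko_id), ko_ids)
  bg_pool <- c(setdiff(ko_ids, unlist(lapply(cassettes, `[[`, "kos"))), host_kos)
  members <- with_seed(seeds[6L], {
    m <- list()
    for (pid in path_ids) {
      m[[pid]] <- if (pid %in% names(cassettes)) {
        cassettes[[pid]]$kos
      } else {
        sample(bg_pool, min(cfg$pathway_size, length(bg_pool)))
      }
    }
    m
  })
  db <- pathway_db(members,
                   stats::setNames(sprintf("Synthetic pathway %s", sub("^PW", "", path_ids)),
                                   path_ids))

  truth <- rbind(
    comm$truth,
    expr$truth,
    planted_paths)
  bundle <- structure(list(
    otu_table = comm$table, gcm = gcm, expression = expr$table,
    gene_ko_map = expr$map, pathway_db = db, design = comm$design,
    truth = truth, config = cfg, seed = seed), class = "study_bundle")
  if (!is.null(out_dir)) {
    bundle$paths <- write_study(bundle, out_dir)
  }
  bundle
}

#' Write a study bundle to disk as reader-compatible TSV files
#'
#' @param bundle a `study_bundle`.
#' @param out_dir output directory (created if needed).
#' @return named list of file paths.
#' @export
write_study <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- list(
    otu_table = file.path(out_dir, "otu_table.tsv"),
    gene_content = file.path(out_dir, "gene_content.tsv"),
    copy_numbers = file.path(out_dir, "copy_numbers.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    gene_ko_map = file.path(out_dir, "gene2ko.tsv"),
    pathway_db = file.path(out_dir, "pathways.tsv"),
    design = file.path(out_dir, "design.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_feature_table(bundle$otu_table, p$otu_table, id_header = "otu_id")
  write_gene_content(bundle$gcm, p$gene_content, p$copy_numbers)
  write_feature_table(bundle$expression, p$expression, id_header = "gene_id")
  write_gene_ko_map(bundle$gene_ko_map, p$gene_ko_map)
  write_pathway_db(bundle$pathway_db, p$pathway_db)
  write_design(bundle$design, p$design)
  utils::write.table(format_numeric_df(bundle$truth), p$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  p
}

#' Reload a written study bundle through the package readers
#'
#' @param dir directory written by [write_study()].
#' @param contrasts contrasts for the design (defaults to the study arms').
#' @return a `study_bundle` (without a truth manifest if `truth.tsv` is
#'   absent).
#' @export
read_study <- function(dir, contrasts = default_contrasts()) {
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    utils::read.delim(truth_path, stringsAsFactors = FALSE)
  } else NULL
  structure(list(
    otu_table = read_feature_table(file.path(dir, "otu_table.tsv"), scale = "counts"),
    gcm = read_gene_content(file.path(dir, "gene_content.tsv"),
                            file.path(dir, "copy_numbers.tsv")),
    expression = read_feature_table(file.path(dir, "expression.tsv"), scale = "log2"),
    gene_ko_map = read_gene_ko_map(file.path(dir, "gene2ko.tsv")),
    pathway_db = read_pathway_db(file.path(dir, "pathways.tsv")),
    design = read_design(file.path(dir, "design.tsv"), contrasts = contrasts),
    truth = truth), class = "study_bundle")
}
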