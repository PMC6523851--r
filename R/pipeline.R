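# End-to-end orchestration: inference -> differential -> KO mapping ->
# enrichment (per omic and joint) -> deconvolution -> report files.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    komix_stop("stage %s: %s", name, conditionMessage(e))
  })
}

#' Analyse a study bundle in memory
#'
#' Runs the full analysis on an in-memory bundle (as produced by
#' [generate_study()] or [read_study()]): copy-number normalization, KO
#' prediction with contributions, pathway collapse, genus aggregation, the
#' uniform differential analysis on OTU / genus / KO / expression tables,
#' projection of host genes into KO space, per-direction EASE enrichment for
#' the microbiome (GI), host (PBMC) and joint KO sets, and deconvolution of
#' the significant joint pathways into contributing genes and genera.
#'
#' The enrichment universe of each omic is the set of KOs measured in that
#' omic and annotated to at least one pathway; the joint run uses the union
#' of the two universes.
#'
#' @param bundle a `study_bundle` (tables, map, pathway db, design).
#' @param lfc_cut,p_cut,p_gate differential gate, see [select_differential()].
#' @param min_pathway_size minimum measured pathway size for enrichment.
#' @param ease_variant `"ease"` or `"fisher"`.
#' @param ci_level confidence level for log-FC intervals.
#' @param enr_p_cut EASE p threshold below which joint pathways are
#'   deconvoluted.
#' @param round_predictions legacy flag of [predict_metagenome()].
#' @return list of class `study_analysis` with elements `ko_table`,
#'   `contributions`, `pathway_table`, `genus_table`, `diff` (list per
#'   table), `ko_sets`, `enrichment` (stacked `enrichment_result` with an
#'   `omic` column), `deconvolution`, `counts` (filter bookkeeping).
#' @export
run_study_analysis <- function(bundle, lfc_cut = 1, p_cut = 0.05,
                               p_gate = "lte", min_pathway_size = 3L,
                               ease_variant = "ease", ci_level = 0.95,
                               enr_p_cut = 0.05, round_predictions = FALSE) {
  design <- bundle$design
  if (is.null(design$contrasts) || !nrow(design$contrasts)) {
    komix_stop("stage design: no contrasts configured")
  }
  norm <- stage("normalize", normalize_by_copy_number(bundle$otu_table, bundle$gcm))
  pm <- stage("predict_metagenome",
              predict_metagenome(norm, bundle$gcm, contributions = TRUE,
                                 round_predictions = round_predictions))
  pathway_table <- stage("collapse_to_pathways",
                         collapse_to_pathways(pm$ko_table, bundle$pathway_db))
  genus_table <- stage("aggregate_to_genus", aggregate_to_genus(bundle$otu_table))
  gate <- list(lfc_cut = lfc_cut, p_cut = p_cut, p_gate = p_gate)
  diff <- list(
    otu = stage("differential_otu",
                run_differential(bundle$otu_table, design, ci_level = ci_level,
                                 lfc_cut = lfc_cut, p_cut = p_cut, p_gate = p_gate)),
    genus = stage("differential_genus",
                  run_differential(genus_table, design, ci_level = ci_level,
                                   lfc_cut = lfc_cut, p_cut = p_cut, p_gate = p_gate)),
    ko = stage("differential_ko",
               run_differential(pm$ko_table, design, ci_level = ci_level,
                                lfc_cut = lfc_cut, p_cut = p_cut, p_gate = p_gate)),
    expression = stage("differential_expression",
                       run_differential(bundle$expression, design, use_voom = FALSE,
                                        ci_level = ci_level, lfc_cut = lfc_cut,
                                        p_cut = p_cut, p_gate = p_gate)))

  annotated <- unique(unlist(bundle$pathway_db$members))
  mic_universe <- intersect(pm$ko_table$feature_ids, annotated)
  host_measured_kos <- unique(bundle$gene_ko_map$ko_id[
    bundle$gene_ko_map$gene_id %in% bundle$expression$feature_ids])
  host_universe <- intersect(host_measured_kos, annotated)
  joint_universe <- union(mic_universe, host_universe)
  otu_genus <- stats::setNames(genus_of(bundle$otu_table), bundle$otu_table$feature_ids)

  enr_rows <- list(); decon <- list(); ko_sets <- list()
  for (i in seq_len(nrow(design$contrasts))) {
    lab <- design$contrasts$label[i]
    d_expr <- diff$expression[diff$expression$contrast == lab, ]
    d_ko <- diff$ko[diff$ko$contrast == lab, ]
    gene_sel <- do.call(select_differential, c(list(d_expr), gate))
    host <- stage("map_genes_to_kos",
                  map_genes_to_kos(gene_sel$up, gene_sel$down, bundle$gene_ko_map,
                                   comparison = lab))
    mic <- do.call(kos_from_microbiome, c(list(d_ko), gate))
    joint <- stage("joint_union", joint_union(host, mic))
    ko_sets[[lab]] <- list(GI = mic, PBMC = host, JOINT = joint)
    for (omic in c("GI", "PBMC", "JOINT")) {
      uni <- switch(omic, GI = mic_universe, PBMC = host_universe,
                    JOINT = joint_universe)
      sets <- ko_sets[[lab]][[omic]]
      for (dir in c("ALL", "UP", "DOWN")) {
        e <- stage("enrich",
                   suppressWarnings(enrich(sets[[dir]], bundle$pathway_db, uni,
                                           min_size = min_pathway_size,
                                           variant = ease_variant)))
        if (nrow(e)) e$omic <- omic
        enr_rows[[length(enr_rows) + 1L]] <- e
      }
    }
    # deconvolute the significant joint pathways (ALL/UP/DOWN) for this contrast
    joint_hits <- do.call(rbind, enr_rows[(length(enr_rows) - 2L):length(enr_rows)])
    joint_hits <- joint_hits[joint_hits$p_ease <= enr_p_cut, , drop = FALSE]
    if (nrow(joint_hits)) {
      genus_sel <- do.call(select_differential,
                           c(list(diff$genus[diff$genus$contrast == lab, ]), gate))
      prov <- joint$ALL$provenance
      decon[[lab]] <- stage("deconvolute",
        deconvolute_contributors(joint_hits, pm$contributions, prov,
                                 gene_sets = gene_sel, otu_genus = otu_genus,
                                 genus_sets = genus_sel))
    }
  }
  enrichment <- do.call(rbind, enr_rows)
  rownames(enrichment) <- NULL
  class(enrichment) <- c("enrichment_result", "data.frame")
  deconvolution <- list(
    summary = bind_or_empty(lapply(decon, `[[`, "summary"),
                            c("pathway", "genes", "microbes", "comparison")),
    genes = bind_or_empty(lapply(decon, `[[`, "genes"),
                          c("pathway", "comparison", "direction", "gene", "gene_direction")),
    taxa = bind_or_empty(lapply(decon, `[[`, "taxa"),
                         c("pathway", "comparison", "direction", "genus", "share",
                           "genus_direction")))
  counts <- list(
    n_otus = nrow(bundle$otu_table$values),
    n_kos_predicted = nrow(pm$ko_table$values),
    n_pathways_measured = nrow(pathway_table$values),
    n_genera = nrow(genus_table$values),
    n_genes = nrow(bundle$expression$values),
    universe_gi = length(mic_universe),
    universe_pbmc = length(host_universe),
    universe_joint = length(joint_universe),
    selected = lapply(diff, function(d) {
      tab <- table(d$contrast, d$direction)
      as.data.frame(tab, stringsAsFactors = FALSE)
    }))
  structure(list(ko_table = pm$ko_table, contributions = pm$contributions,
                 pathway_table = pathway_table, genus_table = genus_table,
                 diff = diff, ko_sets = ko_sets, enrichment = enrichment,
                 deconvolution = deconvolution, counts = counts),
            class = "study_analysis")
}

#' Pathway x condition significance matrix
#'
#' Pivots enrichment rows into a pathways-by-(comparison, direction) matrix
#' of EASE p-values with star annotations, the layout of the significance
#' heatmaps (rows: enriched functions; columns: compared conditions labelled
#' Up/Down/All).
#'
#' @param enr an `enrichment_result` (one omic).
#' @return list: `p` (data.frame, `pathway` + one numeric column per
#'   `comparison_direction`), `annotated` (same shape, `"p stars"` strings).
#' @export
render_significance_matrix <- function(enr) {
  if (!nrow(enr)) {
    empty <- data.frame(pathway = character(), stringsAsFactors = FALSE)
    return(list(p = empty, annotated = empty))
  }
  enr$cond <- paste0(enr$comparison, "_", enr$direction)
  paths <- sort(unique(enr$pathway))
  conds <- unique(enr$cond)
  p <- matrix(NA_real_, length(paths), length(conds),
              dimnames = list(paths, conds))
  p[cbind(match(enr$pathway, paths), match(enr$cond, conds))] <- enr$p_ease
  ann <- matrix("", length(paths), length(conds), dimnames = dimnames(p))
  ann[] <- ifelse(is.na(p), "", paste0(sprintf("%.4g", p), star_label(p)))
  list(p = data.frame(pathway = paths, p, check.names = FALSE,
                      stringsAsFactors = FALSE, row.names = NULL),
       annotated = data.frame(pathway = paths, ann, check.names = FALSE,
                              stringsAsFactors = FALSE, row.names = NULL))
}

write_matrix_tsv <- function(df, path) {
  utils::write.table(format_numeric_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' The configuration (a list or a YAML file) either names the input files
#' (`inputs:` with `otu_table`, `gene_content`, `copy_numbers`,
#' `expression`, `gene_ko_map`, `pathway_db`, `design`) or requests a
#' synthetic study (`simulate:` with [study_config()] fields), plus
#' `contrasts`, a `seed`, and optional `thresholds` (`lfc_cut`, `p_cut`,
#' `p_gate`, `min_pathway_size`, `ease_variant`, `ci_level`, `enr_p_cut`).
#' All result tables, significance matrices, a run log and a manifest
#' (embedding the configuration verbatim and the record counts at every
#' filter) are written to `out_dir`. Outputs are byte-identical across runs
#' with the same configuration and seed.
#'
#' @param config list or path to a YAML file.
#' @param out_dir output directory.
#' @return the `study_analysis`, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  old_opt <- options(komix.log_con = log_con)
  on.exit({ options(old_opt); close(log_con) }, add = TRUE)

  seed <- config$seed %||% 1L
  contrasts <- config$contrasts %||% default_contrasts()
  th <- config$thresholds %||% list()
  lfc_cut <- th$lfc_cut %||% 1
  p_cut <- th$p_cut %||% 0.05
  p_gate <- th$p_gate %||% "lte"
  min_pathway_size <- th$min_pathway_size %||% 3L
  ease_variant <- th$ease_variant %||% "ease"
  ci_level <- th$ci_level %||% 0.95
  enr_p_cut <- th$enr_p_cut %||% 0.05
  round_predictions <- isTRUE(th$round_predictions)

  if (!is.null(config$simulate)) {
    sim_cfg <- study_config(c(config$simulate, list(contrasts = contrasts)))
    bundle <- stage("simulate", generate_study(sim_cfg, seed = seed))
    komix_log("simulate: generated study with seed %d", seed)
  } else if (!is.null(config$inputs)) {
    ip <- config$inputs
    need <- c("otu_table", "gene_content", "copy_numbers", "expression",
              "gene_ko_map", "pathway_db", "design")
    miss <- setdiff(need, names(ip))
    if (length(miss)) komix_stop("stage config: missing input path(s): %s", id_list(miss))
    bundle <- stage("read_inputs", structure(list(
      otu_table = read_feature_table(ip$otu_table, scale = "counts"),
      gcm = read_gene_content(ip$gene_content, ip$copy_numbers),
      expression = read_feature_table(ip$expression, scale = "log2"),
      gene_ko_map = read_gene_ko_map(ip$gene_ko_map),
      pathway_db = read_pathway_db(ip$pathway_db),
      design = read_design(ip$design, contrasts = contrasts),
      truth = NULL), class = "study_bundle"))
  } else {
    komix_stop("stage config: config needs either 'simulate' or 'inputs'")
  }
  bundle$design <- stage("config", study_design(bundle$design$groups,
                                                contrasts = contrasts))

  res <- run_study_analysis(bundle, lfc_cut = lfc_cut, p_cut = p_cut,
                            p_gate = p_gate, min_pathway_size = min_pathway_size,
                            ease_variant = ease_variant, ci_level = ci_level,
                            enr_p_cut = enr_p_cut,
                            round_predictions = round_predictions)

  if (!is.null(config$simulate)) {
    write_study(bundle, file.path(out_dir, "inputs"))
  }
  write_feature_table(res$ko_table, file.path(out_dir, "ko_table.tsv"),
                      id_header = "ko_id")
  write_feature_table(res$pathway_table, file.path(out_dir, "pathway_table.tsv"),
                      id_header = "pathway_id")
  write_feature_table(res$genus_table, file.path(out_dir, "genus_table.tsv"),
                      id_header = "genus")
  utils::write.table(format_numeric_df(res$contributions),
                     file.path(out_dir, "contributions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  for (nm in names(res$diff)) {
    write_differential(res$diff[[nm]], file.path(out_dir, paste0("diff_", nm, ".tsv")))
  }
  write_enrichment(res$enrichment, file.path(out_dir, "enrichment.tsv"))
  write_matrix_tsv(res$deconvolution$summary, file.path(out_dir, "deconvolution.tsv"))
  write_matrix_tsv(res$deconvolution$taxa, file.path(out_dir, "deconvolution_taxa.tsv"))
  write_matrix_tsv(res$deconvolution$genes, file.path(out_dir, "deconvolution_genes.tsv"))
  for (omic in unique(res$enrichment$omic)) {
    sm <- render_significance_matrix(res$enrichment[res$enrichment$omic == omic, ])
    write_matrix_tsv(sm$p, file.path(out_dir, sprintf("significance_%s_p.tsv", omic)))
    write_matrix_tsv(sm$annotated,
                     file.path(out_dir, sprintf("significance_%s_stars.tsv", omic)))
  }
  manifest <- list(
    package = "komix",
    version = as.character(utils::packageVersion("komix")),
    seed = seed,
    thresholds = list(lfc_cut = lfc_cut, p_cut = p_cut, p_gate = p_gate,
                      min_pathway_size = min_pathway_size,
                      ease_variant = ease_variant, ci_level = ci_level,
                      enr_p_cut = enr_p_cut),
    config = config,
    counts = res$counts[c("n_otus", "n_kos_predicted", "n_pathways_measured",
                          "n_genera", "n_genes", "universe_gi", "universe_pbmc",
                          "universe_joint")])
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  komix_log("pipeline complete: %d enrichment rows, %d deconvoluted pathways",
            nrow(res$enrichment), nrow(res$deconvolution$summary))
  invisible(res)
}
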