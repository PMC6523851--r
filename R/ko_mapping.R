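# Projection of host differential genes into KO space, and direct KO-set
# extraction from the microbiome differential results. Both omics end up as
# directional KO sets (ALL / UP / DOWN) with per-KO provenance, the common
# currency of the enrichment stage.

#' Directional KO set with provenance
#'
#' @param comparison contrast label, e.g. `"MS-CIA"`.
#' @param direction one of `"ALL"`, `"UP"`, `"DOWN"` — whether the set holds
#'   all differential KOs, only increased, or only reduced ones.
#' @param kos character vector of KO ids.
#' @param provenance named list: KO id -> character vector of source ids
#'   (gene symbols, or `"microbiome"`); required non-empty for every member.
#' @param conflicts KOs excluded from UP/DOWN because their sources disagree
#'   on direction (kept in ALL).
#' @return object of class `ko_set`.
#' @export
ko_set <- function(comparison, direction = c("ALL", "UP", "DOWN"), kos,
                   provenance, conflicts = character()) {
  direction <- match.arg(direction)
  kos <- sort(unique(as.character(kos)))
  miss <- setdiff(kos, names(provenance)[lengths(provenance) > 0L])
  if (length(miss)) komix_stop("ko_set: members without provenance: %s", id_list(miss))
  structure(list(comparison = comparison, direction = direction, kos = kos,
                 provenance = provenance[kos], conflicts = sort(unique(conflicts))),
            class = "ko_set")
}

#' @export
print.ko_set <- function(x, ...) {
  cat(sprintf("ko_set %s_%s: %d KOs (%d conflict-flagged)\n",
              x$comparison, x$direction, length(x$kos), length(x$conflicts)))
  invisible(x)
}

#' Map host differential gene sets into KO space
#'
#' A KO enters the UP (resp. DOWN) set if any up- (resp. down-) regulated
#' gene maps to it. A KO reached from both an up and a down gene is flagged
#' as a direction conflict: it stays in ALL but is excluded from UP and
#' DOWN. Genes with no mapping record are dropped with a logged count.
#'
#' @param genes_up,genes_down disjoint character vectors of gene ids.
#' @param map a [gene_ko_map()].
#' @param comparison contrast label carried into the resulting sets.
#' @return list of three [ko_set()]s: `ALL`, `UP`, `DOWN`.
#' @export
map_genes_to_kos <- function(genes_up, genes_down, map, comparison = "") {
  if (!inherits(map, "gene_ko_map") || !nrow(map)) komix_stop("gene->KO map is empty")
  overlap <- intersect(genes_up, genes_down)
  if (length(overlap)) {
    komix_stop("gene(s) present in both up and down sets: %s", id_list(overlap))
  }
  genes <- c(genes_up, genes_down)
  sub <- map[map$gene_id %in% genes, , drop = FALSE]
  unmapped <- setdiff(genes, sub$gene_id)
  if (length(unmapped)) {
    komix_log("map_genes_to_kos: %d gene(s) with no KO mapping dropped", length(unmapped))
  }
  prov <- split(sub$gene_id, sub$ko_id)
  prov <- lapply(prov, function(x) sort(unique(x)))
  kos_up <- unique(sub$ko_id[sub$gene_id %in% genes_up])
  kos_down <- unique(sub$ko_id[sub$gene_id %in% genes_down])
  conflicts <- intersect(kos_up, kos_down)
  list(
    ALL = ko_set(comparison, "ALL", union(kos_up, kos_down), prov, conflicts),
    UP = ko_set(comparison, "UP", setdiff(kos_up, conflicts), prov, conflicts),
    DOWN = ko_set(comparison, "DOWN", setdiff(kos_down, conflicts), prov, conflicts)
  )
}

#' Extract directional KO sets from a microbiome KO differential result
#'
#' Thresholded selection (see [select_differential()]) of the KO features;
#' provenance of every member is `"microbiome"`.
#'
#' @param diff a `differential_result` on a KO table, single contrast.
#' @param lfc_cut,p_cut,p_gate gate parameters, see [select_differential()].
#' @return list of three [ko_set()]s: `ALL`, `UP`, `DOWN`.
#' @export
kos_from_microbiome <- function(diff, lfc_cut = 1, p_cut = 0.05,
                                p_gate = c("lte", "lt")) {
  p_gate <- match.arg(p_gate)
  comparison <- unique(diff$contrast)
  if (length(comparison) != 1L) {
    komix_stop("kos_from_microbiome expects a single-contrast result, got: %s",
               id_list(comparison))
  }
  sel <- select_differential(diff, lfc_cut, p_cut, p_gate)
  all_kos <- union(sel$up, sel$down)
  prov <- stats::setNames(rep(list("microbiome"), length(all_kos)), all_kos)
  list(
    ALL = ko_set(comparison, "ALL", all_kos, prov),
    UP = ko_set(comparison, "UP", sel$up, prov),
    DOWN = ko_set(comparison, "DOWN", sel$down, prov)
  )
}

#' Join host and microbiome KO sets for the joint analysis
#'
#' Per-direction set union with merged provenance. A KO that is UP in one
#' omic and DOWN in the other is a cross-omic direction conflict: it is kept
#' in the joint ALL set, flagged, and excluded from joint UP and DOWN —
#' the same policy as within-omic gene conflicts.
#'
#' @param host,microbiome lists of three [ko_set()]s (`ALL`, `UP`, `DOWN`)
#'   for the same comparison.
#' @return list of three joint [ko_set()]s.
#' @export
joint_union <- function(host, microbiome) {
  for (side in list(host, microbiome)) {
    stopifnot(all(c("ALL", "UP", "DOWN") %in% names(side)))
  }
  if (!identical(host$ALL$comparison, microbiome$ALL$comparison)) {
    komix_stop("joint_union: comparison labels differ ('%s' vs '%s')",
               host$ALL$comparison, microbiome$ALL$comparison)
  }
  comparison <- host$ALL$comparison
  prov <- merge_provenance(host$ALL$provenance, microbiome$ALL$provenance)
  up <- union(host$UP$kos, microbiome$UP$kos)
  down <- union(host$DOWN$kos, microbiome$DOWN$kos)
  cross <- intersect(up, down)
  conflicts <- sort(unique(c(host$ALL$conflicts, microbiome$ALL$conflicts, cross)))
  all_kos <- union(host$ALL$kos, microbiome$ALL$kos)
  list(
    ALL = ko_set(comparison, "ALL", all_kos, prov, conflicts),
    UP = ko_set(comparison, "UP", setdiff(up, cross), prov, conflicts),
    DOWN = ko_set(comparison, "DOWN", setdiff(down, cross), prov, conflicts)
  )
}

merge_provenance <- function(a, b) {
  kos <- union(names(a), names(b))
  out <- lapply(kos, function(k) sort(unique(c(a[[k]], b[[k]]))))
  names(out) <- kos
  out
}
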