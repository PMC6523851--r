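# Readers and writers for every table the pipeline touches.
#
# Dialect: tab-separated, UTF-8, '#' lines are comments (the QIIME/PICRUSt
# legacy table convention). First column of a feature table is the feature
# id, header row holds sample ids; a column named "taxonomy" (any case) is
# moved into feature_meta. Values are written with %.17g so a write/read
# round trip is bit-exact.

read_tsv_raw <- function(path, header = TRUE) {
  if (!file.exists(path)) komix_stop("file not found: %s", path)
  df <- utils::read.delim(path, header = header, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, fileEncoding = "UTF-8",
                          blank.lines.skip = TRUE)
  if (nrow(df) == 0L) komix_stop("empty file: %s", path)
  df
}

#' Read a feature-by-sample table from TSV
#'
#' @param path TSV file: first column feature ids, header row sample ids,
#'   optional `taxonomy` column, `#` comment lines ignored.
#' @param scale `"counts"` or `"log2"` — the declared scale of the values.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, scale = c("counts", "log2")) {
  scale <- match.arg(scale)
  df <- read_tsv_raw(path)
  if (ncol(df) < 2L) komix_stop("feature table %s needs >= 2 columns", path)
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  tax_col <- which(tolower(colnames(body)) == "taxonomy")
  meta <- NULL
  if (length(tax_col)) {
    meta <- data.frame(taxonomy = as.character(body[[tax_col[1L]]]),
                       stringsAsFactors = FALSE)
    body <- body[, -tax_col, drop = FALSE]
  }
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad_cells <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(df) && length(bad_cells) && nrow(bad_cells)) {
    komix_stop("non-numeric value '%s' at feature '%s', column '%s' in %s",
               as.matrix(body)[bad_cells[1L, 1L], bad_cells[1L, 2L]],
               ids[bad_cells[1L, 1L]], colnames(body)[bad_cells[1L, 2L]], path)
  }
  feature_table(num, feature_ids = ids, sample_ids = colnames(body),
                feature_meta = meta, scale = scale)
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]: values serialized at full double
#' precision, taxonomy metadata restored as a trailing `taxonomy` column.
#'
#' @param ft a `feature_table`.
#' @param path output path.
#' @param id_header header for the id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, id_header = "feature_id") {
  stopifnot(inherits(ft, "feature_table"))
  vals <- apply(ft$values, 2L, function(col) sprintf("%.17g", col))
  if (nrow(ft$values) == 1L) vals <- matrix(vals, nrow = 1L)
  out <- data.frame(ft$feature_ids, vals, stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out) <- c(id_header, ft$sample_ids)
  if (!is.null(ft$feature_meta) && "taxonomy" %in% colnames(ft$feature_meta)) {
    out$taxonomy <- ft$feature_meta$taxonomy
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' OTU gene-content matrix with 16S copy numbers
#'
#' Couples the predicted per-genome KO gene copies of each OTU with its 16S
#' rRNA gene copy number, the two ingredients of metagenome prediction.
#'
#' @param content non-negative numeric matrix, OTUs x KOs, dimnames required.
#' @param copy_number named positive numeric vector covering every OTU in
#'   `content`.
#' @return an object of class `gene_content_matrix`.
#' @export
gene_content_matrix <- function(content, copy_number) {
  if (!is.matrix(content)) content <- as.matrix(content)
  storage.mode(content) <- "double"
  otus <- rownames(content); kos <- colnames(content)
  if (is.null(otus) || is.null(kos)) komix_stop("gene content matrix needs OTU rownames and KO colnames")
  if (anyDuplicated(otus)) komix_stop("duplicate OTU ids: %s", id_list(otus[duplicated(otus)]))
  if (anyDuplicated(kos)) komix_stop("duplicate KO ids: %s", id_list(kos[duplicated(kos)]))
  if (any(content < 0) || anyNA(content)) komix_stop("gene content must be non-negative and complete")
  missing <- setdiff(otus, names(copy_number))
  if (length(missing)) {
    komix_stop("OTUs missing a 16S copy number: %s", id_list(missing))
  }
  copy_number <- copy_number[otus]
  if (any(!is.finite(copy_number)) || any(copy_number <= 0)) {
    bad <- otus[!is.finite(copy_number) | copy_number <= 0]
    komix_stop("non-positive 16S copy number for: %s", id_list(bad))
  }
  structure(list(otu_ids = otus, ko_ids = kos, content = content,
                 copy_number = copy_number),
            class = "gene_content_matrix")
}

#' Read a gene-content matrix and per-OTU 16S copy numbers
#'
#' @param content_path TSV, OTUs x KOs, first column OTU id.
#' @param copy_number_path two-column TSV `(otu_id, copy_number)`.
#' @return a [gene_content_matrix()].
#' @export
read_gene_content <- function(content_path, copy_number_path) {
  cdf <- read_tsv_raw(content_path)
  content <- as.matrix(cdf[, -1L, drop = FALSE])
  storage.mode(content) <- "double"
  rownames(content) <- as.character(cdf[[1L]])
  cn <- read_tsv_raw(copy_number_path)
  if (ncol(cn) < 2L) komix_stop("copy-number file needs 2 columns")
  copy_number <- as.numeric(cn[[2L]])
  names(copy_number) <- as.character(cn[[1L]])
  gene_content_matrix(content, copy_number)
}

#' Pathway membership database
#'
#' @param members named list: pathway id -> character vector of member KO ids.
#' @param pathway_names optional named character vector of display names.
#' @return an object of class `pathway_db`.
#' @export
pathway_db <- function(members, pathway_names = NULL) {
  if (!length(members)) komix_stop("pathway database is empty")
  if (any(!nzchar(names(members)))) komix_stop("pathway ids must be non-empty")
  empty <- names(members)[lengths(members) == 0L]
  if (length(empty)) komix_stop("pathways with empty membership: %s", id_list(empty))
  members <- lapply(members, function(x) sort(unique(as.character(x))))
  nm <- names(members)
  if (is.null(pathway_names)) pathway_names <- stats::setNames(nm, nm)
  structure(list(members = members, pathway_names = pathway_names[nm]),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways, %d distinct KOs\n",
              length(x$members), length(unique(unlist(x$members)))))
  invisible(x)
}

read_two_col <- function(path, what) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 2L) komix_stop("%s file %s needs 2 columns", what, path)
  df <- data.frame(a = as.character(df[[1L]]), b = as.character(df[[2L]]),
                   stringsAsFactors = FALSE)
  ndup <- sum(duplicated(df))
  if (ndup > 0L) {
    komix_log("%s: collapsed %d duplicate record(s) in %s", what, ndup, path)
    df <- unique(df)
  }
  df
}

#' Read a pathway membership file
#'
#' Two-column TSV `(pathway_id, ko_id)`; an optional third column carries the
#' pathway display name. Exact duplicate rows are collapsed with a logged
#' warning.
#'
#' @param path file path.
#' @return a [pathway_db()].
#' @export
read_pathway_db <- function(path) {
  raw <- read_tsv_raw(path)
  if (ncol(raw) < 2L) komix_stop("pathway file %s needs 2 columns", path)
  df <- read_two_col(path, "pathway_db")
  members <- split(df$b, df$a)
  pnames <- NULL
  if (ncol(raw) >= 3L) {
    pnames <- tapply(as.character(raw[[3L]]), as.character(raw[[1L]]), `[`, 1L)
    pnames <- stats::setNames(as.character(pnames), names(pnames))
  }
  pathway_db(members, pnames)
}

#' Read a gene-to-KO mapping file
#'
#' Two-column TSV `(gene_id, ko_id)`, many-to-many allowed; exact duplicates
#' collapsed with a logged warning.
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `ko_id`, class `gene_ko_map`.
#' @export
read_gene_ko_map <- function(path) {
  df <- read_two_col(path, "gene_ko_map")
  gene_ko_map(df$a, df$b)
}

#' @rdname read_gene_ko_map
#' @param gene_id,ko_id character vectors of equal length.
#' @export
gene_ko_map <- function(gene_id, ko_id) {
  df <- unique(data.frame(gene_id = as.character(gene_id),
                          ko_id = as.character(ko_id),
                          stringsAsFactors = FALSE))
  if (!nrow(df)) komix_stop("gene->KO map is empty")
  class(df) <- c("gene_ko_map", "data.frame")
  df
}

#' Sample-to-group design with pairwise contrasts
#'
#' A contrast `(A, B)`, labelled `"A-B"`, means "A versus B" with
#' log2 fold change = mean(A) - mean(B).
#'
#' @param groups named character vector: sample id -> group label.
#' @param contrasts data.frame with columns `A`, `B`, or a character vector
#'   of `"A-B"` labels; `NULL` keeps no contrasts (must be supplied before
#'   fitting).
#' @return an object of class `study_design`.
#' @export
study_design <- function(groups, contrasts = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    komix_stop("design: sample ids (names of groups) are required")
  }
  if (anyDuplicated(names(groups))) {
    komix_stop("design: duplicate sample ids: %s",
               id_list(names(groups)[duplicated(names(groups))]))
  }
  groups <- stats::setNames(as.character(groups), names(groups))
  sizes <- table(groups)
  singletons <- names(sizes)[sizes < 2L]
  if (length(singletons)) {
    komix_stop("design: group(s) with fewer than 2 samples: %s", id_list(singletons))
  }
  contrasts <- normalize_contrasts(contrasts)
  if (!is.null(contrasts)) {
    unknown <- setdiff(unique(c(contrasts$A, contrasts$B)), unique(groups))
    if (length(unknown)) {
      komix_stop("design: contrast group(s) absent from design: %s", id_list(unknown))
    }
  }
  structure(list(groups = groups, contrasts = contrasts), class = "study_design")
}

normalize_contrasts <- function(contrasts) {
  if (is.null(contrasts)) return(NULL)
  if (is.character(contrasts)) {
    parts <- strsplit(contrasts, "-", fixed = TRUE)
    bad <- contrasts[lengths(parts) != 2L]
    if (length(bad)) komix_stop("contrast labels must be 'A-B': %s", id_list(bad))
    contrasts <- data.frame(A = vapply(parts, `[`, "", 1L),
                            B = vapply(parts, `[`, "", 2L),
                            stringsAsFactors = FALSE)
  }
  contrasts <- as.data.frame(contrasts, stringsAsFactors = FALSE)
  stopifnot(all(c("A", "B") %in% colnames(contrasts)))
  contrasts$label <- paste0(contrasts$A, "-", contrasts$B)
  contrasts[, c("A", "B", "label")]
}

#' Read a sample-group design file
#'
#' Two-column TSV `(sample_id, group)`.
#'
#' @param path file path.
#' @param contrasts optional contrasts, see [study_design()].
#' @return a [study_design()].
#' @export
read_design <- function(path, contrasts = NULL) {
  df <- read_two_col(path, "design")
  if (anyDuplicated(df$a)) {
    komix_stop("design: sample(s) assigned to more than one group: %s",
               id_list(unique(df$a[duplicated(df$a)])))
  }
  study_design(stats::setNames(df$b, df$a), contrasts = contrasts)
}

#' Write pathway membership, gene->KO map, or design to TSV
#'
#' @param db a `pathway_db`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  df <- data.frame(
    pathway_id = rep(names(db$members), lengths(db$members)),
    ko_id = unlist(db$members, use.names = FALSE),
    pathway_name = rep(unname(db$pathway_names), lengths(db$members)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pathway_db
#' @param map a `gene_ko_map`.
#' @export
write_gene_ko_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pathway_db
#' @param design a `study_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  df <- data.frame(sample_id = names(design$groups), group = unname(design$groups),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_pathway_db
#' @param gcm a `gene_content_matrix`.
#' @param content_path,copy_number_path output paths.
#' @export
write_gene_content <- function(gcm, content_path, copy_number_path) {
  stopifnot(inherits(gcm, "gene_content_matrix"))
  out <- data.frame(otu_id = gcm$otu_ids,
                    apply(gcm$content, 2L, function(col) sprintf("%.17g", col)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out) <- c("otu_id", gcm$ko_ids)
  utils::write.table(out, content_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  cn <- data.frame(otu_id = gcm$otu_ids,
                   copy_number = sprintf("%.17g", gcm$copy_number),
                   stringsAsFactors = FALSE)
  utils::write.table(cn, copy_number_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(content_path)
}

#' Read a BIOM-format OTU table (convenience adapter)
#'
#' Requires the optional `biomformat` package; converts a BIOM file into the
#' package's native [feature_table()] with any `taxonomy` observation
#' metadata collapsed to a Greengenes-style string.
#'
#' @param path BIOM file.
#' @param scale declared scale of the values.
#' @return a [feature_table()].
#' @export
read_biom_table <- function(path, scale = "counts") {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    komix_stop("read_biom_table needs the 'biomformat' package")
  }
  b <- biomformat::read_biom(path)
  vals <- as(biomformat::biom_data(b), "matrix")
  meta <- NULL
  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  if (!is.null(om)) {
    tax <- if (is.data.frame(om)) {
      apply(om, 1L, paste, collapse = ";")
    } else {
      vapply(om, function(x) paste(unlist(x), collapse = ";"), character(1L))
    }
    meta <- data.frame(taxonomy = unname(tax), stringsAsFactors = FALSE)
  }
  feature_table(vals, rownames(vals), colnames(vals), feature_meta = meta,
                scale = scale)
}
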