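#' Feature-by-sample abundance table
#'
#' The central container of the pipeline: a non-negative numeric matrix with
#' features (OTUs, genera, KOs, pathways or genes) as rows and samples as
#' columns, optional per-feature string metadata (taxonomy), and a declared
#' scale. `scale = "counts"` marks raw or copy-number-normalized abundances
#' (non-negative reals; integers are not required); `scale = "log2"` marks
#' log-scale expression-like data where negative values are meaningful.
#' Absences are explicit zeros: missing cells are rejected.
#'
#' @param values numeric matrix, features x samples.
#' @param feature_ids unique character vector of row ids (default: rownames).
#' @param sample_ids unique character vector of column ids (default: colnames).
#' @param feature_meta optional data.frame of per-feature string metadata
#'   (e.g. a `taxonomy` column in Greengenes `k__...;g__...;s__` form), one
#'   row per feature, in feature order.
#' @param scale `"counts"` or `"log2"`.
#' @return an object of class `feature_table`.
#' @examples
#' m <- matrix(c(10, 0, 3, 5, 2, 8), nrow = 3,
#'             dimnames = list(c("OTU_1", "OTU_2", "OTU_3"), c("s1", "s2")))
#' ft <- feature_table(m, scale = "counts")
#' dim(ft)
#' @export
feature_table <- function(values, feature_ids = rownames(values),
                          sample_ids = colnames(values),
                          feature_meta = NULL, scale = c("counts", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids)) {
    komix_stop("feature_table: feature_ids and sample_ids are required")
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    komix_stop("feature_table: id lengths (%d, %d) do not match matrix shape (%d, %d)",
               length(feature_ids), length(sample_ids), nrow(values), ncol(values))
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  if (!is.null(feature_meta)) {
    feature_meta <- as.data.frame(feature_meta, stringsAsFactors = FALSE)
    if (nrow(feature_meta) != nrow(values)) {
      komix_stop("feature_table: feature_meta has %d rows for %d features",
                 nrow(feature_meta), nrow(values))
    }
    rownames(feature_meta) <- feature_ids
  }
  ft <- structure(
    list(values = values, feature_ids = feature_ids, sample_ids = sample_ids,
         feature_meta = feature_meta, scale = scale),
    class = "feature_table"
  )
  validate_feature_table(ft)
  ft
}

validate_feature_table <- function(ft) {
  dup_f <- unique(ft$feature_ids[duplicated(ft$feature_ids)])
  if (length(dup_f)) {
    komix_stop("duplicate feature ids: %s", id_list(dup_f))
  }
  dup_s <- unique(ft$sample_ids[duplicated(ft$sample_ids)])
  if (length(dup_s)) {
    komix_stop("duplicate sample ids: %s", id_list(dup_s))
  }
  if (anyNA(ft$values)) {
    bad <- which(is.na(ft$values), arr.ind = TRUE)[1L, ]
    komix_stop("missing cell at feature '%s', sample '%s' (absences must be explicit zeros)",
               ft$feature_ids[bad[1L]], ft$sample_ids[bad[2L]])
  }
  if (ft$scale == "counts" && any(ft$values < 0)) {
    bad <- which(ft$values < 0, arr.ind = TRUE)[1L, ]
    komix_stop("negative value %g at feature '%s', sample '%s' with scale=counts",
               ft$values[bad[1L], bad[2L]],
               ft$feature_ids[bad[1L]], ft$sample_ids[bad[2L]])
  }
  invisible(ft)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (scale=%s)\n",
              nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$feature_meta)) {
    cat("feature_meta columns:", paste(colnames(x$feature_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a feature table
#'
#' @param x a `feature_table`.
#' @param features,samples index vectors (ids, logical, or integer positions).
#' @return a `feature_table` with the selected rows/columns and metadata.
#' @export
ft_subset <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "feature_table"))
  fi <- features %||% seq_len(nrow(x$values))
  si <- samples %||% seq_len(ncol(x$values))
  v <- x$values[fi, si, drop = FALSE]
  meta <- if (!is.null(x$feature_meta)) x$feature_meta[fi, , drop = FALSE] else NULL
  feature_table(v, rownames(v), colnames(v), feature_meta = meta, scale = x$scale)
}

#' Extract the genus of each feature from its taxonomy metadata
#'
#' Parses Greengenes-style 7-rank taxonomy strings
#' (`k__...;p__...;c__...;o__...;f__...;g__...;s__...`). Features whose
#' `g__` field is empty are labelled `unclassified_<lowest named rank>`,
#' e.g. an OTU classified only to family `f__S24-7` becomes
#' `unclassified_S24-7`; a fully unclassified string becomes
#' `unclassified_unknown`.
#'
#' @param ft a `feature_table` whose `feature_meta` has a `taxonomy` column.
#' @return character vector of genus labels, one per feature.
#' @export
genus_of <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(ft$feature_meta) || !"taxonomy" %in% colnames(ft$feature_meta)) {
    komix_stop("genus_of: feature_meta lacks a 'taxonomy' column")
  }
  vapply(ft$feature_meta$taxonomy, parse_genus, character(1L), USE.NAMES = FALSE)
}

parse_genus <- function(tax) {
  ranks <- trimws(strsplit(tax, ";", fixed = TRUE)[[1L]])
  get_rank <- function(prefix) {
    hit <- grep(paste0("^", prefix, "__"), ranks, value = TRUE)
    if (!length(hit)) return("")
    sub(paste0("^", prefix, "__"), "", hit[1L])
  }
  g <- get_rank("g")
  if (nzchar(g)) return(g)
  # fall back to the lowest named rank above genus
  for (prefix in c("f", "o", "c", "p", "k")) {
    r <- get_rank(prefix)
    if (nzchar(r)) return(paste0("unclassified_", r))
  }
  "unclassified_unknown"
}
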