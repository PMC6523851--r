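# The uniform differential engine: precision-weighted log-cpm transform for
# count tables, per-feature weighted group-means fit, empirical-Bayes
# variance moderation, log-FC confidence intervals, and the FC/p gate.
# Applied identically to OTU, genus, and KO tables (with the count
# transform) and to log-scale expression tables (unit weights).

# Samples are put in a canonical order (group, then sample id) before any
# row-wise accumulation, so permuting input columns together with the design
# leaves every statistic bit-identical.
canonical_order <- function(sample_ids, groups) {
  g <- groups[sample_ids]
  order(g, sample_ids)
}

#' Log-cpm transform with precision weights for count tables
#'
#' Converts counts to `log2((c + 0.5) / (L + 1) * 1e6)` (L = library size),
#' fits a group-means model per feature, smooths the square-root residual
#' standard deviation against average log2 count with LOWESS (span 0.5,
#' 3 robustness iterations), and converts each observation's fitted log2
#' count through the trend into an inverse-variance weight
#' `trend(.)^(-4)`. The trend is clamped to its boundary values outside the
#' fitted range.
#'
#' @param counts a `feature_table` with `scale = "counts"`.
#' @param design a [study_design()] covering every sample.
#' @param span LOWESS span.
#' @return list of class `voom_fit`: `logcpm` (`feature_table`, log2 scale),
#'   `weights` (positive matrix, same shape), `trend` (function: mean log2
#'   count -> sqrt residual SD, clamped).
#' @export
voom_transform <- function(counts, design, span = 0.5) {
  stopifnot(inherits(counts, "feature_table"), inherits(design, "study_design"))
  if (counts$scale != "counts") komix_stop("voom_transform needs scale=counts")
  missing <- setdiff(counts$sample_ids, names(design$groups))
  if (length(missing)) komix_stop("samples absent from design: %s", id_list(missing))
  ord <- canonical_order(counts$sample_ids, design$groups)
  vals <- counts$values[, ord, drop = FALSE]
  groups <- design$groups[colnames(vals)]
  if (nrow(vals) < 10L) {
    warning("fewer than 10 features: mean-variance trend will be unstable")
  }
  lib <- colSums(vals)
  if (any(lib == 0)) {
    komix_stop("sample(s) with zero library size: %s", id_list(colnames(vals)[lib == 0]))
  }
  y <- t(log2(t(vals + 0.5) / (lib + 1) * 1e6))
  fit <- group_means_fit(y, NULL, groups)
  s2 <- floor_variances(fit$s2)
  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sqrt(s2))  # quarter-root of variance = sqrt residual SD
  lo <- stats::lowess(sx, sy, f = span, iter = 3L)
  trend <- make_trend(lo)
  fitted_logcount <- fit$fitted + matrix(log2(lib + 1), nrow(y), ncol(y), byrow = TRUE) -
    log2(1e6)
  w <- matrix(trend(fitted_logcount), nrow(y), ncol(y), dimnames = dimnames(y))^(-4)
  structure(list(
    logcpm = feature_table(y, rownames(y), colnames(y),
                           feature_meta = if (is.null(counts$feature_meta)) NULL
                                          else counts$feature_meta[counts$feature_ids, ,
                                                                   drop = FALSE],
                           scale = "log2"),
    weights = w, trend = trend), class = "voom_fit")
}

# Piecewise-linear interpolant through the LOWESS curve, clamped outside the
# fitted range, floored away from zero so weights stay finite.
make_trend <- function(lo) {
  ox <- lo$x; oy <- pmax(lo$y, 1e-6)
  if (length(unique(ox)) < 2L) {
    const <- mean(oy)
    return(function(x) rep(const, length(as.vector(x))))
  }
  function(x) stats::approx(ox, oy, xout = as.vector(x), rule = 2, ties = mean)$y
}

# Closed-form weighted group-means fit: for an indicator design, the WLS
# coefficient for group g is the weighted mean of its samples.
group_means_fit <- function(y, w, groups) {
  if (is.null(w)) w <- matrix(1, nrow(y), ncol(y))
  glev <- sort(unique(groups))
  G <- length(glev)
  Wg <- matrix(0, nrow(y), G, dimnames = list(rownames(y), glev))
  Mg <- Wg
  for (g in glev) {
    idx <- which(groups == g)
    Wg[, g] <- rowSums(w[, idx, drop = FALSE])
    Mg[, g] <- rowSums((w * y)[, idx, drop = FALSE]) / Wg[, g]
  }
  fitted <- Mg[, match(groups, glev), drop = FALSE]
  colnames(fitted) <- colnames(y)
  df_resid <- ncol(y) - G
  rss <- rowSums(w * (y - fitted)^2)
  s2 <- if (df_resid > 0) rss / df_resid else rep(NA_real_, nrow(y))
  list(group_weights = Wg, group_means = Mg, fitted = fitted,
       s2 = s2, df_resid = df_resid)
}

# Degenerate-variance guard: exact zeros (all replicates identical) are set
# to the 1st percentile of the positive variances, or 1e-8 if none exist.
floor_variances <- function(s2, eps = 1e-12) {
  low <- s2 < eps
  if (any(low)) {
    pos <- s2[!low]
    repl <- if (length(pos)) stats::quantile(pos, 0.01, names = FALSE) else 1e-8
    s2[low] <- repl
  }
  s2
}

#' Estimate the variance prior by moment matching on log variances
#'
#' Matches the first two moments of `log(s^2)` to a scaled-F model for the
#' sample variances: `e = log(s2) - digamma(d/2) + log(d/2)` has mean
#' `log(s0^2) + digamma(d0/2) - log(d0/2)` and excess variance
#' `trigamma(d0/2)`. The trigamma equation is inverted by Newton's method
#' (tolerance 1e-10); when the observed spread of log variances does not
#' exceed what `d` residual df alone produce, the prior df is infinite.
#'
#' @param s2 positive per-feature residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list `df_prior` (possibly `Inf`) and `var_prior`.
#' @export
estimate_variance_prior <- function(s2, df) {
  stopifnot(all(s2 > 0), df > 0)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(df_prior = Inf, var_prior = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  list(df_prior = d0, var_prior = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

# Newton inversion of the trigamma function (solve trigamma(y) = x, y > 0).
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(100L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moderated differential statistics for one pairwise contrast
#'
#' Fits a weighted group-means linear model per feature over all design
#' groups, shrinks the residual variances toward an empirically estimated
#' prior, and tests the contrast `mean(A) - mean(B)` with a moderated
#' t-statistic on `d0 + d_g` degrees of freedom. Confidence intervals use
#' the moderated standard error and the same df.
#'
#' @param y a log2-scale `feature_table` (or plain matrix) of responses.
#' @param weights positive precision weights, same shape, or `NULL` for unit
#'   weights.
#' @param design a [study_design()].
#' @param contrast length-2 character `c(A, B)` or a label `"A-B"`.
#' @param prior_df `"auto"` (estimate by moments), `0` (no moderation:
#'   ordinary t), `Inf` (full shrinkage to the prior variance), or a
#'   positive number.
#' @param ci_level confidence level for the log-FC interval.
#' @param lfc_cut,p_cut,p_gate thresholds for the direction call, see
#'   [select_differential()].
#' @return a `differential_result` data.frame: one row per feature with
#'   `log2fc`, moderated `se`, `ci_low`/`ci_high`, `t_mod`, `df_total`,
#'   `p_raw`, informational `fdr` (Benjamini-Hochberg), `direction`.
#' @export
fit_moderated <- function(y, weights = NULL, design, contrast,
                          prior_df = "auto", ci_level = 0.95,
                          lfc_cut = 1, p_cut = 0.05, p_gate = c("lte", "lt")) {
  p_gate <- match.arg(p_gate)
  if (inherits(y, "feature_table")) {
    ymat <- y$values
  } else {
    ymat <- as.matrix(y)
  }
  stopifnot(inherits(design, "study_design"))
  contrast <- parse_contrast(contrast)
  missing <- setdiff(colnames(ymat), names(design$groups))
  if (length(missing)) komix_stop("samples absent from design: %s", id_list(missing))
  ord <- canonical_order(colnames(ymat), design$groups)
  ymat <- ymat[, ord, drop = FALSE]
  groups <- design$groups[colnames(ymat)]
  for (g in contrast) {
    if (!g %in% groups) komix_stop("contrast group '%s' has no samples in the table", g)
  }
  w <- NULL
  if (!is.null(weights)) {
    w <- as.matrix(weights)[, colnames(ymat), drop = FALSE]
    if (any(!is.finite(w)) || any(w <= 0)) komix_stop("weights must be finite and positive")
  }
  fit <- group_means_fit(ymat, w, groups)
  if (is.na(fit$df_resid) || fit$df_resid <= 0L) {
    komix_stop("no residual degrees of freedom (need > %d samples for %d groups)",
               length(unique(groups)), length(unique(groups)))
  }
  beta <- fit$group_means[, contrast[1L]] - fit$group_means[, contrast[2L]]
  u <- sqrt(1 / fit$group_weights[, contrast[1L]] + 1 / fit$group_weights[, contrast[2L]])
  s2 <- floor_variances(fit$s2)
  if (identical(prior_df, "auto")) {
    prior <- estimate_variance_prior(s2, fit$df_resid)
  } else {
    stopifnot(is.numeric(prior_df), prior_df >= 0)
    prior <- list(df_prior = prior_df,
                  var_prior = estimate_variance_prior(s2, fit$df_resid)$var_prior)
  }
  d0 <- prior$df_prior
  s2_post <- if (is.infinite(d0)) {
    rep(prior$var_prior, length(s2))
  } else {
    (d0 * prior$var_prior + fit$df_resid * s2) / (d0 + fit$df_resid)
  }
  df_total <- d0 + fit$df_resid
  se <- u * sqrt(s2_post)
  t_mod <- beta / se
  # p_raw lives in (0, 1]: guard against underflow on floored-variance features
  p_raw <- pmax(2 * stats::pt(-abs(t_mod), df = df_total), .Machine$double.xmin)
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df = df_total)
  res <- data.frame(
    feature = rownames(ymat),
    contrast = paste0(contrast[1L], "-", contrast[2L]),
    log2fc = unname(beta),
    se = unname(se),
    ci_low = unname(beta - tcrit * se),
    ci_high = unname(beta + tcrit * se),
    t_mod = unname(t_mod),
    df_total = df_total,
    p_raw = unname(p_raw),
    stringsAsFactors = FALSE
  )
  res$fdr <- stats::p.adjust(res$p_raw, method = "BH")
  res$direction <- classify_direction(res$log2fc, res$p_raw, lfc_cut, p_cut, p_gate)
  attr(res, "df_prior") <- d0
  attr(res, "var_prior") <- prior$var_prior
  class(res) <- c("differential_result", "data.frame")
  res
}

parse_contrast <- function(contrast) {
  if (length(contrast) == 1L && grepl("-", contrast, fixed = TRUE)) {
    contrast <- strsplit(contrast, "-", fixed = TRUE)[[1L]]
  }
  if (length(contrast) != 2L) komix_stop("contrast must be c(A, B) or 'A-B'")
  as.character(contrast)
}

classify_direction <- function(log2fc, p_raw, lfc_cut, p_cut, p_gate) {
  pass_p <- if (p_gate == "lte") p_raw <= p_cut else p_raw < p_cut
  ifelse(pass_p & log2fc >= lfc_cut, "up",
         ifelse(pass_p & log2fc <= -lfc_cut, "down", "ns"))
}

#' Select differential features with the fold-change / p-value gate
#'
#' The selection rule used throughout: a feature is called up if
#' `log2fc >= 1` (fold change >= 2) and its raw p-value passes the gate
#' (default `p <= 0.05`), down if `log2fc <= -1` with the same p gate.
#' No multiple-testing correction is applied to the gate; the `fdr` column
#' of the result is informational only.
#'
#' @param res a `differential_result` (one contrast).
#' @param lfc_cut absolute log2 fold-change threshold.
#' @param p_cut raw p-value threshold.
#' @param p_gate `"lte"` for `p <= p_cut`, `"lt"` for strict.
#' @return list with character vectors `up` and `down` of feature ids.
#' @export
select_differential <- function(res, lfc_cut = 1, p_cut = 0.05,
                                p_gate = c("lte", "lt")) {
  p_gate <- match.arg(p_gate)
  dir <- classify_direction(res$log2fc, res$p_raw, lfc_cut, p_cut, p_gate)
  list(up = res$feature[dir == "up"], down = res$feature[dir == "down"])
}

#' Run the uniform differential analysis over a set of contrasts
#'
#' Count-scale tables go through [voom_transform()] and are fitted with
#' precision weights; log2-scale (expression) tables skip the transform and
#' use unit weights. One moderated fit is computed per contrast.
#'
#' @param table a `feature_table`.
#' @param design a [study_design()]; its contrasts are used unless
#'   `contrasts` is given.
#' @param contrasts optional contrasts (see [study_design()]).
#' @param use_voom `NULL` (auto: counts scale), `TRUE`, or `FALSE`. `TRUE`
#'   with a log2-scale table is an error.
#' @param ... passed to [fit_moderated()] (`prior_df`, `ci_level`,
#'   `lfc_cut`, `p_cut`, `p_gate`).
#' @return a `differential_result` data.frame stacked over contrasts.
#' @export
run_differential <- function(table, design, contrasts = NULL, use_voom = NULL, ...) {
  stopifnot(inherits(table, "feature_table"), inherits(design, "study_design"))
  contrasts <- normalize_contrasts(contrasts) %||% design$contrasts
  if (is.null(contrasts) || !nrow(contrasts)) komix_stop("no contrasts specified")
  if (is.null(use_voom)) use_voom <- table$scale == "counts"
  if (use_voom && table$scale == "log2") {
    komix_stop("use_voom=TRUE is invalid for a log2-scale table")
  }
  if (use_voom) {
    vf <- voom_transform(table, design)
    y <- vf$logcpm
    w <- vf$weights
  } else {
    y <- table
    w <- NULL
  }
  out <- do.call(rbind, lapply(seq_len(nrow(contrasts)), function(i) {
    fit_moderated(y, w, design, c(contrasts$A[i], contrasts$B[i]), ...)
  }))
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Write a differential result to TSV
#'
#' @param res a `differential_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(res, path) {
  utils::write.table(format_numeric_df(as.data.frame(res)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Render numeric columns at full precision for deterministic text output.
format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}
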