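test_that("log-cpm transform reproduces the offset formula", {
  # a zero count in a library of 999,999 reads: log2(0.5/1e6 * 1e6) = -1
  col <- c(0, rep(90909, 11))          # sums to 999,999
  m <- cbind(A_1 = col, A_2 = col, B_1 = rev(col), B_2 = rev(col))
  rownames(m) <- paste0("f", 1:12)
  des <- two_group_design(2)
  vf <- voom_transform(feature_table(m, scale = "counts"), des)
  expect_equal(vf$logcpm$values["f1", "A_1"], -1)
  expect_equal(vf$logcpm$values["f1", "A_2"], -1)
})

test_that("degenerate all-identical counts give equal floored weights", {
  m <- matrix(5, 12, 8,
              dimnames = list(paste0("f", 1:12),
                              paste0(rep(c("A", "B"), each = 4), "_", 1:4)))
  des <- two_group_design()
  vf <- voom_transform(feature_table(m, scale = "counts"), des)
  expect_true(all(is.finite(vf$weights)) && all(vf$weights > 0))
  expect_equal(max(vf$weights), min(vf$weights))
})

test_that("mean-variance trend decreases over the bulk of the count range", {
  # frozen from a 10-seed negative-binomial simulation (alpha = 0.1, n = 5/group)
  for (seed in 1:5) {
    com <- generate_community(n_otus = 500, n_per_group = 5, n_planted = 0,
                              effect_log2 = 0, dispersion = 0.1, seed = seed)
    vf <- voom_transform(com$table, com$design)
    sx <- environment(vf$trend)$ox
    lo <- stats::quantile(sx, 0.2)
    hi <- stats::quantile(sx, 0.9)
    expect_lte(vf$trend(hi), vf$trend(lo))           # sqrt-SD falls with count
    expect_gte(vf$trend(hi)^-4, vf$trend(lo)^-4)     # so precision weight rises
    xs <- seq(stats::quantile(sx, 0.05), stats::quantile(sx, 0.95), length.out = 100)
    expect_gte(mean(diff(vf$trend(xs)) <= 1e-8), 0.8)
  }
  zl <- matrix(0, 12, 4, dimnames = list(paste0("f", 1:12),
                                         c("A_1", "A_2", "B_1", "B_2")))
  expect_error(voom_transform(feature_table(zl, scale = "counts"),
                              two_group_design(2)), "zero library")
})

test_that("moderated fit handles zero-variance features via the floor", {
  m <- cbind(matrix(3, 4, 3), matrix(1, 4, 3))
  m[2, ] <- c(rep(8, 3), rep(2, 3))
  dimnames(m) <- list(paste0("f", 1:4),
                      paste0(rep(c("A", "B"), each = 3), "_", 1:3))
  des <- two_group_design(3)
  fit <- fit_moderated(m, NULL, des, "A-B")
  expect_true(all(is.finite(fit$t_mod)))
  expect_true(all(fit$p_raw > 0 & fit$p_raw <= 1))
  expect_equal(fit$log2fc[1], 2)
  expect_equal(fit$direction[1], "up")
})

test_that("prior-df limits recover ordinary t and the pooled-variance form", {
  set.seed(77)
  n <- 400
  y <- cbind(matrix(rnorm(n * 4, 1), n), matrix(rnorm(n * 4), n))
  dimnames(y) <- list(paste0("f", 1:n),
                      paste0(rep(c("A", "B"), each = 4), "_", 1:4))
  des <- two_group_design(4)
  fit0 <- fit_moderated(y, NULL, des, "A-B", prior_df = 0)
  ref_p <- apply(y, 1, function(r) {
    stats::t.test(r[1:4], r[5:8], var.equal = TRUE)$p.value
  })
  expect_equal(fit0$p_raw, unname(ref_p), tolerance = 1e-12)

  fitI <- fit_moderated(y, NULL, des, "A-B", prior_df = Inf)
  s0 <- attr(fitI, "var_prior")
  u <- sqrt(1 / 4 + 1 / 4)
  expect_equal(fitI$t_mod, fit0$log2fc / (u * sqrt(s0)))

  # equal per-feature variances: the estimated prior df is infinite and the
  # moderated t equals the ordinary t up to the analytic log-scale bias
  # factor exp((log(d/2) - digamma(d/2)) / 2), which tends to 1 with d
  base <- rnorm(8)
  yc <- t(sapply(1:50, function(i) base + i))  # same residuals, shifted means
  dimnames(yc) <- list(paste0("g", 1:50), colnames(y))
  fit_eq <- fit_moderated(yc, NULL, des, "A-B")
  fit_eq0 <- fit_moderated(yc, NULL, des, "A-B", prior_df = 0)
  expect_equal(attr(fit_eq, "df_prior"), Inf)
  d <- 8 - 2
  bias <- exp((log(d / 2) - digamma(d / 2)) / 2)
  expect_equal(fit_eq$t_mod * bias, fit_eq0$t_mod, tolerance = 1e-10)
  expect_lt(abs(bias - 1), 0.1)
})

test_that("null gaussian p-values are calibrated and |t| is monotone in |beta|", {
  set.seed(101)
  n <- 4000
  y <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(paste0("f", 1:n),
                              paste0(rep(c("A", "B"), each = 5), "_", 1:5)))
  des <- two_group_design(5)
  fit <- fit_moderated(y, NULL, des, "A-B")
  expect_lt(abs(mean(fit$p_raw <= 0.05) - 0.05), 0.01)
  expect_true(all(fit$ci_low <= fit$log2fc & fit$log2fc <= fit$ci_high))

  # recenter one feature's group A at increasing deltas, residuals fixed:
  # beta equals delta exactly and |t| must strictly increase
  resid_a <- y[7, 1:5] - mean(y[7, 1:5])
  mean_b <- mean(y[7, 6:10])
  tvals <- sapply(c(0.5, 1, 2, 4), function(delta) {
    y2 <- y
    y2[7, 1:5] <- mean_b + delta + resid_a
    abs(fit_moderated(y2, NULL, des, "A-B")$t_mod[7])
  })
  expect_true(all(diff(tvals) > 0))
})

test_that("moderated fit matches limma voom + eBayes on a simulated table", {
  skip_if_not_installed("limma")
  com <- generate_community(n_otus = 300, n_per_group = 5, n_planted = 20,
                            effect_log2 = 2, dispersion = 0.1, seed = 12)
  ft <- com$table
  des <- com$design
  grp <- factor(des$groups[ft$sample_ids])
  X <- stats::model.matrix(~ 0 + grp)
  colnames(X) <- levels(grp)
  v <- limma::voom(ft$values, X)
  fit <- limma::lmFit(v, X)
  cm <- limma::makeContrasts(MS - CIA, levels = X)
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
  tt <- limma::topTable(fit2, number = Inf, sort.by = "none")
  mine <- run_differential(ft, des, contrasts = "MS-CIA")
  expect_equal(mine$log2fc, tt$logFC, tolerance = 1e-10)
  expect_lt(max(abs(mine$t_mod - tt$t)), 1e-2)
  expect_lt(max(abs(mine$p_raw - tt$P.Value)), 1e-3)
  expect_gt(stats::cor(mine$t_mod, tt$t), 0.99999)
})

test_that("selection gate enforces FC >= 2 with the p <= 0.05 rule", {
  res <- data.frame(feature = c("a", "b", "c", "d"),
                    log2fc = c(1.0, 0.99, 3.0, -1.2),
                    p_raw = c(0.049, 0.001, 0.051, 0.03))
  sel <- select_differential(res)
  expect_true("a" %in% sel$up)      # log2fc = 1.0, p = 0.049 -> selected
  expect_false("b" %in% sel$up)     # fails the fold-change gate
  expect_false("c" %in% sel$up)     # fails the p gate
  expect_true("d" %in% sel$down)
  # boundary: p exactly 0.05 passes the default inclusive gate, not the strict one
  bd <- data.frame(feature = "e", log2fc = 2, p_raw = 0.05)
  expect_equal(select_differential(bd)$up, "e")
  expect_length(select_differential(bd, p_gate = "lt")$up, 0)
})

test_that("run_differential is deterministic and invariant to sample permutation", {
  com <- generate_community(n_otus = 150, n_per_group = 5, n_planted = 10,
                            effect_log2 = 2, seed = 8)
  r1 <- run_differential(com$table, com$design)
  r2 <- run_differential(com$table, com$design)
  expect_identical(r1, r2)

  perm <- sample(ncol(com$table$values))
  shuffled <- ft_subset(com$table, samples = perm)
  r3 <- run_differential(shuffled, com$design)
  expect_identical(r1, r3)

  expr <- feature_table(matrix(rnorm(80), 10, 8,
                               dimnames = list(paste0("g", 1:10),
                                               paste0(rep(c("A", "B"), each = 4),
                                                      "_", 1:4))),
                        scale = "log2")
  expect_error(run_differential(expr, two_group_design(), use_voom = TRUE),
               "log2")
})
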