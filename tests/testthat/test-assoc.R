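test_that("signed-rank test matches hand case and exhaustive enumeration", {
  r <- wilcoxon_signed_rank(c(-1, -2, -3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.25)   # 2 of the 8 sign assignments as extreme
  expect_true(r$exact)

  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    v <- round(rnorm(n, sd = 3), 2)
    v <- v[v != 0]
    if (length(v) < 4 || anyDuplicated(abs(v))) next
    expect_equal(wilcoxon_signed_rank(v)$p_value, oracle_signed_rank_p(v),
                 tolerance = 1e-12, label = paste("rep", rep))
  }
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), ">= 3 nonzero")
})

test_that("rank-sum test matches hand case and permutation enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)    # U for the first sample
  expect_equal(r$p_value, 1 / 3)

  expect_equal(wilcoxon_rank_sum(c(5, 1, 3), c(5, 1, 3))$p_value, 1)

  set.seed(7)
  for (rep in 1:20) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    v <- round(rnorm(na + nb, sd = 5), 2)
    if (anyDuplicated(v)) next
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, oracle_rank_sum_p(a, b),
                 tolerance = 1e-12, label = paste("rep", rep))
  }
  expect_error(wilcoxon_rank_sum(1, c(2, 3)), ">= 2")
})

test_that("spearman handles perfect, tied and monotone-transformed data", {
  expect_equal(spearman(1:5, 5:1)$rho, -1)
  expect_equal(spearman(1:5, 1:5)$rho, 1)
  # ties: rank-then-Pearson oracle
  x <- c(1, 1, 2, 3, 7)
  y <- c(2, 1, 4, 3, 3)
  expect_equal(spearman(x, y)$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearman(exp(a), b)$rho, spearman(a, b)$rho,
               tolerance = 1e-12)
  expect_equal(spearman(a, b^3 + 2 * b)$rho, spearman(a, b)$rho,
               tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "zero rank variance")
})

test_that("PLS recovers exact rank-1 signal and is monotone in components", {
  set.seed(11)
  # exactly centered orthogonal predictors, so scaling preserves
  # orthogonality and one component captures a one-column signal fully
  X <- qr.Q(qr(scale(matrix(rnorm(300), 50, 6), scale = FALSE)))
  y <- 2 * X[, 3]
  fit <- pls_regression(X, y, n_components = 3)
  expect_equal(fit$r2y_cum[1], 1, tolerance = 1e-6)
  expect_true(all(diff(fit$r2y_cum) >= -1e-10))
  expect_true(all(fit$r2y_cum <= 1 + 1e-10))

  # null: y independent of X explains little
  set.seed(12)
  Xn <- matrix(rnorm(1000 * 10), 1000, 10)
  yn <- rnorm(1000)
  fn <- pls_regression(Xn, yn, n_components = 3)
  expect_lt(fn$r2y_cum[3], 0.05)

  # generative recovery: known R2 from two latent X directions
  set.seed(13)
  Xg <- matrix(rnorm(500 * 8), 500, 8)
  signal <- Xg[, 1] - 0.5 * Xg[, 2]
  signal <- signal / sd(signal)
  noise <- rnorm(500)
  r2_true <- 0.65
  yg <- sqrt(r2_true) * signal + sqrt(1 - r2_true) * noise / sd(noise)
  fg <- pls_regression(Xg, yg, n_components = 3)
  expect_lt(abs(fg$r2y_cum[3] - r2_true), 0.05)

  expect_error(pls_regression(X, rep(1, 50)), "constant response")
})

test_that("PLS R2Y agrees with the mixOmics reference implementation", {
  set.seed(21)
  X <- matrix(rnorm(80 * 7), 80, 7)
  y <- X %*% rnorm(7) + rnorm(80)
  fit <- pls_regression(X, y, n_components = 3)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  # fitted-value R2 per cumulative component from mixOmics scores
  pred <- stats::fitted(stats::lm(y ~ mo$variates$X))
  expect_equal(fit$r2y_cum[3], 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
               tolerance = 0.02)
})

test_that("nri_climate_assoc returns rho/p per group and factor", {
  set.seed(5)
  groups <- rep(1:3, c(12, 17, 31))
  clim <- simulate_climate(groups, seed = 6)$climate
  nri_t <- data.frame(plot = clim$plot,
                      nri = 0.8 * scale(clim$ai)[, 1] + rnorm(60, 0, 0.3))
  g <- setNames(groups, clim$plot)
  a <- nri_climate_assoc(nri_t, clim, g, cols = c("ai", "bio1"))
  expect_equal(nrow(a), 6)
  expect_true(all(a$rho >= -1 & a$rho <= 1, na.rm = TRUE))
  # pooled association with ai must be strongly positive
  pooled <- nri_climate_assoc(nri_t, clim, NULL, cols = "ai")
  expect_gt(pooled$rho, 0.5)
  expect_lt(pooled$p_value, 0.01)
  # BH adjustment never decreases p-values
  a_bh <- nri_climate_assoc(nri_t, clim, g, cols = c("ai", "bio1"),
                            p_adjust = "BH")
  expect_true(all(a_bh$p_value >= a$p_value - 1e-12, na.rm = TRUE))
})

test_that("group_summaries reports medians, vs-zero and pairwise tests", {
  set.seed(9)
  plots <- sprintf("p%02d", 1:40)
  g <- setNames(rep(1:2, each = 20), plots)
  nri_t <- data.frame(plot = plots,
                      nri = c(rnorm(20, 1.5, 0.5), rnorm(20, -1.5, 0.5)))
  pd_t <- data.frame(plot = plots, SR = rep(c(4, 8), each = 20),
                     PD = rep(c(10, 30), each = 20) + rnorm(40))
  gs <- group_summaries(nri_t, pd_t, g)
  expect_equal(nrow(gs$per_group), 2)
  expect_gt(gs$per_group$median_nri[1], 0)
  expect_lt(gs$per_group$median_nri[2], 0)
  expect_true(all(gs$per_group$nri_vs_zero_p < 0.01))
  expect_equal(gs$per_group$flag, c("***", "***"))
  pw <- gs$pairwise
  expect_lt(pw$p_value[pw$quantity == "nri"], 0.01)
  expect_lt(pw$p_value[pw$quantity == "PD"], 0.01)

  # single group: no pairwise table
  g1 <- setNames(rep(1, 40), plots)
  expect_null(group_summaries(nri_t, pd_t, g1)$pairwise)

  # degenerate all-zero NRI: test skipped and flagged
  nri0 <- data.frame(plot = plots, nri = 0)
  gs0 <- group_summaries(nri0, pd_t, g)
  expect_true(all(gs0$per_group$tests_skipped))
})
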