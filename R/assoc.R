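#' Wilcoxon signed-rank test against a location
#'
#' Two-sided one-sample signed-rank test of \code{values} against
#' \code{mu0}. The exact null distribution is used for n <= 25 without ties
#' or zeros; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param values numeric vector with >= 3 nonzero deviations from mu0.
#' @param mu0 hypothesized location (default 0).
#' @return list: statistic (W+), p_value, n (nonzero deviations), exact.
#' @export
wilcoxon_signed_rank <- function(values, mu0 = 0) {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n < 3) stop("need >= 3 nonzero deviations from mu0")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, n = n,
       exact = exact)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided two-sample rank-sum test. Exact null distribution for small
#' samples without ties; normal approximation with tie and continuity
#' correction otherwise.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list: statistic (U for sample a), p_value, exact.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 50 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of average ranks (ties get average
#' ranks); the p-value uses the t approximation with n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list: rho, p_value, n.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("zero rank variance")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Partial least squares regression (NIPALS, single response)
#'
#' PLS1 by the NIPALS algorithm: predictors are standardized internally and
#' the response centered; components are extracted sequentially with X- and
#' y-deflation. Reports the fraction of response variance explained per
#' component (cumulative R2Y from the cumulative fitted values) and, for
#' reference, the fraction of predictor variance captured (R2X).
#'
#' @param X plot x factor numeric matrix (no missing values).
#' @param y response vector (the NRI), not constant.
#' @param n_components number of latent components (default 3).
#' @return list: n_components, r2y (per-component), r2y_cum, r2x_cum,
#'   loadings (predictor weights per component), scores.
#' @export
pls_regression <- function(X, y, n_components = 3) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(y) == 0) stop("constant response")
  if (nrow(X) != length(y)) stop("dimension mismatch")
  if (nrow(X) <= n_components) stop("need more observations than components")
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  Xs <- scale(X)
  y0 <- y - mean(y)
  ssy <- sum(y0^2)
  ssx <- sum(Xs^2)
  n_components <- min(n_components, ncol(Xs), qr(Xs)$rank)
  E <- Xs; f <- y0
  W <- P <- matrix(0, ncol(Xs), n_components,
                   dimnames = list(colnames(Xs), NULL))
  Tm <- matrix(0, nrow(Xs), n_components)
  q <- numeric(n_components)
  r2y_cum <- r2x_cum <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- a - 1L; break }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    p <- crossprod(E, t) / tt
    qa <- sum(f * t) / tt
    E <- E - t %*% t(p)
    f <- f - qa * t
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; q[a] <- qa
    r2y_cum[a] <- 1 - sum(f^2) / ssy
    r2x_cum[a] <- 1 - sum(E^2) / ssx
  }
  if (n_components == 0) stop("no usable PLS component (X orthogonal to y)")
  idx <- seq_len(n_components)
  r2y_cum <- r2y_cum[idx]; r2x_cum <- r2x_cum[idx]
  list(n_components = n_components,
       r2y = diff(c(0, r2y_cum)), r2y_cum = r2y_cum, r2x_cum = r2x_cum,
       loadings = W[, idx, drop = FALSE],
       scores = Tm[, idx, drop = FALSE])
}

#' Spearman associations between NRI and climate factors per habitat group
#'
#' @param nri_table data.frame with plot and nri columns (from
#'   [nri_batch()]).
#' @param climate climate data.frame (plot + factor columns).
#' @param groups named group vector (plot -> group), or NULL for a single
#'   pooled group.
#' @param cols climate columns to correlate (default all 21 plus any
#'   anomaly columns present).
#' @param p_adjust "none" (default; no multiple-testing correction) or
#'   "BH" for Benjamini-Hochberg within each group.
#' @return data.frame: group, factor, rho, p_value, n (NA rows where a
#'   group is too small or degenerate).
#' @export
nri_climate_assoc <- function(nri_table, climate, groups = NULL,
                              cols = NULL, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(cols))
    cols <- intersect(c(bioclim_cols(), "d_amt", "d_mtd", "d_ap"),
                      names(climate))
  merged <- merge(nri_table[, c("plot", "nri")], climate, by = "plot")
  if (is.null(groups)) {
    groups <- rep(1L, nrow(merged))
    names(groups) <- merged$plot
  }
  merged$group <- groups[as.character(merged$plot)]
  out <- list()
  for (g in sort(unique(merged$group))) {
    sub <- merged[merged$group == g & !is.na(merged$nri), ]
    for (cl in cols) {
      res <- tryCatch(spearman(sub[[cl]], sub$nri), error = function(e) NULL)
      out[[length(out) + 1L]] <- data.frame(
        group = g, factor = cl,
        rho = if (is.null(res)) NA_real_ else res$rho,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (p_adjust == "BH") {
    for (g in unique(res$group)) {
      sel <- res$group == g
      res$p_value[sel] <- stats::p.adjust(res$p_value[sel], method = "BH")
    }
  }
  res
}

signif_flag <- function(p) {
  ifelse(is.na(p), "", ifelse(p < .01, "***", ifelse(p < .05, "**",
                                                     ifelse(p < .1, "*", ""))))
}

#' Per-group summaries of NRI, PD and richness with rank tests
#'
#' For each habitat group: median NRI/PD/SR, a Wilcoxon signed-rank test of
#' NRI against zero, and pairwise Wilcoxon rank-sum tests between groups for
#' each quantity. Significance tiers: * p < .1, ** p < .05, *** p < .01.
#' Groups with fewer than 3 plots have their tests skipped and flagged.
#'
#' @param nri_table data.frame with plot, nri (from [nri_batch()]).
#' @param pd_table data.frame with plot, PD, SR (from [pd_batch()]).
#' @param groups named vector plot -> group.
#' @return list: per_group (medians + vs-zero test), pairwise (rank-sum
#'   tests per quantity).
#' @export
group_summaries <- function(nri_table, pd_table, groups) {
  df <- merge(nri_table[, c("plot", "nri")], pd_table, by = "plot")
  df$group <- groups[as.character(df$plot)]
  if (anyNA(df$group)) stop("every plot must belong to exactly one group")
  gs <- sort(unique(df$group))
  per_group <- do.call(rbind, lapply(gs, function(g) {
    sub <- df[df$group == g, ]
    v <- sub$nri[!is.na(sub$nri)]
    test <- if (length(v) >= 3 && any(v != 0))
      tryCatch(wilcoxon_signed_rank(v), error = function(e) NULL) else NULL
    p <- if (is.null(test)) NA_real_ else test$p_value
    data.frame(group = g, n = nrow(sub),
               median_nri = stats::median(v),
               median_pd = stats::median(sub$PD),
               median_sr = stats::median(sub$SR),
               nri_vs_zero_p = p, flag = signif_flag(p),
               tests_skipped = is.null(test), stringsAsFactors = FALSE)
  }))
  pairwise <- list()
  if (length(gs) > 1) {
    for (i in seq_along(gs)[-length(gs)]) for (j in (i + 1):length(gs)) {
      a <- df[df$group == gs[i], ]; b <- df[df$group == gs[j], ]
      for (q in c("nri", "PD", "SR")) {
        va <- a[[q]][!is.na(a[[q]])]; vb <- b[[q]][!is.na(b[[q]])]
        res <- if (length(va) >= 3 && length(vb) >= 3)
          tryCatch(wilcoxon_rank_sum(va, vb), error = function(e) NULL)
          else NULL
        p <- if (is.null(res)) NA_real_ else res$p_value
        pairwise[[length(pairwise) + 1L]] <- data.frame(
          group_a = gs[i], group_b = gs[j], quantity = q, p_value = p,
          flag = signif_flag(p), stringsAsFactors = FALSE)
      }
    }
  }
  list(per_group = per_group,
       pairwise = if (length(pairwise)) do.call(rbind, pairwise) else NULL)
}
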