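#' Mean pairwise phylogenetic distance of a community
#'
#' Unweighted: mean of the patristic distance over all unordered species
#' pairs present. Abundance-weighted: the pair-product weighting
#' \deqn{MPD_w = \sum_{i<j} w_i w_j d_{ij} / \sum_{i<j} w_i w_j,}
#' which is invariant to rescaling of the weights and reduces to the
#' unweighted mean when all weights are equal.
#'
#' @param weights named nonnegative numeric vector of importance values;
#'   species with weight 0 are treated as absent.
#' @param D patristic distance matrix (see [cophenetic_matrix()]).
#' @param weighted logical; use abundance weighting.
#' @return the MPD (scalar).
#' @export
mpd <- function(weights, D, weighted = TRUE) {
  w <- weights[weights > 0]
  sp <- names(w)
  if (length(sp) < 2)
    stop("MPD undefined: fewer than 2 species with positive weight")
  miss <- setdiff(sp, rownames(D))
  if (length(miss)) stop("species not in distance matrix: ",
                         paste(miss, collapse = ", "))
  d <- D[sp, sp]
  if (!weighted) w <- rep(1, length(sp))
  num <- as.numeric(w %*% d %*% w)          # = 2 * sum_{i<j} w_i w_j d_ij
  den <- sum(w)^2 - sum(w^2)                # = 2 * sum_{i<j} w_i w_j
  num / den
}

#' Randomization null distribution of MPD
#'
#' Each draw samples \code{S} species uniformly without replacement from the
#' regional pool and reassigns the observed abundance values to them in
#' random order, preserving both the richness and the abundance multiset of
#' the observed community; the (weighted) MPD of the randomized community is
#' recorded. Reproducible given \code{seed}.
#'
#' @param weights observed positive abundance values (the multiset to
#'   reassign); \code{length(weights)} is the richness S.
#' @param pool character vector of pool species (all must be in \code{D}).
#' @param D patristic distance matrix.
#' @param n_rand number of randomizations (default 999).
#' @param seed integer seed.
#' @param weighted logical; use abundance weighting.
#' @return object of class \code{null_mpd}: list(values, n_rand, seed, model).
#' @export
null_mpd <- function(weights, pool, D, n_rand = 999, seed = NULL,
                     weighted = TRUE) {
  S <- length(weights)
  if (S < 2) stop("richness must be >= 2")
  if (S > length(pool)) stop("richness exceeds pool size")
  if (any(weights <= 0)) stop("observed weights must be positive")
  miss <- setdiff(pool, rownames(D))
  if (length(miss)) stop("pool species not in distance matrix: ",
                         paste(miss, collapse = ", "))
  Dp <- unname(D[pool, pool, drop = FALSE])
  npool <- length(pool)
  w <- as.numeric(weights)
  if (!weighted) w <- rep(1, S)
  # a uniform random subset taken in sample() order against a fixed weight
  # vector is a uniform random assignment of the abundance multiset
  V <- tcrossprod(w)
  den <- sum(w)^2 - sum(w^2)
  vals <- with_seed(seed, {
    vapply(seq_len(n_rand), function(k) {
      idx <- sample.int(npool, S)
      sum(Dp[idx, idx] * V) / den
    }, numeric(1))
  })
  structure(list(values = vals, n_rand = n_rand, seed = seed,
                 model = "richness_abundance_shuffle"),
            class = "null_mpd")
}

#' Net relatedness index from an observed MPD and its null distribution
#'
#' \deqn{NRI = -1 (MPD_{obs} - mean(MPD_{rand})) / SD(MPD_{rand})}
#' with the SD using the n-1 denominator. NRI > 0 is classified as
#' phylogenetically clustered, NRI < 0 as overdispersed. A degenerate null
#' (SD = 0) yields a missing NRI classified \code{"random/undefined"}.
#'
#' @param observed observed MPD.
#' @param null a \code{null_mpd} object (or numeric vector of null MPDs).
#' @return one-row data.frame: mpd_obs, null_mean, null_sd, nri, class.
#' @export
nri <- function(observed, null) {
  vals <- if (inherits(null, "null_mpd")) null$values else as.numeric(null)
  if (!length(vals)) stop("empty null distribution")
  m <- mean(vals)
  s <- stats::sd(vals)
  if (s > 0) {
    z <- -1 * (observed - m) / s
    cls <- if (z > 0) "clustered" else if (z < 0) "overdispersed"
           else "random/undefined"
  } else {
    z <- NA_real_
    cls <- "random/undefined"
  }
  data.frame(mpd_obs = observed, null_mean = m, null_sd = s, nri = z,
             class = cls, stringsAsFactors = FALSE)
}

#' NRI for every plot of a community matrix
#'
#' The regional species pool is the union of all species observed across all
#' plots. Plots with fewer than 2 species are reported as skipped, not
#' errored. Per-plot child seeds are derived deterministically from the
#' master seed and the plot id, so results do not depend on plot order.
#'
#' @param comm plot-by-species matrix of nonnegative importance values
#'   (rownames = plot ids, colnames = species), e.g. from [read_community()].
#' @param tree a \code{phylo} object containing all community species.
#' @param n_rand randomizations per plot (default 999).
#' @param seed master integer seed.
#' @param weighted logical; abundance-weighted MPD (default TRUE).
#' @return list with elements \code{results} (data.frame: plot, S, mpd_obs,
#'   null_mean, null_sd, nri, class), \code{skipped} (plot ids with S < 2)
#'   and \code{summary} (percent clustered/overdispersed and Wilcoxon
#'   signed-rank p of NRI against zero).
#' @export
nri_batch <- function(comm, tree, n_rand = 999, seed = 1L, weighted = TRUE) {
  if (!is.matrix(comm) || nrow(comm) == 0 || ncol(comm) == 0)
    stop("empty community matrix")
  colnames(comm) <- canonical_name(colnames(comm))
  pool <- colnames(comm)[colSums(comm > 0) > 0]
  miss <- setdiff(pool, tree$tip.label)
  if (length(miss))
    stop("community species missing from tree: ", paste(miss, collapse = ", "))
  D <- cophenetic_matrix(tree)
  rows <- vector("list", nrow(comm))
  skipped <- character(0)
  for (p in seq_len(nrow(comm))) {
    plot_id <- rownames(comm)[p]
    w <- comm[p, ]
    w <- w[w > 0]
    if (length(w) < 2) {
      skipped <- c(skipped, plot_id)
      next
    }
    obs <- mpd(w, D, weighted = weighted)
    nd <- null_mpd(as.numeric(w), pool, D, n_rand = n_rand,
                   seed = child_seed(seed, plot_id), weighted = weighted)
    r <- nri(obs, nd)
    rows[[p]] <- cbind(data.frame(plot = plot_id, S = length(w),
                                  stringsAsFactors = FALSE), r)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  summary <- summarize_nri(results)
  list(results = results, skipped = skipped, summary = summary)
}

summarize_nri <- function(results) {
  ok <- results[!is.na(results$nri), , drop = FALSE]
  n <- nrow(ok)
  pct_clustered <- if (n) 100 * mean(ok$nri > 0) else NA_real_
  pct_overdispersed <- if (n) 100 * mean(ok$nri < 0) else NA_real_
  p <- if (n >= 3 && any(ok$nri != 0))
    wilcoxon_signed_rank(ok$nri)$p_value else NA_real_
  list(n = n, mean_nri = if (n) mean(ok$nri) else NA_real_,
       pct_clustered = pct_clustered, pct_overdispersed = pct_overdispersed,
       signed_rank_p = p)
}

#' Read a plot-by-species community CSV
#'
#' Accepts long format (columns \code{plot, species, importance_value}) or
#' wide format (first column \code{plot}, remaining columns one species
#' each). Missing combinations are zeros.
#'
#' @param file path to the CSV.
#' @return numeric matrix, plots in rows, species in columns.
#' @export
read_community <- function(file) {
  df <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  if (all(c("plot", "species", "importance_value") %in% names(df))) {
    df$species <- canonical_name(df$species)
    if (any(df$importance_value < 0)) stop("negative importance value")
    plots <- unique(df$plot)
    species <- sort(unique(df$species))
    m <- matrix(0, length(plots), length(species),
                dimnames = list(as.character(plots), species))
    m[cbind(match(df$plot, plots), match(df$species, species))] <-
      df$importance_value
    m
  } else if (names(df)[1] == "plot") {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df$plot)
    colnames(m) <- canonical_name(colnames(m))
    if (any(m < 0)) stop("negative importance value")
    m
  } else {
    stop("community CSV must be long (plot,species,importance_value) or ",
         "wide with a leading plot column")
  }
}

#' Faith's PD and species richness for every plot
#'
#' @param comm plot-by-species matrix (see [nri_batch()]).
#' @param tree a \code{phylo} object.
#' @return data.frame: plot, SR (richness), PD (root-inclusive Faith's PD).
#' @export
pd_batch <- function(comm, tree) {
  colnames(comm) <- canonical_name(colnames(comm))
  out <- lapply(seq_len(nrow(comm)), function(p) {
    sp <- colnames(comm)[comm[p, ] > 0]
    data.frame(plot = rownames(comm)[p], SR = length(sp),
               PD = if (length(sp)) faith_pd(tree, sp) else 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
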