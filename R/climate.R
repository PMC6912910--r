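bioclim_cols <- function() c(paste0("bio", 1:19), "pet", "ai")

#' Read a plot-by-climate CSV
#'
#' Expects columns \code{plot, bio1..bio19, pet, ai} and optionally
#' \code{lgm_bio1, lgm_bio9, lgm_bio12}. Internal-consistency invariants are
#' checked: bio5 >= bio6, bio7 = bio5 - bio6 (within 0.5 for source
#' rounding), ai > 0.
#'
#' @param file path to the CSV.
#' @return data.frame keyed by \code{plot}.
#' @export
read_climate <- function(file) {
  df <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("plot", bioclim_cols())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("climate CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$bio5 < df$bio6)) stop("bio5 < bio6: inconsistent temperatures")
  if (any(abs(df$bio7 - (df$bio5 - df$bio6)) > 0.5))
    stop("bio7 deviates from bio5 - bio6 by more than 0.5")
  if (any(df$ai <= 0)) stop("aridity index must be > 0")
  df
}

#' Aridity index and aridity classification
#'
#' AI = MAP / PET. AI below 0.3 is classified arid; the 0.3 boundary and
#' above is semiarid (the conventional arid/semiarid demarcation).
#'
#' @param map_mm mean annual precipitation (mm/yr), >= 0.
#' @param pet_mm potential evapotranspiration (mm/yr), > 0.
#' @return data.frame: ai, class ("arid"/"semiarid").
#' @export
aridity_index <- function(map_mm, pet_mm) {
  if (any(pet_mm <= 0)) stop("PET must be > 0")
  if (any(map_mm < 0)) stop("MAP must be >= 0")
  ai <- map_mm / pet_mm
  data.frame(ai = ai, class = ifelse(ai < 0.3, "arid", "semiarid"),
             stringsAsFactors = FALSE)
}

#' PCA of the climate table
#'
#' Variables are standardized to zero mean and unit variance before the
#' decomposition (the climate factors mix degrees C, mm and unitless
#' quantities, so covariance-scale PCA would be dominated by precipitation
#' variance). Constant columns are dropped with a warning; missing values
#' are refused.
#'
#' @param climate data.frame from [read_climate()] (or any plot + numeric
#'   columns table).
#' @param cols columns to use; defaults to the 21 climate factors.
#' @return list: scores (plot x component matrix), loadings, variance
#'   fractions (summing to 1), sdev.
#' @export
climate_pca <- function(climate, cols = bioclim_cols()) {
  x <- as.matrix(climate[, intersect(cols, names(climate)), drop = FALSE])
  if (nrow(x) < 3) stop("need >= 3 plots for PCA")
  if (anyNA(x)) stop("missing values in climate table (imputation refused)")
  keep <- apply(x, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping constant columns: ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  fractions <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  rownames(scores) <- as.character(climate$plot)
  list(scores = scores, loadings = pc$rotation, fractions = fractions,
       sdev = pc$sdev)
}

#' Number of components needed to reach a variance threshold
#'
#' @param fractions per-component variance fractions.
#' @param threshold cumulative fraction to reach (default 0.85).
#' @return the smallest k with cumulative fraction >= threshold.
#' @export
select_components <- function(fractions, threshold = 0.85) {
  if (any(fractions < 0)) stop("negative variance fraction")
  cum <- cumsum(fractions)
  k <- which(cum >= threshold - 1e-12)[1]
  if (is.na(k)) k <- sum(fractions > 0)
  k
}

#' UPGMA habitat groups from PCA scores
#'
#' Average-linkage (UPGMA) agglomerative clustering of the Euclidean
#' distances between plots in the selected principal-component space, cut
#' into exactly \code{n_groups} clusters. Group labels are canonicalized by
#' decreasing group size (ties by smallest plot id) so labels do not depend
#' on plot input order.
#'
#' @param scores plot x component numeric matrix (rownames = plot ids).
#' @param n_groups number of habitat groups (default 3).
#' @return list: groups (named integer vector plot -> group), dendrogram
#'   (hclust object), k, scores.
#' @export
upgma_groups <- function(scores, n_groups = 3) {
  if (nrow(scores) < n_groups)
    stop("more groups requested than plots available")
  d <- stats::dist(scores, method = "euclidean")
  hc <- stats::hclust(d, method = "average")
  raw <- stats::cutree(hc, k = n_groups)
  groups <- canonical_group_labels(raw)
  list(groups = groups, dendrogram = hc, k = n_groups, scores = scores)
}

# Relabel cluster ids 1..k by decreasing size, breaking ties by the
# lexicographically smallest member id, so labels are reproducible across
# plot orderings.
canonical_group_labels <- function(raw) {
  ids <- names(raw)
  if (is.null(ids)) ids <- as.character(seq_along(raw))
  sizes <- table(raw)
  firsts <- vapply(names(sizes), function(g) min(ids[raw == g]), character(1))
  ord <- order(-as.integer(sizes), firsts)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  out <- relabel[raw]
  names(out) <- ids
  out
}

#' Climate anomaly since the Last Glacial Maximum
#'
#' Per-plot difference current - LGM for annual mean temperature (bio1,
#' "AMT"), mean temperature of the driest quarter (bio9, "MTD") and annual
#' precipitation (bio12, "AP"), with a mean +/- SD summary. Implausible
#' temperature anomalies (|delta AMT| > 30 C) abort, as they indicate a
#' units mismatch between the two tables.
#'
#' @param current climate data.frame with plot, bio1, bio9, bio12.
#' @param lgm LGM climate data.frame with the same columns and plots.
#' @return list: anomalies (plot, d_amt, d_mtd, d_ap), summary (variable,
#'   mean, sd).
#' @export
climate_anomaly <- function(current, lgm) {
  if (!all(current$plot %in% lgm$plot) || !all(lgm$plot %in% current$plot))
    stop("plot ids do not match between current and LGM tables")
  lgm <- lgm[match(current$plot, lgm$plot), ]
  an <- data.frame(plot = current$plot,
                   d_amt = current$bio1 - lgm$bio1,
                   d_mtd = current$bio9 - lgm$bio9,
                   d_ap = current$bio12 - lgm$bio12,
                   stringsAsFactors = FALSE)
  if (anyNA(an[-1])) stop("missing values in anomaly computation")
  if (any(abs(an$d_amt) > 30))
    stop("|delta AMT| > 30 C: current and LGM tables look unit-mismatched")
  summ <- data.frame(
    variable = c("AMT_C", "MTD_C", "AP_mm"),
    mean = c(mean(an$d_amt), mean(an$d_mtd), mean(an$d_ap)),
    sd = c(stats::sd(an$d_amt), stats::sd(an$d_mtd), stats::sd(an$d_ap)),
    stringsAsFactors = FALSE)
  list(anomalies = an, summary = summ)
}

# Extract the LGM columns of a combined climate table as an LGM table
# aligned with the current one.
lgm_table <- function(climate) {
  need <- c("lgm_bio1", "lgm_bio9", "lgm_bio12")
  if (!all(need %in% names(climate))) return(NULL)
  data.frame(plot = climate$plot, bio1 = climate$lgm_bio1,
             bio9 = climate$lgm_bio9, bio12 = climate$lgm_bio12,
             stringsAsFactors = FALSE)
}
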