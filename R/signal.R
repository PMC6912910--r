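#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries of \code{C} by \code{lam}, leaving the
#' diagonal unchanged. \code{lam = 1} returns the Brownian-motion covariance;
#' \code{lam = 0} removes all phylogenetic covariance (a star phylogeny).
#'
#' @param C phylogenetic covariance matrix (see [phylo_covariance()]).
#' @param lam lambda in \[0, 1\].
#' @return the transformed covariance matrix.
#' @export
lambda_transform <- function(C, lam) {
  if (!is.numeric(lam) || length(lam) != 1 || is.na(lam) || lam < 0 || lam > 1)
    stop("lambda must be a single value in [0, 1]")
  V <- C * lam
  diag(V) <- diag(C)
  V
}

#' Brownian-motion log-likelihood of a trait vector
#'
#' Multivariate-normal log density of \code{x} with mean \code{mu * 1} and
#' covariance \code{sigma2 * C}.
#'
#' @param x numeric trait vector, one value per taxon (order matching C).
#' @param C covariance structure matrix.
#' @param sigma2 Brownian rate, > 0.
#' @param mu root state.
#' @return the log-likelihood (scalar).
#' @export
bm_loglik <- function(x, C, sigma2, mu) {
  n <- length(x)
  if (nrow(C) != n || ncol(C) != n) stop("dimension mismatch")
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  R <- tryCatch(chol(C), error = function(e) stop("singular covariance"))
  z <- backsolve(R, x - mu, transpose = TRUE)
  logdet <- 2 * sum(log(diag(R))) + n * log(sigma2)
  -0.5 * (n * log(2 * pi) + logdet + sum(z^2) / sigma2)
}

# Profile log-likelihood over lambda: mu and sigma2 have closed-form GLS
# solutions given lambda, so the search is one-dimensional.
#   mu_hat    = (1' V^-1 x) / (1' V^-1 1)
#   sigma2_ml = (x - mu_hat)' V^-1 (x - mu_hat) / n
profile_loglik_lambda <- function(lam, x, C) {
  n <- length(x)
  V <- lambda_transform(C, lam)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf, mu = NA_real_, sigma2 = NA_real_))
  xs <- backsolve(R, x, transpose = TRUE)
  os <- backsolve(R, rep(1, n), transpose = TRUE)
  mu <- sum(os * xs) / sum(os * os)
  rss <- sum((xs - mu * os)^2)
  sigma2 <- rss / n
  if (sigma2 <= 0) return(list(loglik = -Inf, mu = mu, sigma2 = sigma2))
  ll <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + n * log(sigma2) + n)
  list(loglik = ll, mu = mu, sigma2 = sigma2)
}

#' Maximum-likelihood estimate of Pagel's lambda for one trait
#'
#' Maximizes the profile log-likelihood of lambda over \[0, 1\] (root state and
#' Brownian rate profiled out in closed form by generalized least squares),
#' using a 21-point grid pre-scan followed by bounded scalar optimization to
#' avoid local optima. Significance is a likelihood-ratio test of the fitted
#' lambda against lambda = 0 with a chi-square(1) reference, halved because
#' lambda = 0 sits on the boundary of the parameter space.
#'
#' @param tree a \code{phylo} object.
#' @param x named numeric trait vector; names are matched against tip labels
#'   and the tree is pruned to the species with non-missing values.
#' @param trait optional trait name carried into the result.
#' @return a one-row data.frame: trait, n, lambda, sigma2, mu, loglik,
#'   loglik0, p_value.
#' @export
fit_lambda <- function(tree, x, trait = "trait") {
  names(x) <- canonical_name(names(x))
  x <- x[!is.na(x)]
  common <- intersect(tree$tip.label, names(x))
  if (length(common) < 4)
    stop("need >= 4 species shared between tree and trait (have ",
         length(common), ")")
  if (length(common) < length(tree$tip.label)) {
    tree <- ape::drop.tip(tree, setdiff(tree$tip.label, common))
  }
  x <- x[tree$tip.label]
  if (stats::var(x) == 0) stop("zero-variance trait")
  C <- phylo_covariance(tree)

  grid <- seq(0, 1, length.out = 21)
  gl <- vapply(grid, function(l) profile_loglik_lambda(l, x, C)$loglik,
               numeric(1))
  i <- which.max(gl)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(function(l) profile_loglik_lambda(l, x, C)$loglik,
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  # the optimum may sit exactly on a grid point (incl. the 0/1 boundary)
  if (gl[i] > opt$objective) {
    lam_hat <- grid[i]
    ll_hat <- gl[i]
  } else {
    lam_hat <- opt$maximum
    ll_hat <- opt$objective
  }
  fit <- profile_loglik_lambda(lam_hat, x, C)
  ll0 <- profile_loglik_lambda(0, x, C)$loglik
  lrt <- 2 * (ll_hat - ll0)
  p <- if (lrt <= 0) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  data.frame(trait = trait, n = length(x), lambda = lam_hat,
             sigma2 = fit$sigma2, mu = fit$mu,
             loglik = ll_hat, loglik0 = ll0, p_value = p,
             stringsAsFactors = FALSE)
}

#' Phylogenetic-signal report for a trait table
#'
#' Fits Pagel's lambda independently for each trait column, dropping species
#' with missing values per trait (the tree is re-pruned per trait).
#'
#' @param tree a \code{phylo} object.
#' @param traits data.frame with a \code{species} column and one numeric
#'   column per trait.
#' @param log_transform if TRUE, traits are log-transformed before fitting
#'   (all values must be positive). Default FALSE: raw scale.
#' @return data.frame with one row per trait (see [fit_lambda()]).
#' @export
signal_report <- function(tree, traits, log_transform = FALSE) {
  if (!"species" %in% names(traits)) stop("traits must have a species column")
  sp <- canonical_name(traits$species)
  if (anyDuplicated(sp)) stop("duplicate species in trait table")
  cols <- setdiff(names(traits), "species")
  cols <- cols[vapply(traits[cols], is.numeric, logical(1))]
  if (!length(cols)) stop("no numeric trait columns")
  res <- lapply(cols, function(cl) {
    x <- traits[[cl]]
    names(x) <- sp
    if (log_transform) {
      if (any(x[!is.na(x)] <= 0))
        stop("log transform requires positive values (trait ", cl, ")")
      x <- log(x)
    }
    fit_lambda(tree, x, trait = cl)
  })
  do.call(rbind, res)
}

#' Read a species-by-trait CSV
#'
#' Expected columns: \code{species}, then numeric trait columns (the study
#' layout is \code{height_m, canopy_m2, leaf_length_mm, leaf_width_mm}).
#'
#' @param file path to the CSV.
#' @return data.frame with canonical species names.
#' @export
read_traits <- function(file) {
  df <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("trait CSV must have a species column")
  df$species <- canonical_name(df$species)
  df
}

#' Canopy area from crown length and width
#'
#' The crown is approximated as an ellipse: area = length x width x pi / 4.
#'
#' @param length_m,width_m crown extents in metres.
#' @return canopy area in square metres.
#' @export
canopy_area <- function(length_m, width_m) {
  if (any(length_m < 0 | width_m < 0, na.rm = TRUE))
    stop("crown extents must be nonnegative")
  length_m * width_m * pi / 4
}
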