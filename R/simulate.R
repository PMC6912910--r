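#' Default configuration for the synthetic-data generator
#'
#' The defaults emulate the shapes of a dryland shrub survey: 47 species,
#' 116 plots with richness 2-15, four positive traits (height m, canopy
#' m2, leaf length mm, leaf width mm) generated log-normally on a
#' birth-death tree with per-trait lambda targets (0.05, 0.05, 0.5, 0.75),
#' three latent climate habitat groups of 12/17/87 plots, and LGM offsets
#' drawn from Normal(6.37, 0.55) degrees C for annual mean temperature,
#' Normal(5.38, 2.20) degrees C for driest-quarter temperature and
#' Normal(41.05, 21.28) mm for annual precipitation.
#'
#' @param seed master seed.
#' @param ... overrides for any default field.
#' @return a list of generator settings.
#' @export
synth_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    n_species = 47L,
    n_plots = 116L,
    birth = 0.2, death = 0,             # per Myr; pure-birth default
    trait_lambda = c(height_m = 0.05, canopy_m2 = 0.05,
                     leaf_length_mm = 0.5, leaf_width_mm = 0.75),
    trait_mu_log = c(height_m = log(0.8), canopy_m2 = log(0.5),
                     leaf_length_mm = log(20), leaf_width_mm = log(5)),
    trait_sd_log = c(height_m = 0.45, canopy_m2 = 0.6,
                     leaf_length_mm = 0.5, leaf_width_mm = 0.5),
    assembly = "filtering",
    tau_sd = 0.15,                      # filter width, units of trait SD
    delta_sd = 3.0,                     # limiting radius, units of trait SD
    richness = c(2L, 15L),
    iv_meanlog = 0, iv_sdlog = 1,       # importance-value log-normal
    n_groups = 3L,
    group_weights = c(12, 17, 87),      # sandy / steppified / desert
    effect_size = 3,
    lgm_amt = c(6.37, 0.55),
    lgm_mtd = c(5.38, 2.20),
    lgm_ap = c(41.05, 21.28))
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(cfg$birth > cfg$death, cfg$birth >= 0, cfg$death >= 0,
            all(cfg$trait_lambda >= 0 & cfg$trait_lambda <= 1),
            cfg$richness[1] >= 2, cfg$richness[2] <= cfg$n_species)
  cfg
}

#' Simulate an ultrametric birth-death phylogeny
#'
#' Conditioned on the number of extant tips; tips are labelled
#' \code{sp_01, sp_02, ...}.
#'
#' @param n_species number of tips.
#' @param birth,death speciation and extinction rates (per Myr).
#' @param seed integer seed.
#' @return an ultrametric \code{phylo}.
#' @export
simulate_tree <- function(n_species, birth = 0.2, death = 0.05,
                          seed = NULL) {
  tree <- with_seed(seed, ape::rphylo(n_species, birth = birth,
                                      death = death, T0 = 50))
  tree$tip.label <- sprintf("sp_%02d", seq_len(n_species))
  validate_phylogeny(tree)
}

#' Simulate a continuous trait under the lambda model
#'
#' One draw from a multivariate normal with mean \code{mu} and covariance
#' \code{sigma2 *} [lambda_transform()] of the tree's Brownian covariance.
#'
#' @param tree a \code{phylo}.
#' @param lambda signal strength in \[0, 1\].
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param mu root state.
#' @param seed integer seed.
#' @return named trait vector (names = tip labels).
#' @export
simulate_traits <- function(tree, lambda, sigma2 = 1, mu = 0, seed = NULL) {
  C <- phylo_covariance(tree)
  V <- sigma2 * lambda_transform(C, lambda)
  n <- nrow(V)
  x <- if (sigma2 == 0) rep(mu, n)
       else with_seed(seed, as.numeric(MASS::mvrnorm(1, rep(mu, n), V)))
  names(x) <- rownames(C)
  x
}

# sigma2 giving a target SD of tip values on a given tree
rate_for_tip_sd <- function(tree, sd_tip) {
  depth <- mean(diag(phylo_covariance(tree)))
  sd_tip^2 / depth
}

#' Simulate community assembly over a species pool
#'
#' Assembles \code{n_plots} communities from the tree's tips under one of
#' three mechanisms. \code{"neutral"}: species drawn uniformly.
#' \code{"filtering"}: inclusion probability proportional to
#' \code{exp(-(t - opt)^2 / (2 tau^2))} around a per-plot trait optimum
#' (optima spread over the trait range, or supplied, e.g. tied to a
#' moisture gradient). \code{"limiting"}: sequential draws rejecting
#' candidates within trait distance \code{delta} of an already-selected
#' species (stalled selections restart from a fresh anchor); after 1000
#' rejections delta is relaxed by 10\% with a warning.
#' Importance values are drawn log-normally and assigned to the selected
#' species.
#'
#' @param tree a \code{phylo}; its tips are the pool.
#' @param trait named trait vector (required for non-neutral modes).
#' @param n_plots number of plots.
#' @param mode "neutral", "filtering" or "limiting".
#' @param richness length-2 integer range of per-plot richness.
#' @param tau filter width in trait units (default 0.15 trait SD).
#' @param delta limiting radius in trait units (default 3 trait SD).
#' @param optima optional vector of per-plot trait optima (filtering mode).
#' @param iv_meanlog,iv_sdlog log-normal importance-value parameters.
#' @param seed integer seed.
#' @return plot-by-species matrix of importance values with attribute
#'   \code{"mode"}.
#' @export
simulate_communities <- function(tree, trait = NULL, n_plots = 116,
                                 mode = c("neutral", "filtering", "limiting"),
                                 richness = c(2L, 15L),
                                 tau = NULL, delta = NULL, optima = NULL,
                                 iv_meanlog = 0, iv_sdlog = 1, seed = NULL) {
  mode <- match.arg(mode)
  pool <- tree$tip.label
  npool <- length(pool)
  if (richness[2] > npool) stop("richness range exceeds pool size")
  if (mode != "neutral") {
    if (is.null(trait)) stop("trait required for mode ", mode)
    trait <- trait[pool]
    if (anyNA(trait)) stop("trait missing for some pool species")
    if (is.null(tau)) tau <- 0.15 * stats::sd(trait)
    if (is.null(delta)) delta <- 3 * stats::sd(trait)
  }
  m <- matrix(0, n_plots, npool,
              dimnames = list(sprintf("plot_%03d", seq_len(n_plots)), pool))
  with_seed(seed, {
    if (mode == "filtering" && is.null(optima))
      optima <- stats::runif(n_plots, min(trait), max(trait))
    rich_vals <- seq.int(richness[1], richness[2])
    for (p in seq_len(n_plots)) {
      S <- rich_vals[sample.int(length(rich_vals), 1)]
      sel <- switch(mode,
        neutral = sample.int(npool, S),
        filtering = {
          pr <- exp(-(trait - optima[p])^2 / (2 * tau^2)) + 1e-12
          sample.int(npool, S, prob = pr)
        },
        limiting = draw_limiting(trait, S, delta))
      m[p, sel] <- stats::rlnorm(S, iv_meanlog, iv_sdlog)
    }
  })
  attr(m, "mode") <- mode
  m
}

# Sequential limiting-similarity sampler: uniformly propose species and
# reject any within `delta` (trait units) of the selected set. A stalled
# selection (50 consecutive rejections) is restarted from a fresh first
# species, so an unlucky mid-trait anchor does not force the radius down;
# after 1000 total rejections delta is relaxed by 10% with a warning.
draw_limiting <- function(trait, S, delta) {
  n <- length(trait)
  d <- delta
  total <- 0L
  repeat {
    sel <- sample.int(n, 1)
    stall <- 0L
    while (length(sel) < S && stall < 50L) {
      cand <- sample.int(n, 1)
      if (!(cand %in% sel) && all(abs(trait[cand] - trait[sel]) >= d)) {
        sel <- c(sel, cand)
        stall <- 0L
      } else {
        stall <- stall + 1L
        total <- total + 1L
      }
    }
    if (length(sel) == S) return(sel)
    if (total >= 1000L) {
      d <- 0.9 * d
      total <- 0L
      warning("limiting-similarity radius relaxed to ", signif(d, 3),
              call. = FALSE)
    }
  }
}

#' Simulate a correlated bioclimatic table with latent habitat groups
#'
#' The 21 climate factors are generated from three latent plot-level
#' factors (moisture, temperature, seasonality) plus independent noise, so
#' that three principal components capture most of the variance. Group
#' centroids in latent space are separated by \code{effect_size} latent
#' standard deviations; \code{effect_size = 0} gives indistinguishable
#' groups. Internal consistency is enforced (bio7 = bio5 - bio6,
#' bio3 = bio2 * 100 / bio7, ai = bio12 / pet) and LGM columns are the
#' current values minus offsets drawn from the configured normals.
#'
#' @param groups integer vector of true group memberships (one per plot).
#' @param effect_size centroid separation in latent SD units (default 3).
#' @param lgm_amt,lgm_mtd,lgm_ap length-2 (mean, sd) of the LGM anomaly
#'   draws for annual mean temperature (C), driest-quarter temperature (C)
#'   and annual precipitation (mm).
#' @param seed integer seed.
#' @return list: \code{climate} (data.frame plot, bio1..bio19, pet, ai,
#'   lgm_bio1, lgm_bio9, lgm_bio12), \code{latent} (data.frame moisture,
#'   temperature, seasonality), \code{groups}.
#' @export
simulate_climate <- function(groups, effect_size = 3,
                             lgm_amt = c(6.37, 0.55),
                             lgm_mtd = c(5.38, 2.20),
                             lgm_ap = c(41.05, 21.28), seed = NULL) {
  n <- length(groups)
  k <- max(groups)
  # unit-scale centroids: sandy (warm, humid), steppified (cold, dry),
  # desert (hot, extremely arid); recycled beyond 3 groups
  cen <- matrix(c( 1.2,  0.9, -0.6,
                  -0.3, -1.7,  1.0,
                  -1.4,  0.5, -0.2), ncol = 3, byrow = TRUE)
  cen <- cen[((seq_len(k) - 1) %% 3) + 1, , drop = FALSE] * effect_size
  # within-group latent noise is truncated at 2.2 SD: habitat envelopes
  # are compact (a plot of one habitat type does not sit in another's
  # climate), and unbounded tails would mostly probe UPGMA's known
  # sensitivity to single outliers rather than habitat structure
  rtnorm <- function(n, trunc = 2.2) {
    z <- stats::rnorm(n)
    while (any(bad <- abs(z) > trunc)) z[bad] <- stats::rnorm(sum(bad))
    z
  }
  with_seed(seed, {
    M <- cen[groups, 1] + rtnorm(n)
    Tt <- cen[groups, 2] + rtnorm(n)
    Ss <- cen[groups, 3] + rtnorm(n)
    e <- function(s = 1) stats::rnorm(n, 0, s)
    bio1 <- 4 + 2.5 * Tt + e(0.3)
    bio4 <- 950 + 120 * Ss - 40 * M + e(30)
    bio5 <- 29 + 2.5 * Tt + 1.2 * Ss + e(0.3)
    bio6 <- -17 + 3 * Tt - 1.5 * Ss + e(0.3)
    bio7 <- bio5 - bio6
    bio2 <- 13 + 0.8 * Ss + e(0.2)
    bio3 <- bio2 * 100 / bio7
    bio8 <- 18 + 2.5 * Tt + e(0.5)
    bio9 <- -12 + 3 * Tt - Ss + e(0.5)
    bio10 <- 21 + 2.5 * Tt + e(0.3)
    bio11 <- -14 + 3 * Tt - 0.5 * Ss + e(0.3)
    bio12 <- 25 + 115 * exp(0.2 * M + e(0.05))
    bio13 <- bio12 * pmax(0.25 + 0.03 * Ss + e(0.01), 0.05)
    bio14 <- bio12 * pmax(0.015 + e(0.005), 0.001)
    bio15 <- 95 + 15 * Ss + e(3)
    bio16 <- bio12 * pmax(0.55 + 0.04 * Ss + e(0.01), 0.2)
    bio17 <- bio12 * pmax(0.05 + e(0.01), 0.005)
    bio18 <- bio12 * pmax(0.6 + e(0.03), 0.2)
    bio19 <- bio12 * pmax(0.03 + e(0.005), 0.002)
    pet <- pmax(1250 - 120 * M + 40 * Tt + e(20), 400)
    ai <- bio12 / pet
    climate <- data.frame(
      plot = sprintf("plot_%03d", seq_len(n)),
      bio1, bio2, bio3, bio4, bio5, bio6, bio7, bio8, bio9, bio10, bio11,
      bio12, bio13, bio14, bio15, bio16, bio17, bio18, bio19, pet, ai,
      lgm_bio1 = bio1 - stats::rnorm(n, lgm_amt[1], lgm_amt[2]),
      lgm_bio9 = bio9 - stats::rnorm(n, lgm_mtd[1], lgm_mtd[2]),
      lgm_bio12 = bio12 - stats::rnorm(n, lgm_ap[1], lgm_ap[2]),
      stringsAsFactors = FALSE)
    list(climate = climate,
         latent = data.frame(moisture = M, temperature = Tt,
                             seasonality = Ss),
         groups = groups)
  })
}

#' Write a complete synthetic fixture emulating the study's data shapes
#'
#' Generates a 47-tip tree, four log-normal traits with lambda targets
#' (0.05, 0.05, 0.5, 0.75), a 116-plot climate table with three habitat
#' groups (12/17/87 plots), and communities assembled by the configured
#' mechanism (default: habitat filtering on log leaf width, with plot
#' optima tied to the latent moisture factor so NRI-climate correlations
#' have a known sign). Files written: \code{tree.nwk, traits.csv,
#' community.csv, climate.csv, groups_true.csv, config.yaml}. Byte-stable
#' given the seed.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed.
#' @param config a [synth_config()] list.
#' @return (invisibly) a list with the generated objects and file paths.
#' @export
make_fixture <- function(outdir, seed = 1L, config = synth_config(seed)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(config$n_species, config$birth, config$death,
                        seed = child_seed(config$seed, "tree"))
  traits <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  log_traits <- list()
  for (tr in names(config$trait_lambda)) {
    z <- simulate_traits(tree, config$trait_lambda[[tr]],
                         sigma2 = rate_for_tip_sd(tree,
                                                  config$trait_sd_log[[tr]]),
                         mu = config$trait_mu_log[[tr]],
                         seed = child_seed(config$seed, paste0("trait_", tr)))
    log_traits[[tr]] <- z
    traits[[tr]] <- exp(z)[traits$species]
  }
  sizes <- round(config$group_weights / sum(config$group_weights) *
                   config$n_plots)
  sizes[length(sizes)] <- config$n_plots - sum(sizes[-length(sizes)])
  groups <- rep(seq_along(sizes), times = sizes)
  clim <- simulate_climate(groups, effect_size = config$effect_size,
                           lgm_amt = config$lgm_amt, lgm_mtd = config$lgm_mtd,
                           lgm_ap = config$lgm_ap,
                           seed = child_seed(config$seed, "climate"))
  # filtering optima follow the latent moisture gradient on the assembly
  # trait's scale, giving NRI-climate associations a known sign
  atrait <- log_traits[["leaf_width_mm"]]
  optima <- mean(atrait) + stats::sd(atrait) *
    scale(clim$latent$moisture)[, 1]
  comm <- simulate_communities(
    tree, trait = atrait, n_plots = config$n_plots, mode = config$assembly,
    richness = config$richness,
    tau = config$tau_sd * stats::sd(atrait),
    delta = config$delta_sd * stats::sd(atrait),
    optima = if (config$assembly == "filtering") optima else NULL,
    iv_meanlog = config$iv_meanlog, iv_sdlog = config$iv_sdlog,
    seed = child_seed(config$seed, "community"))

  paths <- list(tree = file.path(outdir, "tree.nwk"),
                traits = file.path(outdir, "traits.csv"),
                community = file.path(outdir, "community.csv"),
                climate = file.path(outdir, "climate.csv"),
                groups_true = file.path(outdir, "groups_true.csv"),
                config = file.path(outdir, "config.yaml"))
  write_newick(tree, paths$tree)
  write_output_csv(traits, paths$traits)
  long <- community_to_long(comm)
  write_output_csv(long, paths$community)
  write_output_csv(clim$climate, paths$climate)
  write_output_csv(data.frame(plot = clim$climate$plot, group = groups),
                   paths$groups_true)
  yaml::write_yaml(config, paths$config)
  invisible(list(tree = tree, traits = traits, community = comm,
                 climate = clim$climate, latent = clim$latent,
                 groups = groups, paths = paths, config = config))
}

#' Convert a plot-by-species matrix to long format
#' @param comm plot-by-species matrix.
#' @return data.frame plot, species, importance_value (positive cells only).
#' @export
community_to_long <- function(comm) {
  idx <- which(comm > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(plot = rownames(comm)[idx[, 1]],
             species = colnames(comm)[idx[, 2]],
             importance_value = comm[idx],
             stringsAsFactors = FALSE)
}
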