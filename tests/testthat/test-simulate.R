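test_that("simulate_tree yields ultrametric, seed-stable trees", {
  tr <- simulate_tree(3, seed = 1)
  depths <- diag(phylo_covariance(tr))
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
  expect_identical(write_newick(simulate_tree(12, seed = 9)),
                   write_newick(simulate_tree(12, seed = 9)))
  expect_false(identical(write_newick(simulate_tree(12, seed = 9)),
                         write_newick(simulate_tree(12, seed = 10))))
})

test_that("pure-birth lineage growth tracks the speciation rate", {
  # E[N(t)] = exp(b t) for a Yule process started from one lineage:
  # regress log mean lineage count on elapsed time over replicates
  b <- 0.25
  set.seed(33)
  times <- c(6, 9, 12, 15)
  mean_n <- vapply(times, function(tmax)
    mean(vapply(1:200, function(i)
      length(ape::rlineage(birth = b, death = 0, Tmax = tmax)$tip.label),
      numeric(1))), numeric(1))
  slope <- coef(lm(log(mean_n) ~ times))[["times"]]
  expect_lt(abs(slope - b) / b, 0.10)
})

test_that("simulate_traits honors lambda covariance structure", {
  tr <- simulate_tree(10, seed = 2)
  C <- phylo_covariance(tr)
  # sigma2 = 0 collapses to the root state
  expect_equal(unname(simulate_traits(tr, 1, sigma2 = 0, mu = 3)),
               rep(3, 10))
  # lambda = 0: off-diagonal covariance vanishes (Monte Carlo)
  X0 <- vapply(1:1000, function(i)
    simulate_traits(tr, 0, sigma2 = 0.1, mu = 0, seed = i), numeric(10))
  cv0 <- cov(t(X0))
  off <- cv0[upper.tri(cv0)]
  expect_lt(abs(mean(off)), 3 * sd(off) / sqrt(length(off)))
  # lambda = 1: sister-pair correlation approximates C_ij/sqrt(C_ii C_jj)
  D <- cophenetic_matrix(tr)
  pair <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  X1 <- vapply(1:1000, function(i)
    simulate_traits(tr, 1, sigma2 = 0.1, mu = 0, seed = 5000 + i),
    numeric(10))
  rho_hat <- cor(X1[pair[1], ], X1[pair[2], ])
  rho_exp <- C[pair[1], pair[2]] / sqrt(C[pair[1], pair[1]] *
                                          C[pair[2], pair[2]])
  expect_lt(abs(rho_hat - rho_exp), 0.08)
  expect_error(simulate_traits(tr, 1.5), "lambda")
})

test_that("simulate_communities respects richness, pool and determinism", {
  tr <- simulate_tree(20, seed = 3)
  x <- simulate_traits(tr, 1, sigma2 = 0.05, mu = 0, seed = 4)
  for (mode in c("neutral", "filtering", "limiting")) {
    m <- suppressWarnings(
      simulate_communities(tr, x, n_plots = 15, mode = mode,
                           richness = c(2, 8), seed = 6))
    expect_true(all(rowSums(m > 0) >= 2 & rowSums(m > 0) <= 8))
    expect_true(all(m >= 0))
    m2 <- suppressWarnings(
      simulate_communities(tr, x, n_plots = 15, mode = mode,
                           richness = c(2, 8), seed = 6))
    expect_identical(m, m2)
  }
  expect_error(simulate_communities(tr, n_plots = 3, mode = "filtering"),
               "trait required")
  expect_error(simulate_communities(tr, n_plots = 3, richness = c(2, 50)),
               "exceeds pool")
})

test_that("filtering selects trait-near species; limiting spreads them", {
  tr <- simulate_tree(40, seed = 7)
  x <- simulate_traits(tr, 1, sigma2 = 0.05, mu = 0, seed = 8)
  mf <- simulate_communities(tr, x, n_plots = 40, mode = "filtering",
                             richness = c(6, 6), seed = 9)
  ml <- suppressWarnings(
    simulate_communities(tr, x, n_plots = 40, mode = "limiting",
                         richness = c(6, 6), seed = 10))
  spread <- function(m) mean(vapply(seq_len(nrow(m)), function(i)
    sd(x[colnames(m)[m[i, ] > 0]]), numeric(1)))
  expect_lt(spread(mf), sd(x))       # filtered plots are trait-narrow
  expect_gt(spread(ml), spread(mf))  # limiting plots are trait-spread
})

test_that("simulate_climate satisfies table invariants and group recovery", {
  groups <- rep(1:3, c(12, 17, 87))
  out <- simulate_climate(groups, seed = 14)
  clim <- out$climate
  expect_true(all(clim$bio5 >= clim$bio6))
  expect_equal(clim$bio7, clim$bio5 - clim$bio6, tolerance = 1e-12)
  expect_equal(clim$ai, clim$bio12 / clim$pet, tolerance = 1e-12)
  expect_true(all(clim$ai > 0))
  # three components carry most variance by construction
  pc <- climate_pca(clim)
  expect_gte(sum(pc$fractions[1:3]), 0.85)

  # default effect size separates groups; zero effect size does not
  k <- select_components(pc$fractions)
  ug <- upgma_groups(pc$scores[, 1:k, drop = FALSE], 3)
  expect_gte(oracle_ari(ug$groups[clim$plot], groups), 0.9)
  ari0 <- vapply(1:5, function(i) {
    c0 <- simulate_climate(groups, effect_size = 0, seed = 20 + i)$climate
    p0 <- climate_pca(c0)
    u0 <- upgma_groups(p0$scores[, 1:select_components(p0$fractions),
                                 drop = FALSE], 3)
    oracle_ari(u0$groups[c0$plot], groups)
  }, numeric(1))
  expect_lt(mean(ari0), 0.2)
})

test_that("make_fixture writes byte-stable files that all readers accept", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  cfg <- synth_config(seed = 5, n_species = 20L, n_plots = 30L,
                      richness = c(2L, 8L))
  fx1 <- make_fixture(d1, seed = 5, config = cfg)
  fx2 <- make_fixture(d2, seed = 5, config = cfg)
  for (f in names(fx1$paths)) {
    expect_identical(readLines(fx1$paths[[f]]), readLines(fx2$paths[[f]]),
                     label = f)
  }
  tree <- read_newick(file = fx1$paths$tree)
  comm <- read_community(fx1$paths$community)
  traits <- read_traits(fx1$paths$traits)
  clim <- read_climate(fx1$paths$climate)
  expect_setequal(colnames(comm), intersect(tree$tip.label,
                                            colnames(comm)))
  expect_equal(nrow(clim), 30)
  expect_true(all(traits[, -1] > 0))
})
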