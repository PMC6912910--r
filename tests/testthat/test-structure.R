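toy_setup <- function() {
  t <- read_newick("((A:1.0,B:1.0):1.0,C:2.0);")
  list(tree = t, D = cophenetic_matrix(t))
}

test_that("mpd matches hand values on the 3-tip tree", {
  s <- toy_setup()
  eq <- c(A = 1, B = 1, C = 1)
  expect_equal(mpd(eq, s$D, weighted = FALSE), 10 / 3)
  expect_equal(mpd(c(A = 2, B = 1, C = 1), s$D, weighted = TRUE), 3.2)
  expect_equal(mpd(c(A = 5, B = 3), s$D), s$D["A", "B"])  # single pair
  expect_error(mpd(c(A = 1), s$D), "fewer than 2")
})

test_that("mpd properties: weight rescaling and equal-weight reduction", {
  for (seed in 1:10) {
    set.seed(seed)
    tr <- random_tree(sample(4:10, 1))
    D <- cophenetic_matrix(tr)
    n <- sample(3:length(tr$tip.label), 1)
    sp <- sample(tr$tip.label, n)
    w <- setNames(runif(n, 0.1, 5), sp)
    expect_equal(mpd(w, D), mpd(w * 17.3, D), tolerance = 1e-12)
    expect_equal(mpd(setNames(rep(2.5, n), sp), D, weighted = TRUE),
                 mpd(w, D, weighted = FALSE), tolerance = 1e-12)
    expect_equal(mpd(w, D, TRUE), oracle_mpd(w, D, TRUE), tolerance = 1e-12)
    expect_equal(mpd(w, D, FALSE), oracle_mpd(w, D, FALSE),
                 tolerance = 1e-12)
  }
})

test_that("unweighted mpd agrees with picante", {
  for (seed in 1:5) {
    tr <- simulate_tree(15, seed = seed)
    D <- cophenetic_matrix(tr)
    set.seed(seed)
    sp <- sample(tr$tip.label, 6)
    m <- matrix(as.numeric(tr$tip.label %in% sp), 1,
                dimnames = list("p", tr$tip.label))
    expect_equal(mpd(setNames(m[1, sp], sp), D, weighted = FALSE),
                 picante::mpd(m, D)[1], tolerance = 1e-10)
  }
})

test_that("null_mpd is seed-reproducible and matches enumeration", {
  s <- toy_setup()
  n1 <- null_mpd(c(1, 1), rownames(s$D), s$D, n_rand = 99, seed = 5,
                 weighted = FALSE)
  n2 <- null_mpd(c(1, 1), rownames(s$D), s$D, n_rand = 99, seed = 5,
                 weighted = FALSE)
  expect_identical(n1$values, n2$values)
  # S=2 from 3-species pool: null supported on the three pair distances
  expect_true(all(n1$values %in% c(2, 4)))
  n_big <- null_mpd(c(1, 1), rownames(s$D), s$D, n_rand = 999, seed = 1,
                    weighted = FALSE)
  exact <- oracle_null_mean(c(1, 1), rownames(s$D), s$D, weighted = FALSE)
  se <- sd(n_big$values) / sqrt(999)
  expect_lt(abs(mean(n_big$values) - exact), 3 * se)
  expect_error(null_mpd(rep(1, 4), rownames(s$D), s$D), "exceeds pool")
})

test_that("weighted null mean matches subset-and-assignment enumeration", {
  for (seed in 1:4) {
    tr <- simulate_tree(7, seed = seed)
    D <- cophenetic_matrix(tr)
    set.seed(seed)
    w <- runif(3, 0.5, 4)
    nd <- null_mpd(w, tr$tip.label, D, n_rand = 999, seed = seed + 9,
                   weighted = TRUE)
    exact <- oracle_null_mean(w, tr$tip.label, D, weighted = TRUE)
    se <- sd(nd$values) / sqrt(999)
    expect_lt(abs(mean(nd$values) - exact), 3 * se)
  }
})

test_that("null with S = pool size is degenerate and flagged downstream", {
  s <- toy_setup()
  nd <- null_mpd(c(1, 1, 1), rownames(s$D), s$D, n_rand = 99, seed = 2,
                 weighted = FALSE)
  expect_equal(sd(nd$values), 0)
  r <- nri(mpd(c(A = 1, B = 1, C = 1), s$D, weighted = FALSE), nd)
  expect_true(is.na(r$nri))
  expect_equal(r$class, "random/undefined")
})

test_that("nri follows the sign convention and centering", {
  null <- structure(list(values = c(3.25, 3.5, 3.75)), class = "null_mpd")
  # SD of (3.25, 3.5, 3.75) with n-1 denominator is 0.25
  expect_equal(nri(3.0, null)$nri, 2)
  expect_equal(nri(3.0, null)$class, "clustered")
  expect_equal(nri(4.0, null)$nri, -2)
  expect_equal(nri(4.0, null)$class, "overdispersed")
  expect_equal(nri(3.5, null)$nri, 0)
  expect_error(nri(3, structure(list(values = numeric(0)),
                                class = "null_mpd")), "empty")
})

test_that("nri_batch is reproducible, order-independent, skips S < 2", {
  tr <- simulate_tree(12, seed = 6)
  comm <- simulate_communities(tr, n_plots = 8, mode = "neutral",
                               richness = c(2, 5), seed = 21)
  comm[3, ] <- 0
  comm[3, 2] <- 1  # singleton plot -> skipped
  b1 <- nri_batch(comm, tr, n_rand = 99, seed = 11)
  b2 <- nri_batch(comm, tr, n_rand = 99, seed = 11)
  expect_identical(b1$results, b2$results)
  expect_equal(b1$skipped, rownames(comm)[3])
  # plot order must not change per-plot results (child seeds keyed by id)
  perm <- sample(nrow(comm))
  b3 <- nri_batch(comm[perm, ], tr, n_rand = 99, seed = 11)
  m3 <- b3$results[match(b1$results$plot, b3$results$plot), ]
  expect_equal(m3$nri, b1$results$nri)
  expect_error(nri_batch(comm[0, , drop = FALSE], tr), "empty")
})

test_that("community round-trips through long and wide CSV formats", {
  tr <- simulate_tree(10, seed = 4)
  comm <- simulate_communities(tr, n_plots = 6, mode = "neutral",
                               richness = c(2, 6), seed = 5)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write.csv(community_to_long(comm), f, row.names = FALSE)
  m <- read_community(f)
  expect_equal(m[rownames(comm), colnames(comm)], comm,
               ignore_attr = TRUE)
  wide <- data.frame(plot = rownames(comm), comm, check.names = FALSE)
  write.csv(wide, f, row.names = FALSE)
  m2 <- read_community(f)
  expect_equal(m2[rownames(comm), colnames(comm)], comm,
               ignore_attr = TRUE)
})

test_that("pd_batch reports richness and root-inclusive PD per plot", {
  tr <- simulate_tree(10, seed = 8)
  comm <- simulate_communities(tr, n_plots = 5, mode = "neutral",
                               richness = c(2, 6), seed = 9)
  pb <- pd_batch(comm, tr)
  expect_equal(pb$SR, unname(rowSums(comm > 0)))
  i <- which.max(pb$SR)
  sp <- colnames(comm)[comm[i, ] > 0]
  expect_equal(pb$PD[i], faith_pd(tr, sp))
})
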