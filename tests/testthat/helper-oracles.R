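# Independent oracles used to cross-check the package implementations.
# These deliberately use naive algorithms (path enumeration, brute-force
# pair sums, exhaustive sign/permutation enumeration) so they share no
# code path with the functions they verify.

# Patristic distance by explicit path enumeration: climb from each tip to
# the root recording cumulative distance, then d(i,j) = depth_i + depth_j
# - 2 * depth at the deepest shared ancestor.
oracle_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- ntip + 1L
  path_to_root <- function(tip) {
    nodes <- tip
    dist <- 0
    node <- tip
    while (node != root) {
      dist <- c(dist, dist[length(dist)] + elen[node])
      node <- parent_of[node]
      nodes <- c(nodes, node)
    }
    stats::setNames(dist, nodes)
  }
  paths <- lapply(seq_len(ntip), path_to_root)
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    if (i == j) next
    shared <- intersect(names(paths[[i]]), names(paths[[j]]))
    # deepest shared ancestor = shared node reached earliest from tip i
    anc <- shared[which.min(match(shared, names(paths[[i]])))]
    D[i, j] <- paths[[i]][[anc]] + paths[[j]][[anc]]
  }
  D
}

# Brute-force MPD over explicit unordered pairs.
oracle_mpd <- function(weights, D, weighted = TRUE) {
  sp <- names(weights)[weights > 0]
  w <- weights[sp]
  if (!weighted) w[] <- 1
  num <- den <- 0
  for (i in seq_along(sp)[-length(sp)]) for (j in (i + 1):length(sp)) {
    num <- num + w[i] * w[j] * D[sp[i], sp[j]]
    den <- den + w[i] * w[j]
  }
  as.numeric(num / den)
}

# Exact expectation of the null MPD by enumerating every subset of the
# pool (weight assignment does not change the expectation for unweighted
# MPD; for weighted MPD we also enumerate assignments for small S).
oracle_null_mean <- function(weights, pool, D, weighted = TRUE) {
  S <- length(weights)
  subsets <- utils::combn(pool, S, simplify = FALSE)
  vals <- unlist(lapply(subsets, function(sp) {
    if (!weighted) {
      oracle_mpd(stats::setNames(rep(1, S), sp), D, weighted = FALSE)
    } else {
      perms <- all_permutations(seq_len(S))
      mean(vapply(perms, function(p)
        oracle_mpd(stats::setNames(weights[p], sp), D, TRUE), numeric(1)))
    }
  }))
  mean(vals)
}

all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_permutations(v[-i]), function(p) c(v[i], p)))
  out
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# assignments of the absolute values (requires no zeros).
oracle_signed_rank_p <- function(values) {
  d <- values[values != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  m <- n * (n + 1) / 4                      # null mean of W+
  min(1, mean(abs(w_all - m) >= abs(w_obs - m) - 1e-9))
}

# Exact two-sided rank-sum p-value by enumerating all group assignments.
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  sets <- utils::combn(length(pooled), na, simplify = FALSE)
  w_all <- vapply(sets, function(s) sum(r[s]), numeric(1))
  m <- na * (length(pooled) + 1) / 2        # null mean of W
  min(1, mean(abs(w_all - m) >= abs(w_obs - m) - 1e-9))
}

# Random tree with random (non-ultrametric) branch lengths, for
# property tests that should not depend on ultrametricity.
random_tree <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# Adjusted Rand index between two partitions (Hubert & Arabie).
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  total <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / total
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}
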