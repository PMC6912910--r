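#!/usr/bin/env Rscript
# Net relatedness index per plot against the richness- and
# abundance-preserving randomization null (999 draws), plus Faith's PD
# and species richness. The fixture is assembled by habitat filtering on
# a partly conserved trait, so clustering (NRI > 0) should predominate.

suppressMessages(library(shrubphylo))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

tree <- read_newick(file = "results/fixture/tree.nwk")
comm <- read_community("results/fixture/community.csv")
comm <- comm[, intersect(colnames(comm), tree$tip.label), drop = FALSE]

nb <- nri_batch(comm, tree, n_rand = 999, seed = seed)
write.csv(nb$results, "results/nri.csv", row.names = FALSE)
pdsr <- pd_batch(comm, tree)
write.csv(pdsr, "results/pd_sr.csv", row.names = FALSE)

s <- nb$summary
cat(sprintf("NRI over %d plots (%d skipped): mean %+.3f\n", s$n,
            length(nb$skipped), s$mean_nri))
cat(sprintf("clustered %.2f%% / overdispersed %.2f%%; signed-rank p vs 0: %.3g\n",
            s$pct_clustered, s$pct_overdispersed, s$signed_rank_p))
cat(sprintf("Faith's PD: median %.1f (range %.1f-%.1f); richness median %d\n",
            median(pdsr$PD), min(pdsr$PD), max(pdsr$PD),
            as.integer(median(pdsr$SR))))
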