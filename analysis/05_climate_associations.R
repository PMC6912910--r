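#!/usr/bin/env Rscript
# The inferential layer: per-habitat-group summaries of NRI / PD / SR
# with Wilcoxon tests, Spearman correlations of NRI with the 21 climate
# factors and the LGM anomalies, and per-group PLS regression of NRI on
# climate. The fixture ties filtering optima to the moisture factor, so
# NRI-moisture associations have a known (positive or negative) sign.

suppressMessages(library(shrubphylo))

climate <- read_climate("results/fixture/climate.csv")
nri_t <- read.csv("results/nri.csv", comment.char = "#")
pdsr <- read.csv("results/pd_sr.csv", comment.char = "#")
grp <- read.csv("results/groups.csv", comment.char = "#")
groups <- setNames(grp$group, grp$plot)

an <- climate_anomaly(climate[, c("plot", "bio1", "bio9", "bio12")],
                      data.frame(plot = climate$plot,
                                 bio1 = climate$lgm_bio1,
                                 bio9 = climate$lgm_bio9,
                                 bio12 = climate$lgm_bio12))
write.csv(an$anomalies, "results/anomaly.csv", row.names = FALSE)
cat("LGM anomaly (current - LGM), mean +/- SD:\n")
with(an$summary, cat(sprintf("  %s: %.2f +/- %.2f\n", variable, mean, sd)))

gsum <- group_summaries(nri_t, pdsr, groups)
write.csv(gsum$per_group, "results/group_summary.csv", row.names = FALSE)
if (!is.null(gsum$pairwise))
  write.csv(gsum$pairwise, "results/group_pairwise.csv", row.names = FALSE)
cat("\nper-group NRI medians and tests vs zero:\n")
print(gsum$per_group[, c("group", "n", "median_nri", "nri_vs_zero_p",
                         "flag")], digits = 3, row.names = FALSE)

clim_plus <- merge(climate, an$anomalies, by = "plot")
assoc <- nri_climate_assoc(nri_t, clim_plus, groups)
write.csv(assoc, "results/assoc.csv", row.names = FALSE)
ai_rows <- assoc[assoc$factor == "ai", ]
cat("\nSpearman rho of NRI vs aridity index per group:\n")
print(ai_rows[, c("group", "rho", "p_value", "n")], digits = 3,
      row.names = FALSE)

merged <- merge(nri_t[, c("plot", "nri")], climate, by = "plot")
merged$group <- groups[as.character(merged$plot)]
pls_rows <- do.call(rbind, lapply(sort(unique(merged$group)), function(g) {
  sub <- merged[merged$group == g & !is.na(merged$nri), ]
  if (nrow(sub) < 5) return(NULL)
  fit <- pls_regression(as.matrix(sub[, paste0("bio", 1:19)]), sub$nri,
                        n_components = 3)
  data.frame(group = g, component = seq_len(fit$n_components),
             r2y_cum = fit$r2y_cum)
}))
write.csv(pls_rows, "results/pls.csv", row.names = FALSE)
cat("\nPLS: cumulative NRI variance explained by 3 components per group:\n")
print(aggregate(r2y_cum ~ group, pls_rows, max), digits = 3,
      row.names = FALSE)
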