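# shrubphylo

Community phylogenetics of dryland shrub communities: do the shrubs that
grow together descend from close relatives (phylogenetic clustering,
the fingerprint of habitat filtering when niches are conserved) or from
distant ones (overdispersion, the fingerprint of limiting similarity /
competitive exclusion)? The package implements the full analysis chain
for plot-survey data from arid and semiarid regions, and a synthetic-data
generator with the same statistical structure so everything is testable
end to end without any download.

The chain:

1. **Phylogenetic signal** — Pagel's λ for continuous traits by profile
   maximum likelihood on [0, 1], with a boundary-halved likelihood-ratio
   test against λ = 0. Under the λ model the trait covariance is
   σ²·(λC + (1−λ)·diag C), where C is the Brownian-motion covariance of
   the tree.
2. **Community structure** — abundance-weighted mean pairwise patristic
   distance, MPD_w = Σ_{i<j} w_i w_j d_ij / Σ_{i<j} w_i w_j, compared
   with a null that redraws each plot's species uniformly from the
   regional pool while keeping its richness and abundance multiset
   (999 draws). The net relatedness index is
   NRI = −(MPD_obs − mean MPD_rand)/SD(MPD_rand); NRI > 0 means
   clustering, NRI < 0 overdispersion. Faith's PD (root-inclusive) and
   species richness are reported per plot.
3. **Climate habitats** — PCA of 21 standardized bioclimatic variables
   (Bio1–Bio19, PET, aridity index AI = MAP/PET), components kept to 85%
   cumulative variance, UPGMA clustering of Euclidean distances in
   component space, cut at k = 3 habitat groups.
4. **Associations** — Wilcoxon signed-rank (NRI vs 0) and rank-sum
   (between habitats) tests, Spearman correlations of NRI with climate
   and with climate anomalies since the Last Glacial Maximum
   (current − LGM), and NIPALS partial-least-squares regression of NRI
   on climate with cumulative R²Y per component.

Trees are read/written as Newick (ape), communities as long or wide CSV,
traits and climate as CSV; a taxon-list file drives clade filtering
(e.g. removing gymnosperms before the species pool is built).

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data shaped like a dryland shrub survey (47 species, 116 plots, three
climate habitats of 12/17/87 plots, communities assembled by habitat
filtering along the moisture gradient):

```sh
Rscript analysis/01_simulate_data.R 1      # fixture -> results/fixture/
Rscript analysis/02_phylogenetic_signal.R
Rscript analysis/03_community_structure.R 1
Rscript analysis/04_habitat_groups.R
Rscript analysis/05_climate_associations.R
```

Output of step 2 (λ targets were 0.05, 0.05, 0.5, 0.75 for height,
canopy, leaf length, leaf width):

```
phylogenetic signal (Pagel's lambda, log scale):
          trait  n lambda  p_value
       height_m 47  0.341 0.011792
      canopy_m2 47  0.000 1.000000
 leaf_length_mm 47  0.479 0.002652
  leaf_width_mm 47  0.589 0.000725
mean lambda: leaf traits 0.53 vs size traits 0.17 (ordering as generated)
```

The leaf traits carry significant signal and the size traits mostly do
not; single-trait estimates at n = 47 are noisy (height draws 0.34 from
a 0.05 truth), which is why inference leans on the ordering, not the
point values. Step 3 then shows the filtering-assembled communities are
clustered:

```
NRI over 116 plots (0 skipped): mean +0.685
clustered 79.31% / overdispersed 20.69%; signed-rank p vs 0: 3.24e-09
```

and step 4 recovers the three latent climate habitats exactly
(best-match agreement 100%, PCA's first three components carrying 96% of
the variance). Step 5 reports the LGM anomaly summary (e.g. annual mean
temperature 6.40 ± 0.55 °C against generator truth 6.37 ± 0.55), the
per-habitat NRI medians with significance flags, Spearman NRI–climate
correlations, and per-habitat PLS R²Y.

The same pipeline runs on real inputs via `run_config()` + `run_all()`,
which write the full CSV bundle (signal, NRI, PD/SR, groups, PCA scores,
associations, PLS, anomalies) plus a JSON manifest, byte-reproducibly
for a given seed.

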