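#' Build and validate a pipeline run configuration
#'
#' @param tree,community,traits,climate input file paths (Newick + CSVs).
#' @param clade_filter optional path to a taxon-list file of taxa to remove
#'   (e.g. gymnosperms) before the species pool is built.
#' @param outdir output directory.
#' @param n_rand randomizations per plot (default 999).
#' @param seed master seed.
#' @param n_groups habitat groups (default 3).
#' @param pca_threshold cumulative-variance threshold for component
#'   selection (default 0.85).
#' @param weighted abundance-weighted MPD (default TRUE).
#' @param log_traits log-transform traits before the signal fit.
#' @return a validated \code{run_config} list.
#' @export
run_config <- function(tree, community, traits, climate,
                       clade_filter = NULL, outdir = "results",
                       n_rand = 999L, seed = 1L, n_groups = 3L,
                       pca_threshold = 0.85, weighted = TRUE,
                       log_traits = FALSE) {
  cfg <- list(tree = tree, community = community, traits = traits,
              climate = climate, clade_filter = clade_filter,
              outdir = outdir, n_rand = as.integer(n_rand),
              seed = as.integer(seed), n_groups = as.integer(n_groups),
              pca_threshold = pca_threshold, weighted = weighted,
              log_traits = log_traits)
  for (f in c("tree", "community", "traits", "climate")) {
    if (!file.exists(cfg[[f]]))
      stop("input file for `", f, "` does not exist: ", cfg[[f]])
  }
  if (!is.null(clade_filter) && !file.exists(clade_filter))
    stop("clade filter file does not exist: ", clade_filter)
  if (cfg$n_rand < 1) stop("n_rand must be >= 1")
  if (cfg$pca_threshold <= 0 || cfg$pca_threshold > 1)
    stop("pca_threshold must be in (0, 1]")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a YAML file
#' @param file YAML file whose keys mirror the [run_config()] arguments.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(run_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full community-phylogenetics pipeline
#'
#' Stages: read inputs -> clade filter -> phylogenetic-signal report ->
#' NRI and Faith's PD per plot -> climate PCA + UPGMA habitat groups ->
#' group summaries, NRI-climate Spearman associations and per-group PLS ->
#' LGM climate anomaly. All outputs are CSV (with a seed/config-hash
#' header comment) plus a JSON run manifest; a rerun with the same config
#' reproduces every file byte for byte.
#'
#' @param config a [run_config()] list.
#' @return (invisibly) a list with all computed tables.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  seed <- config$seed
  out <- function(name) file.path(config$outdir, name)
  emit <- function(df, name) write_output_csv(df, out(name), seed, hash)

  tree <- stage("read", read_newick(file = config$tree))
  comm <- stage("read", read_community(config$community))
  traits <- stage("read", read_traits(config$traits))
  climate <- stage("read", read_climate(config$climate))

  n_filtered <- 0L
  if (!is.null(config$clade_filter)) {
    tree <- stage("filter", {
      taxa <- read_taxon_list(config$clade_filter)
      n_filtered <- length(intersect(canonical_name(taxa),
                                     canonical_name(colnames(comm))))
      apply_clade_filter(tree, taxa)
    })
  }
  # community restricted to the filtered tree's tips (removed taxa leave
  # the analysis entirely, pool included)
  comm <- stage("filter", {
    colnames(comm) <- canonical_name(colnames(comm))
    keep <- intersect(colnames(comm), tree$tip.label)
    if (!length(keep)) stop("no community species left on the tree")
    comm[, keep, drop = FALSE]
  })

  signal <- stage("signal",
                  signal_report(tree, traits,
                                log_transform = config$log_traits))
  emit(signal, "signal.csv")

  nb <- stage("structure", nri_batch(comm, tree, n_rand = config$n_rand,
                                     seed = seed,
                                     weighted = config$weighted))
  emit(nb$results, "nri.csv")
  pdsr <- stage("structure", pd_batch(comm, tree))
  emit(pdsr, "pd_sr.csv")
  jsonlite::write_json(nb$summary, out("nri_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  hab <- stage("habitat", {
    pca <- climate_pca(climate)
    k <- select_components(pca$fractions, config$pca_threshold)
    ug <- upgma_groups(pca$scores[, seq_len(k), drop = FALSE],
                       n_groups = config$n_groups)
    list(pca = pca, k = k, groups = ug)
  })
  sc <- as.data.frame(hab$pca$scores[, seq_len(hab$k), drop = FALSE])
  emit(cbind(plot = rownames(hab$pca$scores), sc), "pca_scores.csv")
  emit(data.frame(plot = names(hab$groups$groups),
                  group = hab$groups$groups), "groups.csv")
  write_newick(ape::as.phylo(hab$groups$dendrogram), out("dendrogram.nwk"))

  anomaly <- NULL
  lgm <- lgm_table(climate)
  if (!is.null(lgm)) {
    anomaly <- stage("anomaly",
                     climate_anomaly(climate[, c("plot", "bio1", "bio9",
                                                 "bio12")], lgm))
    emit(anomaly$anomalies, "anomaly.csv")
    emit(anomaly$summary, "anomaly_summary.csv")
  }

  assoc <- stage("associate", {
    clim_plus <- if (is.null(anomaly)) climate
      else merge(climate, anomaly$anomalies, by = "plot")
    nri_climate_assoc(nb$results, clim_plus, hab$groups$groups)
  })
  emit(assoc, "assoc.csv")

  gsum <- stage("associate",
                group_summaries(nb$results, pdsr, hab$groups$groups))
  emit(gsum$per_group, "group_summary.csv")
  if (!is.null(gsum$pairwise)) emit(gsum$pairwise, "group_pairwise.csv")

  pls <- stage("associate", {
    merged <- merge(nb$results[, c("plot", "nri")], climate, by = "plot")
    merged$group <- hab$groups$groups[as.character(merged$plot)]
    rows <- list()
    for (g in sort(unique(merged$group))) {
      sub <- merged[merged$group == g & !is.na(merged$nri), ]
      if (nrow(sub) < 5) next
      X <- as.matrix(sub[, bioclim_cols()])
      fit <- tryCatch(pls_regression(X, sub$nri, n_components = 3),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, component = seq_len(fit$n_components),
        r2y = fit$r2y, r2y_cum = fit$r2y_cum, r2x_cum = fit$r2x_cum)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  if (!is.null(pls)) emit(pls, "pls.csv")

  manifest <- list(seed = seed, config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("shrubphylo")),
                   n_plots = nrow(comm), n_species = ncol(comm),
                   n_species_filtered = n_filtered,
                   plots_skipped = nb$skipped,
                   pca_components = hab$k,
                   outputs = sort(setdiff(list.files(config$outdir),
                                          "manifest.json")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(tree = tree, community = comm, signal = signal, nri = nb,
                 pd_sr = pdsr, habitat = hab, assoc = assoc,
                 group_summary = gsum, pls = pls, anomaly = anomaly,
                 manifest = manifest))
}
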