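#' Analysis configuration
#'
#' A validated configuration for [run_pipeline()].  Exactly one input source
#' must be given: file paths (`ct_table` + `metadata`, optionally
#' `dilution_series`) or a `simulate` block (see [simulate_block()]).
#' Defaults mirror the study settings: fixed efficiency 2.0, 2\% input,
#' per-sample mean normalization, Cd36/Gapdh dropped from the H3K4me3 /
#' H3K27ac multivariate panels, phenotype and 16-vs-16 weight groupings,
#' 10,000,000 permutation iterations averaged over 3 runs.
#'
#' @param ct_table,metadata,dilution_series CSV paths (long Ct table, mouse
#'   metadata, dilution series with columns fraction/ct).
#' @param simulate A [simulate_block()] instead of input files.
#' @param markers IP channel markers to analyze.
#' @param efficiency_policy `"fixed"` uses `efficiency` throughout;
#'   `"estimated"` calibrates from the dilution series when one is present.
#' @param efficiency Per-cycle amplification factor for the fixed policy.
#' @param input_fraction Input-control fraction.
#' @param normalization `"mean"` or `"gapdh"` for the analysis matrices
#'   (both are always computed and reported).
#' @param reference_locus Reference for the gapdh normalization.
#' @param dropped_locus Named character: locus dropped per marker before
#'   MANOVA/PCA/clustering.
#' @param exclude_mice Named list of mouse ids excluded per marker (the
#'   high-variance flags are advisory; exclusion is this config choice).
#' @param groupings Subset of `"phenotype"`, `"weight"`, `"nest"`,
#'   `"batch"` to test per locus.
#' @param weight_group_size Mice per tail in the light-vs-heavy grouping.
#' @param nest_pair Two nest codes for the nest grouping.
#' @param n_split_axes Number of leading PC axis splits tested.
#' @param n_iterations,n_runs Permutation settings.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(ct_table = NULL, metadata = NULL,
                            dilution_series = NULL, simulate = NULL,
                            markers = c("h3k4me3", "h3k27ac"),
                            efficiency_policy = c("fixed", "estimated"),
                            efficiency = 2, input_fraction = 0.02,
                            normalization = c("mean", "gapdh"),
                            reference_locus = "Gapdh",
                            dropped_locus = c(h3k4me3 = "Cd36",
                                              h3k27ac = "Gapdh"),
                            exclude_mice = list(),
                            groupings = c("phenotype", "weight"),
                            weight_group_size = 16,
                            nest_pair = c("A", "H"),
                            n_split_axes = 2,
                            n_iterations = 1e7, n_runs = 3, seed = 1) {
  have_files <- !is.null(ct_table) || !is.null(metadata)
  if (have_files == !is.null(simulate))
    stopf("give either input file paths or a simulate block, not both")
  if (have_files && (is.null(ct_table) || is.null(metadata)))
    stopf("file input needs both 'ct_table' and 'metadata'")
  groupings <- match.arg(groupings, c("phenotype", "weight", "nest", "batch"),
                         several.ok = TRUE)
  structure(list(
    ct_table = ct_table, metadata = metadata,
    dilution_series = dilution_series, simulate = simulate,
    markers = markers,
    efficiency_policy = match.arg(efficiency_policy),
    efficiency = check_number(efficiency, "efficiency", lower = 1,
                              strict_lower = TRUE),
    input_fraction = check_number(input_fraction, "input_fraction", lower = 0,
                                  upper = 1, strict_lower = TRUE),
    normalization = match.arg(normalization),
    reference_locus = reference_locus,
    dropped_locus = dropped_locus,
    exclude_mice = exclude_mice,
    groupings = groupings,
    weight_group_size = check_count(weight_group_size, "weight_group_size",
                                    min = 2L),
    nest_pair = nest_pair,
    n_split_axes = check_count(n_split_axes, "n_split_axes"),
    n_iterations = check_count(n_iterations, "n_iterations"),
    n_runs = check_count(n_runs, "n_runs"),
    seed = check_count(seed, "seed", min = -.Machine$integer.max)
  ), class = "analysis_config")
}

#' Simulation block for a configuration
#'
#' Study conditions for the synthetic generator when the pipeline runs
#' without measured data; defaults are the study layout (25 + 16 mice,
#' 15 loci, 2\% input, E = 2).
#'
#' @param cohort A [cohort_spec()].
#' @param loci List of [locus_spec()]s.
#' @param efficiency True amplification factor used to synthesize Cts.
#' @param sample_scale_sd,bio_noise_sd,outlier_ids,outlier_sd Passed to
#'   [generate_ct_table()].
#' @return A list understood by [run_pipeline()].
#' @export
simulate_block <- function(cohort = cohort_spec(), loci = default_locus_panel(),
                           efficiency = 2, sample_scale_sd = 0.5,
                           bio_noise_sd = 0.3, outlier_ids = character(),
                           outlier_sd = 1.5) {
  list(cohort = cohort, loci = loci, efficiency = efficiency,
       sample_scale_sd = sample_scale_sd, bio_noise_sd = bio_noise_sd,
       outlier_ids = outlier_ids, outlier_sd = outlier_sd)
}

#' Read a configuration from a YAML file
#'
#' Keys mirror the [analysis_config()] arguments; a `simulate:` mapping may
#' override the [cohort_spec()] fields (`cohort:`) and generator noise
#' settings, with the default locus panel.
#'
#' @param path YAML file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sb <- y$simulate
    cohort <- do.call(cohort_spec, if (is.null(sb$cohort)) list() else sb$cohort)
    sim_args <- sb[setdiff(names(sb), "cohort")]
    y$simulate <- do.call(simulate_block, c(list(cohort = cohort), sim_args))
  }
  if (!is.null(y$dropped_locus)) y$dropped_locus <- unlist(y$dropped_locus)
  do.call(analysis_config, y)
}

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, efficiency = 23L, locus_tests = 37L,
               pca_split = 53L, cluster_split = 71L)
  (abs(seed) * 977L + offsets[[stage]]) %% 2147480000L
}

make_grouping <- function(metadata, type, weight_group_size, nest_pair) {
  n <- nrow(metadata)
  g <- rep(NA_character_, n)
  if (type == "phenotype") g <- as.character(metadata$phenotype)
  if (type == "weight") {
    ord <- order(metadata$weight_g)
    g[ord[seq_len(weight_group_size)]] <- "light"
    g[rev(ord)[seq_len(weight_group_size)]] <- "heavy"
  }
  if (type == "nest") g[metadata$nest %in% nest_pair] <-
      metadata$nest[metadata$nest %in% nest_pair]
  if (type == "batch") g <- paste0("prep", metadata$batch)
  names(g) <- metadata$mouse_id
  g
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data acquisition (simulation or files), efficiency
#' policy, replicate aggregation, enrichment over input, IgG fold QC, both
#' normalizations, high-variance sample flagging, per-locus permutation
#' tests per grouping, MANOVA on the reduced locus panel, PCA with axis
#' split tests and weight correlations, Ward clustering with deepest-split
#' tests.  Deterministic given `config$seed`.
#'
#' @param config An [analysis_config()].
#' @return Object of class `report_bundle`; see [write_report_bundle()].
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "analysis_config")) stopf("'config' must be an analysis_config")
  log <- list()
  note <- function(stage, ...) log[[length(log) + 1L]] <<-
    data.frame(stage = stage, ..., stringsAsFactors = FALSE)

  # --- data ---
  truth <- NULL
  if (!is.null(config$simulate)) {
    sb <- config$simulate
    sim_seed <- stage_seed(config$seed, "simulate")
    metadata <- generate_cohort(sb$cohort, seed = sim_seed)
    gen <- generate_ct_table(
      metadata, sb$loci, input_fraction = config$input_fraction,
      efficiency = sb$efficiency, markers = config$markers,
      sample_scale_sd = sb$sample_scale_sd, bio_noise_sd = sb$bio_noise_sd,
      outlier_ids = sb$outlier_ids, outlier_sd = sb$outlier_sd)
    ct <- gen$ct
    truth <- gen$truth
    dilution <- generate_dilution_series(sb$efficiency, noise_sd = 0.1)
    note("simulate", seed = sim_seed)
  } else {
    ct <- read_ct_table(config$ct_table)
    metadata <- read_mouse_table(config$metadata)
    dilution <- if (!is.null(config$dilution_series))
      utils::read.csv(config$dilution_series) else NULL
  }

  # --- efficiency policy ---
  eff_est <- if (!is.null(dilution)) estimate_efficiency(dilution) else NA_real_
  efficiency <- if (config$efficiency_policy == "estimated" && !is.na(eff_est))
    eff_est else config$efficiency
  note("efficiency", value = efficiency, estimated = eff_est)

  mean_ct <- aggregate_replicates(ct)

  markers <- list()
  for (mk in config$markers) {
    ip <- paste0("ip_", mk)
    raw <- enrichment_over_input(mean_ct, ip, efficiency,
                                 config$input_fraction)
    qc <- if ("igg" %in% mean_ct$channel)
      fold_over_negative_control(mean_ct, ip, efficiency) else NULL
    norm_mean <- normalize_matrix(raw, "mean")
    norm_gapdh <- if (config$reference_locus %in% colnames(raw))
      normalize_matrix(raw, "gapdh", config$reference_locus) else NULL
    flags <- flag_high_variance_samples(norm_mean)
    excl <- unique(as.character(config$exclude_mice[[mk]]))
    norm <- if (config$normalization == "mean") norm_mean else norm_gapdh
    keep <- !(rownames(norm) %in% excl)
    meta_k <- metadata[match(rownames(norm)[keep], metadata$mouse_id), ]

    cfg_tests <- perm_config(config$n_iterations, config$n_runs,
                             statistic = "mean_diff")

    # per-locus tests per grouping
    locus_tables <- list()
    for (gtype in config$groupings) {
      g <- make_grouping(meta_k, gtype, config$weight_group_size,
                         config$nest_pair)
      ok <- !is.na(g)
      if (length(unique(g[ok])) != 2L) next
      cfg_tests$seed <- stage_seed(config$seed, "locus_tests")
      locus_tables[[gtype]] <- per_locus_analysis(
        norm[keep, , drop = FALSE][ok, , drop = FALSE], g[ok], cfg_tests)
      note("locus_tests", marker = mk, grouping = gtype,
           seed = cfg_tests$seed, n_iterations = config$n_iterations,
           n_runs = config$n_runs)
    }

    # multivariate battery on the reduced panel
    panel <- select_multivariate_loci(norm, config$dropped_locus[[mk]])
    panel <- panel[keep, , drop = FALSE]
    labels <- meta_k$phenotype
    man <- manova_test(panel, labels)
    pca <- run_pca(panel)
    cfg_split <- perm_config(config$n_iterations, config$n_runs,
                             seed = stage_seed(config$seed, "pca_split"))
    splits <- lapply(seq_len(min(config$n_split_axes, ncol(pca$scores))),
                     function(ax) {
                       s <- split_significance(pca, labels,
                                               split_line("axis", axis = ax),
                                               cfg_split)
                       note("pca_split", marker = mk, axis = ax,
                            seed = cfg_split$seed,
                            n_iterations = config$n_iterations)
                       s
                     })
    names(splits) <- paste0("PC", seq_along(splits))
    weight_cor <- lapply(seq_len(min(2L, ncol(pca$scores))), function(ax)
      pc_covariate_correlation(pca$scores[, ax], meta_k$weight_g))
    names(weight_cor) <- paste0("PC", seq_along(weight_cor))

    tree <- ward_cluster(panel)
    cfg_clu <- perm_config(config$n_iterations, config$n_runs,
                           seed = stage_seed(config$seed, "cluster_split"))
    split_pheno <- deepest_split_test(
      tree, as.numeric(labels != labels[1]), cfg_clu)
    split_weight <- deepest_split_test(tree, meta_k$weight_g, cfg_clu)
    note("cluster_split", marker = mk, seed = cfg_clu$seed,
         n_iterations = config$n_iterations)

    markers[[mk]] <- list(
      raw = raw, norm_mean = norm_mean, norm_gapdh = norm_gapdh,
      igg_qc = qc, sample_flags = flags, excluded = excl,
      locus_tables = locus_tables, manova = man, pca = pca,
      pca_splits = splits, weight_correlations = weight_cor,
      tree = tree, deepest_split = list(phenotype = split_pheno,
                                        weight = split_weight))
  }

  structure(list(metadata = metadata, truth = truth,
                 efficiency = efficiency, efficiency_estimate = eff_est,
                 markers = markers, config = config,
                 log = rbind_fill(log)),
            class = "report_bundle")
}

# rbind data.frames with differing columns (log bookkeeping)
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  }))
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("ChIP-qPCR analysis report: %d mice, markers: %s\n",
              nrow(x$metadata), paste(names(x$markers), collapse = ", ")))
  cat(sprintf("efficiency used: %.3f\n", x$efficiency))
  for (mk in names(x$markers)) {
    m <- x$markers[[mk]]
    cat(sprintf("\n== %s ==\n", mk))
    if (!is.null(m$igg_qc) && any(m$igg_qc$loci$excluded))
      cat("loci below 2-fold over IgG:",
          paste(m$igg_qc$loci$locus[m$igg_qc$loci$excluded], collapse = ", "),
          "\n")
    if (any(m$sample_flags$flagged))
      cat("high-variance samples:",
          paste(m$sample_flags$mouse_id[m$sample_flags$flagged], collapse = ", "),
          "\n")
    if (!is.null(m$locus_tables$phenotype)) {
      lt <- m$locus_tables$phenotype
      sig <- lt$locus[lt$p_mean_adj <= 0.05]
      cat(sprintf("loci with BH-adjusted mean-difference p <= 0.05: %s\n",
                  if (length(sig)) paste(sig, collapse = ", ") else "none"))
    }
    cat(sprintf("MANOVA (%s): p = %.3g\n", m$manova$statistic, m$manova$p))
    for (ax in names(m$pca_splits))
      cat(sprintf("PCA %s split: p = %.3g (%.0f%% variance)\n", ax,
                  m$pca_splits[[ax]]$p,
                  100 * m$pca$variance_fractions[as.integer(sub("PC", "", ax))]))
    ds <- m$deepest_split$phenotype
    cat(sprintf("deepest split (%d vs %d): phenotype perm p = %.3g, Welch p = %.3g\n",
                ds$cluster_sizes[1], ds$cluster_sizes[2], ds$perm_p, ds$welch_p))
  }
  invisible(x)
}

#' Write a report bundle as delimited text files
#'
#' Enrichment matrices (both normalizations), per-locus test tables, MANOVA
#' and split-test summaries, PCA scores/loadings/variance fractions,
#' dendrograms (merge table and Newick) and the run log, one subdirectory
#' per marker.
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$log, file.path(dir, "run_log.csv"), row.names = FALSE)
  for (mk in names(bundle$markers)) {
    m <- bundle$markers[[mk]]
    d <- file.path(dir, mk)
    dir.create(d, showWarnings = FALSE)
    write_enrichment_matrix(m$raw, file.path(d, "enrichment_raw.csv"))
    write_enrichment_matrix(m$norm_mean, file.path(d, "enrichment_mean_norm.csv"))
    if (!is.null(m$norm_gapdh))
      write_enrichment_matrix(m$norm_gapdh, file.path(d, "enrichment_gapdh_norm.csv"))
    if (!is.null(m$igg_qc))
      utils::write.csv(m$igg_qc$loci, file.path(d, "igg_fold_qc.csv"),
                       row.names = FALSE)
    utils::write.csv(m$sample_flags, file.path(d, "sample_flags.csv"),
                     row.names = FALSE)
    for (g in names(m$locus_tables))
      utils::write.csv(m$locus_tables[[g]],
                       file.path(d, sprintf("locus_tests_%s.csv", g)),
                       row.names = FALSE)
    utils::write.csv(data.frame(component = seq_along(m$pca$variance_fractions),
                                variance_fraction = m$pca$variance_fractions),
                     file.path(d, "pca_variance.csv"), row.names = FALSE)
    utils::write.csv(data.frame(mouse_id = rownames(m$pca$scores),
                                m$pca$scores),
                     file.path(d, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(locus = rownames(m$pca$loadings),
                                m$pca$loadings),
                     file.path(d, "pca_loadings.csv"), row.names = FALSE)
    utils::write.csv(data.frame(merge1 = m$tree$merge[, 1],
                                merge2 = m$tree$merge[, 2],
                                height = m$tree$height),
                     file.path(d, "dendrogram_merges.csv"), row.names = FALSE)
    dendrogram_newick(m$tree, file.path(d, "dendrogram.nwk"))
    tests <- data.frame(
      test = c("manova",
               paste0("pca_split_", names(m$pca_splits)),
               "deepest_split_phenotype_perm", "deepest_split_phenotype_welch",
               "deepest_split_weight_perm", "deepest_split_weight_welch"),
      p = c(m$manova$p,
            vapply(m$pca_splits, `[[`, numeric(1), "p"),
            m$deepest_split$phenotype$perm_p, m$deepest_split$phenotype$welch_p,
            m$deepest_split$weight$perm_p, m$deepest_split$weight$welch_p))
    utils::write.csv(tests, file.path(d, "multivariate_tests.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
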