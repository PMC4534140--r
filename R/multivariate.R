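#' Drop the normalization-dependent locus before multivariate analysis
#'
#' Per-sample mean normalization makes the 15 loci linearly dependent, so
#' multivariate analyses run on 14 loci: the weakest/near-zero locus is
#' dropped per marker (Cd36 for H3K4me3, Gapdh for H3K27ac in the study
#' design).  Column order of the remaining loci is preserved.
#'
#' @param norm An `enrichment_matrix`.
#' @param dropped_locus Locus to remove.
#' @return The matrix without that column (attributes preserved).
#' @export
select_multivariate_loci <- function(norm, dropped_locus) {
  if (!dropped_locus %in% colnames(norm))
    stopf("locus '%s' not present in the matrix", dropped_locus)
  out <- unclass(norm)[, setdiff(colnames(norm), dropped_locus), drop = FALSE]
  new_enrichment_matrix(out, attr(norm, "normalization"), attr(norm, "marker"))
}

#' Principal components analysis of an enrichment matrix
#'
#' Columns are centered and scaled to unit sd (n - 1 denominator, the
#' `scale()` convention) and decomposed by singular values.  The sign of
#' each component is fixed deterministically: the largest-magnitude loading
#' is made positive, so score files reproduce byte-for-byte.
#'
#' @param mat Numeric matrix, mice x loci (>= 3 mice, >= 2 loci).
#' @return Object of class `pca_result`: `scores` (mice x components),
#'   `loadings` (loci x components), `variance_fractions`.
#' @export
run_pca <- function(mat) {
  m <- unclass(mat)
  if (nrow(m) < 3L || ncol(m) < 2L) stopf("need >= 3 mice and >= 2 loci")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance locus: %s", paste(colnames(m)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(
    scores = pc$x,
    loadings = pc$rotation,
    variance_fractions = pc$sdev^2 / sum(pc$sdev^2)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d samples, %d components\n", nrow(x$scores),
              ncol(x$scores)))
  vf <- x$variance_fractions[seq_len(min(5L, length(x$variance_fractions)))]
  cat("variance explained:",
      paste0(names(vf <- stats::setNames(vf, paste0("PC", seq_along(vf)))),
             " ", sprintf("%.0f%%", 100 * vf), collapse = ", "), "\n")
  invisible(x)
}

#' Define the split line for a PCA separation test
#'
#' Axis mode splits the score plane at `PC<axis> = 0`; diagonal mode splits
#' along a line through the origin with slope +1 or -1 in the plane of a
#' component pair (the two usages seen in score plots).
#'
#' @param mode `"axis"` or `"diagonal"`.
#' @param axis Component index (axis mode).
#' @param components Length-2 component pair (diagonal mode).
#' @param slope +1 or -1 (diagonal mode).
#' @return Object of class `split_line`.
#' @export
split_line <- function(mode = c("axis", "diagonal"), axis = 1,
                       components = c(1, 2), slope = -1) {
  mode <- match.arg(mode)
  if (mode == "diagonal") {
    if (!slope %in% c(-1, 1)) stopf("diagonal slope must be +1 or -1")
    if (length(components) != 2L) stopf("'components' must name two components")
  }
  structure(list(mode = mode, axis = check_count(axis, "axis"),
                 components = as.integer(components), slope = slope),
            class = "split_line")
}

split_coordinate <- function(pca, line) {
  s <- pca$scores
  if (line$mode == "axis") {
    if (line$axis > ncol(s)) stopf("axis %d beyond available components", line$axis)
    return(s[, line$axis])
  }
  i <- line$components[1]; j <- line$components[2]
  # signed perpendicular distance to the origin line y = slope * x
  (s[, j] - line$slope * s[, i]) / sqrt(2)
}

#' Permutation significance of a PCA group split
#'
#' Each mouse is projected to a signed coordinate: its score on one
#' component (axis mode) or its signed perpendicular distance to an
#' origin-line of slope +/-1 in a component-pair plane (diagonal mode).  The
#' statistic is the absolute difference of group means of that coordinate;
#' group labels are permuted while the (label-independent) projection stays
#' fixed.  Add-one-smoothed p, averaged over runs.
#'
#' @param pca A [run_pca()] result.
#' @param labels Binary group label per mouse.
#' @param line A [split_line()].
#' @param cfg A [perm_config()].
#' @return List: `p`, `runs`, `t_obs`.
#' @export
split_significance <- function(pca, labels, line = split_line(), cfg = perm_config()) {
  coord <- split_coordinate(pca, line)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stopf("labels must have exactly two levels")
  n_a <- sum(labels == lev[1])
  if (n_a == 0L || n_a == length(labels)) stopf("one group is empty")
  ord <- c(coord[labels == lev[1]], coord[labels == lev[2]])
  mc_perm_pvalue(ord, n_a, "mean_diff", cfg$n_iterations, cfg$n_runs, cfg$seed)
}

#' Correlation of a principal component with a covariate
#'
#' Pearson product-moment and Spearman rank correlations (average ranks for
#' ties, normal approximation) with two-sided p-values, e.g. PC scores
#' against body weight.
#'
#' @param scores_pc Per-mouse component coordinate.
#' @param covariate Per-mouse covariate value.
#' @return List: `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`.
#' @export
pc_covariate_correlation <- function(scores_pc, covariate) {
  if (length(scores_pc) != length(covariate) || length(scores_pc) < 4L)
    stopf("need >= 4 paired values")
  if (stats::sd(scores_pc) == 0 || stats::sd(covariate) == 0)
    stopf("zero variance in one of the vectors")
  pe <- stats::cor.test(scores_pc, covariate, method = "pearson")
  sp <- suppressWarnings(
    stats::cor.test(scores_pc, covariate, method = "spearman", exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' One-way MANOVA on a locus panel
#'
#' Tests equality of the two groups' multivariate mean enrichment vectors.
#' Default statistic is Pillai's trace with its standard F approximation;
#' for a two-level factor this is equivalent to Hotelling's T^2.  With a
#' single response column the test reduces to the one-way ANOVA F-test.
#'
#' @param mat Numeric matrix, mice x loci.
#' @param labels Binary group label per mouse.
#' @param statistic `"Pillai"` or `"Wilks"`.
#' @return Object of class `manova_result`: statistic name/value, approx_f,
#'   df, p.
#' @export
manova_test <- function(mat, labels, statistic = c("Pillai", "Wilks")) {
  statistic <- match.arg(statistic)
  m <- as.matrix(unclass(mat))
  f <- factor(labels)
  if (nlevels(f) != 2L) stopf("labels must have exactly two levels")
  if (ncol(m) == 1L) {
    fit <- stats::anova(stats::lm(m[, 1] ~ f))
    return(structure(list(statistic = "F", value = fit$`F value`[1],
                          approx_f = fit$`F value`[1],
                          df = c(fit$Df[1], fit$Df[2]),
                          p = fit$`Pr(>F)`[1]), class = "manova_result"))
  }
  if (nrow(m) <= ncol(m) + 1L)
    stopf(paste("more loci than the F approximation supports for n = %d mice;",
                "reduce the locus panel"), nrow(m))
  fit <- tryCatch(summary(stats::manova(m ~ f), test = statistic)$stats,
                  error = function(e)
                    stopf("MANOVA failed (%s); consider reducing the locus panel",
                          conditionMessage(e)))
  structure(list(statistic = statistic, value = fit[1, statistic],
                 approx_f = fit[1, "approx F"],
                 df = unname(fit[1, c("num Df", "den Df")]),
                 p = fit[1, "Pr(>F)"]), class = "manova_result")
}

#' @export
print.manova_result <- function(x, ...) {
  cat(sprintf("One-way MANOVA (%s = %.4f): approx F = %.3f on %g and %g df, p = %.3g\n",
              x$statistic, x$value, x$approx_f, x$df[1], x$df[2], x$p))
  invisible(x)
}

#' Ward hierarchical clustering of mice
#'
#' Agglomerative clustering of the (centered and scaled, as in [run_pca()])
#' enrichment rows using Euclidean distances and Ward's minimum-variance
#' criterion.  `ward_d2` is the textbook variant (squared distances in the
#' Lance-Williams update); `ward_d` is the legacy variant that historical
#' "ward" implementations applied to unsquared distances, exposed for
#' parity with older analyses.
#'
#' @param mat Numeric matrix, mice x loci, with unique row names.
#' @param variant `"ward_d2"` or `"ward_d"`.
#' @param scale Center and scale columns first (default TRUE).
#' @return An `hclust` object with attribute `variant`.
#' @export
ward_cluster <- function(mat, variant = c("ward_d2", "ward_d"), scale = TRUE) {
  variant <- match.arg(variant)
  m <- as.matrix(unclass(mat))
  if (nrow(m) < 2L) stopf("need at least 2 mice")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stopf("matrix must carry unique mouse ids as row names")
  if (scale) m <- base::scale(m)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = if (variant == "ward_d2") "ward.D2" else "ward.D")
  attr(hc, "variant") <- variant
  hc
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param tree An `hclust` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}

#' Test a variable across the deepest split of a dendrogram
#'
#' Cuts the tree into the two clusters formed by the root merge and tests
#' whether a per-mouse variable (a 0/1 phenotype code or body weight)
#' differs between them: a Monte-Carlo permutation test that shuffles the
#' variable across mice with cluster memberships fixed (statistic =
#' |difference of cluster means|), plus a Welch two-sample t-test.  If a
#' cluster has fewer than 2 mice the Welch p is omitted with a flag.
#'
#' @param tree An `hclust` object from [ward_cluster()].
#' @param variable Per-mouse value, aligned with the tree's labels.
#' @param cfg A [perm_config()].
#' @return List: `perm_p`, `runs`, `welch_p`, `welch_omitted`,
#'   `cluster_sizes`, `cluster_means`, `membership`.
#' @export
deepest_split_test <- function(tree, variable, cfg = perm_config()) {
  memb <- stats::cutree(tree, k = 2)
  if (length(variable) != length(memb))
    stopf("'variable' must have one value per tree leaf")
  variable <- as.numeric(variable)
  sizes <- as.vector(table(memb))
  ord <- c(variable[memb == 1], variable[memb == 2])
  pm <- mc_perm_pvalue(ord, sizes[1], "mean_diff",
                       cfg$n_iterations, cfg$n_runs, cfg$seed)
  welch_ok <- min(sizes) >= 2L &&
    (stats::var(variable[memb == 1]) > 0 || stats::var(variable[memb == 2]) > 0)
  welch_p <- if (welch_ok)
    stats::t.test(variable[memb == 1], variable[memb == 2])$p.value
  else NA_real_
  list(perm_p = pm$p, runs = pm$runs, welch_p = welch_p,
       welch_omitted = !welch_ok, cluster_sizes = sizes,
       cluster_means = c(mean(variable[memb == 1]), mean(variable[memb == 2])),
       membership = memb)
}
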