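perm_stat_code <- function(statistic) {
  switch(statistic, mean_diff = 0L, var_log_ratio = 1L, t_stat = 2L,
         stopf("unknown permutation statistic '%s'", statistic))
}

#' Permutation-test configuration
#'
#' Bundles the Monte-Carlo settings used throughout: iterations per run,
#' number of runs averaged (the reported p is the mean over runs), seed, and
#' the test statistic.  The study design uses 10,000,000 iterations and
#' 3 runs; reduced settings are appropriate for simulation studies.
#'
#' @param n_iterations Label shuffles per run.
#' @param n_runs Independent runs; the reported p averages over them.
#' @param seed Integer seed (`NULL` = continue the current RNG stream).
#' @param statistic `"mean_diff"` (|difference of group means|),
#'   `"var_log_ratio"` (|log ratio of sample variances|) or `"t_stat"`
#'   (studentized option).
#' @return Object of class `perm_config`.
#' @export
perm_config <- function(n_iterations = 1e7, n_runs = 3, seed = NULL,
                        statistic = c("mean_diff", "var_log_ratio", "t_stat")) {
  structure(list(
    n_iterations = check_count(n_iterations, "n_iterations"),
    n_runs = check_count(n_runs, "n_runs"),
    seed = seed,
    statistic = match.arg(statistic)
  ), class = "perm_config")
}

mc_perm_pvalue <- function(x, n_a, statistic, n_iterations, n_runs,
                           seed = NULL) {
  maybe_set_seed(seed)
  code <- perm_stat_code(statistic)
  t_obs <- perm_stat_cpp(x, n_a, code)
  runs <- vapply(seq_len(n_runs), function(r) {
    b <- perm_count_cpp(x, n_a, t_obs, n_iterations, code)
    (b + 1) / (n_iterations + 1)
  }, numeric(1))
  list(p = mean(runs), runs = runs, t_obs = t_obs, degenerate = FALSE)
}

check_two_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stopf("both groups need at least 2 observations")
  if (anyNA(a) || anyNA(b)) stopf("missing values in the group data")
}

#' Monte-Carlo permutation test for equality of means
#'
#' Shuffles group labels; the statistic is the absolute difference of group
#' means.  Each run estimates `p = (#\{T_perm >= T_obs\} + 1) /
#' (n_iterations + 1)` (add-one smoothing, so p is never 0) and the reported
#' p averages the runs.
#'
#' @param a,b Numeric samples (>= 2 each).
#' @param cfg A [perm_config()].
#' @return List: `p` (mean over runs), `runs` (per-run estimates), `t_obs`.
#' @examples
#' p <- permutation_mean_test(rnorm(10), rnorm(10),
#'                            perm_config(1e4, 3, seed = 1))
#' @export
permutation_mean_test <- function(a, b, cfg = perm_config()) {
  check_two_groups(a, b)
  mc_perm_pvalue(c(a, b), length(a), "mean_diff",
                 cfg$n_iterations, cfg$n_runs, cfg$seed)
}

#' Monte-Carlo permutation test for equality of variances
#'
#' Same estimator and multi-run averaging as [permutation_mean_test()] with
#' statistic |log(s2_a / s2_b)| on the sample variances.  If both groups are
#' constant the statistic is undefined: p = 1 is returned with
#' `degenerate = TRUE`.
#'
#' @inheritParams permutation_mean_test
#' @return List: `p`, `runs`, `t_obs`, `degenerate`.
#' @export
permutation_variance_test <- function(a, b, cfg = perm_config()) {
  check_two_groups(a, b)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(list(p = 1, runs = rep(1, cfg$n_runs), t_obs = NA_real_,
                degenerate = TRUE))
  mc_perm_pvalue(c(a, b), length(a), "var_log_ratio",
                 cfg$n_iterations, cfg$n_runs, cfg$seed)
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Enumerates all `choose(n_a + n_b, n_a)` label assignments and returns the
#' exact tail probability of `T_perm >= T_obs`.  Intended as a small-sample
#' oracle; refuses designs beyond 1e6 assignments.
#'
#' @inheritParams permutation_mean_test
#' @param statistic `"mean_diff"`, `"var_log_ratio"` or `"t_stat"`.
#' @return Exact p-value.
#' @export
exact_permutation_p <- function(a, b, statistic = "mean_diff") {
  check_two_groups(a, b)
  n_a <- length(a)
  x <- c(a, b)
  n <- length(x)
  if (choose(n, n_a) > 1e6)
    stopf("combinatorial bound exceeded: choose(%d, %d) > 1e6", n, n_a)
  code <- perm_stat_code(statistic)
  t_obs <- perm_stat_cpp(x, n_a, code)
  eps <- if (is.finite(t_obs)) 1e-12 * (1 + abs(t_obs)) else 0
  idx <- utils::combn(n, n_a)
  stats <- apply(idx, 2, function(i) perm_stat_cpp(c(x[i], x[-i]), n_a, code))
  mean(stats >= t_obs - eps)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across a family of p-values
#' (delegates to [stats::p.adjust()], method `"BH"`), with input validation.
#'
#' @param pvals Numeric p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stopf("p-values must be numeric in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Classical two-group tests
#'
#' Two-sided Student's t (equal variances), Welch t (unequal variances) and
#' the F-test of equal variances, as the conventional companions to the
#' permutation tests.
#'
#' @inheritParams permutation_mean_test
#' @return List with `student_p`, `welch_p`, `f_p`.
#' @export
classical_tests <- function(a, b) {
  check_two_groups(a, b)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stopf("degenerate variance: Student and Welch t-tests undefined")
  list(
    student_p = stats::t.test(a, b, var.equal = TRUE)$p.value,
    welch_p = stats::t.test(a, b)$p.value,
    f_p = if (stats::var(a) > 0 && stats::var(b) > 0)
      stats::var.test(a, b)$p.value else NA_real_
  )
}

#' Per-locus two-group analysis of an enrichment matrix
#'
#' For every locus: group means, sds and coefficients of variation
#' (sd / mean), Monte-Carlo permutation tests of equality of means and of
#' variances, Benjamini-Hochberg adjustment of each permutation family
#' across loci, and the classical-test battery.
#'
#' @param norm An `enrichment_matrix` (typically mean-normalized).
#' @param grouping Group label per mouse (length `nrow(norm)`, two levels).
#' @param cfg A [perm_config()]; its seed governs the whole table.
#' @param exclude Mouse ids removed before testing (e.g. flagged outliers).
#' @return `data.frame`, one row per locus, class `locus_stats_table`.
#' @export
per_locus_analysis <- function(norm, grouping, cfg = perm_config(),
                               exclude = character()) {
  mat <- unclass(norm)
  keep <- !(rownames(mat) %in% exclude)
  mat <- mat[keep, , drop = FALSE]
  grouping <- as.character(grouping[keep])
  lev <- unique(grouping)
  if (length(lev) != 2L) stopf("grouping must have exactly two levels")
  if (min(table(grouping)) < 2L) stopf("each group needs at least 2 mice")
  maybe_set_seed(cfg$seed)
  rows <- lapply(colnames(mat), function(loc) {
    a <- mat[grouping == lev[1], loc]
    b <- mat[grouping == lev[2], loc]
    pm <- mc_perm_pvalue(c(a, b), length(a), cfg$statistic,
                         cfg$n_iterations, cfg$n_runs)
    pv <- if (stats::var(a) == 0 && stats::var(b) == 0)
      list(p = 1, degenerate = TRUE)
    else mc_perm_pvalue(c(a, b), length(a), "var_log_ratio",
                        cfg$n_iterations, cfg$n_runs)
    cl <- classical_tests(a, b)
    data.frame(
      locus = loc,
      mean_a = mean(a), mean_b = mean(b),
      sd_a = stats::sd(a), sd_b = stats::sd(b),
      cv_a = stats::sd(a) / mean(a), cv_b = stats::sd(b) / mean(b),
      p_mean = pm$p, p_var = pv$p,
      student_p = cl$student_p, welch_p = cl$welch_p, f_p = cl$f_p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_mean_adj <- bh_adjust(out$p_mean)
  out$p_var_adj <- bh_adjust(out$p_var)
  attr(out, "groups") <- lev
  attr(out, "n") <- as.vector(table(factor(grouping, levels = lev)))
  class(out) <- c("locus_stats_table", "data.frame")
  out
}

#' @export
print.locus_stats_table <- function(x, ...) {
  g <- attr(x, "groups")
  n <- attr(x, "n")
  cat(sprintf("Per-locus two-group analysis: %s (n = %d) vs %s (n = %d)\n",
              g[1], n[1], g[2], n[2]))
  df <- as.data.frame(x)[, c("locus", "mean_a", "mean_b", "p_mean",
                             "p_mean_adj", "p_var_adj")]
  print(format(df, digits = 3), row.names = FALSE)
  invisible(x)
}
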