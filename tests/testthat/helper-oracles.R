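# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths (and, where the package delegates to a stats
# function, avoid that function too).

# Benjamini-Hochberg step-up by hand: sort, scale by m/i, enforce
# monotonicity by cumulative minimum from the largest rank down, cap at 1,
# map back to input positions.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(scaled))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact two-group permutation p by direct enumeration, written independently
# of exact_permutation_p (plain R, no compiled statistic).
enum_perm_p <- function(a, b, stat = c("mean_diff", "var_log_ratio")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean_diff") {
    function(x, y) abs(mean(x) - mean(y))
  } else {
    function(x, y) {
      va <- stats::var(x); vb <- stats::var(y)
      if (va <= 0 || vb <= 0) Inf else abs(log(va / vb))
    }
  }
  x <- c(a, b)
  n_a <- length(a)
  t_obs <- f(a, b)
  cmb <- utils::combn(length(x), n_a)
  vals <- apply(cmb, 2, function(i) f(x[i], x[-i]))
  thr <- if (is.finite(t_obs)) t_obs - 1e-12 * (1 + abs(t_obs)) else t_obs
  mean(vals >= thr)
}

# Three-sigma Monte-Carlo band around an exact tail probability.
mc_band <- function(p_exact, n_iter) 3 * sqrt(p_exact * (1 - p_exact) / n_iter)

# Hotelling's T^2 for two groups, with its exact F transform.  Used as the
# MANOVA cross-check (two-level Pillai/Hotelling equivalence).
hotelling_p <- function(x, g) {
  g <- factor(g)
  x1 <- x[g == levels(g)[1], , drop = FALSE]
  x2 <- x[g == levels(g)[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x)
  d <- colMeans(x1) - colMeans(x2)
  S <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(S, d))
  f <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
  stats::pf(f, p, n1 + n2 - p - 1, lower.tail = FALSE)
}

# Brute-force Ward (minimum-variance) agglomeration: at every step merge the
# pair of clusters whose union minimally increases the total within-cluster
# sum of squares.  Returns the sequence of partitions as canonical strings.
ward_bruteforce_partitions <- function(x) {
  ss <- function(idx) {
    m <- x[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  parts <- character(0)
  while (length(clusters) > 1L) {
    best <- NULL; best_inc <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      inc <- ss(c(clusters[[i]], clusters[[j]])) -
        ss(clusters[[i]]) - ss(clusters[[j]])
      if (inc < best_inc) { best_inc <- inc; best <- c(j, i) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
    parts <- c(parts, paste(sort(vapply(clusters, function(cl)
      paste(sort(cl), collapse = ","), character(1))), collapse = "|"))
  }
  parts
}

# Partition sequence of an hclust tree in the same canonical encoding.
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  vapply(seq_len(n - 1L), function(k) {
    memb <- stats::cutree(hc, k = n - k)
    paste(sort(vapply(split(seq_len(n), memb), function(cl)
      paste(sort(cl), collapse = ","), character(1))), collapse = "|")
  }, character(1))
}

# Small simulated study dataset: returns the mean-normalized matrix and the
# cohort for one marker.
sim_marker_dataset <- function(seed, n_a = 24, n_b = 15, loci = default_locus_panel(),
                               marker = "h3k4me3", ...) {
  co <- generate_cohort(cohort_spec(n_group_a = n_a, n_group_b = n_b),
                        seed = seed)
  g <- generate_ct_table(co, loci, markers = marker, seed = seed + 1L, ...)
  em <- enrichment_over_input(aggregate_replicates(g$ct),
                              paste0("ip_", marker))
  list(cohort = co, raw = em, norm = normalize_matrix(em, "mean"),
       truth = g$truth)
}
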