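#' Aggregate replicate Ct measurements
#'
#' Averages the determined replicates of every (mouse, locus, channel) cell.
#' Cells whose replicate sd exceeds `max_rep_sd` are flagged; cells where all
#' replicates are undetermined carry the cycle cap (40) and an undetermined
#' flag, which propagates downstream as a minimum-detectable enrichment
#' rather than a missing value.
#'
#' @param ct Long Ct table (mouse_id, locus, channel, replicate, ct; `NA` =
#'   undetermined).
#' @param max_rep_sd Replicate-sd flag threshold in cycles.
#' @param ct_cap Cap substituted for all-undetermined cells.
#' @return `data.frame` with one row per (mouse_id, locus, channel):
#'   ct_mean, n_used, high_sd, undetermined.
#' @export
aggregate_replicates <- function(ct, max_rep_sd = 0.5, ct_cap = 40) {
  if (is.null(ct) || nrow(ct) == 0L) stopf("empty Ct table")
  need <- c("mouse_id", "locus", "channel", "replicate", "ct")
  if (!all(need %in% names(ct)))
    stopf("Ct table must have columns %s", paste(need, collapse = ", "))
  key <- interaction(ct$mouse_id, ct$locus, ct$channel, drop = TRUE, sep = "\r")
  agg <- function(f) as.vector(tapply(ct$ct, key, f))
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  out <- data.frame(
    mouse_id = parts[, 1], locus = parts[, 2], channel = parts[, 3],
    ct_mean = agg(function(v) mean(v, na.rm = TRUE)),
    ct_sd = agg(function(v) stats::sd(v[!is.na(v)])),
    n_used = agg(function(v) sum(!is.na(v))),
    stringsAsFactors = FALSE
  )
  out$undetermined <- out$n_used == 0L
  out$ct_mean[out$undetermined] <- ct_cap
  out$high_sd <- !is.na(out$ct_sd) & out$ct_sd > max_rep_sd
  rownames(out) <- NULL
  out[order(match(out$mouse_id, unique(ct$mouse_id)),
            match(out$locus, unique(ct$locus)),
            match(out$channel, unique(ct$channel))), , drop = FALSE]
}

#' Estimate primer efficiency from a dilution series
#'
#' Fits Ct against log10(input fraction) by least squares; the per-cycle
#' amplification factor is `E = 10^(-1/slope)`.  With exactly two distinct
#' fractions this reduces to the two-point formula.  A perfect 1:10 series at
#' E = 2 has slope -3.3219.
#'
#' @param series `data.frame` with columns fraction and ct (replicates
#'   allowed), e.g. from [generate_dilution_series()].
#' @return Efficiency estimate (single number, > 1 for any sensible series).
#' @export
estimate_efficiency <- function(series) {
  if (!all(c("fraction", "ct") %in% names(series)))
    stopf("'series' must have columns 'fraction' and 'ct'")
  ok <- !is.na(series$ct)
  series <- series[ok, , drop = FALSE]
  if (length(unique(series$fraction)) < 2L)
    stopf("degenerate design: need >= 2 distinct fractions with determined Cts")
  b <- stats::coef(stats::lm(ct ~ log10(fraction), data = series))[[2]]
  if (b >= 0)
    stopf("non-negative slope %.3f: Ct must increase as the input is diluted", b)
  10^(-1 / b)
}

new_enrichment_matrix <- function(mat, normalization, marker) {
  structure(mat, normalization = normalization, marker = marker,
            class = c("enrichment_matrix", "matrix", "array"))
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("ChIP-qPCR enrichment matrix: %d mice x %d loci (%s, %s-normalized)\n",
              nrow(x), ncol(x), attr(x, "marker"), attr(x, "normalization")))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE], digits = 3)
  if (nrow(x) > 6L) cat(sprintf("... %d more mice\n", nrow(x) - 6L))
  invisible(x)
}

mean_ct_matrix <- function(mean_ct, channel) {
  sub <- mean_ct[mean_ct$channel == channel, , drop = FALSE]
  if (nrow(sub) == 0L) stopf("channel '%s' absent from the mean Ct table", channel)
  mice <- unique(mean_ct$mouse_id)
  loci <- unique(mean_ct$locus)
  m <- matrix(NA_real_, length(mice), length(loci),
              dimnames = list(mice, loci))
  m[cbind(match(sub$mouse_id, mice), match(sub$locus, loci))] <- sub$ct_mean
  m
}

#' Enrichment over input by the delta-Ct method
#'
#' `enrichment = E^((Ct_input - log_E(1/input_fraction)) - Ct_IP)`: the input
#' Ct is first corrected down to a 100\% input equivalent (with 2\% input and
#' E = 2 the correction is 5.644 cycles), then the IP Ct is subtracted in the
#' exponent.  The correction is a per-mouse constant, so it cancels under
#' both normalizations.
#'
#' @param mean_ct Aggregated Ct table from [aggregate_replicates()].
#' @param ip_channel Name of the immunoprecipitate channel, e.g.
#'   `"ip_h3k4me3"`.
#' @param efficiency Per-cycle amplification factor (the study fixes 2.0).
#' @param input_fraction Input-control fraction in (0, 1].
#' @return An `enrichment_matrix` (mice x loci, tag `"raw"`).
#' @export
enrichment_over_input <- function(mean_ct, ip_channel, efficiency = 2,
                                  input_fraction = 0.02) {
  check_number(efficiency, "efficiency", lower = 1, strict_lower = TRUE)
  check_number(input_fraction, "input_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  ct_in <- mean_ct_matrix(mean_ct, "input")
  ct_ip <- mean_ct_matrix(mean_ct, ip_channel)
  if (anyNA(ct_in)) stopf("missing input-channel Ct for some (mouse, locus) cell")
  if (anyNA(ct_ip)) stopf("missing IP-channel Ct for some (mouse, locus) cell")
  delta <- (ct_in - log(1 / input_fraction, base = efficiency)) - ct_ip
  new_enrichment_matrix(efficiency^delta, "raw",
                        sub("^ip_", "", ip_channel))
}

#' Fold enrichment over the IgG negative control
#'
#' Per (mouse, locus): `fold = E^(Ct_IgG - Ct_IP)`.  The per-locus summary is
#' the mean fold over mice; loci whose summary is strictly below
#' `min_fold` (default 2) are flagged for exclusion from interpretation.
#'
#' @inheritParams enrichment_over_input
#' @param min_fold Exclusion threshold on the per-locus mean fold.
#' @return List: `fold` (mice x loci matrix) and `loci` (`data.frame` with
#'   mean_fold and excluded flag).
#' @export
fold_over_negative_control <- function(mean_ct, ip_channel, efficiency = 2,
                                       min_fold = 2) {
  check_number(efficiency, "efficiency", lower = 1, strict_lower = TRUE)
  ct_ip <- mean_ct_matrix(mean_ct, ip_channel)
  ct_igg <- mean_ct_matrix(mean_ct, "igg")
  if (anyNA(ct_igg)) stopf("missing IgG-channel Ct for some (mouse, locus) cell")
  fold <- efficiency^(ct_igg - ct_ip)
  mean_fold <- colMeans(fold)
  list(fold = fold,
       loci = data.frame(locus = colnames(fold), mean_fold = mean_fold,
                         excluded = mean_fold < min_fold,
                         row.names = NULL, stringsAsFactors = FALSE))
}

#' Normalize an enrichment matrix per sample
#'
#' Two normalizations: `"gapdh"` divides each mouse's row by its value at a
#' reference locus (reference column becomes exactly 1); `"mean"` divides by
#' the mouse's arithmetic mean over the full locus panel (row means become
#' exactly 1), which centers every sample and cancels chromatin-amount
#' differences.
#'
#' @param raw A raw `enrichment_matrix`.
#' @param method `"mean"` or `"gapdh"`.
#' @param reference_locus Reference column for the `"gapdh"` method.
#' @return A normalized `enrichment_matrix`.
#' @export
normalize_matrix <- function(raw, method = c("mean", "gapdh"),
                             reference_locus = "Gapdh") {
  method <- match.arg(method)
  m <- unclass(raw)
  if (anyNA(m)) stopf("enrichment matrix has missing cells")
  if (method == "gapdh") {
    if (!reference_locus %in% colnames(m))
      stopf("reference locus '%s' not in the matrix", reference_locus)
    ref <- m[, reference_locus]
    if (any(ref <= 0)) stopf("non-positive reference value for some mouse")
    out <- m / ref
  } else {
    out <- m / rowMeans(m)
  }
  new_enrichment_matrix(out, method, attr(raw, "marker"))
}

#' Flag high-variance samples in a mean-normalized matrix
#'
#' Outlier samples swing between extreme low and high normalized values and
#' therefore show a large per-mouse dispersion across loci.  Because loci
#' differ widely in typical marking strength, the dispersion is measured on
#' log2 deviations from the per-locus median profile (so the locus hierarchy
#' itself does not mask sample-level swings): for mouse m,
#' `sd_m = sd over loci of log2(x[m, l] / median_l)`.  A mouse is flagged
#' when its sd exceeds `median(sds) + k * mad(sds)`.  Flags are advisory;
#' exclusion is an analysis choice.
#'
#' @param norm A mean-normalized `enrichment_matrix`.
#' @param k Robust threshold multiplier (default 3.5).
#' @return `data.frame` with mouse_id, sd, flagged.
#' @export
flag_high_variance_samples <- function(norm, k = 3.5) {
  if (!identical(attr(norm, "normalization"), "mean"))
    stopf("sample flagging expects a mean-normalized matrix")
  if (nrow(norm) < 3L) stopf("need at least 3 mice")
  m <- unclass(norm)
  profile <- apply(m, 2, stats::median)
  dev <- log2(sweep(m, 2, profile, `/`))
  sds <- apply(dev, 1, stats::sd)
  thr <- stats::median(sds) + k * stats::mad(sds)
  data.frame(mouse_id = rownames(norm), sd = sds,
             flagged = is.finite(thr) & sds > thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read an enrichment matrix as delimited text
#'
#' Mice as rows, loci as columns, preceded by a `#` tag line recording the
#' marker and normalization.
#'
#' @param x An `enrichment_matrix`.
#' @param path File path.
#' @name enrichment_io
NULL

#' @rdname enrichment_io
#' @export
write_enrichment_matrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# marker=%s normalization=%s",
                     attr(x, "marker"), attr(x, "normalization")), con)
  utils::write.csv(data.frame(mouse_id = rownames(x), unclass(x),
                              check.names = FALSE), con, row.names = FALSE)
  invisible(path)
}

#' @rdname enrichment_io
#' @export
read_enrichment_matrix <- function(path) {
  tag <- readLines(path, n = 1L)
  marker <- sub(".*marker=(\\S+).*", "\\1", tag)
  normalization <- sub(".*normalization=(\\S+).*", "\\1", tag)
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$mouse_id
  new_enrichment_matrix(m, normalization, marker)
}
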