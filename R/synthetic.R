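#' Cohort specification for the synthetic study population
#'
#' Describes a two-group cohort of mice (e.g. socialized nest-box males vs
#' ostracized free-roaming males): group sizes, body-weight distributions,
#' number of chromatin-preparation batches and the nest labels over which
#' group-A mice are distributed.
#'
#' @param n_group_a,n_group_b Number of mice in each phenotype group (>= 2).
#' @param weight_mean_a,weight_sd_a,weight_mean_b,weight_sd_b Body-weight
#'   normal parameters in grams; weights are truncated below at 13 g (the
#'   adult threshold).
#' @param n_batches Number of preparation batches, assigned round-robin.
#' @param nest_labels Location codes for group-A mice (round-robin); group-B
#'   mice are free-roaming and carry the code `"Z"`.
#' @return An object of class `cohort_spec`.
#' @examples
#' cohort_spec()  # the default 25 + 16 study layout
#' @export
cohort_spec <- function(n_group_a = 25, n_group_b = 16,
                        weight_mean_a = 22.7, weight_sd_a = 1.8,
                        weight_mean_b = 25.4, weight_sd_b = 2.3,
                        n_batches = 2,
                        nest_labels = c("A", "E", "F", "G", "H")) {
  spec <- list(
    n_group_a = check_count(n_group_a, "n_group_a", min = 2L),
    n_group_b = check_count(n_group_b, "n_group_b", min = 2L),
    weight_mean_a = check_number(weight_mean_a, "weight_mean_a", lower = 0,
                                 strict_lower = TRUE),
    weight_sd_a = check_number(weight_sd_a, "weight_sd_a", lower = 0),
    weight_mean_b = check_number(weight_mean_b, "weight_mean_b", lower = 0,
                                 strict_lower = TRUE),
    weight_sd_b = check_number(weight_sd_b, "weight_sd_b", lower = 0),
    n_batches = check_count(n_batches, "n_batches", min = 1L),
    nest_labels = as.character(nest_labels)
  )
  if (length(spec$nest_labels) < 1L) stopf("'nest_labels' must be non-empty")
  structure(spec, class = "cohort_spec")
}

#' Locus specification for the synthetic generator
#'
#' Holds the per-locus ground truth: baseline log2 enrichment over input, the
#' planted group effect (group B minus group A, log2 units), the IgG
#' background offset (how many log2 units the negative control sits below the
#' immunoprecipitate) and the replicate-level Ct noise.
#'
#' `base_log2_enrichment` and `effect_log2` may be single numbers (shared by
#' all markers) or named vectors with one entry per marker, e.g.
#' `c(h3k4me3 = 5, h3k27ac = 0.8)`.
#'
#' @param name Unique locus identifier.
#' @param base_log2_enrichment Baseline log2 enrichment over input.
#' @param effect_log2 Planted group effect in log2 units (default 0).
#' @param igg_log2_offset Log2 units separating the first marker's IP signal
#'   from the IgG background (>= 0).
#' @param ct_noise_sd Replicate Ct jitter sd in cycles (>= 0).
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(name, base_log2_enrichment, effect_log2 = 0,
                       igg_log2_offset = 3, ct_noise_sd = 0.15) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stopf("'name' must be a non-empty string")
  if (!is.numeric(base_log2_enrichment) || length(base_log2_enrichment) < 1L)
    stopf("'base_log2_enrichment' must be numeric")
  if (!is.numeric(effect_log2)) stopf("'effect_log2' must be numeric")
  structure(list(
    name = name,
    base_log2_enrichment = base_log2_enrichment,
    effect_log2 = effect_log2,
    igg_log2_offset = check_number(igg_log2_offset, "igg_log2_offset", lower = 0),
    ct_noise_sd = check_number(ct_noise_sd, "ct_noise_sd", lower = 0)
  ), class = "locus_spec")
}

#' Default 15-locus panel with the study's effect pattern
#'
#' Fifteen TSS amplicons around metabolic genes plus the house-keeping
#' control Gapdh.  Baselines echo the observed enrichment hierarchy (Gapdh,
#' Fasn, Nr3c1, Insig2 strong for H3K4me3; Slc27a5 and Acox2 strong for
#' H3K27ac; Cyp4a14 near the detection floor) and planted effects follow the
#' reported direction of change: for H3K4me3 six effect loci (Nr3c1, Sqle,
#' Ppara up; Cyp4a14, Pck1, Gapdh down), for H3K27ac three (Nr3c1 up; Fasn,
#' Plin5 down).  Cd36 carries a small IgG offset so its fold over the
#' negative control falls below 2 and triggers the exclusion flag.
#'
#' @param effect_scale Multiplier on all planted effects; 0 yields a global
#'   null panel.
#' @param ct_noise_sd Replicate Ct jitter applied to every locus.
#' @return List of [locus_spec()] objects.
#' @export
default_locus_panel <- function(effect_scale = 1, ct_noise_sd = 0.15) {
  effect_scale <- check_number(effect_scale, "effect_scale")
  p <- list(
    #         name        k4.base k27.base  k4.eff k27.eff igg
    list("Gapdh",    5.0, 0.8, -0.6,  0.0, 5.0),
    list("Cd36",     1.5, 1.5,  0.0, -0.6, 0.8),
    list("Slc27a5",  2.5, 3.5,  0.0,  0.0, 2.5),
    list("Ppara",    2.5, 2.0,  0.6,  0.0, 2.5),
    list("Pparg",    2.0, 2.0,  0.0,  0.0, 2.5),
    list("Acox2",    2.5, 3.5,  0.0,  0.0, 2.5),
    list("Cyp4a14",  0.8, 1.5, -1.0,  0.0, 2.0),
    list("Fasn",     4.5, 2.5,  0.0, -0.6, 4.0),
    list("Nr3c1",    4.5, 2.5,  0.6,  0.6, 4.0),
    list("Pck1",     3.0, 2.5, -0.6,  0.0, 3.0),
    list("Insig2",   4.5, 3.0,  0.0,  0.0, 4.0),
    list("Plin5",    3.0, 2.5,  0.0, -0.8, 3.0),
    list("Igfbp2",   2.5, 2.0,  0.0,  0.0, 2.5),
    list("Sqle",     3.0, 2.5,  0.6,  0.0, 3.0),
    list("Serpina6", 2.0, 2.0,  0.0,  0.0, 2.5)
  )
  lapply(p, function(x) locus_spec(
    name = x[[1]],
    base_log2_enrichment = c(h3k4me3 = x[[2]], h3k27ac = x[[3]]),
    effect_log2 = effect_scale * c(h3k4me3 = x[[4]], h3k27ac = x[[5]]),
    igg_log2_offset = x[[6]],
    ct_noise_sd = ct_noise_sd
  ))
}

#' Generate a synthetic mouse cohort
#'
#' Draws one record per mouse: id, phenotype, nest code, body weight (normal
#' within group, truncated below 13 g) and a round-robin batch assignment.
#' Group-A ids are prefixed with the lower-case nest letter, group-B mice
#' are free-roaming (`z` prefix, nest `"Z"`).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical seeds reproduce the table exactly.
#' @return `data.frame` with columns mouse_id, phenotype, nest, weight_g,
#'   batch.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!inherits(spec, "cohort_spec")) stopf("'spec' must be a cohort_spec")
  maybe_set_seed(seed)
  rtruncnorm13 <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    w <- stats::rnorm(n, mean, sd)
    while (any(bad <- w <= 13)) w[bad] <- stats::rnorm(sum(bad), mean, sd)
    w
  }
  nests_a <- rep_len(spec$nest_labels, spec$n_group_a)
  idx_a <- stats::ave(seq_len(spec$n_group_a), nests_a, FUN = seq_along)
  df <- data.frame(
    mouse_id = c(paste0(tolower(nests_a), idx_a),
                 paste0("z", seq_len(spec$n_group_b))),
    phenotype = rep(c("socialized", "ostracized"),
                    c(spec$n_group_a, spec$n_group_b)),
    nest = c(nests_a, rep("Z", spec$n_group_b)),
    weight_g = c(rtruncnorm13(spec$n_group_a, spec$weight_mean_a, spec$weight_sd_a),
                 rtruncnorm13(spec$n_group_b, spec$weight_mean_b, spec$weight_sd_b)),
    stringsAsFactors = FALSE
  )
  df$batch <- rep_len(seq_len(spec$n_batches), nrow(df))
  df
}

resolve_marker_value <- function(x, markers, what, locus) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(x, length(markers)), markers))
  if (is.null(names(x)) || !all(markers %in% names(x)))
    stopf("locus '%s': '%s' must be a scalar or named with entries for %s",
          locus, what, paste(markers, collapse = ", "))
  x[markers]
}

#' Generate a synthetic Ct table with known ground truth
#'
#' Inverts the delta-Ct percent-input enrichment calculation: for every
#' (mouse, locus) cell a true log2 enrichment is drawn as
#' `base + effect * [group B] + biological noise (+ outlier noise)`, then Ct
#' values are constructed so that [enrichment_over_input()] applied to the
#' table recovers the truth exactly in the noiseless limit.  Channels are
#' the input control (measured at `input_fraction` of the IP material), one
#' IP channel per marker, and an IgG negative control placed
#' `igg_log2_offset` log2 units below the first marker's IP signal.  Each
#' channel is measured in `n_replicates` replicates with normal Ct jitter;
#' Cts beyond the 40-cycle cap are recorded as undetermined (`NA`).
#'
#' @param cohort Mouse table from [generate_cohort()].
#' @param loci List of [locus_spec()] objects with unique names.
#' @param input_fraction Fraction of material in the input control, in
#'   (0, 1]; the study design uses 2\%.
#' @param efficiency Per-cycle amplification factor E (> 1).
#' @param markers Marker names; each contributes an `ip_<marker>` channel.
#' @param base_input_ct Noiseless Ct of a 100\% input measurement.
#' @param sample_scale_sd Per-mouse chromatin-amount scaling, sd in cycles;
#'   shifts all channels of a mouse equally and cancels under per-sample
#'   normalization.
#' @param bio_noise_sd Per-(mouse, locus, marker) biological noise on log2
#'   enrichment.
#' @param outlier_ids Mouse ids receiving outlier noise: extra log2 noise of
#'   sd `outlier_sd` whose sign alternates across loci, so the mouse swings
#'   between extreme low and high values.
#' @param outlier_sd Outlier noise magnitude in log2 units.
#' @param n_replicates Replicates per channel (study design: 3).
#' @param ct_cap Cycle cap; Cts above it are undetermined.
#' @param seed Integer seed.
#' @return List with elements `ct` (long `data.frame`: mouse_id, locus,
#'   channel, replicate, ct) and `truth` (class `truth_table`: `$cells` with
#'   true enrichment per mouse/locus/marker, `$mice` with scaling, outlier
#'   flag and batch, `$loci` with the planted effects).
#' @export
generate_ct_table <- function(cohort, loci,
                              input_fraction = 0.02, efficiency = 2,
                              markers = c("h3k4me3", "h3k27ac"),
                              base_input_ct = 24,
                              sample_scale_sd = 0.5, bio_noise_sd = 0.3,
                              outlier_ids = character(), outlier_sd = 1.5,
                              n_replicates = 3, ct_cap = 40, seed = NULL) {
  if (length(loci) == 0L) stopf("'loci' must contain at least one locus_spec")
  if (!all(vapply(loci, inherits, logical(1), "locus_spec")))
    stopf("'loci' must be a list of locus_spec objects")
  locus_names <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(locus_names)) stopf("locus names must be unique")
  check_number(input_fraction, "input_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(efficiency, "efficiency", lower = 1, strict_lower = TRUE)
  if (!all(outlier_ids %in% cohort$mouse_id))
    stopf("unknown mouse id in 'outlier_ids'")
  maybe_set_seed(seed)

  n_m <- nrow(cohort)
  n_l <- length(loci)
  n_k <- length(markers)
  log2E <- log2(efficiency)
  # group-B indicator: any phenotype differing from the first row's
  is_b <- as.numeric(cohort$phenotype != cohort$phenotype[1])

  scale_m <- stats::rnorm(n_m, 0, sample_scale_sd)
  bio <- array(stats::rnorm(n_m * n_l * n_k, 0, bio_noise_sd),
               dim = c(n_m, n_l, n_k))
  out_flag <- cohort$mouse_id %in% outlier_ids
  outlier <- matrix(0, n_m, n_l)
  if (any(out_flag)) {
    mag <- matrix(abs(stats::rnorm(sum(out_flag) * n_l, 0, outlier_sd)),
                  nrow = sum(out_flag))
    signs <- rep_len(c(1, -1), n_l)
    outlier[out_flag, ] <- sweep(mag, 2, signs, `*`)
  }

  base <- vapply(loci, function(l)
    resolve_marker_value(l$base_log2_enrichment, markers,
                         "base_log2_enrichment", l$name), numeric(n_k))
  eff <- vapply(loci, function(l)
    resolve_marker_value(l$effect_log2, markers, "effect_log2", l$name),
    numeric(n_k))
  base <- matrix(base, nrow = n_k)  # markers x loci
  eff <- matrix(eff, nrow = n_k)
  igg_off <- vapply(loci, `[[`, numeric(1), "igg_log2_offset")
  noise_sd <- vapply(loci, `[[`, numeric(1), "ct_noise_sd")

  # true log2 enrichment, mice x loci x markers
  L <- array(0, dim = c(n_m, n_l, n_k))
  for (k in seq_len(n_k))
    L[, , k] <- outer(is_b, eff[k, ]) +
      matrix(base[k, ], n_m, n_l, byrow = TRUE) + bio[, , k] + outlier

  ct0_input <- base_input_ct - log(input_fraction, base = efficiency) + scale_m
  # noiseless channel Cts, mice x loci per channel
  ct0 <- list(input = matrix(ct0_input, n_m, n_l))
  for (k in seq_len(n_k))
    ct0[[paste0("ip_", markers[k])]] <-
      base_input_ct + scale_m - matrix(L[, , k], n_m, n_l) / log2E
  ct0$igg <- ct0[[paste0("ip_", markers[1])]] +
    matrix(igg_off / log2E, n_m, n_l, byrow = TRUE)

  channels <- names(ct0)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      mouse = seq_len(n_m), locus = seq_len(n_l),
                      channel = seq_along(channels))
  ct_val <- numeric(nrow(grid))
  for (ch in seq_along(channels)) {
    sel <- grid$channel == ch
    mu <- ct0[[ch]][cbind(grid$mouse[sel], grid$locus[sel])]
    jitter_sd <- noise_sd[grid$locus[sel]]
    ct_val[sel] <- mu + stats::rnorm(sum(sel), 0, jitter_sd)
  }
  ct_val[ct_val > ct_cap] <- NA_real_
  ct <- data.frame(
    mouse_id = cohort$mouse_id[grid$mouse],
    locus = locus_names[grid$locus],
    channel = channels[grid$channel],
    replicate = grid$replicate,
    ct = ct_val,
    stringsAsFactors = FALSE
  )
  ct <- ct[order(match(ct$mouse_id, cohort$mouse_id),
                 match(ct$locus, locus_names),
                 match(ct$channel, channels), ct$replicate), ]
  rownames(ct) <- NULL

  cells <- expand.grid(mouse_id = cohort$mouse_id, locus = locus_names,
                       marker = markers, stringsAsFactors = FALSE)
  cells$true_enrichment <- 2^as.vector(L)
  truth <- structure(list(
    cells = cells,
    mice = data.frame(mouse_id = cohort$mouse_id, scale_cycles = scale_m,
                      outlier = out_flag, batch = cohort$batch,
                      stringsAsFactors = FALSE),
    loci = data.frame(locus = rep(locus_names, each = n_k),
                      marker = rep(markers, n_l),
                      effect_log2 = as.vector(eff),
                      stringsAsFactors = FALSE)
  ), class = "truth_table")
  list(ct = ct, truth = truth)
}

#' Generate a primer-calibration dilution series
#'
#' Emulates a 1:10 input dilution series (e.g. 20\%, 2\%, 0.2\% of input):
#' `Ct_i = base_ct - log_E(fraction_i / fraction_1) + noise`, measured in
#' triplicate.
#'
#' @param efficiency True per-cycle amplification factor (> 1).
#' @param fractions Strictly decreasing input fractions in (0, 1], >= 2.
#' @param base_ct Ct of the first (largest) fraction.
#' @param noise_sd Replicate Ct noise in cycles.
#' @param n_replicates Replicates per fraction.
#' @param seed Integer seed.
#' @return `data.frame` with columns fraction, replicate, ct.
#' @export
generate_dilution_series <- function(efficiency, fractions = c(0.2, 0.02, 0.002),
                                     base_ct = 20, noise_sd = 0,
                                     n_replicates = 3, seed = NULL) {
  check_number(efficiency, "efficiency", lower = 1, strict_lower = TRUE)
  if (length(fractions) < 2L) stopf("need at least 2 dilution fractions")
  if (any(fractions <= 0) || any(fractions > 1))
    stopf("fractions must lie in (0, 1]")
  if (any(diff(fractions) >= 0)) stopf("fractions must be strictly decreasing")
  maybe_set_seed(seed)
  mu <- base_ct - log(fractions / fractions[1], base = efficiency)
  df <- data.frame(
    fraction = rep(fractions, each = n_replicates),
    replicate = rep(seq_len(n_replicates), length(fractions)),
    ct = rep(mu, each = n_replicates) +
      stats::rnorm(length(fractions) * n_replicates, 0, noise_sd)
  )
  df
}

#' Read or write Ct tables and mouse metadata as CSV
#'
#' Ct tables are written in long format (mouse_id, locus, channel, replicate,
#' ct) with an empty ct field for undetermined measurements; metadata carries
#' mouse_id, phenotype, nest, weight_g, batch.
#'
#' @param x Table to write.
#' @param path File path.
#' @return `read_*` return a `data.frame`; `write_*` return `path` invisibly.
#' @name ct_io
NULL

#' @rdname ct_io
#' @export
write_ct_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname ct_io
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(ct = "numeric"))
  df
}

#' @rdname ct_io
#' @export
write_mouse_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname ct_io
#' @export
read_mouse_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
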