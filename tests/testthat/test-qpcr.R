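make_ct <- function(reps, mouse = "m1", locus = "L", channel = "input") {
  data.frame(mouse_id = mouse, locus = locus, channel = channel,
             replicate = seq_along(reps), ct = reps,
             stringsAsFactors = FALSE)
}

test_that("replicate aggregation averages, drops undetermined and flags dispersion", {
  agg <- aggregate_replicates(make_ct(c(20.0, 20.1, 20.2)))
  expect_equal(agg$ct_mean, 20.1)
  expect_false(agg$high_sd)
  expect_equal(agg$n_used, 3L)

  agg2 <- aggregate_replicates(make_ct(c(20.0, 20.0, NA)))
  expect_equal(agg2$ct_mean, 20.0)
  expect_equal(agg2$n_used, 2L)

  agg3 <- aggregate_replicates(make_ct(c(NA, NA, NA)))
  expect_equal(agg3$ct_mean, 40)
  expect_true(agg3$undetermined)

  agg4 <- aggregate_replicates(make_ct(c(19, 20, 21)))
  expect_true(agg4$high_sd)  # sd = 1 > 0.5 cycles

  empty <- data.frame(mouse_id = character(0), locus = character(0),
                      channel = character(0), replicate = integer(0),
                      ct = numeric(0))
  expect_error(aggregate_replicates(empty), "empty")
})

test_that("an all-undetermined IP cell propagates as the floor enrichment", {
  ct <- rbind(make_ct(c(25, 25, 25), channel = "input"),
              make_ct(c(NA, NA, NA), channel = "ip_h3k4me3"))
  em <- enrichment_over_input(aggregate_replicates(ct), "ip_h3k4me3",
                              efficiency = 2, input_fraction = 0.02)
  # hand computation with the cap: 2^(25 - log2(50) - 40)
  expect_equal(unname(unclass(em)[1, 1]), 2^(25 - log2(1 / 0.02) - 40))
})

test_that("efficiency estimation inverts the dilution slope", {
  series <- data.frame(fraction = c(0.2, 0.02, 0.002),
                       ct = c(20, 23.3219, 26.6439))
  expect_equal(estimate_efficiency(series), 2, tolerance = 1e-4)

  # two-point formula: Ct 20 at 20%, 23 at 2% -> E = 10^(1/3)
  two <- data.frame(fraction = c(0.2, 0.02), ct = c(20, 23))
  expect_equal(estimate_efficiency(two), 10^(1 / 3), tolerance = 1e-12)

  # exact on noiseless synthetic series across the plausible E range
  for (E in c(1.6, 1.9, 2.0, 2.2, 2.5)) {
    ds <- generate_dilution_series(E, noise_sd = 0)
    expect_equal(estimate_efficiency(ds), E, tolerance = 1e-4)
  }

  expect_error(estimate_efficiency(data.frame(fraction = c(0.2, 0.2),
                                              ct = c(20, 20.1))),
               "degenerate")
})

test_that("noisy dilution series keep the efficiency estimate in the 1.9-2.1 window", {
  est <- vapply(1:50, function(s)
    estimate_efficiency(generate_dilution_series(2, noise_sd = 0.2,
                                                 seed = 100 + s)),
    numeric(1))
  expect_true(all(est >= 1.9 & est <= 2.1))
})

test_that("delta-Ct enrichment matches hand evaluation", {
  ct <- rbind(make_ct(25, channel = "input"), make_ct(20, channel = "ip_h3k4me3"))
  em <- enrichment_over_input(aggregate_replicates(ct), "ip_h3k4me3",
                              efficiency = 2, input_fraction = 0.02)
  expect_equal(unname(unclass(em)[1, 1]), 2^(25 - log2(50) - 20),
               tolerance = 1e-12)
  expect_equal(unname(unclass(em)[1, 1]), 0.640, tolerance = 1e-3)

  # equal Cts at full input give enrichment exactly 1
  ct2 <- rbind(make_ct(22, channel = "input"), make_ct(22, channel = "ip_h3k4me3"))
  em2 <- enrichment_over_input(aggregate_replicates(ct2), "ip_h3k4me3",
                               efficiency = 2, input_fraction = 1)
  expect_equal(unname(unclass(em2)[1, 1]), 1)

  expect_error(enrichment_over_input(aggregate_replicates(ct), "ip_h3k27ac"),
               "ip_h3k27ac")
})

test_that("IgG fold QC flags only loci strictly below two-fold", {
  ct <- rbind(make_ct(20, channel = "ip_h3k4me3"), make_ct(20, channel = "igg"),
              make_ct(19, locus = "M", channel = "ip_h3k4me3"),
              make_ct(20, locus = "M", channel = "igg"))
  qc <- fold_over_negative_control(aggregate_replicates(ct), "ip_h3k4me3")
  folds <- setNames(qc$loci$mean_fold, qc$loci$locus)
  expect_equal(unname(folds["L"]), 1)   # no enrichment over background
  expect_equal(unname(folds["M"]), 2)   # boundary
  expect_true(qc$loci$excluded[qc$loci$locus == "L"])
  expect_false(qc$loci$excluded[qc$loci$locus == "M"])
})

test_that("normalizations satisfy their defining identities and cancellations", {
  m <- matrix(c(2, 4, 6,
                4, 2, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("Gapdh", "La", "Lb")))
  raw <- epiqpcr:::new_enrichment_matrix(m, "raw", "h3k4me3")

  mn <- normalize_matrix(raw, "mean")
  expect_equal(unname(unclass(mn)["m1", ]), c(0.5, 1.0, 1.5))
  expect_equal(unname(rowMeans(unclass(mn))), c(1, 1), tolerance = 1e-12)

  gn <- normalize_matrix(raw, "gapdh")
  expect_equal(unname(unclass(gn)["m2", ]), c(1.0, 0.5, 2.0))
  expect_equal(unname(unclass(gn)[, "Gapdh"]), c(1, 1))

  # a per-mouse constant factor cancels under both normalizations
  scaled <- epiqpcr:::new_enrichment_matrix(m * c(3.7, 0.4), "raw", "h3k4me3")
  expect_equal(unclass(normalize_matrix(scaled, "mean")), unclass(mn))
  expect_equal(unclass(normalize_matrix(scaled, "gapdh")), unclass(gn))

  expect_error(normalize_matrix(raw, "gapdh", reference_locus = "Nope"),
               "Nope")
})

test_that("enrichment is invariant to per-mouse Ct offsets after normalization", {
  co <- generate_cohort(cohort_spec(n_group_a = 3, n_group_b = 3), seed = 21)
  loci <- default_locus_panel()
  g <- generate_ct_table(co, loci, seed = 22, markers = "h3k4me3")
  norm1 <- normalize_matrix(enrichment_over_input(
    aggregate_replicates(g$ct), "ip_h3k4me3"), "mean")
  shift <- setNames(seq(-2, 3, length.out = nrow(co)), co$mouse_id)
  ct2 <- g$ct
  ct2$ct <- ct2$ct + shift[ct2$mouse_id]
  norm2 <- normalize_matrix(enrichment_over_input(
    aggregate_replicates(ct2), "ip_h3k4me3"), "mean")
  expect_equal(unclass(norm1), unclass(norm2), tolerance = 1e-9)
})

test_that("input-fraction misspecification rescales raw enrichment but not normalized values", {
  co <- generate_cohort(cohort_spec(n_group_a = 3, n_group_b = 3), seed = 31)
  g <- generate_ct_table(co, default_locus_panel(), seed = 32,
                         markers = "h3k4me3")
  mc <- aggregate_replicates(g$ct)
  e1 <- enrichment_over_input(mc, "ip_h3k4me3", input_fraction = 0.02)
  e2 <- enrichment_over_input(mc, "ip_h3k4me3", input_fraction = 1)
  # omitting the percent-input correction inflates raw enrichment by 1/f
  expect_equal(unclass(e2), unclass(e1) / 0.02, tolerance = 1e-9)
  expect_equal(unclass(normalize_matrix(e1, "mean")),
               unclass(normalize_matrix(e2, "mean")), tolerance = 1e-9)
})

test_that("high-variance sample flagging is robust and tunable", {
  m <- matrix(1, 5, 4, dimnames = list(paste0("m", 1:5), paste0("L", 1:4)))
  norm <- epiqpcr:::new_enrichment_matrix(m / rowMeans(m), "mean", "h3k4me3")
  expect_false(any(flag_high_variance_samples(norm)$flagged))

  # an injected alternating-sign outlier mouse is caught in >= 95% of seeds
  loci <- default_locus_panel(effect_scale = 0)
  hits <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(n_group_a = 20, n_group_b = 20),
                          seed = 700 + s)
    g <- generate_ct_table(co, loci, markers = "h3k4me3",
                           outlier_ids = "a1", seed = 800 + s)
    nm <- normalize_matrix(enrichment_over_input(
      aggregate_replicates(g$ct), "ip_h3k4me3"), "mean")
    fl <- flag_high_variance_samples(nm)
    fl$flagged[fl$mouse_id == "a1"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # an infinite threshold flags nothing
  d <- sim_marker_dataset(41, n_a = 5, n_b = 5)
  expect_false(any(flag_high_variance_samples(d$norm, k = Inf)$flagged))
  expect_error(flag_high_variance_samples(d$raw), "mean-normalized")
})

test_that("enrichment matrices round-trip through tagged CSV", {
  d <- sim_marker_dataset(51, n_a = 3, n_b = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_enrichment_matrix(d$norm, path)
  back <- read_enrichment_matrix(path)
  expect_equal(unclass(back), unclass(d$norm), tolerance = 1e-12)
  expect_equal(attr(back, "normalization"), "mean")
  expect_equal(attr(back, "marker"), "h3k4me3")
})
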