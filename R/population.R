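#' Descriptive population-structure summary
#'
#' Summarizes an enclosure census per location (nest boxes plus free-roaming)
#' and in total: counts by sex and weight class (adults > 13 g, prepubertal
#' 8-13 g, pups < 8 g), sex ratios (fraction male), adult weight means and
#' sample sds, and wounded counts and fractions among adults.  Fractions and
#' ratios are rounded to 2 decimals (half away from zero), weights to 1
#' decimal; undefined cells (zero denominator, sd of a single mouse) are
#' `NA`.
#'
#' @param metadata `data.frame` with columns `location`, `sex` (`"m"`,
#'   `"f"`, or `"u"` for unsexed pups), `weight_g`, `wounded` (logical).
#' @return `data.frame`, one row per location plus `"Total"`.
#' @seealso [expand_population_counts()] to build per-mouse records from a
#'   printed census table.
#' @export
summarize_population <- function(metadata) {
  need <- c("location", "sex", "weight_g", "wounded")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stopf("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  cls <- ifelse(metadata$weight_g > 13, "adult",
                ifelse(metadata$weight_g >= 8, "young", "pup"))
  locs <- c(sort(unique(metadata$location)), "Total")
  one <- function(loc) {
    d <- if (loc == "Total") metadata else metadata[metadata$location == loc, ]
    k <- cls[if (loc == "Total") rep(TRUE, nrow(metadata))
             else metadata$location == loc]
    ma <- sum(d$sex == "m" & k == "adult"); fa <- sum(d$sex == "f" & k == "adult")
    my <- sum(d$sex == "m" & k == "young"); fy <- sum(d$sex == "f" & k == "young")
    ratio <- function(m, f) if (m + f == 0) NA_real_ else
      round_half_up(m / (m + f), 2L)
    wstats <- function(sx) {
      w <- d$weight_g[d$sex == sx & k == "adult"]
      c(mean = if (length(w)) round_half_up(mean(w), 1L) else NA_real_,
        sd = if (length(w) >= 2L) round_half_up(stats::sd(w), 1L) else NA_real_)
    }
    wm <- wstats("m"); wf <- wstats("f")
    wnd <- function(sx) {
      tot <- sum(d$sex == sx & k == "adult")
      n <- sum(d$sex == sx & k == "adult" & d$wounded)
      c(n = n, frac = if (tot == 0) NA_real_ else round_half_up(n / tot, 2L))
    }
    wm_w <- wnd("m"); wf_w <- wnd("f")
    data.frame(
      location = loc, n_mice = nrow(d),
      males_adult = ma, females_adult = fa,
      males_young = my, females_young = fy,
      pups = sum(k == "pup"),
      sex_ratio_adult = ratio(ma, fa), sex_ratio_young = ratio(my, fy),
      weight_mean_male_adult = wm[["mean"]], weight_sd_male_adult = wm[["sd"]],
      weight_mean_female_adult = wf[["mean"]], weight_sd_female_adult = wf[["sd"]],
      wounded_males_adult = wm_w[["n"]],
      fraction_wounded_males = wm_w[["frac"]],
      wounded_females_adult = wf_w[["n"]],
      fraction_wounded_females = wf_w[["frac"]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(locs, one))
  rownames(out) <- NULL
  out
}

#' Expand a printed census-count table into per-mouse records
#'
#' Builds one row per animal from aggregate counts (per location: adult
#' males/females, prepubertal males/females, pups, wounded adult counts),
#' assigning nominal class weights (adults 20 g, prepubertal 10 g, pups 5 g,
#' unsexed).  Count-derived statistics (sex ratios, wounded fractions) from
#' [summarize_population()] are then exact; weight statistics are nominal.
#'
#' @param counts `data.frame` with columns `location`, `males_adult`,
#'   `females_adult`, `males_young`, `females_young`, `pups`,
#'   `wounded_males_adult`, `wounded_females_adult`.
#' @return Per-mouse `data.frame` suitable for [summarize_population()].
#' @export
expand_population_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    mk <- function(n, sex, w, n_wounded = 0) {
      if (n == 0) return(NULL)
      data.frame(location = r$location, sex = sex, weight_g = w,
                 wounded = seq_len(n) <= n_wounded, stringsAsFactors = FALSE)
    }
    do.call(rbind, list(
      mk(r$males_adult, "m", 20, r$wounded_males_adult),
      mk(r$females_adult, "f", 20, r$wounded_females_adult),
      mk(r$males_young, "m", 10), mk(r$females_young, "f", 10),
      mk(r$pups, "u", 5)
    ))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled enclosure census counts
#'
#' The printed census of the source enclosure population at sampling time
#' (408 mice over ten nest boxes A-J and the free-roaming class Z), as
#' aggregate counts per location.
#'
#' @return `data.frame` of counts; see [expand_population_counts()].
#' @export
enclosure_census_counts <- function() {
  utils::read.csv(system.file("extdata", "enclosure_census_counts.csv",
                              package = "epiqpcr"),
                  stringsAsFactors = FALSE)
}
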