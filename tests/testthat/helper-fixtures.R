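# Shared in-code fixtures; no files on disk.

# parameter table for a generic test taxon
test_params_table <- function(taxon = "frog", Ma = 0.5, Mp = 0.8, Ms = 0.5,
                              hearing = 150) {
  data.frame(taxon = taxon, Ma = Ma, sd_Ma = 0, Mp = Mp, sd_Mp = 0,
             Ms = Ms, sd_Ms = 0, ms_L = NA_real_, sd_ms_L = NA_real_,
             ms_E = NA_real_, sd_ms_E = NA_real_,
             hearing_distance_m = hearing, range_area_km2 = NA_real_,
             presence_fraction = NA_real_, stringsAsFactors = FALSE)
}

test_params <- function(...) taxon_params("frog", test_params_table(...))

# Hand-computable two-year dataset on one plot:
#   2016 site maxima: w1=5, w2=3, w3=1 (total 9); survey totals S1=5, S2=6
#   2017 site maxima: w1=1, w4=4 (total 5)
#   best year 2016; CMPS = 6/9; IYF = 3/4; WDP(2016, with visual at w4) = 3/4
toy_survey <- function(visual = TRUE) {
  wb <- data.frame(
    waterbody_id = c("w1", "w2", "w3", "w4", "w5", "d1"),
    plot_id = "A",
    category = c(rep("small", 5), "ditch"),
    area_ha = c(rep(0.1, 5), NA),
    perimeter_m = NA_real_,
    length_m = c(rep(NA, 5), 1000),
    surveyed = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    sampled_length_m = c(rep(NA, 5), 300),
    stringsAsFactors = FALSE
  )
  sv <- data.frame(
    survey_id = c("S1", "S2", "S3", "S4"),
    plot_id = "A",
    year = c(2016L, 2016L, 2017L, 2017L),
    date = c("2016-04-10", "2016-04-20", "2017-04-12", "2017-04-25"),
    mid_time_h = c(14, 18.5, 15, 20),
    sunset_time_h = c(20.4, 20.9, 20.5, 21.1),
    stringsAsFactors = FALSE
  )
  cc <- data.frame(
    survey_id     = c("S1", "S1", "S2", "S2", "S3", "S4"),
    waterbody_id  = c("w1", "w2", "w1", "w3", "w1", "w4"),
    taxon = "frog",
    count = c(2, 3, 5, 1, 1, 4),
    chorus_averaged = FALSE,
    stringsAsFactors = FALSE
  )
  vr <- if (visual) {
    data.frame(waterbody_id = "w4", taxon = "frog", year = 2016L,
               adults_seen = 2, sex_known = TRUE, egg_masses = 0,
               visibility_class = "clear_active", stringsAsFactors = FALSE)
  }
  anuran_survey(wb, sv, cc, vr)
}

# Single-plot fixture reproducing the worked Dc example:
# small C=12 Pt=60 Ps=20; medium C=5 Pt=4000 Ps=1000; ditch C=3 Pt=12000
# Ps=3000; S=25 -> Dc = (36 + 20 + 12) / 25 = 2.72
eq1_survey <- function(taxon = "frog") {
  n_small <- 60
  small <- data.frame(
    waterbody_id = sprintf("s%02d", seq_len(n_small)),
    plot_id = "A", category = "small", area_ha = 0.1,
    perimeter_m = NA_real_, length_m = NA_real_,
    surveyed = c(rep(TRUE, 20), rep(FALSE, 40)),
    sampled_length_m = NA_real_, stringsAsFactors = FALSE
  )
  med <- data.frame(
    waterbody_id = c("m1", "m2"), plot_id = "A", category = "medium",
    area_ha = c(2, 1), perimeter_m = c(2500, 1500),
    length_m = NA_real_, surveyed = TRUE,
    sampled_length_m = c(600, 400), stringsAsFactors = FALSE
  )
  ditch <- data.frame(
    waterbody_id = sprintf("d%d", 1:6), plot_id = "A", category = "ditch",
    area_ha = NA_real_, perimeter_m = NA_real_, length_m = 2000,
    surveyed = TRUE, sampled_length_m = 500, stringsAsFactors = FALSE
  )
  wb <- rbind(small, med, ditch)
  sv <- data.frame(survey_id = "S1", plot_id = "A", year = 2016L,
                   date = "2016-04-20", stringsAsFactors = FALSE)
  cc <- data.frame(
    survey_id = "S1",
    waterbody_id = c("s01", "s02", "s03", "m1", "m2", "d1"),
    taxon = taxon, count = c(4, 6, 2, 3, 2, 3),
    chorus_averaged = FALSE, stringsAsFactors = FALSE
  )
  anuran_survey(wb, sv, cc)
}

# naive reference implementation of Eq. 1/2: plain per-waterbody loop
naive_dc_mafd <- function(wb, best, hearing, S, Ma, Mp, Ms_by_cat) {
  dc_cat <- setNames(rep(0, 4), waterbody_categories())
  for (cat in waterbody_categories()) {
    C <- 0; Pt <- 0; Ps <- 0
    for (i in seq_len(nrow(wb))) {
      if (wb$category[i] != cat) next
      if (cat == "small") {
        Pt <- Pt + 1
        if (wb$surveyed[i]) Ps <- Ps + 1
      } else {
        tot <- if (cat == "ditch") wb$length_m[i] else wb$perimeter_m[i]
        Pt <- Pt + tot
        if (wb$surveyed[i]) {
          sl <- wb$sampled_length_m[i]
          if (is.na(sl)) sl <- min(tot, 2 * hearing)
          Ps <- Ps + sl
        }
      }
      if (wb$surveyed[i]) {
        b <- best$best[best$waterbody_id == wb$waterbody_id[i]]
        if (length(b)) C <- C + b
      }
    }
    if (Ps > 0) dc_cat[cat] <- C * Pt / Ps / S
  }
  mafd <- sum(dc_cat / (Ma * Mp * Ms_by_cat[names(dc_cat)]))
  list(dc = sum(dc_cat), dc_cat = dc_cat, mafd = mafd)
}

# random single-plot world for oracle-equivalence sweeps
random_plot_data <- function() {
  n_small <- sample(3:20, 1)
  n_med <- sample(0:4, 1)
  n_large <- sample(0:2, 1)
  n_ditch <- sample(0:4, 1)
  mk <- function(n, prefix, cat) {
    if (n == 0) return(NULL)
    area <- switch(cat, small = runif(n, 0.02, 0.49),
                   medium = runif(n, 0.5, 10), large = runif(n, 10.5, 40),
                   ditch = rep(NA_real_, n))
    data.frame(
      waterbody_id = paste0(prefix, seq_len(n)), plot_id = "A",
      category = cat, area_ha = area,
      perimeter_m = if (cat %in% c("medium", "large"))
        runif(n, 300, 5000) else NA_real_,
      length_m = if (cat == "ditch") runif(n, 500, 4000) else NA_real_,
      surveyed = runif(n) < 0.6, sampled_length_m = NA_real_,
      stringsAsFactors = FALSE)
  }
  wb <- rbind(mk(n_small, "s", "small"), mk(n_med, "m", "medium"),
              mk(n_large, "l", "large"), mk(n_ditch, "d", "ditch"))
  if (!any(wb$surveyed)) wb$surveyed[1] <- TRUE
  surveyed <- wb$waterbody_id[wb$surveyed]
  k <- sample(seq_along(surveyed), max(1, length(surveyed) %/% 2))
  best <- data.frame(waterbody_id = surveyed[k],
                     best = rpois(length(k), 3), stringsAsFactors = FALSE)
  list(wb = wb, best = best, S = runif(1, 10, 30),
       hearing = sample(c(50, 100, 150, 500), 1))
}
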