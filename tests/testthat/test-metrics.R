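test_that("best_site_count is the maximum over visits", {
  expect_equal(best_site_count(c(0, 3, 1)), 3)
  expect_equal(best_site_count(5), 5)
  expect_equal(best_site_count(c(2.5, 2)), 2.5)  # chorus-averaged reals
  expect_true(is.na(best_site_count(numeric(0))))
  expect_error(best_site_count(c(1, -1)), ">= 0")
})

test_that("select_best_year maximises the plot total and breaks ties early", {
  d <- toy_survey()
  expect_identical(select_best_year(d, "A", "frog"), 2016L)  # 9 vs 5
  expect_true(is.na(select_best_year(d, "A", "unseen taxon")))

  # tie: duplicate 2016's counts into 2018 -> earliest year wins
  cc <- d$call_counts
  extra_sv <- data.frame(survey_id = c("S5", "S6"), plot_id = "A",
                         year = 2018L, date = c("2018-04-10", "2018-04-20"),
                         mid_time_h = 14, sunset_time_h = 20.4,
                         stringsAsFactors = FALSE)
  cc2 <- cc[cc$survey_id %in% c("S1", "S2"), ]
  cc2$survey_id <- ifelse(cc2$survey_id == "S1", "S5", "S6")
  sv <- rbind(d$surveys, extra_sv)
  d2 <- anuran_survey(d$waterbodies, sv, rbind(cc, cc2), d$visual_records)
  expect_identical(select_best_year(d2, "A", "frog"), 2016L)
})

test_that("WDP counts audial detections among all presence evidence", {
  d <- toy_survey()
  # 2016: audial {w1,w2,w3}; visual-only adds w4 -> 3/4
  expect_equal(compute_wdp(d, "A", "frog", year = 2016), 0.75)
  # all evidence audial -> 1
  expect_equal(compute_wdp(toy_survey(visual = FALSE), "A", "frog",
                           year = 2016), 1)
  expect_true(is.na(compute_wdp(d, "A", "unseen taxon")))
})

test_that("adding visual-only evidence can only decrease or preserve WDP", {
  d <- toy_survey(visual = FALSE)
  base <- compute_wdp(d, "A", "frog", year = 2016)
  for (id in c("w1", "w4")) {  # already-audial site, then a new site
    vr <- data.frame(waterbody_id = id, taxon = "frog", year = 2016L,
                     adults_seen = 1, sex_known = TRUE, egg_masses = 0,
                     visibility_class = "casual", stringsAsFactors = FALSE)
    d2 <- anuran_survey(d$waterbodies, d$surveys, d$call_counts, vr)
    expect_lte(compute_wdp(d2, "A", "frog", year = 2016), base)
  }
})

test_that("IYF is the best-year share of pooled call-positive sites", {
  d <- toy_survey()
  expect_equal(compute_iyf(d, "A", "frog"), 0.75)  # {w1,w2,w3} of {w1..w4}

  # single-year plot -> undefined
  one <- d$surveys[d$surveys$year == 2016, ]
  cc <- d$call_counts[d$call_counts$survey_id %in% one$survey_id, ]
  d1 <- anuran_survey(d$waterbodies, one, cc)
  expect_true(is.na(compute_iyf(d1, "A", "frog")))
})

test_that("IYF is invariant to relabelling years", {
  d <- toy_survey()
  sv <- d$surveys
  sv$year <- ifelse(sv$year == 2016L, 2018L, 2011L)
  sv$date <- sub("^2016", "2018", sub("^2017", "2011", sv$date))
  d2 <- anuran_survey(d$waterbodies, sv, d$call_counts, d$visual_records)
  expect_equal(compute_iyf(d2, "A", "frog"), compute_iyf(d, "A", "frog"))
})

test_that("CMPS is best survey total over the year's site-maxima total", {
  d <- toy_survey()
  expect_equal(compute_cmps(d, "A", "frog", 2016), 6 / 9)
  expect_equal(compute_cmps(d, "A", "frog", 2017), 4 / 5)

  # two surveys, disjoint sites, equal totals -> 0.5
  wb <- data.frame(waterbody_id = c("x1", "x2"), plot_id = "B",
                   category = "small", area_ha = 0.1, perimeter_m = NA_real_,
                   length_m = NA_real_, surveyed = TRUE,
                   sampled_length_m = NA_real_, stringsAsFactors = FALSE)
  sv <- data.frame(survey_id = c("T1", "T2"), plot_id = "B", year = 2016L,
                   date = c("2016-04-10", "2016-04-20"),
                   stringsAsFactors = FALSE)
  cc <- data.frame(survey_id = c("T1", "T2"),
                   waterbody_id = c("x1", "x2"), taxon = "frog",
                   count = c(10, 10), chorus_averaged = FALSE,
                   stringsAsFactors = FALSE)
  d2 <- anuran_survey(wb, sv, cc)
  expect_equal(compute_cmps(d2, "B", "frog", 2016), 0.5)
})

test_that("CMPS is bounded below by 1/n_surveys and above by 1", {
  for (seed in 1:5) {
    sim <- simulate_dataset(simulation_config(n_plots = 2, seed = seed))
    m <- plot_taxon_metrics(sim$data)
    v <- m$cmps[!is.na(m$cmps)]
    n_surv <- length(unique(sim$data$surveys$survey_id)) /
      length(unique(sim$data$surveys$plot_id))
    expect_true(all(v >= 1 / n_surv - 1e-12 & v <= 1 + 1e-12))
  }
})

test_that("summarize_plot averages only occupied waterbodies", {
  d <- toy_survey()
  s <- summarize_plot(d, "A", "frog", year = 2016)
  expect_equal(s$mean_calling_males, 3)        # (5 + 3 + 1) / 3
  expect_equal(s$fraction_occupied, 3 / 5)     # 5 surveyed sites
  expect_equal(s$best_year, 2016L)
  expect_equal(s$cmps, 6 / 9)

  # no occupied sites -> mean undefined, occupancy 0
  cc0 <- d$call_counts
  cc0$count <- 0
  d0 <- anuran_survey(d$waterbodies, d$surveys, cc0)
  s0 <- summarize_plot(d0, "A", "frog", year = 2016)
  expect_true(is.na(s0$mean_calling_males))
  expect_equal(s0$fraction_occupied, 0)
})

test_that("metric ratios always lie in [0, 1] on simulated data", {
  for (seed in c(3, 11)) {
    sim <- simulate_dataset(simulation_config(n_plots = 3, n_years = 2,
                                              seed = seed,
                                              simulate_visual = TRUE))
    m <- plot_taxon_metrics(sim$data)
    for (col in c("wdp", "iyf", "cmps", "fraction_occupied")) {
      v <- m[[col]][!is.na(m[[col]])]
      expect_true(all(v >= 0 & v <= 1), label = col)
    }
  }
})

test_that("mean IYF increases with the site-fidelity parameter", {
  mean_iyf <- function(phi) {
    vals <- vapply(1:6, function(s) {
      sim <- simulate_dataset(simulation_config(
        n_plots = 3, n_years = 2, seed = 100 + s, phi = phi))
      m <- plot_taxon_metrics(sim$data)
      mean(m$iyf, na.rm = TRUE)
    }, numeric(1))
    mean(vals)
  }
  expect_gt(mean_iyf(1.0), mean_iyf(0.5))
})
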