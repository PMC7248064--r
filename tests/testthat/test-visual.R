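test_that("estimate_present_males inverts the detection probabilities", {
  bufo <- taxon_params("Bufo bufo")
  expect_equal(estimate_present_males(10, visibility_class = "clear_active",
                                      params = bufo),
               10 / 0.75)
  # egg masses: one mass = one female, converted via Ms / (1 - Ms)
  rana <- taxon_params("Rana arvalis")
  expect_equal(estimate_present_males(0, egg_masses = 10, params = rana),
               (10 / 0.9) * 0.48 / 0.52)
  expect_equal(round(estimate_present_males(0, egg_masses = 10,
                                            params = rana), 2), 10.26)
  expect_equal(estimate_present_males(0, 0, params = bufo), 0)
  expect_error(estimate_present_males(3, params = bufo), "visibility_class")
})

test_that("unknown-sex adults are scaled by the category sex ratio", {
  pel <- taxon_params("Pelophylax spp.")
  got <- estimate_present_males(10, visibility_class = "clear_inactive",
                                sex_known = FALSE, params = pel,
                                category = "small")
  expect_equal(got, 10 / 0.5 * 0.47)
  got_l <- estimate_present_males(10, visibility_class = "clear_inactive",
                                  sex_known = FALSE, params = pel,
                                  category = "large")
  expect_equal(got_l, 10 / 0.5 * 0.36)
})

test_that("adult and egg components combine by max (sum on request)", {
  rana <- taxon_params("Rana arvalis")
  a <- estimate_present_males(10, visibility_class = "clear_active",
                              params = rana)          # 13.33
  e <- estimate_present_males(0, egg_masses = 20, params = rana)
  both_max <- estimate_present_males(10, egg_masses = 20,
                                     visibility_class = "clear_active",
                                     params = rana)
  expect_equal(both_max, max(a, e))
  both_sum <- estimate_present_males(10, egg_masses = 20,
                                     visibility_class = "clear_active",
                                     params = rana, combine = "sum")
  expect_equal(both_sum, a + e)
})

test_that("virtual calling males never reduce the recorded count", {
  expect_equal(virtual_calling_males(80, 0.18, 4), 14.4)
  expect_equal(virtual_calling_males(13.33, 0.18, 4), 4)  # 2.4 < recorded
  expect_equal(virtual_calling_males(0, 0.5, 0), 0)
  expect_error(virtual_calling_males(-1, 0.5), ">= 0")
})

test_that("compute_nde augments counts and reports coverage eligibility", {
  # single-category fully-sampled plot: Eq. 1-2 are linear in counts, so
  # fraction_covered = summed recorded / summed augmented counts
  wb <- data.frame(
    waterbody_id = c("w1", "w2", "w3", "w4"), plot_id = "A",
    category = "small", area_ha = 0.1, perimeter_m = NA_real_,
    length_m = NA_real_, surveyed = TRUE, sampled_length_m = NA_real_,
    stringsAsFactors = FALSE)
  sv <- data.frame(survey_id = "S1", plot_id = "A", year = 2016L,
                   date = "2016-05-01", stringsAsFactors = FALSE)
  cc <- data.frame(survey_id = "S1", waterbody_id = c("w1", "w2", "w3"),
                   taxon = "frog", count = c(4, 4, 2),
                   chorus_averaged = FALSE, stringsAsFactors = FALSE)
  # w1 visually estimated at 80 present males -> virtual 80 * Ma
  vr <- data.frame(waterbody_id = c("w1", "w2", "w3"), taxon = "frog",
                   year = 2016L, adults_seen = c(60, 0, 0),
                   sex_known = TRUE, egg_masses = 0,
                   visibility_class = c("clear_active", NA, NA),
                   stringsAsFactors = FALSE)
  d <- anuran_survey(wb, sv, cc, vr)
  p <- test_params(Ma = 0.18, Mp = 1, Ms = 1)
  res <- compute_nde(d, "A", "frog", params = p)
  # present = 60/0.75 = 80; virtual = 14.4 replaces w1's 4
  expect_true(res$eligible)          # 3 of 4 surveyed covered
  expect_equal(res$visual_coverage, 0.75)
  expect_equal(res$fraction_covered, 10 / 20.4)
  expect_equal(res$nde, res$mafd / res$fraction_covered)

  # coverage below threshold -> ineligible, fraction undefined
  vr50 <- vr[1:2, ]
  d50 <- anuran_survey(wb, sv, cc, vr50)
  res50 <- compute_nde(d50, "A", "frog", params = p)
  expect_false(res50$eligible)
  expect_true(is.na(res50$fraction_covered))

  # no visual record exceeding the audial counts -> NDE = MAFD, fraction 1
  vr0 <- vr
  vr0$adults_seen <- c(1, 0, 0)
  d0 <- anuran_survey(wb, sv, cc, vr0)
  res0 <- compute_nde(d0, "A", "frog", params = p)
  expect_equal(res0$nde, res0$mafd)
  expect_equal(res0$fraction_covered, 1)
})

test_that("fraction_covered is scale-invariant", {
  wb <- toy_survey()$waterbodies
  sv <- toy_survey()$surveys
  base_cc <- toy_survey()$call_counts
  vr <- data.frame(waterbody_id = c("w1", "w2", "w3", "w4"), taxon = "frog",
                   year = 2016L, adults_seen = c(30, 10, 0, 8),
                   sex_known = TRUE, egg_masses = 0,
                   visibility_class = c("clear_active", "obstructed", NA,
                                        "casual"),
                   stringsAsFactors = FALSE)
  p <- test_params(Ma = 0.3, Mp = 0.9, Ms = 0.5)
  frac <- function(c_scale) {
    cc <- base_cc
    cc$count <- cc$count * c_scale
    cc$chorus_averaged <- TRUE
    v <- vr
    v$adults_seen <- v$adults_seen * c_scale
    d <- anuran_survey(wb, sv, cc, v)
    compute_nde(d, "A", "frog", year = 2016, params = p,
                min_coverage = 0.5)$fraction_covered
  }
  expect_equal(frac(1), frac(3))
  expect_equal(frac(1), frac(0.5))
})

test_that("NDE >= MAFD and fraction_covered in (0, 1] on simulated data", {
  for (seed in c(5, 21)) {
    sim <- simulate_dataset(simulation_config(n_plots = 3, seed = seed,
                                              simulate_visual = TRUE))
    cv <- suppressWarnings(correct_visual(sim$data, sim$params))
    expect_true(all(cv$nde >= cv$mafd - 1e-9))
    f <- cv$fraction_covered[!is.na(cv$fraction_covered)]
    expect_true(all(f > 0 & f <= 1 + 1e-12))
  }
})

test_that("with perfect detection and Ma = 1, NDE matches the max oracle", {
  # dp = 1 everywhere and Ma = 1: augmented count per site is
  # max(recorded, present males seen), which the oracle recomputes directly
  wb <- data.frame(
    waterbody_id = c("w1", "w2", "w3"), plot_id = "A", category = "small",
    area_ha = 0.1, perimeter_m = NA_real_, length_m = NA_real_,
    surveyed = TRUE, sampled_length_m = NA_real_, stringsAsFactors = FALSE)
  sv <- data.frame(survey_id = "S1", plot_id = "A", year = 2016L,
                   date = "2016-05-01", stringsAsFactors = FALSE)
  cc <- data.frame(survey_id = "S1", waterbody_id = c("w1", "w2"),
                   taxon = "frog", count = c(7, 2),
                   chorus_averaged = FALSE, stringsAsFactors = FALSE)
  vr <- data.frame(waterbody_id = c("w1", "w2", "w3"), taxon = "frog",
                   year = 2016L, adults_seen = c(3, 6, 5), sex_known = TRUE,
                   egg_masses = 0, visibility_class = "clear_active",
                   stringsAsFactors = FALSE)
  d <- anuran_survey(wb, sv, cc, vr)
  dp1 <- detection_probabilities(1, 1, 1, 1, 1)
  p <- test_params(Ma = 1, Mp = 1, Ms = 1)
  res <- compute_nde(d, "A", "frog", params = p, dp = dp1)
  oracle <- sum(pmax(c(7, 2, 0), c(3, 6, 5))) / 25  # counts fully sampled
  expect_equal(res$nde, oracle)
})
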