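test_that("sampled_length applies the listening-point rule with a cap", {
  expect_equal(sampled_length(5000, 150), 300)
  expect_equal(sampled_length(400, 500), 400)          # fully covered
  expect_equal(sampled_length(5000, 150, n_points = 3), 900)
  expect_equal(sampled_length(5000, 150, sampled_length_m = 250), 250)
  expect_error(sampled_length(NA, 150), "total")
  expect_error(sampled_length(1000, 150, sampled_length_m = 2000), "exceeds")
})

test_that("tally_categories reproduces hand tallies", {
  d <- eq1_survey()
  tl <- tally_categories(d, "A", "frog", 2016, test_params())
  tl <- tl[order(tl$category), ]
  expect_equal(tl$C[tl$category == "small"], 12)
  expect_equal(tl$Pt[tl$category == "small"], 60)
  expect_equal(tl$Ps[tl$category == "small"], 20)
  expect_equal(tl$C[tl$category == "medium"], 5)
  expect_equal(tl$Pt[tl$category == "medium"], 4000)
  expect_equal(tl$Ps[tl$category == "medium"], 1000)
  expect_equal(tl$C[tl$category == "ditch"], 3)
  expect_equal(tl$Pt[tl$category == "ditch"], 12000)
  expect_equal(tl$Ps[tl$category == "ditch"], 3000)
  # no large waterbodies: all-zero stratum contributes 0
  expect_equal(unlist(tl[tl$category == "large", c("C", "Pt", "Ps")]),
               c(C = 0, Pt = 0, Ps = 0))
})

test_that("compute_dc implements the stratified extrapolation", {
  d <- eq1_survey()
  tl <- tally_categories(d, "A", "frog", 2016, test_params())
  expect_equal(compute_dc(tl, 25), 2.72)
  dcc <- compute_dc(tl, 25, by_category = TRUE)
  expect_equal(unname(dcc[c("small", "medium", "ditch")]),
               c(36, 20, 12) / 25)

  # all habitat surveyed -> Dc * S equals the raw summed counts
  tl_full <- tl
  tl_full$Ps <- tl_full$Pt
  expect_equal(compute_dc(tl_full, 25) * 25, sum(tl$C))

  # zero counts everywhere -> 0
  tl0 <- tl
  tl0$C <- 0
  expect_equal(compute_dc(tl0, 25), 0)
})

test_that("compute_mafd divides by the detection proportions", {
  bombina <- taxon_params("Bombina bombina")
  expect_equal(round(compute_mafd(4.1, bombina), 1), 12.0)
  # identity when all proportions are 1
  p1 <- test_params(Ma = 1, Mp = 1, Ms = 1)
  expect_equal(compute_mafd(3.21, p1), 3.21)
  expect_error(compute_mafd(1, test_params(Ma = 0)), "Ma")
})

test_that("water-frog complex applies category-specific sex ratios", {
  pel <- taxon_params("Pelophylax spp.")
  dc <- c(small = 2.0, medium = 1.0, large = 0.5, ditch = 0.5)
  # small + ditch via L = 0.47, medium via (L+E)/2, large via E = 0.36
  expected <- 2.5 / (0.63 * 0.47) + 1.0 / (0.63 * 0.415) +
    0.5 / (0.63 * 0.36)
  expect_equal(compute_mafd(dc, pel), expected, tolerance = 1e-12)
  expect_equal(round(compute_mafd(dc, pel), 2), 14.47)
  # scalar dc is refused: the category split matters
  expect_error(compute_mafd(4, pel), "category")

  fr <- category_contributions(dc, pel)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr[["small"]] + fr[["ditch"]]),
               (2.5 / (0.63 * 0.47)) / expected)
})

test_that("category contributions sum to 1 and match Dc shares for scalar Ms", {
  d <- eq1_survey()
  p <- test_params()
  dcc <- compute_dc(tally_categories(d, "A", "frog", 2016, p), 25,
                    by_category = TRUE)
  fr <- category_contributions(dcc, p)
  expect_equal(sum(fr), 1)
  expect_equal(unname(fr["small"]), 36 / 68)
  expect_equal(unname(fr), unname(dcc / sum(dcc)))
  # zero density -> undefined fractions
  expect_true(all(is.na(category_contributions(dcc * 0, p))))
})

test_that("operational sex ratios are reduced by 15%", {
  expect_equal(round(adjust_operational_sex_ratio(0.565), 2), 0.48)
  expect_equal(adjust_operational_sex_ratio(1), 0.85)
  expect_equal(round(adjust_operational_sex_ratio(0.647), 2), 0.55)
  expect_error(adjust_operational_sex_ratio(1.2), "\\(0, 1\\]")
  expect_error(adjust_operational_sex_ratio(0), "\\(0, 1\\]")
})

test_that("MAFD is homogeneous of degree 1 and monotone in counts", {
  d <- eq1_survey()
  p <- test_params()
  est <- estimate_density(d, test_params_table())
  cc2 <- d$call_counts
  cc2$count <- cc2$count * 2
  d2 <- anuran_survey(d$waterbodies, d$surveys, cc2)
  est2 <- estimate_density(d2, test_params_table())
  expect_equal(est2$dc, 2 * est$dc)
  expect_equal(est2$mafd, 2 * est$mafd)

  cc3 <- d$call_counts
  cc3$count[3] <- cc3$count[3] + 5  # raise one site count
  d3 <- anuran_survey(d$waterbodies, d$surveys, cc3)
  est3 <- estimate_density(d3, test_params_table())
  expect_gte(est3$dc, est$dc)
  expect_gte(est3$mafd, est$mafd)
})

test_that("MAFD >= Dc on arbitrary simulated worlds", {
  for (seed in c(2, 7)) {
    sim <- simulate_dataset(simulation_config(n_plots = 3, seed = seed))
    est <- suppressWarnings(estimate_density(sim$data, sim$params))
    expect_true(all(est$mafd >= est$dc - 1e-12))
  }
})

test_that("inconsistent tallies (counts in unsampled strata) are rejected", {
  tl <- data.frame(category = waterbody_categories(),
                   C = c(1, 0, 0, 0), Pt = c(10, 0, 0, 0), Ps = c(0, 0, 0, 0))
  expect_error(compute_dc(tl, 25), "C > 0 with Ps = 0")
})

test_that("production estimator equals the naive per-waterbody loop", {
  set.seed(42)
  p <- test_params()
  for (i in 1:50) {
    rp <- random_plot_data()
    tl <- mafd:::tally_from_best(rp$wb, rp$best, rp$hearing)
    dcc <- compute_dc(tl, rp$S, by_category = TRUE)
    got_mafd <- compute_mafd(sum(dcc), p)
    ms <- setNames(rep(p$Ms, 4), waterbody_categories())
    ref <- naive_dc_mafd(rp$wb, rp$best, rp$hearing, rp$S,
                         p$Ma, p$Mp, ms)
    expect_equal(sum(dcc), ref$dc, tolerance = 1e-12)
    expect_equal(got_mafd, ref$mafd, tolerance = 1e-12)
  }
})
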