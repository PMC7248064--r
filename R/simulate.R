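#' Configuration for the synthetic survey generator
#'
#' Defines a fully-specified survey world with known truth. Defaults
#' emulate the published study design: 25 km^2 plots whose waterbody
#' stock is ~91% small ponds plus a few medium/large waterbodies and
#' ditch segments, with 27% / 49% / 57% of small / medium / large
#' waterbodies surveyed, and three surveys per season.
#'
#' @param n_plots Number of plots (>= 1).
#' @param plot_area_km2 Plot area (5 x 5 km plots by default).
#' @param n_years Number of survey years.
#' @param seed Integer seed; all randomness flows from it.
#' @param waterbody_means Named means (Poisson) of waterbody counts per
#'   plot for `small`, `medium`, `large`, `ditch`.
#' @param surveyed_fractions Named probabilities that a waterbody of each
#'   category is surveyed.
#' @param taxa `data.frame` with one row per simulated taxon: `taxon`,
#'   `density` (true adults/km^2), `Ma`, `Mp`, `Ms`, `breeding`
#'   (`"lek"`: broad Gaussian seasonal activity; `"explosive"`: fast rise,
#'   exponential decay), `peak` (relative date of peak activity), `width`
#'   (curve width/decay constant, days), `site_asynchrony_sd` (SD of
#'   per-site peak offsets, days; large values emulate populations
#'   breeding at different times), `hearing_distance_m`.
#' @param survey_rel_dates Survey schedule as days since season onset,
#'   shared by all plots and years.
#' @param phi Inter-year breeding-site fidelity in \[0, 1\]: each
#'   waterbody keeps its previous-year adults with probability `phi`;
#'   displaced adults are reallocated.
#' @param daily_modifier Multiplier on `Ma` for time-of-day effects
#'   (default 1: no daily pattern, as observed for most taxa).
#' @param activity_scale Global multiplier on the seasonal activity curve,
#'   for controlled off-peak experiments.
#' @param simulate_visual Also generate visual observation records.
#' @param visual_coverage Probability that a surveyed waterbody receives a
#'   visual check.
#' @return A validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_plots = 6,
                              plot_area_km2 = 25,
                              n_years = 1,
                              seed = 1,
                              waterbody_means = c(small = 60, medium = 5,
                                                  large = 1, ditch = 6),
                              surveyed_fractions = c(small = 0.27,
                                                     medium = 0.49,
                                                     large = 0.57,
                                                     ditch = 0.5),
                              taxa = data.frame(
                                taxon = "Synthetic frog", density = 30,
                                Ma = 0.5, Mp = 0.9, Ms = 0.5,
                                breeding = "lek", peak = 20, width = 12,
                                site_asynchrony_sd = 2,
                                hearing_distance_m = 200,
                                stringsAsFactors = FALSE),
                              survey_rel_dates = c(5, 20, 50),
                              phi = 0.8,
                              daily_modifier = 1,
                              activity_scale = 1,
                              simulate_visual = FALSE,
                              visual_coverage = 0.8) {
  stopifnot(n_plots >= 1, plot_area_km2 > 0, n_years >= 1,
            phi >= 0, phi <= 1,
            all(waterbody_categories() %in% names(waterbody_means)),
            all(waterbody_categories() %in% names(surveyed_fractions)),
            all(surveyed_fractions >= 0), all(surveyed_fractions <= 1),
            all(taxa$density >= 0),
            all(taxa$Ma > 0 & taxa$Ma <= 1),
            all(taxa$Mp > 0 & taxa$Mp <= 1),
            all(taxa$Ms > 0 & taxa$Ms <= 1),
            all(taxa$breeding %in% c("lek", "explosive")),
            activity_scale >= 0, activity_scale <= 1,
            daily_modifier >= 0, daily_modifier <= 1)
  structure(list(n_plots = n_plots, plot_area_km2 = plot_area_km2,
                 n_years = n_years, seed = as.integer(seed),
                 waterbody_means = waterbody_means,
                 surveyed_fractions = surveyed_fractions, taxa = taxa,
                 survey_rel_dates = survey_rel_dates, phi = phi,
                 daily_modifier = daily_modifier,
                 activity_scale = activity_scale,
                 simulate_visual = simulate_visual,
                 visual_coverage = visual_coverage),
            class = "simulation_config")
}

clamp01 <- function(p) pmin(pmax(p, 0), 1)

#' Seasonal calling-activity curve
#'
#' Lek breeders: scaled Gaussian around the peak date (prolonged
#' territorial calling). Explosive breeders: linear rise over the three
#' days before the peak, then exponential decay with time constant
#' `width` (short synchronous breeding).
#'
#' @param rel_date Days since season onset.
#' @param breeding `"lek"` or `"explosive"`.
#' @param peak Peak relative date.
#' @param width Gaussian SD (lek) or decay constant (explosive), days.
#' @param offset Per-site peak offset, days.
#' @return Activity multiplier in \[0, 1\].
#' @export
activity_curve <- function(rel_date, breeding, peak, width, offset = 0) {
  t <- rel_date - offset
  if (breeding == "lek") {
    a <- exp(-0.5 * ((t - peak) / width)^2)
  } else {
    rise <- 3
    a <- ifelse(t < peak - rise, 0,
                ifelse(t <= peak, (t - (peak - rise)) / rise,
                       exp(-(t - peak) / width)))
  }
  clamp01(a)
}

# parameter table for running the estimators on simulated data
sim_taxon_parameters <- function(config) {
  tx <- config$taxa
  data.frame(taxon = tx$taxon, Ma = tx$Ma, sd_Ma = 0, Mp = tx$Mp, sd_Mp = 0,
             Ms = tx$Ms, sd_Ms = 0, ms_L = NA_real_, sd_ms_L = NA_real_,
             ms_E = NA_real_, sd_ms_E = NA_real_,
             hearing_distance_m = tx$hearing_distance_m,
             range_area_km2 = NA_real_, presence_fraction = NA_real_,
             stringsAsFactors = FALSE)
}

#' Simulate a survey dataset with known truth
#'
#' Generates waterbodies, survey events, calling-male counts and
#' (optionally) visual records by the exact probabilistic reading of the
#' MAFD decomposition as a binomial thinning chain: adults are allocated
#' to waterbodies proportionally to habitat, `males ~ Binom(adults, Ms)`,
#' per survey `present ~ Binom(males, Mp * activity(date))`, `calling ~
#' Binom(present, Ma * daily_modifier)`, and for linear habitats only the
#' fraction within hearing range is audible. Counts are recorded only at
#' surveyed sites. Deterministic under a fixed seed.
#'
#' @param config A `"simulation_config"`.
#' @return A list of class `"mafd_simulation"`: `data` (an
#'   `"anuran_survey"`), `truth` (list with `adults` -- per
#'   plot x taxon x year adults and males -- and `latent` -- per
#'   site x survey x taxon latent males/present/calling/audible), and
#'   `params` (the estimator parameter table matching the generative
#'   truth).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cats <- waterbody_categories()
  years <- 2016 + seq_len(config$n_years) - 1L

  ## -- waterbody inventory ---------------------------------------------------
  wb_list <- lapply(seq_len(config$n_plots), function(i) {
    plot <- sprintf("P%02d", i)
    n <- setNames(rpois(4, config$waterbody_means[cats]), cats)
    n["small"] <- max(n["small"], 3)  # a plot always has some ponds
    rows <- lapply(cats, function(cat) {
      k <- n[[cat]]
      if (k == 0) return(NULL)
      area <- switch(cat,
                     small = runif(k, 0.02, 0.49),
                     medium = 10^runif(k, log10(0.5), log10(10)),
                     large = 10^runif(k, log10(10.5), log10(50)),
                     ditch = rep(NA_real_, k))
      perim <- if (cat %in% c("medium", "large")) {
        round(1.3 * 2 * sqrt(pi * area * 1e4), 1)
      } else rep(NA_real_, k)
      len <- if (cat == "ditch") round(runif(k, 800, 4000), 1) else
        rep(NA_real_, k)
      data.frame(plot_id = plot, category = cat,
                 area_ha = if (cat == "ditch") NA_real_ else round(area, 4),
                 perimeter_m = perim, length_m = len,
                 surveyed = runif(k) < config$surveyed_fractions[[cat]],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!any(out$surveyed & out$category == "small")) {
      out$surveyed[which(out$category == "small")[1]] <- TRUE
    }
    out$waterbody_id <- sprintf("%s_W%03d", plot, seq_len(nrow(out)))
    out
  })
  wb <- do.call(rbind, wb_list)
  wb$sampled_length_m <- NA_real_
  wb <- wb[, c("waterbody_id", "plot_id", "category", "area_ha",
               "perimeter_m", "length_m", "surveyed", "sampled_length_m")]

  ## -- survey schedule -------------------------------------------------------
  onset_doy <- setNames(95 + round(rnorm(length(years), 0, 4)), years)
  sv_list <- list()
  for (plot in unique(wb$plot_id)) {
    for (y in years) {
      doy <- onset_doy[[as.character(y)]] + config$survey_rel_dates
      date <- as.Date(sprintf("%d-01-01", y)) + doy - 1
      sv_list[[length(sv_list) + 1L]] <- data.frame(
        survey_id = sprintf("S_%s_%d_%02d", plot, y,
                            seq_along(config$survey_rel_dates)),
        plot_id = plot, year = y, date = date,
        rel_date = config$survey_rel_dates,
        mid_time_h = round(runif(length(doy), 13, 21), 2),
        sunset_time_h = round(clamp01((doy - 60) / 200) * 4 + 19, 2),
        stringsAsFactors = FALSE)
    }
  }
  sv <- do.call(rbind, sv_list)

  ## -- latent populations ----------------------------------------------------
  # habitat weight: one small pond ~ 400 m of shoreline / ditch
  w_alloc <- ifelse(wb$category == "small", 1,
                    ifelse(wb$category == "ditch", wb$length_m / 400,
                           wb$perimeter_m / 400))
  audible_frac <- ifelse(wb$category == "small", 1,
                         NA_real_)  # taxon-dependent for linear habitat

  taxa <- config$taxa
  adults_rows <- list()
  latent_rows <- list()
  count_rows <- list()
  visual_rows <- list()

  for (ti in seq_len(nrow(taxa))) {
    tx <- taxa[ti, ]
    lin <- wb$category != "small"
    tot_len <- ifelse(wb$category == "ditch", wb$length_m, wb$perimeter_m)
    afrac <- ifelse(lin, clamp01(2 * tx$hearing_distance_m / tot_len), 1)

    for (plot in unique(wb$plot_id)) {
      idx <- which(wb$plot_id == plot)
      n_adults <- round(tx$density * config$plot_area_km2)
      alloc <- if (n_adults > 0) {
        as.vector(rmultinom(1, n_adults, w_alloc[idx]))
      } else rep(0L, length(idx))
      for (yi in seq_along(years)) {
        y <- years[yi]
        if (yi > 1) {
          keep <- runif(length(idx)) < config$phi
          displaced <- sum(alloc[!keep])
          alloc[!keep] <- 0L
          if (displaced > 0) {
            alloc <- alloc + as.vector(rmultinom(1, displaced, w_alloc[idx]))
          }
        }
        males <- rbinom(length(idx), alloc, tx$Ms)
        females <- alloc - males
        offsets <- rnorm(length(idx), 0, tx$site_asynchrony_sd)
        adults_rows[[length(adults_rows) + 1L]] <- data.frame(
          plot_id = plot, taxon = tx$taxon, year = y,
          adults = sum(alloc), males = sum(males),
          stringsAsFactors = FALSE)

        svp <- sv[sv$plot_id == plot & sv$year == y, , drop = FALSE]
        surveyed_i <- wb$surveyed[idx]
        for (si in seq_len(nrow(svp))) {
          act <- activity_curve(svp$rel_date[si], tx$breeding, tx$peak,
                                tx$width, offsets) * config$activity_scale
          present <- rbinom(length(idx), males, clamp01(tx$Mp * act))
          calling <- rbinom(length(idx), present,
                            clamp01(tx$Ma * config$daily_modifier))
          audible <- rbinom(length(idx), calling, afrac[idx])
          audible[!surveyed_i] <- 0L  # nobody listening
          latent_rows[[length(latent_rows) + 1L]] <- data.frame(
            survey_id = svp$survey_id[si], waterbody_id = wb$waterbody_id[idx],
            taxon = tx$taxon, year = y, males = males, present = present,
            calling = calling, audible = audible,
            stringsAsFactors = FALSE)
          rec <- surveyed_i & audible > 0
          if (any(rec)) {
            count_rows[[length(count_rows) + 1L]] <- data.frame(
              survey_id = svp$survey_id[si],
              waterbody_id = wb$waterbody_id[idx][rec],
              taxon = tx$taxon, count = audible[rec],
              chorus_averaged = FALSE, stringsAsFactors = FALSE)
          }
        }

        if (config$simulate_visual) {
          covered <- surveyed_i & runif(length(idx)) < config$visual_coverage
          if (any(covered)) {
            dp <- detection_probabilities()
            cls <- sample(names(dp$adults), sum(covered), replace = TRUE,
                          prob = c(0.4, 0.3, 0.2, 0.1))
            present_peak <- rbinom(sum(covered), males[covered], tx$Mp)
            seen <- rbinom(sum(covered), present_peak, dp$adults[cls])
            masses <- rbinom(sum(covered), females[covered], dp$egg_mass)
            visual_rows[[length(visual_rows) + 1L]] <- data.frame(
              waterbody_id = wb$waterbody_id[idx][covered],
              taxon = tx$taxon, year = y, adults_seen = seen,
              sex_known = TRUE, egg_masses = masses,
              visibility_class = cls, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }

  cc <- if (length(count_rows)) do.call(rbind, count_rows) else
    data.frame(survey_id = character(), waterbody_id = character(),
               taxon = character(), count = numeric(),
               chorus_averaged = logical(), stringsAsFactors = FALSE)
  vr <- if (length(visual_rows)) do.call(rbind, visual_rows) else NULL
  sv_out <- sv[, c("survey_id", "plot_id", "year", "date", "mid_time_h",
                   "sunset_time_h")]
  pa <- setNames(rep(config$plot_area_km2, config$n_plots),
                 unique(wb$plot_id))
  data <- anuran_survey(wb, sv_out, cc, vr, pa,
                        default_plot_area_km2 = config$plot_area_km2)
  structure(list(data = data,
                 truth = list(adults = do.call(rbind, adults_rows),
                              latent = do.call(rbind, latent_rows),
                              config = config),
                 params = sim_taxon_parameters(config)),
            class = "mafd_simulation")
}

#' @export
print.mafd_simulation <- function(x, ...) {
  cat("mafd_simulation (seed ", x$truth$config$seed, ")\n", sep = "")
  print(x$data)
  tr <- aggregate(adults ~ taxon, data = x$truth$adults, FUN = mean)
  cat("mean true adults per plot-year:\n")
  print(tr, row.names = FALSE)
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates `n_replicates` independent datasets (replicate `r` uses
#' `seed + r`), runs the density estimators with parameters equal to the
#' generative truth, and reports the relative bias and RMSE of MAFD
#' against the true adult density, per taxon. When visual records are
#' simulated, the mean fraction of population covered is reported too.
#' Plot-taxon combinations with no recorded calls enter as MAFD = 0 (a
#' true minimum estimate).
#'
#' @param config A `"simulation_config"`.
#' @param n_replicates Number of replicate datasets (>= 2).
#' @return `data.frame` with one row per taxon: `taxon`, `true_density`,
#'   `mean_mafd`, `rel_bias`, `rmse`, `n_replicates`,
#'   `mean_fraction_covered` (`NA` unless visual records simulated).
#' @export
recovery_experiment <- function(config, n_replicates = 20) {
  stopifnot(inherits(config, "simulation_config"), n_replicates >= 2)
  params <- sim_taxon_parameters(config)
  err <- list()
  frac <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_dataset(cfg)
    est <- suppressWarnings(estimate_density(sim$data, params))
    truth <- aggregate(adults ~ plot_id + taxon, data = sim$truth$adults,
                       FUN = mean)  # adults constant across years per plot
    truth$true_density <- truth$adults / config$plot_area_km2
    m <- merge(truth, est[, c("plot_id", "taxon", "mafd")],
               by = c("plot_id", "taxon"), all.x = TRUE)
    m$mafd[is.na(m$mafd)] <- 0
    m$rel_err <- ifelse(m$true_density > 0,
                        (m$mafd - m$true_density) / m$true_density, NA)
    err[[r]] <- m
    if (config$simulate_visual) {
      cv <- suppressWarnings(correct_visual(sim$data, params))
      frac[[r]] <- cv[, c("taxon", "fraction_covered")]
    }
  }
  all <- do.call(rbind, err)
  out <- lapply(split(all, all$taxon), function(d) {
    data.frame(taxon = d$taxon[1],
               true_density = mean(d$true_density),
               mean_mafd = mean(d$mafd),
               rel_bias = mean(d$rel_err, na.rm = TRUE),
               rmse = sqrt(mean(d$rel_err^2, na.rm = TRUE)),
               n_replicates = n_replicates,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (length(frac)) {
    fr <- do.call(rbind, frac)
    fm <- vapply(split(fr, fr$taxon),
                 function(d) mean(d$fraction_covered, na.rm = TRUE),
                 numeric(1))
    out$mean_fraction_covered <- unname(fm[out$taxon])
  } else {
    out$mean_fraction_covered <- NA_real_
  }
  rownames(out) <- NULL
  out
}
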