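#' Sampled habitat length within hearing range
#'
#' For linear habitats (medium/large waterbody shorelines, ditches) only
#' the stretch within the observer's hearing range is effectively
#' surveyed. An explicitly measured `sampled_length_m` is honoured;
#' otherwise the default rule is `2 * hearing_distance * n_points`
#' (listening both ways along the shoreline from each listening point),
#' capped at the habitat total.
#'
#' @param total_m Total perimeter (medium/large) or ditch length, metres.
#' @param hearing_distance_m Taxon-specific minimum hearing distance.
#' @param n_points Number of listening points along the habitat.
#' @param sampled_length_m Optional explicit measurement overriding the
#'   rule (`NA` to use the rule). Must not exceed `total_m`.
#' @return Sampled length in metres, vectorised over the inputs.
#' @export
#' @examples
#' sampled_length(5000, 150)      # 300
#' sampled_length(400, 500)       # 400, fully covered
sampled_length <- function(total_m, hearing_distance_m, n_points = 1,
                           sampled_length_m = NA_real_) {
  n <- max(length(total_m), length(sampled_length_m))
  total_m <- rep_len(total_m, n)
  sampled_length_m <- rep_len(sampled_length_m, n)
  n_points <- rep_len(n_points, n)
  if (any(is.na(total_m) | total_m <= 0)) {
    stop("missing or non-positive habitat total length", call. = FALSE)
  }
  if (any(hearing_distance_m <= 0)) stop("hearing_distance_m must be > 0")
  rule <- pmin(total_m, 2 * hearing_distance_m * n_points)
  out <- ifelse(is.na(sampled_length_m), rule, sampled_length_m)
  if (any(out > total_m)) {
    stop("sampled_length_m exceeds habitat total", call. = FALSE)
  }
  out
}

# Category tallies from a waterbody table and per-site best counts.
# `best` is a data.frame(waterbody_id, best); sites absent from it count 0.
# Units: small -> waterbody counts; medium/large/ditch -> metres.
tally_from_best <- function(wb, best, hearing_distance_m, n_points = 1) {
  bestv <- setNames(best$best, best$waterbody_id)
  cnt <- function(ids) sum(bestv[intersect(ids, names(bestv))])
  rows <- lapply(waterbody_categories(), function(cat) {
    w <- wb[wb$category == cat, , drop = FALSE]
    sv <- w[w$surveyed, , drop = FALSE]
    if (cat == "small") {
      Pt <- nrow(w); Ps <- nrow(sv)
    } else {
      tot <- if (cat == "ditch") w$length_m else w$perimeter_m
      Pt <- sum(tot)
      stot <- if (cat == "ditch") sv$length_m else sv$perimeter_m
      Ps <- if (nrow(sv)) {
        sum(sampled_length(stot, hearing_distance_m, n_points,
                           sv$sampled_length_m))
      } else 0
    }
    C <- cnt(sv$waterbody_id)
    data.frame(category = cat, C = C, Pt = Pt, Ps = Ps,
               stringsAsFactors = FALSE)
  })
  tl <- do.call(rbind, rows)
  bad <- tl$C > 0 & tl$Ps <= 0
  if (any(bad)) {
    stop("inconsistent tally: counts recorded in unsampled category ",
         paste(tl$category[bad], collapse = ", "), call. = FALSE)
  }
  unsampled <- tl$Pt > 0 & tl$Ps == 0
  if (any(unsampled)) {
    warning("unsampled stratum (Pt > 0, Ps = 0) contributes 0: ",
            paste(tl$category[unsampled], collapse = ", "), call. = FALSE)
  }
  tl
}

#' Tally counts and habitat by waterbody category
#'
#' Builds, for one plot, taxon and year, the per-category inputs of the
#' calling-male density estimator: summed per-site best counts `C`, total
#' habitat `Pt` and surveyed habitat `Ps`. Small waterbodies are counted
#' as units (they lie fully within hearing range); medium/large
#' waterbodies and ditches are treated as linear shoreline habitat in
#' metres, with surveyed lengths from [sampled_length()].
#'
#' @param x An `"anuran_survey"` object.
#' @param plot_id,taxon Plot and taxon.
#' @param year Year; default [select_best_year()].
#' @param params `"taxon_parameters"` (supplies the hearing distance).
#' @param n_points Listening points per linear habitat.
#' @return `data.frame` with one row per category: `category`, `C`, `Pt`,
#'   `Ps`.
#' @export
tally_categories <- function(x, plot_id, taxon, year = NULL,
                             params = taxon_params(taxon), n_points = 1) {
  if (is.null(year)) year <- select_best_year(x, plot_id, taxon)
  wb <- x$waterbodies[x$waterbodies$plot_id == plot_id, , drop = FALSE]
  sb <- site_year_best(x, taxon = taxon, plot_id = plot_id)
  sb <- sb[!is.na(year) & sb$year %in% year, c("waterbody_id", "best")]
  tally_from_best(wb, sb, params$hearing_distance_m, n_points)
}

#' Calling-male density Dc
#'
#' Stratified extrapolation of counted calling males to all plot habitat:
#' `Dc = sum_i (C_i * Pt_i / Ps_i) / S` over the four waterbody
#' categories, where `C` is the summed best count, `Pt`/`Ps` the total and
#' surveyed habitat in a category, and `S` the plot area in km^2.
#' Categories with no habitat, or no surveyed habitat and no counts,
#' contribute 0.
#'
#' @param tallies Output of [tally_categories()].
#' @param plot_area_km2 Plot area `S` (> 0).
#' @param by_category Return the per-category components instead of their
#'   sum.
#' @return Calling males per km^2: a scalar, or a named vector over
#'   categories when `by_category = TRUE`.
#' @export
compute_dc <- function(tallies, plot_area_km2, by_category = FALSE) {
  stopifnot(is.numeric(plot_area_km2), plot_area_km2 > 0)
  if (any(tallies$C > 0 & tallies$Ps <= 0)) {
    stop("inconsistent tally: C > 0 with Ps = 0", call. = FALSE)
  }
  comp <- ifelse(tallies$Ps > 0, tallies$C * tallies$Pt / tallies$Ps, 0) /
    plot_area_km2
  names(comp) <- tallies$category
  if (by_category) comp else sum(comp)
}

#' Minimum adult frog density MAFD
#'
#' Converts calling-male density into a minimum adult density by undoing
#' the three detection proportions: `MAFD = Dc / (Ma * Mp * Ms)`. Because
#' the parameters are peak-activity maxima, the result is a deliberate
#' lower bound on true adult density. For the water-frog complex the sex
#' ratio differs by waterbody category, so the division is applied per
#' category: `MAFD = sum_i Dc_i / (Ma * Mp * Ms_i)` with the
#' *P. lessonae* ratio for small waterbodies and ditches, *P. esculentus*
#' for large, and their mean for medium.
#'
#' @param dc Calling-male density: a scalar for scalar-`Ms` taxa, or a
#'   vector named by waterbody category (as returned by
#'   `compute_dc(..., by_category = TRUE)`), required for the water-frog
#'   complex.
#' @param params A `"taxon_parameters"` list.
#' @return Minimum adult density, individuals per km^2.
#' @export
#' @examples
#' compute_mafd(4.1, taxon_params("Bombina bombina")) # 12.0
compute_mafd <- function(dc, params) {
  validate_taxon_params(params)
  if (any(dc < 0)) stop("dc must be >= 0", call. = FALSE)
  if (is_water_frog(params)) {
    if (is.null(names(dc)) || !all(names(dc) %in% waterbody_categories())) {
      stop("water-frog complex requires dc named by waterbody category ",
           "(use compute_dc(..., by_category = TRUE))", call. = FALSE)
    }
    ms <- taxon_ms(params, names(dc))
  } else {
    ms <- params$Ms
  }
  sum(dc / (params$Ma * params$Mp * ms))
}

#' Relative contributions of waterbody categories to MAFD
#'
#' The share of the total minimum adult density attributable to each
#' waterbody category. For scalar-`Ms` taxa the shares equal the `Dc`
#' shares; for the water-frog complex the category sex ratios reweight
#' them.
#'
#' @param dc_by_category Named per-category `Dc` vector
#'   (`compute_dc(..., by_category = TRUE)`).
#' @param params A `"taxon_parameters"` list.
#' @return Named numeric vector of fractions summing to 1, or all-`NA`
#'   when the total MAFD is 0.
#' @export
category_contributions <- function(dc_by_category, params) {
  stopifnot(!is.null(names(dc_by_category)))
  ms <- taxon_ms(params, names(dc_by_category))
  comp <- dc_by_category / (params$Ma * params$Mp * ms)
  tot <- sum(comp)
  if (tot <= 0) return(setNames(rep(NA_real_, length(comp)), names(comp)))
  comp / tot
}

#' Density estimates for every plot and taxon
#'
#' Runs the full best-year -> tally -> `Dc` -> `MAFD` chain for each plot
#' x taxon combination with call records.
#'
#' @param x An `"anuran_survey"` object.
#' @param params_table Taxon parameter table
#'   ([default_taxon_parameters()] layout).
#' @param taxa Taxa to include; default all recorded taxa that appear in
#'   `params_table`.
#' @param n_points Listening points per linear habitat.
#' @return `data.frame` with one row per plot x taxon: `plot_id`, `taxon`,
#'   `year`, `plot_area_km2`, `dc`, `mafd`, per-category `Dc` components
#'   (`dc_small` ...) and contribution fractions (`frac_small` ...).
#' @export
estimate_density <- function(x, params_table = default_taxon_parameters(),
                             taxa = NULL, n_points = 1) {
  sb <- site_year_best(x)
  if (is.null(taxa)) taxa <- intersect(unique(sb$taxon), params_table$taxon)
  combos <- unique(sb[sb$taxon %in% taxa, c("plot_id", "taxon")])
  rows <- mapply(function(p, t) {
    pars <- taxon_params(t, params_table)
    yr <- select_best_year(x, p, t)
    tl <- tally_categories(x, p, t, year = yr, params = pars,
                           n_points = n_points)
    S <- x$plot_areas[[p]]
    dcc <- compute_dc(tl, S, by_category = TRUE)
    mafd <- compute_mafd(dcc, pars)
    fr <- category_contributions(dcc, pars)
    out <- data.frame(plot_id = p, taxon = t, year = yr,
                      plot_area_km2 = S, dc = sum(dcc), mafd = mafd,
                      stringsAsFactors = FALSE)
    for (cat in waterbody_categories()) {
      out[[paste0("dc_", cat)]] <- dcc[[cat]]
      out[[paste0("frac_", cat)]] <- fr[[cat]]
    }
    out
  }, combos$plot_id, combos$taxon, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$taxon, out$plot_id), , drop = FALSE]
}

#' Taxon-level density summary
#'
#' Mean, standard deviation, median and sample size of `Dc` and `MAFD`
#' per taxon, plus mean category contributions.
#'
#' @param estimates Output of [estimate_density()].
#' @return `data.frame` with one row per taxon.
#' @export
density_summary <- function(estimates) {
  out <- lapply(split(estimates, estimates$taxon), function(d) {
    row <- data.frame(
      taxon = d$taxon[1], n_plots = nrow(d),
      dc_mean = mean(d$dc), dc_sd = if (nrow(d) > 1) sd(d$dc) else NA_real_,
      dc_median = median(d$dc),
      mafd_mean = mean(d$mafd),
      mafd_sd = if (nrow(d) > 1) sd(d$mafd) else NA_real_,
      mafd_median = median(d$mafd),
      stringsAsFactors = FALSE
    )
    for (cat in waterbody_categories()) {
      v <- d[[paste0("frac_", cat)]]
      row[[paste0("frac_", cat, "_mean")]] <- mean(v[!is.na(v)])
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
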