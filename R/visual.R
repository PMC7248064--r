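#' Estimate males present from a visual record
#'
#' Converts a visual observation into an estimate of the males present at
#' the waterbody. Adults seen are divided by the visibility-class
#' detection probability; when the sex of the observed adults is unknown
#' (water frogs) the estimate is multiplied by the sex ratio `Ms`. Egg
#' masses are divided by the egg-mass detection probability (one mass =
#' one breeding female) and converted to males via `Ms / (1 - Ms)`. The
#' two components are two noisy views of the same male pool, so by
#' default the larger one is used; `combine = "sum"` adds them instead.
#'
#' @param adults_seen Number of adults observed (>= 0).
#' @param egg_masses Number of egg masses observed (>= 0).
#' @param visibility_class One of `clear_active`, `clear_inactive`,
#'   `obstructed`, `casual`; required when `adults_seen > 0`.
#' @param sex_known `TRUE` when the observed adults are males (the default
#'   for *Bufo*/*Rana*, where free-moving adults are almost all male);
#'   `FALSE` for unknown-sex records (water frogs).
#' @param params A `"taxon_parameters"` list.
#' @param dp Detection probabilities, see [detection_probabilities()].
#' @param category Waterbody category (selects the sex ratio for the
#'   water-frog complex).
#' @param combine `"max"` (default) or `"sum"` of the adult and egg
#'   components.
#' @return Estimated number of males present (real-valued).
#' @export
#' @examples
#' estimate_present_males(10, visibility_class = "clear_active",
#'                        params = taxon_params("Bufo bufo"))
estimate_present_males <- function(adults_seen, egg_masses = 0,
                                   visibility_class = NA_character_,
                                   sex_known = TRUE,
                                   params,
                                   dp = detection_probabilities(),
                                   category = "small",
                                   combine = c("max", "sum")) {
  combine <- match.arg(combine)
  if (adults_seen < 0 || egg_masses < 0) stop("counts must be >= 0")
  ms <- taxon_ms(params, category)
  adult_comp <- 0
  if (adults_seen > 0) {
    if (is.na(visibility_class) ||
        !visibility_class %in% names(dp$adults)) {
      stop("visibility_class required when adults_seen > 0", call. = FALSE)
    }
    adult_comp <- adults_seen / dp$adults[[visibility_class]]
    if (!isTRUE(sex_known)) adult_comp <- adult_comp * ms
  }
  egg_comp <- 0
  if (egg_masses > 0) {
    females <- egg_masses / dp$egg_mass
    egg_comp <- females * ms / (1 - ms)
  }
  if (combine == "max") max(adult_comp, egg_comp) else adult_comp + egg_comp
}

#' Augment a calling count with virtual calling males
#'
#' Transfers visually estimated present males into virtual calling males
#' via `Ma` and adds only the *undetected* part to the recorded count:
#' the augmented count is `max(recorded, present * Ma)`, never less than
#' what was actually heard.
#'
#' @param present_males Estimated males present (>= 0).
#' @param Ma Proportion of present males vocalising at peak, in (0, 1\].
#' @param recorded_calling Recorded calling-male count (>= 0).
#' @return Augmented calling-male count.
#' @export
#' @examples
#' virtual_calling_males(80, 0.18, 4)    # 14.4
#' virtual_calling_males(13.33, 0.18, 4) # 4: virtual males already heard
virtual_calling_males <- function(present_males, Ma, recorded_calling = 0) {
  if (any(present_males < 0) || any(recorded_calling < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  if (any(Ma <= 0) || any(Ma > 1)) stop("Ma must be in (0, 1]", call. = FALSE)
  pmax(recorded_calling, present_males * Ma)
}

#' Visually corrected density estimate (NDE) and population coverage
#'
#' Re-runs the tally -> `Dc` -> `MAFD` chain after augmenting every
#' waterbody's best count with virtual calling males inferred from visual
#' observations, yielding the new density estimate `NDE >= MAFD`. The
#' fraction of the population covered by the acoustic estimate is
#' `MAFD / NDE`. The comparison is considered reliable only when visual
#' records cover at least `min_coverage` (default 75%) of the surveyed
#' waterbodies on the plot; otherwise the result row is flagged
#' ineligible and the fraction is `NA`.
#'
#' @param x An `"anuran_survey"` object.
#' @param plot_id,taxon Plot and taxon.
#' @param year Year; default [select_best_year()].
#' @param params A `"taxon_parameters"` list.
#' @param dp Detection probabilities ([detection_probabilities()]).
#' @param min_coverage Minimum fraction of surveyed waterbodies with a
#'   visual record for eligibility.
#' @param combine Component combination rule, see
#'   [estimate_present_males()].
#' @param n_points Listening points per linear habitat.
#' @return One-row `data.frame`: `plot_id`, `taxon`, `year`, `mafd`,
#'   `nde`, `fraction_covered`, `visual_coverage`, `eligible`.
#' @export
compute_nde <- function(x, plot_id, taxon, year = NULL,
                        params = taxon_params(taxon),
                        dp = detection_probabilities(),
                        min_coverage = 0.75, combine = c("max", "sum"),
                        n_points = 1) {
  combine <- match.arg(combine)
  if (is.null(year)) year <- select_best_year(x, plot_id, taxon)
  wb <- x$waterbodies[x$waterbodies$plot_id == plot_id, , drop = FALSE]
  surveyed <- wb$waterbody_id[wb$surveyed]
  sb <- site_year_best(x, taxon = taxon, plot_id = plot_id)
  sb <- sb[!is.na(year) & sb$year %in% year, c("waterbody_id", "best")]

  vr <- x$visual_records
  vrec <- if (!is.null(vr) && nrow(vr)) {
    vr[vr$taxon == taxon & vr$year %in% year &
         vr$waterbody_id %in% surveyed, , drop = FALSE]
  } else {
    data.frame(waterbody_id = character(), adults_seen = numeric(),
               egg_masses = numeric(), sex_known = logical(),
               visibility_class = character(), stringsAsFactors = FALSE)
  }
  coverage <- if (length(surveyed)) {
    length(unique(vrec$waterbody_id)) / length(surveyed)
  } else 0
  eligible <- coverage >= min_coverage

  recorded <- setNames(rep(0, length(surveyed)), surveyed)
  recorded[sb$waterbody_id] <- sb$best
  augmented <- recorded
  if (nrow(vrec)) {
    cat_of <- setNames(wb$category, wb$waterbody_id)
    for (i in seq_len(nrow(vrec))) {
      id <- vrec$waterbody_id[i]
      present <- estimate_present_males(
        vrec$adults_seen[i], vrec$egg_masses[i], vrec$visibility_class[i],
        vrec$sex_known[i], params, dp, category = cat_of[[id]],
        combine = combine)
      augmented[id] <- virtual_calling_males(present, params$Ma,
                                             augmented[id])
    }
  }

  S <- x$plot_areas[[plot_id]]
  mk <- function(v) data.frame(waterbody_id = names(v), best = unname(v),
                               stringsAsFactors = FALSE)
  dc_rec <- compute_dc(tally_from_best(wb, mk(recorded),
                                       params$hearing_distance_m, n_points),
                       S, by_category = TRUE)
  dc_aug <- compute_dc(tally_from_best(wb, mk(augmented),
                                       params$hearing_distance_m, n_points),
                       S, by_category = TRUE)
  mafd <- compute_mafd(dc_rec, params)
  nde <- compute_mafd(dc_aug, params)
  data.frame(
    plot_id = plot_id, taxon = taxon,
    year = if (is.na(year)) NA_integer_ else as.integer(year),
    mafd = mafd, nde = nde,
    fraction_covered = if (eligible && nde > 0) mafd / nde else NA_real_,
    visual_coverage = coverage, eligible = eligible,
    stringsAsFactors = FALSE
  )
}

#' Visual correction for every plot and taxon
#'
#' Applies [compute_nde()] to each plot x taxon combination with call or
#' visual records.
#'
#' @param x An `"anuran_survey"` object.
#' @param params_table Taxon parameter table.
#' @param dp Detection probabilities.
#' @param min_coverage,combine,n_points Passed to [compute_nde()].
#' @return `data.frame` of [compute_nde()] rows.
#' @export
correct_visual <- function(x, params_table = default_taxon_parameters(),
                           dp = detection_probabilities(),
                           min_coverage = 0.75, combine = c("max", "sum"),
                           n_points = 1) {
  combine <- match.arg(combine)
  sb <- site_year_best(x)
  combos <- unique(sb[, c("plot_id", "taxon")])
  if (!is.null(x$visual_records) && nrow(x$visual_records)) {
    pm <- wb_plot_map(x)
    vc <- unique(data.frame(plot_id = unname(pm[x$visual_records$waterbody_id]),
                            taxon = x$visual_records$taxon,
                            stringsAsFactors = FALSE))
    combos <- unique(rbind(combos, vc))
  }
  combos <- combos[combos$taxon %in% params_table$taxon, , drop = FALSE]
  rows <- mapply(function(p, t) {
    compute_nde(x, p, t, params = taxon_params(t, params_table), dp = dp,
                min_coverage = min_coverage, combine = combine,
                n_points = n_points)
  }, combos$plot_id, combos$taxon, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$taxon, out$plot_id), , drop = FALSE]
}

#' Taxon-level summary of population coverage
#'
#' Mean, SD and median of the fraction of population covered by the
#' acoustic MAFD estimate, over eligible plots only.
#'
#' @param corrections Output of [correct_visual()].
#' @return `data.frame` with one row per taxon.
#' @export
coverage_summary <- function(corrections) {
  out <- lapply(split(corrections, corrections$taxon), function(d) {
    v <- d$fraction_covered[d$eligible & !is.na(d$fraction_covered)]
    data.frame(taxon = d$taxon[1], n_plots = length(v),
               fraction_mean = if (length(v)) mean(v) else NA_real_,
               fraction_sd = if (length(v) > 1) sd(v) else NA_real_,
               fraction_median = if (length(v)) median(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
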