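#' Best simultaneous count at one site
#'
#' The largest number of simultaneously counted males over the visits to a
#' site within a year; the quantity entering all density tallies. Absences
#' are recorded as 0. Chorus-averaged estimates may be non-integer.
#'
#' @param counts Numeric vector of per-visit counts.
#' @return The maximum, or `NA` for an empty vector (no visits; excluded
#'   downstream).
#' @export
#' @examples
#' best_site_count(c(0, 3, 1))
best_site_count <- function(counts) {
  if (length(counts) == 0) return(NA_real_)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  max(counts)
}

#' Select the best survey year for a plot and taxon
#'
#' The year maximising the plot's total calling-male score (sum over sites
#' of per-site maxima). Years are never pooled: choruses move between
#' neighbouring waterbodies across years, so the best year is the least
#' biased single snapshot. Ties break to the earliest year.
#'
#' @param x An `"anuran_survey"` object.
#' @param plot_id,taxon Plot and taxon to evaluate.
#' @return Integer year, or `NA` if the taxon was never recorded there.
#' @export
select_best_year <- function(x, plot_id, taxon) {
  sb <- site_year_best(x, taxon = taxon, plot_id = plot_id)
  if (!nrow(sb)) return(NA_integer_)
  totals <- tapply(sb$best, sb$year, sum)
  yrs <- as.integer(names(totals))
  min(yrs[totals == max(totals)])
}

#' Waterbody detection probability (WDP)
#'
#' The fraction of waterbodies with any evidence of adult presence
#' (audial, or visual: adults seen, spawn, tadpoles, metamorphs) that were
#' detected audially. Computed per plot for one year (default the best
#' year); set `pool_years = TRUE` to pool evidence across years.
#'
#' @param x An `"anuran_survey"` object.
#' @param plot_id,taxon Plot and taxon.
#' @param year Year to evaluate; default [select_best_year()].
#' @param pool_years Pool all years instead of a single year.
#' @return Ratio in \[0, 1\], or `NA` when no evidence exists.
#' @export
compute_wdp <- function(x, plot_id, taxon, year = NULL, pool_years = FALSE) {
  if (is.null(year) && !pool_years) year <- select_best_year(x, plot_id, taxon)
  sb <- site_year_best(x, taxon = taxon, plot_id = plot_id)
  if (!pool_years) sb <- sb[sb$year %in% year, , drop = FALSE]
  audial <- unique(sb$waterbody_id[sb$best > 0])

  visual <- character()
  vr <- x$visual_records
  if (!is.null(vr) && nrow(vr)) {
    pm <- wb_plot_map(x)
    v <- vr[vr$taxon == taxon &
              pm[vr$waterbody_id] == plot_id &
              (vr$adults_seen > 0 | vr$egg_masses > 0), , drop = FALSE]
    if (!pool_years) v <- v[v$year %in% year, , drop = FALSE]
    visual <- unique(v$waterbody_id)
  }
  evidence <- union(audial, visual)
  if (!length(evidence)) return(NA_real_)
  length(audial) / length(evidence)
}

#' Inter-year breeding-site fidelity (IYF)
#'
#' The fraction of waterbodies with a call record in the pooled data of
#' all years that also had a call record in the most productive year. Low
#' values mean choruses shifted between waterbodies (or detection failed)
#' across years; true shifts and detection failures are deliberately not
#' discriminated.
#'
#' @inheritParams compute_wdp
#' @return Ratio in (0, 1\], or `NA` when the plot has fewer than two
#'   survey years or the taxon was never recorded.
#' @export
compute_iyf <- function(x, plot_id, taxon) {
  if (length(plot_survey_years(x, plot_id)) < 2) return(NA_real_)
  sb <- site_year_best(x, taxon = taxon, plot_id = plot_id)
  pooled <- unique(sb$waterbody_id[sb$best > 0])
  if (!length(pooled)) return(NA_real_)
  by <- select_best_year(x, plot_id, taxon)
  best <- unique(sb$waterbody_id[sb$best > 0 & sb$year == by])
  length(best) / length(pooled)
}

#' Contribution of the most productive survey (CMPS)
#'
#' The ratio of the best single-survey plot total to the plot's total
#' calling-male score for the year (sum over sites of per-site maxima).
#' Values near 1 mean one well-timed survey captured nearly every site at
#' its maximum; low values indicate that site maxima were spread over
#' several surveys and more visits per season are advisable.
#'
#' @inheritParams compute_wdp
#' @return Ratio in (0, 1\], or `NA` for an all-zero year.
#' @export
compute_cmps <- function(x, plot_id, taxon, year = NULL) {
  if (is.null(year)) year <- select_best_year(x, plot_id, taxon)
  if (is.na(year)) return(NA_real_)
  sb <- site_year_best(x, taxon = taxon, plot_id = plot_id)
  sb <- sb[sb$year == year, , drop = FALSE]
  denom <- sum(sb$best)
  if (denom <= 0) return(NA_real_)
  cc <- merge(x$call_counts[x$call_counts$taxon == taxon, , drop = FALSE],
              x$surveys[x$surveys$plot_id == plot_id &
                          x$surveys$year == year,
                        c("survey_id", "plot_id", "year")],
              by = "survey_id")
  tot <- tapply(cc$count, cc$survey_id, sum)
  max(tot) / denom
}

#' Summarise one plot-taxon-year
#'
#' Mean calling males per *occupied* waterbody, the fraction of surveyed
#' waterbodies with audial records, and the quality metrics, for the best
#' (or a given) year.
#'
#' @inheritParams compute_wdp
#' @return One-row `data.frame`: `plot_id`, `taxon`, `best_year`, `wdp`,
#'   `iyf`, `cmps`, `mean_calling_males`, `fraction_occupied`.
#' @export
summarize_plot <- function(x, plot_id, taxon, year = NULL) {
  if (is.null(year)) year <- select_best_year(x, plot_id, taxon)
  n_surveyed <- sum(x$waterbodies$plot_id == plot_id & x$waterbodies$surveyed)
  sb <- site_year_best(x, taxon = taxon, plot_id = plot_id)
  sb <- sb[!is.na(year) & sb$year %in% year, , drop = FALSE]
  occ <- sb$best[sb$best > 0]
  data.frame(
    plot_id = plot_id, taxon = taxon,
    best_year = if (is.na(year)) NA_integer_ else as.integer(year),
    wdp = compute_wdp(x, plot_id, taxon, year = year),
    iyf = compute_iyf(x, plot_id, taxon),
    cmps = if (is.na(year)) NA_real_ else compute_cmps(x, plot_id, taxon, year),
    mean_calling_males = if (length(occ)) mean(occ) else NA_real_,
    fraction_occupied = if (n_surveyed > 0) length(occ) / n_surveyed else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Survey-quality metrics for every plot and taxon
#'
#' Applies [summarize_plot()] to each plot x taxon combination with at
#' least one call record.
#'
#' @param x An `"anuran_survey"` object.
#' @param taxa Taxa to include; default all taxa present in the counts.
#' @return `data.frame` with one row per plot x taxon.
#' @export
plot_taxon_metrics <- function(x, taxa = NULL) {
  sb <- site_year_best(x)
  if (!is.null(taxa)) sb <- sb[sb$taxon %in% taxa, , drop = FALSE]
  combos <- unique(sb[, c("plot_id", "taxon")])
  if (!nrow(combos)) {
    return(data.frame(plot_id = character(), taxon = character(),
                      best_year = integer(), wdp = numeric(),
                      iyf = numeric(), cmps = numeric(),
                      mean_calling_males = numeric(),
                      fraction_occupied = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- mapply(function(p, t) summarize_plot(x, p, t),
                 combos$plot_id, combos$taxon, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$taxon, out$plot_id), , drop = FALSE]
}

#' Taxon-level summary of survey metrics
#'
#' Mean, standard deviation and sample size (number of plots) per taxon
#' for each metric, with plots as the unit of dispersion.
#'
#' @param metrics Output of [plot_taxon_metrics()].
#' @return `data.frame` with one row per taxon.
#' @export
metrics_summary <- function(metrics) {
  summ <- function(v) {
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else NA_real_,
      n = length(v))
  }
  cols <- c("wdp", "iyf", "cmps", "mean_calling_males", "fraction_occupied")
  out <- lapply(split(metrics, metrics$taxon), function(d) {
    res <- unlist(lapply(cols, function(cl) setNames(summ(d[[cl]]),
                                                     paste0(cl, c("_mean", "_sd", "_n")))))
    data.frame(taxon = d$taxon[1], t(res), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
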