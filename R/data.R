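#' Assemble and validate a survey dataset
#'
#' Bundles the four survey tables into a validated container used by all
#' downstream estimators. Referential integrity is enforced: every call
#' count must reference an existing survey and a *surveyed* waterbody on
#' the same plot; opportunistic counts at unsurveyed sites are rejected.
#'
#' Expected columns (extra columns are preserved):
#' \describe{
#'   \item{waterbodies}{`waterbody_id`, `plot_id`, `category` (small /
#'     medium / large / ditch), `area_ha` (lentic), `perimeter_m`
#'     (medium/large), `length_m` (ditch), `surveyed` (logical), optional
#'     `sampled_length_m`.}
#'   \item{surveys}{`survey_id`, `plot_id`, `year`, `date` (ISO-8601),
#'     optional `mid_time_h`, `sunset_time_h` (decimal hours), weather
#'     fields.}
#'   \item{call_counts}{`survey_id`, `waterbody_id`, `taxon`, `count`
#'     (non-negative; integer unless `chorus_averaged` is `TRUE`),
#'     optional `chorus_averaged`, `calling_index`.}
#'   \item{visual_records}{optional; `waterbody_id`, `taxon`, `year`,
#'     `adults_seen`, `sex_known` (logical), `egg_masses`,
#'     `visibility_class` (required whenever `adults_seen > 0`).}
#' }
#'
#' @param waterbodies,surveys,call_counts,visual_records Data frames as
#'   described above; `visual_records` may be `NULL`.
#' @param plot_areas Named numeric vector of plot areas in km^2; plots not
#'   named fall back to `default_plot_area_km2`.
#' @param default_plot_area_km2 Default plot area (standard 5 x 5 km plot).
#' @return An object of class `"anuran_survey"`.
#' @seealso [read_survey_data()], [write_survey_data()]
#' @export
anuran_survey <- function(waterbodies, surveys, call_counts,
                          visual_records = NULL, plot_areas = NULL,
                          default_plot_area_km2 = 25) {
  wb <- as.data.frame(waterbodies)
  sv <- as.data.frame(surveys)
  cc <- as.data.frame(call_counts)
  vr <- if (!is.null(visual_records)) as.data.frame(visual_records)

  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop("load error: ", what, " missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need(wb, c("waterbody_id", "plot_id", "category", "surveyed"), "waterbodies")
  need(sv, c("survey_id", "plot_id", "year", "date"), "surveys")
  need(cc, c("survey_id", "waterbody_id", "taxon", "count"), "call_counts")
  if (!is.null(vr) && nrow(vr)) {
    need(vr, c("waterbody_id", "taxon", "year", "adults_seen", "egg_masses"),
         "visual_records")
    if (is.null(vr$sex_known)) vr$sex_known <- TRUE
    if (is.null(vr$visibility_class)) vr$visibility_class <- NA_character_
  }
  for (opt in c("area_ha", "perimeter_m", "length_m", "sampled_length_m")) {
    if (is.null(wb[[opt]])) wb[[opt]] <- NA_real_
    wb[[opt]] <- as.numeric(wb[[opt]])  # all-NA columns read back as logical
  }
  if (is.null(cc$chorus_averaged)) cc$chorus_averaged <- FALSE
  cc$chorus_averaged[is.na(cc$chorus_averaged)] <- FALSE
  sv$date <- as.Date(sv$date)
  sv$year <- as.integer(sv$year)
  wb$surveyed <- as.logical(wb$surveyed)

  plots <- sort(unique(wb$plot_id))
  pa <- rep(default_plot_area_km2, length(plots))
  names(pa) <- plots
  if (!is.null(plot_areas)) {
    known <- intersect(names(plot_areas), plots)
    pa[known] <- as.numeric(plot_areas[known])
  }

  x <- structure(
    list(waterbodies = wb, surveys = sv, call_counts = cc,
         visual_records = vr, plot_areas = pa),
    class = "anuran_survey"
  )
  validate_survey_data(x)
}

#' Validate an `anuran_survey` object
#'
#' Runs all structural and referential checks; called by [anuran_survey()].
#' Errors list the offending identifiers.
#'
#' @param x An `"anuran_survey"` object.
#' @return `x`, invisibly on success (visibly when called directly).
#' @export
validate_survey_data <- function(x) {
  wb <- x$waterbodies; sv <- x$surveys; cc <- x$call_counts
  vr <- x$visual_records
  problems <- character()
  add <- function(msg, ids) {
    if (length(ids)) {
      problems <<- c(problems,
                     paste0(msg, ": ", paste(unique(ids), collapse = ", ")))
    }
  }

  add("duplicate waterbody_id", wb$waterbody_id[duplicated(wb$waterbody_id)])
  add("duplicate survey_id", sv$survey_id[duplicated(sv$survey_id)])
  add("invalid category",
      wb$waterbody_id[!wb$category %in% waterbody_categories()])
  add("waterbody with NA surveyed flag", wb$waterbody_id[is.na(wb$surveyed)])

  lentic <- wb$category %in% c("small", "medium", "large")
  bad_area <- lentic & (is.na(wb$area_ha) | wb$area_ha <= 0)
  add("lentic waterbody without positive area_ha", wb$waterbody_id[bad_area])
  ok_area <- lentic & !bad_area
  if (any(ok_area)) {
    cls <- classify_waterbody(wb$area_ha[ok_area])
    add("category inconsistent with area_ha",
        wb$waterbody_id[ok_area][cls != wb$category[ok_area]])
  }
  ml <- wb$category %in% c("medium", "large")
  add("medium/large waterbody without positive perimeter_m",
      wb$waterbody_id[ml & (is.na(wb$perimeter_m) | wb$perimeter_m <= 0)])
  dt <- wb$category == "ditch"
  add("ditch without positive length_m",
      wb$waterbody_id[dt & (is.na(wb$length_m) | wb$length_m <= 0)])
  tot <- ifelse(dt, wb$length_m, wb$perimeter_m)
  over <- !is.na(wb$sampled_length_m) & !is.na(tot) & wb$sampled_length_m > tot
  add("sampled_length_m exceeds habitat total", wb$waterbody_id[over])

  add("survey with unparseable date", sv$survey_id[is.na(sv$date)])
  okd <- !is.na(sv$date)
  add("survey date outside its year",
      sv$survey_id[okd & as.integer(format(sv$date, "%Y")) != sv$year])
  if (!is.null(sv$sunset_time_h)) {
    add("sunset at or before astronomic noon",
        sv$survey_id[!is.na(sv$sunset_time_h) & sv$sunset_time_h <= 12])
  }

  add("count referencing unknown survey",
      cc$survey_id[!cc$survey_id %in% sv$survey_id])
  orphan_wb <- !cc$waterbody_id %in% wb$waterbody_id
  add("count referencing unknown waterbody", cc$waterbody_id[orphan_wb])
  surveyed_ids <- wb$waterbody_id[wb$surveyed]
  add("count at unsurveyed waterbody",
      cc$waterbody_id[!orphan_wb & !cc$waterbody_id %in% surveyed_ids])
  wb_plot <- setNames(wb$plot_id, wb$waterbody_id)
  sv_plot <- setNames(sv$plot_id, sv$survey_id)
  both <- !orphan_wb & cc$survey_id %in% sv$survey_id
  mismatch <- both &
    wb_plot[cc$waterbody_id] != sv_plot[cc$survey_id]
  if (any(mismatch)) {
    add("count whose survey and waterbody are on different plots",
        paste0(cc$survey_id[mismatch], "/", cc$waterbody_id[mismatch]))
  }
  add("negative or missing count",
      cc$waterbody_id[is.na(cc$count) | cc$count < 0])
  nonint <- !is.na(cc$count) & cc$count %% 1 != 0 & !cc$chorus_averaged
  add("non-integer count not flagged chorus_averaged",
      cc$waterbody_id[nonint])

  if (!is.null(vr) && nrow(vr)) {
    add("visual record at unknown waterbody",
        vr$waterbody_id[!vr$waterbody_id %in% wb$waterbody_id])
    add("negative visual count",
        vr$waterbody_id[vr$adults_seen < 0 | vr$egg_masses < 0])
    seen <- !is.na(vr$adults_seen) & vr$adults_seen > 0
    add("adults_seen > 0 without visibility_class",
        vr$waterbody_id[seen & (is.na(vr$visibility_class) |
                                !vr$visibility_class %in%
                                  names(detection_probabilities()$adults))])
  }

  if (length(problems)) {
    stop("survey data validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.anuran_survey <- function(x, ...) {
  cat("anuran_survey:",
      length(x$plot_areas), "plots,",
      nrow(x$waterbodies), "waterbodies,",
      nrow(x$surveys), "surveys,",
      nrow(x$call_counts), "call counts,",
      if (is.null(x$visual_records)) 0 else nrow(x$visual_records),
      "visual records\n")
  cat("taxa:", paste(sort(unique(x$call_counts$taxon)), collapse = ", "), "\n")
  invisible(x)
}

#' Read a survey dataset from a directory of delimited files
#'
#' Loads `waterbodies.csv`, `surveys.csv` and `call_counts.csv` (required),
#' `visual_records.csv` and `plots.csv` (optional; the latter carries
#' `plot_id`, `area_km2`) from `dir`. Files are comma-delimited UTF-8 with
#' a mandatory header row. Validation is as in [anuran_survey()].
#'
#' @param dir Directory containing the files.
#' @param default_plot_area_km2 Area assigned to plots absent from
#'   `plots.csv`.
#' @return An `"anuran_survey"` object.
#' @export
read_survey_data <- function(dir, default_plot_area_km2 = 25) {
  fp <- function(name) file.path(dir, name)
  for (f in c("waterbodies.csv", "surveys.csv", "call_counts.csv")) {
    if (!file.exists(fp(f))) stop("load error: missing required file ", f,
                                  call. = FALSE)
  }
  rd <- function(name) read.csv(fp(name), stringsAsFactors = FALSE)
  vr <- if (file.exists(fp("visual_records.csv"))) rd("visual_records.csv")
  pa <- NULL
  if (file.exists(fp("plots.csv"))) {
    pl <- rd("plots.csv")
    pa <- setNames(pl$area_km2, pl$plot_id)
  }
  anuran_survey(rd("waterbodies.csv"), rd("surveys.csv"),
                rd("call_counts.csv"), vr, pa,
                default_plot_area_km2 = default_plot_area_km2)
}

#' Write a survey dataset to a directory of delimited files
#'
#' Inverse of [read_survey_data()]; writes `waterbodies.csv`,
#' `surveys.csv`, `call_counts.csv`, `plots.csv` and (when present)
#' `visual_records.csv`. Text-representable values round-trip exactly.
#'
#' @param x An `"anuran_survey"` object.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_survey_data <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE, quote = TRUE,
              na = "")
  }
  sv <- x$surveys
  sv$date <- format(sv$date, "%Y-%m-%d")
  wr(x$waterbodies, "waterbodies.csv")
  wr(sv, "surveys.csv")
  wr(x$call_counts, "call_counts.csv")
  wr(data.frame(plot_id = names(x$plot_areas),
                area_km2 = unname(x$plot_areas)), "plots.csv")
  if (!is.null(x$visual_records)) wr(x$visual_records, "visual_records.csv")
  invisible(dir)
}

#' Season onset dates
#'
#' The earliest date with any audial record (of any taxon) per year,
#' defining the zero of the relative-date transform.
#'
#' @param x An `"anuran_survey"` object.
#' @return `data.frame` with columns `year`, `onset_date`.
#' @export
season_onsets <- function(x) {
  cc <- merge(x$call_counts[x$call_counts$count > 0, , drop = FALSE],
              x$surveys[, c("survey_id", "year", "date")], by = "survey_id")
  if (!nrow(cc)) return(data.frame(year = integer(), onset_date = as.Date(character())))
  on <- aggregate(date ~ year, data = cc, FUN = min)
  names(on)[2] <- "onset_date"
  on[order(on$year), , drop = FALSE]
}

# ---- internal helpers shared by metrics and density -------------------------

# plot lookup for waterbodies / surveys
wb_plot_map <- function(x) setNames(x$waterbodies$plot_id, x$waterbodies$waterbody_id)

# Per-site best (max) simultaneous count, by plot x waterbody x taxon x year.
# Only recorded counts appear; surveyed sites without records are implicit 0s.
site_year_best <- function(x, taxon = NULL, plot_id = NULL) {
  cc <- x$call_counts
  if (!is.null(taxon)) cc <- cc[cc$taxon %in% taxon, , drop = FALSE]
  cc <- merge(cc, x$surveys[, c("survey_id", "plot_id", "year")],
              by = "survey_id")
  if (!is.null(plot_id)) cc <- cc[cc$plot_id %in% plot_id, , drop = FALSE]
  if (!nrow(cc)) {
    return(data.frame(plot_id = character(), waterbody_id = character(),
                      taxon = character(), year = integer(),
                      best = numeric(), stringsAsFactors = FALSE))
  }
  out <- aggregate(count ~ plot_id + waterbody_id + taxon + year, data = cc,
                   FUN = max)
  names(out)[names(out) == "count"] <- "best"
  out
}

# years with at least one survey on the plot
plot_survey_years <- function(x, plot_id) {
  sort(unique(x$surveys$year[x$surveys$plot_id == plot_id]))
}
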