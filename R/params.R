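#' Default taxon parameters for MAFD estimation
#'
#' Published vocalisation, presence and sex-ratio parameters for the seven
#' Latvian anuran taxa, together with the minimum hearing distances used to
#' derive sampled shoreline lengths, range areas, and the fraction of plots
#' where each taxon was present (used by the range-wide extrapolation).
#'
#' Parameter meanings:
#' \describe{
#'   \item{Ma}{proportion of the males present in a waterbody that vocalise
#'     during peak activity.}
#'   \item{Mp}{proportion of the adult male population present in
#'     waterbodies at the peak of the breeding season.}
#'   \item{Ms}{proportion of males in the total adult population (sex
#'     ratio). For the hybridogenetic water-frog complex (*Pelophylax*
#'     spp.), `Ms` is split into `ms_L` (*P. lessonae*, applied to small
#'     waterbodies and ditches) and `ms_E` (*P. esculentus*, applied to
#'     large waterbodies); medium waterbodies use the mean of the two.}
#' }
#'
#' `Ms` values for the terrestrial taxa (*P. fuscus*, both *Rana*,
#' *H. arborea*) are population sex ratios, i.e. already reduced by 15%
#' from the published operational sex ratios (see
#' [adjust_operational_sex_ratio()]); do not reduce them again.
#'
#' Presence fractions for the two range-restricted taxa (*B. bombina*,
#' *H. arborea*) are 1.0 because they were recorded in every surveyed plot
#' inside their ranges; the other taxa use the fraction of the 65 national
#' plots with records (0.84 for *R. temporaria*, which includes plots with
#' only visual observations).
#'
#' @return A `data.frame` with one row per taxon and columns `taxon`, `Ma`,
#'   `sd_Ma`, `Mp`, `sd_Mp`, `Ms`, `sd_Ms`, `ms_L`, `sd_ms_L`, `ms_E`,
#'   `sd_ms_E`, `hearing_distance_m`, `range_area_km2`, `presence_fraction`.
#' @seealso [taxon_params()] to extract a single taxon as a parameter list,
#'   [read_taxon_parameters()] to override defaults from a JSON config.
#' @export
#' @examples
#' default_taxon_parameters()
default_taxon_parameters <- function() {
  data.frame(
    taxon = c("Bombina bombina", "Pelobates fuscus", "Bufo bufo",
              "Hyla arborea", "Rana arvalis", "Rana temporaria",
              "Pelophylax spp."),
    Ma    = c(0.61, 0.29, 0.18, 0.58, 0.30, 0.30, 0.63),
    sd_Ma = c(0, 0, 0, 0, 0, 0, 0),
    Mp    = c(1.00, 0.65, 0.78, 0.72, 0.95, 0.95, 1.00),
    sd_Mp = c(0.00, 0.04, 0.08, 0.00, 0.05, 0.05, 0.00),
    Ms    = c(0.56, 0.55, 0.66, 0.55, 0.48, 0.48, NA),
    sd_Ms = c(0.07, 0.04, 0.09, 0.04, 0.06, 0.06, NA),
    ms_L    = c(NA, NA, NA, NA, NA, NA, 0.47),
    sd_ms_L = c(NA, NA, NA, NA, NA, NA, 0.14),
    ms_E    = c(NA, NA, NA, NA, NA, NA, 0.36),
    sd_ms_E = c(NA, NA, NA, NA, NA, NA, 0.08),
    hearing_distance_m = c(100, 50, 150, 500, 100, 50, 500),
    range_area_km2     = c(470, 60000, 60000, 4000, 60000, 60000, 60000),
    presence_fraction  = c(1.00, 0.29, 0.97, 1.00, 0.80, 0.84, 0.98),
    stringsAsFactors = FALSE
  )
}

#' Extract parameters for one taxon
#'
#' @param taxon Taxon name, matched exactly against `params_table$taxon`.
#' @param params_table Parameter table, default [default_taxon_parameters()].
#' @return A list of class `"taxon_parameters"` with the row's fields.
#' @export
#' @examples
#' taxon_params("Bombina bombina")
taxon_params <- function(taxon, params_table = default_taxon_parameters()) {
  i <- match(taxon, params_table$taxon)
  if (is.na(i)) {
    stop("unknown taxon '", taxon, "'; known: ",
         paste(params_table$taxon, collapse = ", "), call. = FALSE)
  }
  p <- as.list(params_table[i, , drop = FALSE])
  p <- lapply(p, unname)
  class(p) <- "taxon_parameters"
  validate_taxon_params(p)
  p
}

validate_taxon_params <- function(p) {
  chk01 <- function(v, nm) {
    if (!is.na(v) && (v <= 0 || v > 1)) {
      stop("parameter ", nm, " = ", v, " outside (0, 1]", call. = FALSE)
    }
  }
  chk01(p$Ma, "Ma"); chk01(p$Mp, "Mp")
  if (is_water_frog(p)) {
    chk01(p$ms_L, "ms_L"); chk01(p$ms_E, "ms_E")
  } else {
    if (is.na(p$Ms)) stop("Ms missing for taxon ", p$taxon, call. = FALSE)
    chk01(p$Ms, "Ms")
  }
  for (nm in c("sd_Ma", "sd_Mp", "sd_Ms", "sd_ms_L", "sd_ms_E")) {
    v <- p[[nm]]
    if (!is.null(v) && !is.na(v) && v < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  if (!is.na(p$hearing_distance_m) && p$hearing_distance_m <= 0) {
    stop("hearing_distance_m must be > 0", call. = FALSE)
  }
  invisible(p)
}

is_water_frog <- function(p) !is.null(p$ms_L) && !is.na(p$ms_L)

#' Sex ratio applicable to a waterbody category
#'
#' Scalar-Ms taxa return `Ms` regardless of category. For the water-frog
#' complex the *P. lessonae* ratio applies to small waterbodies and
#' ditches, the *P. esculentus* ratio to large waterbodies, and their mean
#' to medium waterbodies.
#'
#' @param params A `"taxon_parameters"` list.
#' @param category Character vector of waterbody categories.
#' @return Numeric vector of sex ratios, same length as `category`.
#' @export
taxon_ms <- function(params, category) {
  if (!is_water_frog(params)) {
    return(rep(params$Ms, length(category)))
  }
  ms <- c(small  = params$ms_L,
          ditch  = params$ms_L,
          large  = params$ms_E,
          medium = (params$ms_L + params$ms_E) / 2)
  bad <- setdiff(category, names(ms))
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  unname(ms[category])
}

#' Convert an operational sex ratio into a population sex ratio
#'
#' Operational male proportions observed at breeding aggregations of
#' terrestrial taxa overstate the male share of the whole adult population
#' (not all females attend or breed every year). The published average
#' difference is 15%, so `Ms = 0.85 * operational proportion`. This is a
#' configuration-preparation helper for users supplying their own
#' operational ratios; the shipped [default_taxon_parameters()] values are
#' already adjusted.
#'
#' @param operational_male_proportion Numeric in (0, 1].
#' @return Adjusted population male proportion `Ms`.
#' @export
#' @examples
#' adjust_operational_sex_ratio(0.565) # ~0.48, the Rana default
adjust_operational_sex_ratio <- function(operational_male_proportion) {
  x <- operational_male_proportion
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0) || any(x > 1)) {
    stop("operational_male_proportion must be in (0, 1]", call. = FALSE)
  }
  0.85 * x
}

#' Visual detection probabilities
#'
#' Default probabilities of detecting an adult frog visually, by
#' observation condition, and of detecting an egg mass. Values can be
#' overridden but default to the published calibration:
#' \describe{
#'   \item{clear_active}{0.75 -- unobstructed surface and underwater view,
#'     active breeding behaviour observed.}
#'   \item{clear_inactive}{0.50 -- unobstructed surface view, poor
#'     underwater visibility or no active behaviour.}
#'   \item{obstructed}{0.20 -- strong obstacles to visual observation.}
#'   \item{casual}{0.10 -- separate casual observations.}
#'   \item{egg_mass}{0.90 -- detection probability of an egg mass.}
#' }
#'
#' @param clear_active,clear_inactive,obstructed,casual,egg_mass Override
#'   individual probabilities; each must lie in (0, 1].
#' @return A named list with elements `adults` (named numeric vector over
#'   the four visibility classes) and `egg_mass` (scalar).
#' @export
detection_probabilities <- function(clear_active = 0.75,
                                    clear_inactive = 0.50,
                                    obstructed = 0.20,
                                    casual = 0.10,
                                    egg_mass = 0.90) {
  p <- c(clear_active = clear_active, clear_inactive = clear_inactive,
         obstructed = obstructed, casual = casual, egg_mass = egg_mass)
  if (any(p <= 0) || any(p > 1)) {
    stop("detection probabilities must be in (0, 1]", call. = FALSE)
  }
  list(adults = p[1:4], egg_mass = unname(p[5]))
}

#' Published national-assessment inputs
#'
#' The inputs of the range-wide minimum population size estimates for
#' Latvia: median MAFD per taxon (adults/km^2), the fraction of plots with
#' the taxon present, and the potential range area. These are published
#' values and serve as the default inputs to [estimate_state()]; they are
#' not recomputable from this package without the original field data.
#'
#' @return A `data.frame` with columns `taxon`, `median_mafd`,
#'   `presence_fraction`, `range_area_km2`.
#' @export
latvia_reference_inputs <- function() {
  p <- default_taxon_parameters()
  data.frame(
    taxon = p$taxon,
    median_mafd = c(7.8, 9.0, 27.8, 22.1, 25.2, 20.8, 25.6),
    presence_fraction = p$presence_fraction,
    range_area_km2 = p$range_area_km2,
    stringsAsFactors = FALSE
  )
}

#' Read taxon parameters from a JSON configuration file
#'
#' The file holds an object keyed by taxon name; each entry may override
#' any column of [default_taxon_parameters()] and new taxa may be added
#' (all of `Ma`, `Mp`, `Ms` -- or `ms_L`/`ms_E` -- are then required).
#'
#' @param path Path to a JSON file.
#' @param base Parameter table to override, default the shipped defaults.
#' @return A parameter `data.frame` in the same layout as
#'   [default_taxon_parameters()].
#' @export
read_taxon_parameters <- function(path, base = default_taxon_parameters()) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("config must be a JSON object keyed by taxon")
  for (taxon in names(cfg)) {
    entry <- cfg[[taxon]]
    i <- match(taxon, base$taxon)
    if (is.na(i)) {
      base[nrow(base) + 1L, ] <- NA
      i <- nrow(base)
      base$taxon[i] <- taxon
      base$sd_Ma[i] <- base$sd_Mp[i] <- base$sd_Ms[i] <- 0
    }
    bad <- setdiff(names(entry), names(base))
    if (length(bad)) {
      stop("unknown parameter field(s) for ", taxon, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(entry)) base[[nm]][i] <- entry[[nm]]
  }
  for (taxon in base$taxon) taxon_params(taxon, base)  # validate
  base
}
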