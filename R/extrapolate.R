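#' Range-wide minimum population size (central estimate)
#'
#' Extrapolates a median minimum adult density to the taxon's whole range:
#' `N = median_mafd * presence_fraction * range_area_km2`. The median is
#' used as the central tendency because it damps both inadequately low
#' values from low-activity surveys and very high values from
#' overestimated chorus sizes.
#'
#' @param median_mafd Median minimum adult density, individuals/km^2.
#' @param presence_fraction Fraction of plots (within the range) where the
#'   taxon is present, in \[0, 1\].
#' @param range_area_km2 Potential range area, km^2.
#' @return Minimum adult population size, individuals. Vectorised.
#' @export
#' @examples
#' extrapolate_state(22.1, 1.0, 4000) # ~88 thousand
extrapolate_state <- function(median_mafd, presence_fraction, range_area_km2) {
  if (any(median_mafd < 0) || any(range_area_km2 < 0) ||
      any(presence_fraction < 0) || any(presence_fraction > 1)) {
    stop("inputs must be >= 0 and presence_fraction <= 1", call. = FALSE)
  }
  median_mafd * presence_fraction * range_area_km2
}

# truncated-normal sampler on (0, 1] by rejection; sd = 0 degenerates to mean
rtrunc01 <- function(n, mean, sd) {
  if (is.na(sd) || sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    draw <- rnorm(length(todo), mean, sd)
    ok <- draw > 0 & draw <= 1
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# Ms and its SD entering the uncertainty factor. For the water-frog
# complex the small-waterbody (P. lessonae) ratio is used: small
# waterbodies carry >70% of that taxon's MAFD.
uncertainty_ms <- function(params) {
  if (is_water_frog(params)) c(params$ms_L, params$sd_ms_L)
  else c(params$Ms, params$sd_Ms)
}

#' Propagate parameter uncertainty onto a state estimate
#'
#' The central estimate is built with the point values of `Ma`, `Mp`,
#' `Ms`; its uncertainty reflects the published standard deviations of
#' those parameters (not spatial variance between plots). Two methods:
#' \describe{
#'   \item{monte_carlo}{resample each parameter from a normal distribution
#'     truncated to (0, 1\], rescale the estimate by the ratio of the
#'     point product to the resampled product, and report the sample SD.
#'     Deterministic under a fixed `seed`.}
#'   \item{delta}{first-order error propagation for a product of
#'     independent factors: `sd = central * sqrt(sum((sd_i / mu_i)^2))`.}
#' }
#'
#' @param central Central population estimate (individuals).
#' @param params A `"taxon_parameters"` list carrying the SDs.
#' @param method `"monte_carlo"` (default) or `"delta"`.
#' @param n_draws Number of Monte-Carlo draws (>= 1000).
#' @param seed Optional integer seed for the Monte-Carlo draws.
#' @return Standard deviation of the state estimate (individuals).
#' @export
propagate_uncertainty <- function(central, params,
                                  method = c("monte_carlo", "delta"),
                                  n_draws = 10000, seed = NULL) {
  method <- match.arg(method)
  ms <- uncertainty_ms(params)
  mus <- c(params$Ma, params$Mp, ms[1])
  sds <- c(params$sd_Ma, params$sd_Mp, ms[2])
  sds[is.na(sds)] <- 0
  if (all(sds == 0)) return(0)
  if (method == "delta") {
    return(central * sqrt(sum((sds / mus)^2)))
  }
  if (n_draws < 1000) stop("n_draws must be >= 1000", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k0 <- prod(mus)
  kd <- rtrunc01(n_draws, mus[1], sds[1]) *
    rtrunc01(n_draws, mus[2], sds[2]) *
    rtrunc01(n_draws, mus[3], sds[3])
  sd(central * k0 / kd)
}

#' Range-wide minimum population estimates for all taxa
#'
#' Combines [extrapolate_state()] and [propagate_uncertainty()] over a
#' table of inputs, defaulting to the published national-assessment
#' inputs ([latvia_reference_inputs()]).
#'
#' @param inputs `data.frame` with columns `taxon`, `median_mafd`,
#'   `presence_fraction`, `range_area_km2`.
#' @param params_table Taxon parameter table (for the SDs).
#' @param method,n_draws,seed Passed to [propagate_uncertainty()].
#' @return `data.frame` with one row per taxon: inputs, `central`, `sd`,
#'   `method`.
#' @export
#' @examples
#' estimate_state(method = "delta")
estimate_state <- function(inputs = latvia_reference_inputs(),
                           params_table = default_taxon_parameters(),
                           method = c("monte_carlo", "delta"),
                           n_draws = 10000, seed = NULL) {
  method <- match.arg(method)
  central <- extrapolate_state(inputs$median_mafd, inputs$presence_fraction,
                               inputs$range_area_km2)
  sds <- vapply(seq_len(nrow(inputs)), function(i) {
    p <- taxon_params(inputs$taxon[i], params_table)
    propagate_uncertainty(central[i], p, method = method, n_draws = n_draws,
                          seed = if (is.null(seed)) NULL else seed + i)
  }, numeric(1))
  data.frame(inputs, central = central, sd = sds, method = method,
             stringsAsFactors = FALSE)
}
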