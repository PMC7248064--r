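#' Classify a lentic waterbody by surface area
#'
#' Waterbody size categories: small (< 0.5 ha), medium (0.5--10.0 ha),
#' large (> 10.0 ha). The published interval notation overlaps at the
#' boundaries; here the convention is \[0, 0.5) small, \[0.5, 10.0\]
#' medium, (10.0, Inf) large, i.e. both boundary areas are assigned to
#' medium. Ditches are a distinct input class and are never derived from
#' area.
#'
#' @param area_ha Numeric vector of surface areas in hectares; all > 0.
#' @return Character vector: `"small"`, `"medium"` or `"large"`.
#' @export
#' @examples
#' classify_waterbody(c(0.3, 0.5, 15))
classify_waterbody <- function(area_ha) {
  if (!is.numeric(area_ha) || any(!is.finite(area_ha)) || any(area_ha <= 0)) {
    stop("area_ha must be finite and > 0", call. = FALSE)
  }
  ifelse(area_ha < 0.5, "small", ifelse(area_ha <= 10, "medium", "large"))
}

#' Waterbody categories in increasing size order
#'
#' The three lentic size classes plus ditches (linear habitat, always
#' listed last).
#' @return `c("small", "medium", "large", "ditch")`
#' @export
waterbody_categories <- function() c("small", "medium", "large", "ditch")

#' Days since the onset of the calling season
#'
#' Transforms a calendar date into a relative date where 0 is the earliest
#' audial record of any anuran taxon in that year. Negative values (survey
#' before the post-hoc onset) are allowed and indicate pre-onset surveys.
#'
#' @param calendar_date,earliest_season_date `Date`s (or strings coercible
#'   via [as.Date()]); must fall in the same year, recycled to a common
#'   length.
#' @return Numeric vector of days since onset.
#' @export
#' @examples
#' relative_date("2017-05-27", "2017-04-07") # 50
relative_date <- function(calendar_date, earliest_season_date) {
  d <- as.Date(calendar_date)
  o <- as.Date(earliest_season_date)
  if (anyNA(d) || anyNA(o)) stop("unparseable date", call. = FALSE)
  n <- max(length(d), length(o))
  d <- rep_len(d, n); o <- rep_len(o, n)
  if (any(format(d, "%Y") != format(o, "%Y"))) {
    stop("calendar_date and earliest_season_date must be in the same year",
         call. = FALSE)
  }
  as.numeric(d - o)
}

#' Relative time of day between astronomic noon and sunset
#'
#' Linear map of the survey mid-time where 0 is astronomic noon and 1 is
#' sunset on the given date, compensating for day-length changes over the
#' season. Values below 0 (before noon) and above 1 (after sunset) are
#' permitted.
#'
#' @param mid_time Survey mid-time, decimal hours or `"HH:MM[:SS]"`.
#' @param noon_time Astronomic noon, same formats. Default 12.
#' @param sunset_time Sunset, same formats; must be after noon.
#' @return Numeric vector of unitless daytime positions.
#' @export
#' @examples
#' relative_daytime("17:00", "13:00", "21:00") # 0.5
relative_daytime <- function(mid_time, noon_time = 12, sunset_time) {
  m <- parse_time_hours(mid_time)
  no <- parse_time_hours(noon_time)
  su <- parse_time_hours(sunset_time)
  if (any(su <= no)) stop("sunset_time must be after noon_time", call. = FALSE)
  (m - no) / (su - no)
}

#' Parse a time of day into decimal hours
#'
#' @param x Numeric (returned as-is) or character `"HH:MM"` / `"HH:MM:SS"`.
#' @return Numeric decimal hours.
#' @export
#' @examples
#' parse_time_hours("17:30") # 17.5
parse_time_hours <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) < 2 || length(p) > 3 || anyNA(p)) {
      stop("cannot parse time; expected 'HH:MM[:SS]' or numeric hours",
           call. = FALSE)
    }
    p[1] + p[2] / 60 + if (length(p) == 3) p[3] / 3600 else 0
  }, numeric(1))
}
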