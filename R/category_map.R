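#' @title Category maps: predefined frequency and duration answers
#' @description The questionnaire offers predefined answer categories for how
#'   often (times per week) and how long (minutes per occasion) an activity is
#'   performed. A category map binds each label to a numeric midpoint so that
#'   answers resolve to mean daily hours. The published instrument does not
#'   print its full answer sets, so the map is user-configurable; the default
#'   below uses a fine, regular grid.
#' @name category-map
NULL

#' Construct a category map
#'
#' @param frequency named numeric vector: label -> occasions per week midpoint.
#' @param duration named numeric vector: label -> hours per occasion midpoint.
#' @return An `aq_category_map`.
#' @export
category_map <- function(frequency, duration) {
  for (v in list(frequency, duration)) {
    if (is.null(names(v)) || any(!nzchar(names(v)))) {
      stop("category map error: all midpoints must be labelled")
    }
    if (any(v <= 0)) stop("category map error: midpoints must be positive")
    if (anyDuplicated(names(v)) || anyDuplicated(v)) {
      stop("category map error: labels and midpoints must be unique (invertible)")
    }
  }
  structure(list(frequency = frequency, duration = duration),
            class = "aq_category_map")
}

#' Default category map
#'
#' Frequencies: "<1 time/week" (midpoint 0.5) and "1 time/week" ..
#' "28 times/week" (integer midpoints). Durations: "5 min" .. "720 min" in
#' 5-minute steps. "7 times/week" plus a duration therefore encodes an
#' every-day activity whose duration is hours per day.
#'
#' @return An `aq_category_map`.
#' @export
default_category_map <- function() {
  freq <- c(0.5, seq_len(28))
  names(freq) <- c("<1 time/week", "1 time/week",
                   paste0(2:28, " times/week"))
  mins <- seq(5, 720, by = 5)
  dur <- mins / 60
  names(dur) <- paste0(mins, " min")
  category_map(freq, dur)
}

#' Resolve a response item's categories to mean daily hours
#'
#' The weekly frequency midpoint times the per-occasion duration midpoint,
#' divided by 7, gives the average daily duration in hours.
#'
#' @param item list or one-row data.frame with `frequency_category` and
#'   `duration_category`.
#' @param map an `aq_category_map`.
#' @return Mean daily hours (h/d).
#' @examples
#' m <- default_category_map()
#' resolve_daily_hours(list(frequency_category = "7 times/week",
#'                          duration_category = "60 min"), m)  # 1.0
#' @export
resolve_daily_hours <- function(item, map) {
  stopifnot(inherits(map, "aq_category_map"))
  f <- map$frequency[[match_label(item$frequency_category, map$frequency,
                                  "frequency")]]
  d <- map$duration[[match_label(item$duration_category, map$duration,
                                 "duration")]]
  f * d / 7
}

# vectorised version used by the scorer
resolve_daily_hours_vec <- function(freq_labels, dur_labels, map) {
  fi <- match(freq_labels, names(map$frequency))
  di <- match(dur_labels, names(map$duration))
  if (anyNA(fi)) {
    stop("mapping error: unknown frequency label '",
         freq_labels[which(is.na(fi))[1]], "'")
  }
  if (anyNA(di)) {
    stop("mapping error: unknown duration label '",
         dur_labels[which(is.na(di))[1]], "'")
  }
  unname(map$frequency[fi] * map$duration[di] / 7)
}

match_label <- function(label, table, what) {
  i <- match(label, names(table))
  if (is.na(i)) stop("mapping error: unknown ", what, " label '", label, "'")
  i
}

#' Encode mean daily hours as the nearest category pair
#'
#' Inverse of [resolve_daily_hours()] up to category granularity: picks the
#' smallest frequency in {7, 14, 21, 28} occasions/week whose implied
#' per-occasion duration fits the duration grid, then rounds the duration to
#' the nearest grid point. Used by the synthetic-response generator.
#'
#' @param hours_per_day target mean daily hours.
#' @param map an `aq_category_map` (must contain the default-style grid).
#' @return list(frequency_category, duration_category, hours) where `hours`
#'   is the value the chosen pair resolves back to.
#' @export
encode_daily_hours <- function(hours_per_day, map = default_category_map()) {
  stopifnot(hours_per_day > 0)
  dur_max <- max(map$duration)
  for (f in c(7, 14, 21, 28)) {
    flab <- names(map$frequency)[match(f, map$frequency)]
    if (is.na(flab)) next
    per_occ <- hours_per_day * 7 / f
    if (per_occ <= dur_max + 1e-9) {
      di <- which.min(abs(map$duration - per_occ))
      return(list(frequency_category = flab,
                  duration_category = names(map$duration)[di],
                  hours = unname(f * map$duration[di] / 7)))
    }
  }
  stop("allocation error: ", round(hours_per_day, 2),
       " h/d exceeds the encodable range of the category map")
}
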