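#' @title Questionnaire responses: data model, validity flags, exclusions
#' @description A response is one participant's set of answers for one
#'   administration (I or II): an occupation effort rank plus free-entry
#'   occupation hours, and categorical frequency/duration items for
#'   transportation, leisure and sport activities.
#' @name questionnaire
NULL

#' Construct a participant profile
#'
#' @param participant_id identifier.
#' @param sex "female" or "male".
#' @param age_years adult age (>= 18).
#' @param weight_kg body weight, kg.
#' @param height_cm optional height, cm.
#' @return An `aq_profile` list.
#' @export
participant_profile <- function(participant_id, sex, age_years, weight_kg,
                                height_cm = NA_real_) {
  sex <- match.arg(sex, c("female", "male"))
  if (weight_kg <= 0) stop("profile error: weight_kg must be positive")
  if (age_years < 18) stop("profile error: adult questionnaire requires age >= 18")
  structure(list(participant_id = participant_id, sex = sex,
                 age_years = age_years, weight_kg = weight_kg,
                 height_cm = height_cm),
            class = "aq_profile")
}

#' Construct a questionnaire response
#'
#' @param participant_id identifier.
#' @param administration "I" or "II".
#' @param occupation_effort_rank integer 1..5 (overall occupational effort).
#' @param occupation_hours free-entry daily occupation hours.
#' @param items data.frame with columns `activity_id`, `frequency_category`,
#'   `duration_category` (zero rows allowed).
#' @return An `aq_response`.
#' @export
questionnaire_response <- function(participant_id, administration,
                                   occupation_effort_rank, occupation_hours,
                                   items = empty_items()) {
  administration <- match.arg(administration, c("I", "II"))
  if (occupation_hours < 0) stop("response error: negative occupation hours")
  if (!occupation_effort_rank %in% 1:5) {
    stop("response error: occupation_effort_rank must be in 1..5")
  }
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  need <- c("activity_id", "frequency_category", "duration_category")
  if (!all(need %in% names(items))) {
    stop("response error: items need columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(items$activity_id)) {
    stop("response error: duplicate activity_id in items: ",
         paste(unique(items$activity_id[duplicated(items$activity_id)]),
               collapse = ", "))
  }
  structure(list(participant_id = participant_id,
                 administration = administration,
                 occupation_effort_rank = as.integer(occupation_effort_rank),
                 occupation_hours = occupation_hours,
                 items = items[, need, drop = FALSE]),
            class = "aq_response")
}

empty_items <- function() {
  data.frame(activity_id = character(), frequency_category = character(),
             duration_category = character(), stringsAsFactors = FALSE)
}

#' Validity flags for a response
#'
#' Returns character flags, not errors: `INCOMPLETE_LEISURE` when the summed
#' leisure-domain mean daily hours fall below 1 h/d (the study's marker of an
#' incomplete first questionnaire), and `OVERFULL_DAY` when total reported
#' hours (occupation plus all items) exceed 24.
#'
#' @param resp an `aq_response`.
#' @param catalog an `aq_catalog` (for item domains).
#' @param map an `aq_category_map` (to resolve item hours).
#' @return Character vector of flags (possibly empty).
#' @export
validate_response <- function(resp, catalog = load_catalog(),
                              map = default_category_map()) {
  stopifnot(inherits(resp, "aq_response"))
  flags <- character()
  hours <- item_hours(resp, map)
  domains <- if (nrow(resp$items)) lookup_domain(catalog, resp$items$activity_id)
             else character()
  leisure <- sum(hours[domains == "leisure"])
  if (leisure < 1) flags <- c(flags, "INCOMPLETE_LEISURE")
  total <- resp$occupation_hours + sum(hours)
  if (total > 24) flags <- c(flags, "OVERFULL_DAY")
  flags
}

item_hours <- function(resp, map) {
  if (!nrow(resp$items)) return(numeric())
  resolve_daily_hours_vec(resp$items$frequency_category,
                          resp$items$duration_category, map)
}

#' Apply the study's participant exclusions
#'
#' Drops roster rows flagged for illness during data collection, an
#' incomplete first questionnaire, or unreliable DLW data. The flags are
#' explicit booleans: the underlying judgments are clinical and are not
#' re-derived here. Order is preserved.
#'
#' @param roster data.frame with logical columns `illness`,
#'   `incomplete_first_questionnaire`, `unreliable_dlw`.
#' @return The retained rows.
#' @export
apply_study_exclusions <- function(roster) {
  need <- c("illness", "incomplete_first_questionnaire", "unreliable_dlw")
  miss <- setdiff(need, names(roster))
  if (length(miss)) {
    stop("exclusion error: roster lacks flag column(s) ",
         paste(miss, collapse = ", "))
  }
  keep <- !(roster$illness | roster$incomplete_first_questionnaire |
              roster$unreliable_dlw)
  out <- roster[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write responses to a delimited table
#'
#' One row per item (participant_id, administration, activity_id,
#' frequency_category, duration_category) plus one row per response with
#' `activity_id = "occupation"`, whose frequency column carries the effort
#' rank and whose duration column carries the free-entry daily hours.
#'
#' @param responses list of `aq_response`.
#' @param path output path (tab-separated).
#' @export
write_responses <- function(responses, path) {
  rows <- lapply(responses, function(r) {
    occ <- data.frame(participant_id = r$participant_id,
                      administration = r$administration,
                      activity_id = "occupation",
                      frequency_category = as.character(r$occupation_effort_rank),
                      duration_category = format(r$occupation_hours, digits = 15),
                      stringsAsFactors = FALSE)
    if (nrow(r$items)) {
      it <- cbind(participant_id = r$participant_id,
                  administration = r$administration, r$items,
                  stringsAsFactors = FALSE)
      rbind(occ, it)
    } else occ
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read responses from a delimited table
#'
#' Inverse of [write_responses()].
#'
#' @param path file written by [write_responses()].
#' @return List of `aq_response`.
#' @export
read_responses <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  key <- paste(tab$participant_id, tab$administration, sep = "\r")
  lapply(split(seq_len(nrow(tab)), factor(key, levels = unique(key))),
         function(idx) {
           block <- tab[idx, , drop = FALSE]
           occ <- block[block$activity_id == "occupation", , drop = FALSE]
           if (nrow(occ) != 1L) {
             stop("parse error: response for participant ",
                  block$participant_id[1], " administration ",
                  block$administration[1], " needs exactly one occupation row")
           }
           items <- block[block$activity_id != "occupation",
                          c("activity_id", "frequency_category",
                            "duration_category"), drop = FALSE]
           rownames(items) <- NULL
           questionnaire_response(
             participant_id = occ$participant_id,
             administration = occ$administration,
             occupation_effort_rank = as.integer(occ$frequency_category),
             occupation_hours = as.numeric(occ$duration_category),
             items = items)
         }) |> unname()
}
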