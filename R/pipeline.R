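#' @title Study pipeline: end-to-end validation run
#' @description Orchestrates the full validation analysis: exclusions,
#'   scoring of both questionnaire administrations, DLW reference TEE,
#'   validity statistics (questionnaire vs DLW, crude and 24-h adjusted) and
#'   reproducibility statistics (administration I vs II).
#' @name pipeline
NULL

#' Run the full validation study
#'
#' @param profiles data.frame of participant profiles with exclusion-flag
#'   columns (`illness`, `incomplete_first_questionnaire`, `unreliable_dlw`).
#' @param responses_i,responses_ii lists of `aq_response` for administrations
#'   I and II.
#' @param series list of `aq_urine_series`.
#' @param catalog,map scoring configuration.
#' @param constants DLW constants.
#' @param sleep_met sleep MET for the 24-h adjustment.
#' @param ratings optional integer vector of overall grades 1..5.
#' @return An `aq_study_report`: summary table of crude/adjusted means and
#'   SDs per administration, DLW mean/SD, validity and reproducibility
#'   agreement reports, rating summary, and the exclusion log.
#' @export
run_study <- function(profiles, responses_i, responses_ii, series,
                      catalog = load_catalog(), map = default_category_map(),
                      constants = dlw_constants(), sleep_met = 0.9,
                      ratings = NULL) {
  retained <- apply_study_exclusions(profiles)
  excluded <- setdiff(profiles$participant_id, retained$participant_id)
  exclusion_log <- if (length(excluded)) {
    reasons <- vapply(excluded, function(id) {
      row <- profiles[profiles$participant_id == id, ]
      paste(c("illness", "incomplete_first_questionnaire",
              "unreliable_dlw")[c(row$illness,
                                  row$incomplete_first_questionnaire,
                                  row$unreliable_dlw)], collapse = "+")
    }, "")
    data.frame(participant_id = excluded, reason = reasons,
               stringsAsFactors = FALSE)
  } else {
    data.frame(participant_id = character(), reason = character())
  }
  ids <- retained$participant_id

  keep_resp <- function(responses) {
    r_ids <- vapply(responses, `[[`, "", "participant_id")
    orphans <- setdiff(r_ids, profiles$participant_id)
    if (length(orphans)) {
      stop("join error: responses for unknown participant(s) ",
           paste(orphans, collapse = ", "))
    }
    responses[r_ids %in% ids]
  }
  scored_i <- score_responses(keep_resp(responses_i), retained, catalog, map,
                              sleep_met = sleep_met)
  scored_ii <- score_responses(keep_resp(responses_ii), retained, catalog, map,
                               sleep_met = sleep_met)

  s_ids <- vapply(series, `[[`, "", "participant_id")
  orphans <- setdiff(s_ids, profiles$participant_id)
  if (length(orphans)) {
    stop("join error: urine series for unknown participant(s) ",
         paste(orphans, collapse = ", "))
  }
  dlw <- vapply(series[s_ids %in% ids], function(s) {
    dlw_tee(s, constants)$tee_kj_day
  }, 0)
  dlw_ids <- s_ids[s_ids %in% ids]

  align <- function(tab, col) tab[[col]][match(ids, tab$participant_id)]
  adj_i <- align(scored_i, "adjusted_total_kj")
  adj_ii <- align(scored_ii, "adjusted_total_kj")
  crude_i <- align(scored_i, "crude_total_kj")
  crude_ii <- align(scored_ii, "crude_total_kj")
  dlw_tee_v <- dlw[match(ids, dlw_ids)]

  validity_adjusted <- agreement_report(
    paired_measurements(ids, adj_i, dlw_tee_v))
  validity_crude <- agreement_report(
    paired_measurements(ids, crude_i, dlw_tee_v))
  reproducibility_adjusted <- agreement_report(
    paired_measurements(ids, adj_i, adj_ii))
  reproducibility_crude <- agreement_report(
    paired_measurements(ids, crude_i, crude_ii))

  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = stats::sd(x, na.rm = TRUE))
  dom_cols <- c("occupation_kj", "transportation_kj", "leisure_kj", "sport_kj")
  summary_tab <- rbind(
    data.frame(administration = "I",
               t(vapply(c(dom_cols, "crude_total_kj", "crude_hours",
                          "adjusted_total_kj"),
                        function(cn) msd(scored_i[[cn]]), c(mean = 0, sd = 0))),
               check.names = FALSE),
    data.frame(administration = "II",
               t(vapply(c(dom_cols, "crude_total_kj", "crude_hours",
                          "adjusted_total_kj"),
                        function(cn) msd(scored_ii[[cn]]), c(mean = 0, sd = 0))),
               check.names = FALSE))
  summary_tab <- cbind(quantity = rep(c(dom_cols, "crude_total_kj",
                                        "crude_hours", "adjusted_total_kj"), 2),
                       summary_tab)
  rownames(summary_tab) <- NULL

  structure(list(n = length(ids),
                 exclusion_log = exclusion_log,
                 scored_i = scored_i, scored_ii = scored_ii,
                 dlw = data.frame(participant_id = dlw_ids,
                                  tee_kj_day = dlw, stringsAsFactors = FALSE),
                 dlw_mean = mean(dlw_tee_v, na.rm = TRUE),
                 dlw_sd = stats::sd(dlw_tee_v, na.rm = TRUE),
                 summary = summary_tab,
                 validity_adjusted = validity_adjusted,
                 validity_crude = validity_crude,
                 reproducibility_adjusted = reproducibility_adjusted,
                 reproducibility_crude = reproducibility_crude,
                 ratings = if (is.null(ratings)) NULL
                           else summarize_ratings(ratings)),
            class = "aq_study_report")
}

#' Summarize overall questionnaire grades
#'
#' Grades run from 1 (worst) to 5 (best). The mean is rounded half-up to one
#' decimal, matching how such summary grades are conventionally reported.
#'
#' @param grades integer vector with values in 1..5.
#' @return list(counts, mean_grade).
#' @export
summarize_ratings <- function(grades) {
  if (!length(grades)) stop("domain error: no grades supplied")
  if (any(!grades %in% 1:5)) {
    stop("domain error: grades must be integers in 1..5")
  }
  counts <- vapply(1:5, function(g) sum(grades == g), 0L)
  names(counts) <- as.character(1:5)
  mean_grade <- floor(mean(grades) * 10 + 0.5) / 10  # round half-up
  list(counts = counts, mean_grade = mean_grade)
}

#' @export
print.aq_study_report <- function(x, ...) {
  cat("Validation study report\n")
  cat(sprintf("  Participants analysed: %d (%d excluded)\n", x$n,
              nrow(x$exclusion_log)))
  cat(sprintf("  DLW TEE: mean %.0f kJ (SD %.0f)\n", x$dlw_mean, x$dlw_sd))
  for (adm in c("I", "II")) {
    s <- x$summary[x$summary$administration == adm, ]
    crude <- s[s$quantity == "crude_total_kj", ]
    adj <- s[s$quantity == "adjusted_total_kj", ]
    cat(sprintf("  Administration %s: crude %.0f kJ (SD %.0f), adjusted %.0f kJ (SD %.0f)\n",
                adm, crude$mean, crude$sd, adj$mean, adj$sd))
  }
  cat("  Validity (adjusted vs DLW):\n")
  cat(sprintf("    Spearman r = %.2f, mean bias = %.0f kJ, LoA [%.0f, %.0f]\n",
              x$validity_adjusted$spearman_r, x$validity_adjusted$mean_diff,
              x$validity_adjusted$loa_low, x$validity_adjusted$loa_high))
  cat(sprintf("  Reproducibility (I vs II): ICC adjusted = %.2f, crude = %.2f\n",
              x$reproducibility_adjusted$icc, x$reproducibility_crude$icc))
  if (!is.null(x$ratings)) {
    cat(sprintf("  Mean overall grade: %.1f\n", x$ratings$mean_grade))
  }
  invisible(x)
}

#' Machine-readable flat view of a study report
#'
#' @param report an `aq_study_report`.
#' @return data.frame of (metric, value) rows.
#' @export
report_table <- function(report) {
  stopifnot(inherits(report, "aq_study_report"))
  rows <- list(
    c("n", report$n),
    c("dlw_mean_kj", report$dlw_mean),
    c("dlw_sd_kj", report$dlw_sd))
  for (i in seq_len(nrow(report$summary))) {
    s <- report$summary[i, ]
    rows <- c(rows, list(
      c(paste0(s$quantity, "_", s$administration, "_mean"), s$mean),
      c(paste0(s$quantity, "_", s$administration, "_sd"), s$sd)))
  }
  for (nm in c("validity_adjusted", "validity_crude",
               "reproducibility_adjusted", "reproducibility_crude")) {
    rep <- report[[nm]]
    rows <- c(rows, list(
      c(paste0(nm, "_spearman_r"), rep$spearman_r),
      c(paste0(nm, "_mean_diff"), rep$mean_diff),
      c(paste0(nm, "_loa_low"), rep$loa_low),
      c(paste0(nm, "_loa_high"), rep$loa_high),
      c(paste0(nm, "_icc"), rep$icc)))
  }
  data.frame(metric = vapply(rows, `[`, "", 1),
             value = as.numeric(vapply(rows, `[`, "", 2)),
             stringsAsFactors = FALSE)
}
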