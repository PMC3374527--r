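#' Published validation-study summary statistics
#'
#' The participant-level data of the original validation study were never
#' deposited; only summary statistics were printed. This function returns
#' those printed values as structured data. They serve two roles: as inputs
#' to the synthetic-cohort generator (domain energy shares, cohort
#' demographics, DLW mean and SD, bias) and as expected values for the
#' arithmetic-identity checks in the test suite.
#'
#' @return A list with elements:
#'   `n` (37), `female_fraction`, `age_band_counts`, `bmi_mean`, `bmi_sd`,
#'   `dlw_mean_kj`, `dlw_sd_kj`,
#'   `crude_domain_means` (4 x 2 matrix, administrations I and II),
#'   `crude_total_mean` (I and II), `adjusted_mean` (I and II),
#'   `adjusted_sd` (I and II), `bias_kj`, `spearman_adjusted`,
#'   `spearman_crude`, `icc_adjusted`, `icc_adjusted_ci`, `icc_crude`,
#'   `icc_crude_ci`, `grade_counts`, `mean_grade`, `crude_hours_mean`.
#' @export
activeq_reference <- function() {
  list(
    n = 37L,
    recruited = 40L,
    female_fraction = 30 / 37,
    age_band_counts = c("20-29" = 22L, "30-39" = 5L, "40-49" = 5L,
                        "50-59" = 4L, "60-65" = 1L),
    bmi_mean = 23.0, bmi_sd = 3.8,
    dlw_mean_kj = 11229, dlw_sd_kj = 2256,
    crude_domain_means = matrix(
      c(2971, 434, 2243, 1360,
        3005, 365, 2254, 815),
      nrow = 4, dimnames = list(
        c("occupation", "transportation", "leisure", "sport"),
        c("I", "II"))),
    crude_total_mean = c(I = 7008, II = 6439),
    crude_total_sd = c(I = 3854, II = 2614),
    adjusted_mean = c(I = 11667, II = 11529),
    adjusted_sd = c(I = 3212, II = 2758),
    bias_kj = 440,
    spearman_adjusted = 0.52, spearman_crude = 0.42,
    icc_adjusted = 0.83, icc_adjusted_ci = c(0.73, 0.93),
    icc_crude = 0.66, icc_crude_ci = c(0.47, 0.84),
    grade_counts = c("1" = 0L, "2" = 2L, "3" = 7L, "4" = 21L, "5" = 7L),
    mean_grade = 3.9,
    crude_hours_mean = 11.4
  )
}
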