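# Shared fixtures and independent oracles.

CAT <- load_catalog()
MAP <- default_category_map()

make_profile <- function(id = "P1", weight = 70, sex = "female", age = 30) {
  participant_profile(id, sex, age, weight)
}

item_row <- function(activity_id, freq = "7 times/week", dur = "60 min") {
  data.frame(activity_id = activity_id, frequency_category = freq,
             duration_category = dur, stringsAsFactors = FALSE)
}

make_response <- function(id = "P1", administration = "I", rank = 2,
                          occ_hours = 8, items = NULL) {
  questionnaire_response(id, administration, rank, occ_hours,
                         items = if (is.null(items)) empty_items_df() else items)
}

empty_items_df <- function() {
  data.frame(activity_id = character(), frequency_category = character(),
             duration_category = character(), stringsAsFactors = FALSE)
}

# random response built from catalog activities and the default answer grid
random_response <- function(id, n_items = 4, admin = "I") {
  ids <- sample(CAT$entries$activity_id, n_items)
  items <- do.call(rbind, lapply(ids, function(a) {
    item_row(a,
             freq = sample(c("1 time/week", "3 times/week", "7 times/week"), 1),
             dur = sample(c("15 min", "30 min", "60 min", "120 min"), 1))
  }))
  make_response(id, admin, rank = sample(1:5, 1),
                occ_hours = stats::runif(1, 0, 9), items = items)
}

# --- independent oracles -------------------------------------------------

# Spearman via base R ranks and explicit Pearson formula
oracle_spearman <- function(a, b) {
  ra <- rank(a)  # ties.method = "average" is the midrank convention
  rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# one-way ICC from an explicit ANOVA table (sums of squares written out)
oracle_icc_oneway <- function(a, b) {
  x <- cbind(a, b)
  n <- nrow(x); k <- 2
  grand <- mean(x)
  ss_total <- sum((x - grand)^2)
  ss_between <- sum(k * (rowMeans(x) - grand)^2)
  ss_within <- ss_total - ss_between
  msb <- ss_between / (n - 1)
  msw <- ss_within / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}
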