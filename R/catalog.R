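#' @title Activity catalog: MET compendium and lookups
#' @description Functions to load and query the catalog of questionnaire
#'   activities. Each catalog entry binds a stable `activity_id` to a domain
#'   (occupation, transportation, leisure, sport) and a MET value
#'   (kcal per kg per hour). The five-level occupation effort scale is part of
#'   the catalog: occupation is reported as an overall effort rank 1..5 rather
#'   than per-activity items.
#' @name activity-catalog
NULL

AQ_DOMAINS <- c("occupation", "transportation", "leisure", "sport")

#' Load an activity catalog from a delimited text file
#'
#' The catalog file is tab-separated with columns `activity_id`, `label`,
#' `domain`, `met`. Rows with domain `occupation` define the 5-level effort
#' scale (ids `occupation_rank_1` .. `occupation_rank_5`); all other rows are
#' screening-question activities. The default file shipped with the package
#' holds the questionnaire's published MET compendium.
#'
#' @param source path to a catalog file; default is the built-in catalog.
#' @return An object of class `aq_catalog`: a list with `entries`
#'   (data.frame of non-occupation activities) and `occupation_scale`
#'   (named numeric vector, MET for effort ranks 1..5).
#' @examples
#' cat <- load_catalog()
#' lookup_met(cat, "martial_arts")
#' @export
load_catalog <- function(source = default_catalog_path()) {
  raw <- utils::read.delim(source, stringsAsFactors = FALSE,
                           colClasses = c("character", "character",
                                          "character", "numeric"))
  need <- c("activity_id", "label", "domain", "met")
  if (!all(need %in% names(raw))) {
    stop("catalog parse error: missing column(s) ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  bad <- raw$activity_id[is.na(raw$met) | !nzchar(raw$label) |
                           !nzchar(raw$domain)]
  if (length(bad)) {
    stop("catalog parse error: malformed entry: ",
         paste(bad, collapse = ", "))
  }
  as_catalog(raw)
}

#' Build a catalog from a data frame
#'
#' Validates invariants: positive MET values, known domains, unique ids, and
#' an occupation scale with exactly five strictly increasing MET values.
#'
#' @param df data.frame with columns activity_id, label, domain, met.
#' @return `aq_catalog` object.
#' @export
as_catalog <- function(df) {
  if (any(duplicated(df$activity_id))) {
    stop("catalog validation error: duplicate activity_id: ",
         paste(unique(df$activity_id[duplicated(df$activity_id)]),
               collapse = ", "))
  }
  if (any(df$met <= 0)) {
    stop("catalog validation error: non-positive MET for: ",
         paste(df$activity_id[df$met <= 0], collapse = ", "))
  }
  if (!all(df$domain %in% AQ_DOMAINS)) {
    stop("catalog validation error: unknown domain: ",
         paste(unique(setdiff(df$domain, AQ_DOMAINS)), collapse = ", "))
  }
  occ <- df[df$domain == "occupation", , drop = FALSE]
  if (nrow(occ) != 5L) {
    stop("catalog validation error: occupation scale must have 5 entries, got ",
         nrow(occ))
  }
  ranks <- suppressWarnings(as.integer(sub("^occupation_rank_", "",
                                           occ$activity_id)))
  if (any(is.na(ranks)) || !setequal(ranks, 1:5)) {
    stop("catalog validation error: occupation ids must be occupation_rank_1..5")
  }
  scale <- occ$met[order(ranks)]
  if (any(diff(scale) <= 0)) {
    stop("catalog validation error: occupation scale METs must be strictly increasing")
  }
  names(scale) <- as.character(1:5)
  entries <- df[df$domain != "occupation", , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, occupation_scale = scale),
            class = "aq_catalog")
}

#' Path to the built-in catalog file
#' @return Path of the packaged catalog TSV.
#' @export
default_catalog_path <- function() {
  system.file("extdata", "activeq_catalog.tsv", package = "activeq",
              mustWork = TRUE)
}

#' Write a catalog back to its delimited text form
#'
#' Inverse of [load_catalog()]; round-trips exactly.
#'
#' @param catalog an `aq_catalog`.
#' @param path output file path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "aq_catalog"))
  occ_labels <- attr(catalog, "occupation_labels")
  if (is.null(occ_labels)) {
    occ_labels <- c("Mostly sitting", "A combination of sitting and standing up",
                    "Mostly standing up", "Some physical activity",
                    "Heavy manual labor")
  }
  occ <- data.frame(activity_id = paste0("occupation_rank_", 1:5),
                    label = occ_labels, domain = "occupation",
                    met = unname(catalog$occupation_scale),
                    stringsAsFactors = FALSE)
  out <- rbind(occ, catalog$entries)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up the MET value of an activity
#'
#' @param catalog an `aq_catalog`.
#' @param activity_id activity identifier (see the `entries` table).
#' @return MET value (kcal kg^-1 h^-1).
#' @examples
#' lookup_met(load_catalog(), "jogging_running")  # 8.0
#' @export
lookup_met <- function(catalog, activity_id) {
  stopifnot(inherits(catalog, "aq_catalog"))
  i <- match(activity_id, catalog$entries$activity_id)
  if (anyNA(i)) {
    stop("lookup error: unknown activity_id '",
         paste(activity_id[is.na(i)], collapse = "', '"),
         "'; known ids: ",
         paste(catalog$entries$activity_id, collapse = ", "))
  }
  catalog$entries$met[i]
}

#' Look up the domain of an activity
#' @inheritParams lookup_met
#' @return Domain string for each id.
#' @export
lookup_domain <- function(catalog, activity_id) {
  stopifnot(inherits(catalog, "aq_catalog"))
  i <- match(activity_id, catalog$entries$activity_id)
  if (anyNA(i)) {
    stop("lookup error: unknown activity_id '",
         paste(activity_id[is.na(i)], collapse = "', '"), "'")
  }
  catalog$entries$domain[i]
}

#' MET value for an occupation effort rank
#'
#' Occupation is reported as an overall effort rank on a 1..5 scale; each rank
#' maps to a MET value from mostly sitting (1.5) to heavy manual labor (6.0).
#'
#' @param catalog an `aq_catalog`.
#' @param effort_rank integer in 1..5.
#' @return MET value.
#' @examples
#' occupation_met(load_catalog(), 1)  # 1.5
#' @export
occupation_met <- function(catalog, effort_rank) {
  stopifnot(inherits(catalog, "aq_catalog"))
  if (any(effort_rank != as.integer(effort_rank)) ||
      any(effort_rank < 1L) || any(effort_rank > 5L)) {
    stop("range error: effort_rank must be an integer in 1..5, got ",
         paste(effort_rank, collapse = ", "))
  }
  unname(catalog$occupation_scale[as.character(as.integer(effort_rank))])
}

#' @export
print.aq_catalog <- function(x, ...) {
  cat("Activity catalog:", nrow(x$entries), "activities +",
      length(x$occupation_scale), "occupation effort ranks\n")
  tab <- table(x$entries$domain)
  for (d in names(tab)) cat("  ", d, ": ", tab[[d]], "\n", sep = "")
  invisible(x)
}
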