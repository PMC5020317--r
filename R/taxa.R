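#' Load a species-to-group mapping
#'
#' Reads a CSV with columns `scientificName`, `informalGroup`, `higherGroup`
#' mapping each species to its informal recording-community group and the
#' higher group that contains it. Duplicate species entries are a load-time
#' error; each informal group must map to exactly one higher group.
#'
#' @param path CSV path. The informal-to-higher nesting used by the shipped
#'   reference tables (see [volcontrib_extdata()]) covers ten widely
#'   recorded informal groups plus "other".
#' @return A tibble of class `group_mapping`.
#' @export
load_group_mapping <- function(path) {
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                         check.names = FALSE))
  need <- c("scientificName", "informalGroup", "higherGroup")
  if (!all(need %in% names(m))) {
    stop("mapping needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  m$scientificName <- .norm_species(m$scientificName)
  if (anyDuplicated(m$scientificName)) {
    stop("duplicate species in mapping: '",
         m$scientificName[duplicated(m$scientificName)][1], "'",
         call. = FALSE)
  }
  nested <- unique(m[c("informalGroup", "higherGroup")])
  if (anyDuplicated(nested$informalGroup)) {
    stop("informal group mapped to more than one higher group",
         call. = FALSE)
  }
  class(m) <- c("group_mapping", class(m))
  m
}

.norm_species <- function(x) tolower(trimws(as.character(x)))

#' Attach taxonomic group labels to records
#'
#' Joins a species-to-group mapping onto cleaned records; matching is exact
#' on the trimmed, case-folded scientific name (no synonym resolution).
#' Unmapped species fall into the `"other"` / `"others"` catch-all and are
#' flagged.
#'
#' @param records Cleaned records.
#' @param mapping A [load_group_mapping()] table.
#' @return `records` with `informal_group`, `higher_group` and `unmapped`
#'   columns added.
#' @export
assign_groups <- function(records, mapping) {
  key <- .norm_species(records$scientific_name)
  idx <- match(key, mapping$scientificName)
  records$informal_group <- ifelse(is.na(idx), "other",
                                   mapping$informalGroup[idx])
  records$higher_group <- ifelse(is.na(idx), "others",
                                 mapping$higherGroup[idx])
  records$unmapped <- is.na(idx)
  records
}

#' Taxonomic composition percentages
#'
#' Percentage of records per group. At level `"higher"` all records are
#' shared among the higher groups; at `"informal_within_invertebrates"` the
#' denominators are invertebrate records only, split by informal group —
#' the usual way invertebrate recording is summarised.
#'
#' @param records Group-labelled records.
#' @param level `"higher"` or `"informal_within_invertebrates"`.
#' @return A tibble: `group`, `n_records`, `percent` (sums to 100 before
#'   rounding).
#' @export
composition <- function(records,
                        level = c("higher", "informal_within_invertebrates")) {
  level <- match.arg(level)
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  if (level == "higher") {
    df <- records |>
      dplyr::count(group = .data$higher_group, name = "n_records")
  } else {
    inv <- records[records$higher_group == "invertebrates", ]
    if (nrow(inv) == 0) stop("no invertebrate records", call. = FALSE)
    df <- inv |>
      dplyr::count(group = .data$informal_group, name = "n_records")
  }
  df |>
    dplyr::mutate(percent = 100 * .data$n_records / sum(.data$n_records)) |>
    dplyr::arrange(dplyr::desc(.data$n_records))
}

#' Per-group recording statistics with checklist coverage
#'
#' For each informal group: distinct recorders, records, mean records per
#' recorder, distinct species recorded, and — where the group appears in the
#' supplied national checklist — the percentage of the checklist covered.
#'
#' @param records Group-labelled records.
#' @param checklist Data frame with `informalGroup` and
#'   `britishSpeciesTotal` columns (see
#'   `system.file("extdata", "british_list.csv", package = "volcontrib")`
#'   for the shipped reference totals).
#' @return A tibble: `group`, `n_recorders`, `n_records`,
#'   `records_per_recorder`, `n_species_recorded`, `checklist_total`,
#'   `coverage_pct` (rounded percent, `NA` when the group is unlisted).
#' @export
group_stats <- function(records, checklist = NULL) {
  stats_tbl <- records |>
    dplyr::group_by(group = .data$informal_group) |>
    dplyr::summarise(
      n_recorders = dplyr::n_distinct(.data$recorder_id),
      n_records = dplyr::n(),
      n_species_recorded = dplyr::n_distinct(.norm_species(.data$scientific_name)),
      .groups = "drop"
    ) |>
    dplyr::mutate(records_per_recorder = .data$n_records / .data$n_recorders)
  if (!is.null(checklist)) {
    stopifnot(all(c("informalGroup", "britishSpeciesTotal") %in%
                    names(checklist)))
    if (any(checklist$britishSpeciesTotal <= 0)) {
      stop("checklist totals must be positive", call. = FALSE)
    }
    idx <- match(stats_tbl$group, checklist$informalGroup)
    stats_tbl$checklist_total <- checklist$britishSpeciesTotal[idx]
    stats_tbl$coverage_pct <- round(
      100 * stats_tbl$n_species_recorded / stats_tbl$checklist_total)
  } else {
    stats_tbl$checklist_total <- NA_real_
    stats_tbl$coverage_pct <- NA_real_
  }
  dplyr::arrange(stats_tbl, dplyr::desc(.data$n_records))
}

#' Shipped reference tables
#'
#' Paths to the small CSVs installed with the package: the informal-to-higher
#' group lookup and representative British-checklist species totals for the
#' ten most widely recorded informal groups.
#'
#' @param which `"informal_groups"` or `"british_list"`.
#' @return A file path.
#' @export
volcontrib_extdata <- function(which = c("informal_groups", "british_list")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, ".csv"), package = "volcontrib",
              mustWork = TRUE)
}
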