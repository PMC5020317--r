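#' Per-cell recording statistics
#'
#' Aggregates cleaned records to occupied 1-km cells, counting records,
#' distinct recorders, distinct informal taxonomic groups, and volunteer
#' productivity (records per recorder). Cells nobody recorded in are absent;
#' correlation routines decide how to treat them (see [cross_correlation()]).
#'
#' @param records Cleaned records; every row must be located to 1 km or
#'   better (coarser rows should have been filtered during ingestion).
#' @return A tibble: `monad`, `n_records`, `n_volunteers`,
#'   `n_informal_groups`, `productivity`.
#' @export
aggregate_cells <- function(records) {
  stopifnot(all(c("monad", "recorder_id", "precision_m") %in% names(records)))
  if (any(records$precision_m > 1000)) {
    stop("records coarser than 1 km present: filter before aggregating",
         call. = FALSE)
  }
  has_group <- "informal_group" %in% names(records)
  records |>
    dplyr::group_by(.data$monad) |>
    dplyr::summarise(
      n_records = dplyr::n(),
      n_volunteers = dplyr::n_distinct(.data$recorder_id),
      n_informal_groups = if (has_group) {
        dplyr::n_distinct(.data$informal_group)
      } else NA_integer_,
      .groups = "drop"
    ) |>
    dplyr::mutate(productivity = .data$n_records / .data$n_volunteers)
}

#' Rank correlation of a cell metric between two datasets
#'
#' Spearman rank correlation of one per-cell metric between two [aggregate_cells()]
#' tables. Under the default `"union"` pairing the cell set is the union of
#' cells occupied by either dataset, with absence counted as 0 effort; under
#' `"intersection"` only cells occupied by both are compared. The pair count
#' `n` is reported so the pairing choice is auditable.
#'
#' @param a,b Cell-statistics tables.
#' @param metric Column to correlate (default `"productivity"`).
#' @param pairing `"union"` or `"intersection"`.
#' @return A list: `rho`, `n` (paired cells), `p`.
#' @export
cross_correlation <- function(a, b, metric = "productivity",
                              pairing = c("union", "intersection")) {
  pairing <- match.arg(pairing)
  stopifnot(metric %in% names(a), metric %in% names(b))
  aa <- a[c("monad", metric)]
  bb <- b[c("monad", metric)]
  names(aa)[2] <- "va"
  names(bb)[2] <- "vb"
  j <- if (pairing == "union") {
    out <- dplyr::full_join(aa, bb, by = "monad")
    out$va[is.na(out$va)] <- 0
    out$vb[is.na(out$vb)] <- 0
    out
  } else {
    dplyr::inner_join(aa, bb, by = "monad")
  }
  if (nrow(j) < 3) stop("fewer than 3 paired cells", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(j$va, j$vb, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), n = nrow(j), p = ct$p.value)
}

#' Recording-effort hotspots
#'
#' The `top_n` cells by one metric, in descending order with deterministic
#' tie-breaking (value descending, then monad id ascending). A user-supplied
#' cell-attribute table (e.g. a bluespace flag) can be joined on.
#'
#' @param cells An [aggregate_cells()] table (or any per-monad table).
#' @param metric Ranking column (default `"n_records"`).
#' @param top_n Number of cells (default 10).
#' @param attributes Optional data frame keyed by `monad` to join onto the
#'   ranking.
#' @return A tibble: `rank`, `monad`, the metric column, plus any joined
#'   attributes.
#' @export
hotspots <- function(cells, metric = "n_records", top_n = 10,
                     attributes = NULL) {
  if (top_n <= 0) stop("top_n must be positive", call. = FALSE)
  stopifnot(metric %in% names(cells))
  ord <- order(-cells[[metric]], cells$monad)
  out <- cells[utils::head(ord, top_n), c("monad", metric)]
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1)
  if (!is.null(attributes)) {
    out <- dplyr::left_join(out, attributes, by = "monad")
  }
  out
}

#' Per-cell record counts for one informal taxonomic group
#'
#' @param records Cleaned, group-labelled records.
#' @param group An informal group from the configured mapping.
#' @param groups The set of known informal groups; defaults to those present
#'   in the records. A mapped group with no records yields an empty surface;
#'   a group outside the mapping is an error.
#' @return An [aggregate_cells()] table restricted to the group's records
#'   (zero rows if the group has no records).
#' @export
taxon_surface <- function(records, group,
                          groups = unique(records$informal_group)) {
  stopifnot("informal_group" %in% names(records))
  if (!group %in% groups) {
    stop("unknown informal group: '", group, "'", call. = FALSE)
  }
  aggregate_cells(records[records$informal_group == group, ])
}

#' Write cell statistics as GeoJSON squares
#'
#' Emits each occupied monad as a 1-km square polygon in OSGB (EPSG:27700)
#' plane coordinates with the cell metrics as feature properties, for use in
#' any GIS. This replaces cartographic map output.
#'
#' @param cells An [aggregate_cells()] table.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
cells_geojson <- function(cells, path) {
  sw <- monad_coords(cells$monad)
  features <- lapply(seq_len(nrow(cells)), function(i) {
    e <- sw$easting[i]
    n <- sw$northing[i]
    ring <- list(c(e, n), c(e + 1000, n), c(e + 1000, n + 1000),
                 c(e, n + 1000), c(e, n))
    props <- as.list(cells[i, setdiff(names(cells), character(0))])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "urn:ogc:def:crs:EPSG::27700")),
             features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
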