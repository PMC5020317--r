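#' Ingestion policy for raw occurrence tables
#'
#' Bundles the knobs applied while cleaning raw records: the maximum admitted
#' coordinate precision, whether recorder-name synonyms are collapsed to
#' surname + first initial, the keywords that mark a collective (group)
#' identity, and whether anonymous/group records are dropped outright or
#' merely flagged. The default keeps anonymous and group records in the
#' cleaned table (flagged) because spatial and taxonomic summaries use them;
#' engagement profiling excludes them downstream.
#'
#' @param max_precision_m Coarsest admitted precision in metres (default 1000,
#'   i.e. records must be located to 1 km or better).
#' @param collapse_synonyms Collapse recorder names to a canonical
#'   surname + initial token? Default `FALSE`: synthetic and scheme data carry
#'   stable IDs; turn on for real-world name lists where "A. Person" and
#'   "Albert Person" denote one recorder.
#' @param group_keywords Lower-case substrings marking collective recorder
#'   identities.
#' @param drop_anonymous,drop_group Remove (rather than flag) anonymous/group
#'   records during cleaning.
#' @return A list of class `record_policy`.
#' @export
record_policy <- function(max_precision_m = 1000,
                          collapse_synonyms = FALSE,
                          group_keywords = c("group", "society", "team",
                                             "club", "survey"),
                          drop_anonymous = FALSE,
                          drop_group = FALSE) {
  stopifnot(max_precision_m > 0)
  structure(list(max_precision_m = max_precision_m,
                 collapse_synonyms = collapse_synonyms,
                 group_keywords = tolower(group_keywords),
                 drop_anonymous = drop_anonymous,
                 drop_group = drop_group),
            class = "record_policy")
}

#' Classify and canonicalise a recorder name
#'
#' @param name Character vector of free-text recorder names.
#' @param policy A [record_policy()].
#' @return A tibble with `recorder_id`, `is_group`, `is_anonymous`.
#'
#' @details With `collapse_synonyms = TRUE` the canonical id is the lower-case
#'   surname (last whitespace-separated token after stripping punctuation)
#'   joined to the first initial, so "A. Person" and "Albert Person" both
#'   yield `"person_a"`. Two genuinely distinct people sharing surname and
#'   initial collide under this policy; that ambiguity is inherent to
#'   name-keyed recording and is accepted as a documented limitation. Names
#'   containing a group keyword are flagged `is_group`; empty names and
#'   "anon"/"anonymous"/"unknown" are flagged `is_anonymous`.
#' @export
normalize_recorder_id <- function(name, policy = record_policy()) {
  stopifnot(inherits(policy, "record_policy"))
  name <- ifelse(is.na(name), "", trimws(name))
  low <- tolower(name)
  is_anon <- low == "" | low %in% c("anon", "anon.", "anonymous", "unknown")
  kw <- paste0("\\b(", paste(policy$group_keywords, collapse = "|"), ")\\b")
  is_group <- !is_anon & grepl(kw, low)
  id <- character(length(name))
  for (i in seq_along(name)) {
    if (is_anon[i]) {
      id[i] <- NA_character_
    } else if (!policy$collapse_synonyms || is_group[i]) {
      id[i] <- gsub("[[:space:]]+", " ", low[i])
    } else {
      stripped <- gsub("[[:punct:]]", " ", low[i])
      toks <- strsplit(trimws(stripped), "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) == 0) {
        id[i] <- NA_character_
        is_anon[i] <- TRUE
      } else if (length(toks) == 1) {
        id[i] <- toks
      } else {
        id[i] <- paste0(toks[length(toks)], "_", substr(toks[1], 1, 1))
      }
    }
  }
  tibble::tibble(recorder_id = id, is_group = is_group,
                 is_anonymous = is_anon)
}

.parse_exact_date <- function(x) {
  x <- trimws(as.character(x))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d <- rep(as.Date(NA), length(x))
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  d
}

#' Clean and validate raw occurrence records
#'
#' Applies, in order: exact-date filter (records not resolvable to a single
#' calendar day are rejected), precision filter (grid reference or stated
#' coordinate uncertainty coarser than `policy$max_precision_m`), then the
#' anonymous and group-recorder rules. The ordering makes the audit categories
#' disjoint, so the counts always reconcile exactly with the row totals.
#'
#' @param raw A data frame with columns `recordedBy`, `eventDate`,
#'   `gridReference`, `scientificName`, `datasetID` (Darwin-Core-flavoured).
#'   Alternatively `easting`, `northing` and `coordinateUncertaintyInMeters`
#'   may replace `gridReference`.
#' @param policy A [record_policy()].
#' @return A list with `records` (tibble of clean records: `recorder_id`,
#'   `is_group`, `is_anonymous`, `date`, `easting`, `northing`,
#'   `precision_m`, `monad`, `scientific_name`, `dataset_id`) and `audit`
#'   (a `filter_audit` with the rejection counts).
#' @export
clean_records <- function(raw, policy = record_policy()) {
  stopifnot(is.data.frame(raw), inherits(policy, "record_policy"))
  need <- c("recordedBy", "eventDate", "scientificName", "datasetID")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("raw table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_input <- nrow(raw)
  date <- .parse_exact_date(raw$eventDate)
  if ("gridReference" %in% names(raw)) {
    gr <- trimws(as.character(raw$gridReference))
    # parse each distinct reference once; unparseable -> NA (counted below)
    ugr <- unique(gr)
    up <- vapply(ugr, function(g) {
      p <- tryCatch(parse_gridref(g), error = function(e) NULL)
      if (is.null(p)) c(NA_real_, NA_real_, NA_real_) else {
        c(p$easting, p$northing, p$precision_m)
      }
    }, numeric(3))
    idx <- match(gr, ugr)
    east <- up[1, idx]
    north <- up[2, idx]
    prec <- up[3, idx]
  } else if (all(c("easting", "northing",
                   "coordinateUncertaintyInMeters") %in% names(raw))) {
    east <- as.numeric(raw$easting)
    north <- as.numeric(raw$northing)
    prec <- as.numeric(raw$coordinateUncertaintyInMeters)
  } else {
    stop("raw table needs either a gridReference column or ",
         "easting/northing/coordinateUncertaintyInMeters", call. = FALSE)
  }
  who <- normalize_recorder_id(raw$recordedBy, policy)

  rej_date <- is.na(date)
  rej_prec <- !rej_date &
    (is.na(prec) | prec > policy$max_precision_m |
       is.na(east) | is.na(north))
  rej_anon <- !rej_date & !rej_prec & policy$drop_anonymous & who$is_anonymous
  rej_group <- !rej_date & !rej_prec & !rej_anon &
    policy$drop_group & who$is_group
  keep <- !(rej_date | rej_prec | rej_anon | rej_group)

  records <- tibble::tibble(
    recorder_id = who$recorder_id[keep],
    is_group = who$is_group[keep],
    is_anonymous = who$is_anonymous[keep],
    date = date[keep],
    easting = east[keep],
    northing = north[keep],
    precision_m = prec[keep],
    monad = monad_of(east[keep], north[keep]),
    scientific_name = trimws(as.character(raw$scientificName))[keep],
    dataset_id = as.character(raw$datasetID)[keep]
  )
  audit <- structure(list(
    n_input = n_input,
    n_rejected_date = sum(rej_date),
    n_rejected_precision = sum(rej_prec),
    n_rejected_anonymous = sum(rej_anon),
    n_rejected_group = sum(rej_group),
    n_output = sum(keep)
  ), class = "filter_audit")
  list(records = records, audit = audit)
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Record filter audit\n")
  cat(sprintf("  input:               %d\n", x$n_input))
  cat(sprintf("  rejected (date):     %d\n", x$n_rejected_date))
  cat(sprintf("  rejected (precision):%d\n", x$n_rejected_precision))
  cat(sprintf("  rejected (anonymous):%d\n", x$n_rejected_anonymous))
  cat(sprintf("  rejected (group):    %d\n", x$n_rejected_group))
  cat(sprintf("  output:              %d\n", x$n_output))
  invisible(x)
}

#' Subset cleaned records for engagement profiling
#'
#' Engagement metrics describe individual contributors, so records from
#' collective identities and anonymous submissions are excluded here even
#' when the cleaning policy retained them for spatial/taxonomic use.
#'
#' @param records Cleaned records from [clean_records()].
#' @return The individual-recorder subset.
#' @export
engagement_records <- function(records) {
  dplyr::filter(records, !.data$is_group, !.data$is_anonymous)
}

#' Read a raw occurrence CSV
#'
#' @param path Path to a UTF-8 CSV with the Darwin-Core-flavoured header
#'   accepted by [clean_records()].
#' @return A tibble of raw records.
#' @export
read_records <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}
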