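#' Study window
#'
#' The observation period over which relative activity duration is measured.
#' Both endpoints are inclusive, so a one-day window has length 1.
#'
#' @param start,end `Date` (or coercible) endpoints.
#' @return A list of class `study_window` with `start`, `end`, `length_days`.
#' @export
study_window <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  len <- as.numeric(end - start) + 1
  if (is.na(len) || len < 1) stop("window end precedes start", call. = FALSE)
  structure(list(start = start, end = end, length_days = len),
            class = "study_window")
}

#' Per-volunteer activity histories
#'
#' A volunteer counts as active on a day if they made at least one record
#' that day. Returns one row per recorder with their deduplicated active-day
#' count, first/last active day, and total record count.
#'
#' @param records Cleaned records restricted to individual recorders
#'   (see [engagement_records()]).
#' @return A tibble: `recorder_id`, `n_observations`, `n_active_days`,
#'   `first_day`, `last_day`, `linked_days` (first-to-last inclusive).
#' @export
build_histories <- function(records) {
  stopifnot(all(c("recorder_id", "date") %in% names(records)))
  if (nrow(records) == 0) {
    return(tibble::tibble(recorder_id = character(),
                          n_observations = integer(),
                          n_active_days = integer(),
                          first_day = as.Date(character()),
                          last_day = as.Date(character()),
                          linked_days = numeric()))
  }
  records |>
    dplyr::group_by(.data$recorder_id) |>
    dplyr::summarise(
      n_observations = dplyr::n(),
      n_active_days = dplyr::n_distinct(.data$date),
      first_day = min(.data$date),
      last_day = max(.data$date),
      .groups = "drop"
    ) |>
    dplyr::mutate(linked_days =
                    as.numeric(.data$last_day - .data$first_day) + 1)
}

#' Activity ratio
#'
#' Active days divided by the days linked to the dataset (first to last
#' active day, inclusive). A volunteer active on a single day has ratio 1.
#'
#' @param histories Output of [build_histories()].
#' @return Numeric vector in (0, 1\].
#' @export
activity_ratio <- function(histories) {
  histories$n_active_days / histories$linked_days
}

#' Relative activity duration
#'
#' Active days divided by the length of the whole study window.
#'
#' @param histories Output of [build_histories()].
#' @param window A [study_window()] containing every active day.
#' @return Numeric vector in (0, 1\].
#' @export
relative_activity_duration <- function(histories, window) {
  stopifnot(inherits(window, "study_window"))
  if (any(histories$first_day < window$start) ||
      any(histories$last_day > window$end)) {
    stop("active days fall outside the study window", call. = FALSE)
  }
  histories$n_active_days / window$length_days
}

#' Variation in periodicity
#'
#' Each volunteer's mean gap (days) between sequential active days, divided
#' by the cohort average of those individual mean gaps. Volunteers active on
#' fewer than two days have no observed gap and are assigned 0 (and excluded
#' from the cohort average), so that every volunteer — including the large
#' single-day contingent typical of recording schemes — carries a finite
#' metric vector. By construction the mean over multi-day volunteers is 1.
#'
#' @param histories Output of [build_histories()].
#' @return Numeric vector (0 for single-day volunteers).
#' @export
variation_in_periodicity <- function(histories) {
  multi <- histories$n_active_days >= 2
  if (!any(multi)) {
    stop("no volunteer with >= 2 active days: cohort mean gap undefined",
         call. = FALSE)
  }
  # gaps between sequential active days telescope: their mean is
  # (last - first) / (n_active_days - 1)
  g <- rep(0, nrow(histories))
  g[multi] <- as.numeric(histories$last_day[multi] -
                           histories$first_day[multi]) /
    (histories$n_active_days[multi] - 1)
  G <- mean(g[multi])
  vp <- rep(0, nrow(histories))
  vp[multi] <- g[multi] / G
  vp
}

#' Engagement metric table
#'
#' One row per volunteer with the four engagement metrics — observation
#' count, activity ratio, relative activity duration, variation in
#' periodicity — plus the supporting counts.
#'
#' @param records Cleaned records for individual recorders.
#' @param window Optional [study_window()]; defaults to the data's date range.
#' @return A tibble: `recorder_id`, `n_observations`, `n_active_days`,
#'   `linked_days`, `activity_ratio`, `relative_activity_duration`,
#'   `variation_in_periodicity`, `single_day` flag.
#' @export
engagement_table <- function(records, window = NULL) {
  h <- build_histories(records)
  if (nrow(h) == 0) {
    return(tibble::tibble(recorder_id = character(),
                          n_observations = integer(),
                          n_active_days = integer(),
                          linked_days = numeric(),
                          activity_ratio = numeric(),
                          relative_activity_duration = numeric(),
                          variation_in_periodicity = numeric(),
                          single_day = logical()))
  }
  if (is.null(window)) {
    window <- study_window(min(h$first_day), max(h$last_day))
  }
  vp <- if (any(h$n_active_days >= 2)) {
    variation_in_periodicity(h)
  } else {
    rep(0, nrow(h))
  }
  tibble::tibble(
    recorder_id = h$recorder_id,
    n_observations = h$n_observations,
    n_active_days = h$n_active_days,
    linked_days = h$linked_days,
    activity_ratio = activity_ratio(h),
    relative_activity_duration = relative_activity_duration(h, window),
    variation_in_periodicity = vp,
    single_day = h$n_active_days == 1
  )
}
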