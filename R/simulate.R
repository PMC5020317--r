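#' Synthetic occurrence-record generation
#'
#' The generator produces raw occurrence tables with the statistical
#' structure the analysis pipeline assumes: a three-archetype mixture of
#' volunteer engagement behaviour (dabbler / steady / enthusiast), recording
#' effort concentrated on a few hotspot cells of a rectangular pseudo-region
#' of valid OSGB monads, species recording rates log-linear in abundance and
#' trait covariates, and configurable fractions of coarse grid references
#' and perturbed recorder names to exercise the ingestion filters.
#'
#' @name synthetic_data
NULL

.with_seed <- function(seed, expr) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  expr
}

#' Default engagement archetypes
#'
#' Three archetypes whose mean observation counts, activity ratios and
#' relative activity durations follow the reference centroids for a
#' records-centre volunteer base: dabblers (many, brief), steady recorders,
#' and a small cadre of enthusiasts contributing most records. Dispersions
#' default to tight values so the archetypes form well-separated clusters;
#' widen them to stress the profiling stage.
#'
#' @param window_days Study window length the archetypes will be simulated
#'   over (used only for validation here).
#' @return A tibble with one row per archetype: `name`, `weight`,
#'   `mean_n_obs`, `mean_activity_ratio`, `mean_rad`, `sd_activity_ratio`,
#'   `rel_sd_rad`, `sdlog_n_obs`.
#' @export
default_archetypes <- function(window_days = 730) {
  tibble::tibble(
    name = c("dabbler", "steady", "enthusiast"),
    weight = c(0.67, 0.32, 0.01),
    mean_n_obs = c(33, 48, 1524),
    mean_activity_ratio = c(0.60, 0.50, 0.20),
    mean_rad = c(0.030, 0.050, 0.220),
    sd_activity_ratio = c(0.003, 0.003, 0.003),
    rel_sd_rad = c(0.012, 0.012, 0.012),
    sdlog_n_obs = c(0.10, 0.10, 0.10)
  )
}

#' Simulate a volunteer cohort with planted engagement archetypes
#'
#' Each volunteer draws an archetype, a target relative activity duration
#' and activity ratio around the archetype means, and from these an active-day
#' count, a linked period (clamped to the window; first and last days of the
#' linked period are always active so the linked span is exact), uniformly
#' placed active days, and a per-day allocation of a zero-truncated
#' observation count. Variation in periodicity is emergent, not planted:
#' the mean gap between active days is fully determined by the linked span
#' and active-day count.
#'
#' @param n_volunteers Cohort size.
#' @param archetypes An archetype table (see [default_archetypes()]);
#'   weights must sum to 1, activity ratios and durations lie in (0, 1\].
#' @param window_days Study window length in days (default 730).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A tibble with one row per volunteer: `recorder_id`, `archetype`,
#'   `n_active_days`, `linked_days`, `start_day` (1-based offset in the
#'   window), `n_observations`, and list-columns `active_days` (integer day
#'   offsets) and `obs_per_day` (records on each active day).
#' @export
simulate_volunteers <- function(n_volunteers, archetypes = default_archetypes(),
                                window_days = 730, seed = 1) {
  stopifnot(n_volunteers >= 1, window_days >= 2)
  if (abs(sum(archetypes$weight) - 1) > 1e-8) {
    stop("archetype weights must sum to 1", call. = FALSE)
  }
  if (any(archetypes$mean_activity_ratio <= 0 |
          archetypes$mean_activity_ratio > 1) ||
      any(archetypes$mean_rad <= 0 | archetypes$mean_rad > 1)) {
    stop("archetype activity ratios and durations must lie in (0, 1]",
         call. = FALSE)
  }
  .with_seed(seed, {
    arch <- sample.int(nrow(archetypes), n_volunteers, replace = TRUE,
                       prob = archetypes$weight)
    out <- vector("list", n_volunteers)
    for (i in seq_len(n_volunteers)) {
      a <- archetypes[arch[i], ]
      rad <- stats::rnorm(1, a$mean_rad, a$rel_sd_rad * a$mean_rad)
      rad <- min(max(rad, 1 / window_days), 1)
      n_active <- max(1L, as.integer(round(rad * window_days)))
      ar <- stats::rnorm(1, a$mean_activity_ratio, a$sd_activity_ratio)
      ar <- min(max(ar, 0.01), 1)
      linked <- as.integer(round(n_active / ar))
      linked <- min(max(linked, n_active), window_days)
      start <- if (linked == window_days) 1L else {
        sample.int(window_days - linked + 1L, 1)
      }
      days <- if (n_active == 1L) {
        start
      } else if (n_active == 2L) {
        c(start, start + linked - 1L)
      } else {
        interior <- sample(seq(start + 1L, start + linked - 2L),
                           n_active - 2L)
        sort(c(start, interior, start + linked - 1L))
      }
      n_obs <- max(n_active, as.integer(round(
        exp(stats::rnorm(1, log(a$mean_n_obs), a$sdlog_n_obs)))))
      extra <- n_obs - n_active
      alloc <- rep(1L, n_active)
      if (extra > 0) {
        add <- stats::rmultinom(1, extra, rep(1, n_active))[, 1]
        alloc <- alloc + add
      }
      out[[i]] <- tibble::tibble(
        recorder_id = sprintf("vol%04d", i),
        archetype = a$name,
        n_active_days = n_active,
        linked_days = linked,
        start_day = start,
        n_observations = n_obs,
        active_days = list(as.integer(days)),
        obs_per_day = list(as.integer(alloc))
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Default recording landscape
#'
#' A 40 x 50 rectangle of valid OSGB monads in the TQ 100-km square (a
#' pseudo-region of 2000 1-km cells, comparable to a large conurbation),
#' with five hotspot cells whose attraction multiplier concentrates effort
#' the way popular wetland and reserve sites do.
#'
#' @param n_cols,n_rows Extent in cells (eastward, northward from TQ 00 00).
#' @param hotspot_cells Monad ids of the hotspots (must lie in the extent).
#' @param hotspot_multiplier Attraction multiplier (>= 1) applied to each
#'   hotspot cell's unit weight.
#' @return A tibble: `monad`, `easting`, `northing`, `weight`, `hotspot`.
#' @export
default_landscape <- function(n_cols = 40, n_rows = 50,
                              hotspot_cells = c("TQ1012", "TQ2535", "TQ0542",
                                                "TQ3318", "TQ2207"),
                              hotspot_multiplier = 20) {
  stopifnot(hotspot_multiplier >= 1)
  e <- rep(seq_len(n_cols) - 1, each = n_rows) * 1000 + 500000
  n <- rep(seq_len(n_rows) - 1, times = n_cols) * 1000 + 100000
  monad <- monad_of(e, n)
  if (!all(hotspot_cells %in% monad)) {
    stop("hotspot cell outside the landscape extent", call. = FALSE)
  }
  hot <- monad %in% hotspot_cells
  tibble::tibble(monad = monad, easting = e, northing = n,
                 weight = ifelse(hot, hotspot_multiplier, 1),
                 hotspot = hot)
}

#' Default species pool with trait-linked recording rates
#'
#' Species across ten informal groups with lognormal relative abundances,
#' identification-difficulty scores 1-4 (1 easiest), and a per-species
#' recording rate proportional to abundance times
#' `exp(sum(trait_slopes * trait))`. The default slope makes
#' hard-to-identify species less recorded, mirroring how identification
#' skill filters opportunistic records.
#'
#' @param species_per_group Named integer vector: informal group -> species
#'   count.
#' @param abundance_sdlog Lognormal sd of relative abundance.
#' @param trait_slopes Named numeric vector of log-linear trait effects on
#'   the recording rate (names must be trait columns of the pool).
#' @param seed Integer seed for the pool draw.
#' @return A tibble: `scientific_name`, `informal_group`, `higher_group`,
#'   `abundance`, `identification_difficulty`, `rate_weight`.
#' @export
default_species_pool <- function(species_per_group = c(
                                   "bird" = 50, "flowering plant" = 80,
                                   "beetle" = 60, "moth" = 40,
                                   "butterfly" = 20, "terrestrial mammal" = 15,
                                   "dragonfly" = 12, "true bug" = 20,
                                   "spider" = 25, "fungus" = 30),
                                 abundance_sdlog = 1,
                                 trait_slopes = c(identification_difficulty = -0.4),
                                 seed = 1) {
  higher <- utils::read.csv(volcontrib_extdata("informal_groups"),
                            stringsAsFactors = FALSE)
  .with_seed(seed, {
    pool <- dplyr::bind_rows(lapply(names(species_per_group), function(g) {
      ns <- species_per_group[[g]]
      tibble::tibble(
        scientific_name = sprintf("Genus %s_sp%03d",
                                  gsub("[^a-z]", "", g), seq_len(ns)),
        informal_group = g,
        higher_group = higher$higherGroup[match(g, higher$informalGroup)],
        abundance = stats::rlnorm(ns, 0, abundance_sdlog),
        identification_difficulty = sample(1:4, ns, replace = TRUE)
      )
    }))
    lin <- rep(0, nrow(pool))
    for (tr in names(trait_slopes)) {
      if (!tr %in% names(pool)) {
        stop("trait slope refers to unknown trait '", tr, "'", call. = FALSE)
      }
      lin <- lin + trait_slopes[[tr]] * pool[[tr]]
    }
    pool$rate_weight <- pool$abundance * exp(lin)
    pool
  })
}

#' Expand a volunteer cohort into a raw occurrence table
#'
#' Each observation is assigned a cell by a hotspot-weighted categorical
#' draw over the landscape and a species by the volunteer's informal-group
#' preference combined with abundance- and trait-weighted rates. Grid
#' references are emitted at 1-km precision except for a configurable
#' fraction emitted at 10-km precision, and a configurable fraction of rows
#' carries a punctuation-perturbed recorder name, so the ingestion filters
#' have realistic dirt to work on.
#'
#' @param volunteers A [simulate_volunteers()] cohort.
#' @param landscape A [default_landscape()]-style cell table.
#' @param species_pool A [default_species_pool()]-style pool (non-empty).
#' @param window_start First calendar day of the study window.
#' @param dataset_id Label stamped on every row.
#' @param coarse_fraction Fraction of records georeferenced at 10 km.
#' @param synonym_fraction Fraction of records with a perturbed recorder
#'   name.
#' @param group_preference Probability that a record comes from the
#'   volunteer's preferred informal group.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A tibble in the raw-record schema: `recordedBy`, `eventDate`,
#'   `gridReference`, `scientificName`, `datasetID`.
#' @export
simulate_records <- function(volunteers, landscape = default_landscape(),
                             species_pool = default_species_pool(),
                             window_start = as.Date("2010-01-01"),
                             dataset_id = "synthetic",
                             coarse_fraction = 0,
                             synonym_fraction = 0,
                             group_preference = 0.8,
                             seed = 1) {
  if (nrow(species_pool) == 0) stop("empty species pool", call. = FALSE)
  stopifnot(coarse_fraction >= 0, coarse_fraction < 1,
            synonym_fraction >= 0, synonym_fraction < 1)
  groups <- unique(species_pool$informal_group)
  group_w <- vapply(groups, function(g) {
    sum(species_pool$rate_weight[species_pool$informal_group == g])
  }, numeric(1))
  .with_seed(seed, {
    pref <- sample(groups, nrow(volunteers), replace = TRUE, prob = group_w)
    rows <- vector("list", nrow(volunteers))
    for (i in seq_len(nrow(volunteers))) {
      v <- volunteers[i, ]
      days <- v$active_days[[1]]
      alloc <- v$obs_per_day[[1]]
      n_obs <- sum(alloc)
      dates <- window_start + rep(days - 1L, alloc)
      cell_idx <- sample.int(nrow(landscape), n_obs, replace = TRUE,
                             prob = landscape$weight)
      from_pref <- stats::runif(n_obs) < group_preference
      in_pref <- species_pool$informal_group == pref[i]
      sp_idx <- integer(n_obs)
      if (any(from_pref)) {
        sp_idx[from_pref] <- sample(which(in_pref), sum(from_pref),
                                    replace = TRUE,
                                    prob = species_pool$rate_weight[in_pref])
      }
      if (any(!from_pref)) {
        sp_idx[!from_pref] <- sample.int(nrow(species_pool), sum(!from_pref),
                                         replace = TRUE,
                                         prob = species_pool$rate_weight)
      }
      gr <- landscape$monad[cell_idx]
      coarse <- stats::runif(n_obs) < coarse_fraction
      gr[coarse] <- substr(gr[coarse], 1, 3) |>
        paste0(substr(gr[coarse], 5, 5))
      name <- rep(v$recorder_id, n_obs)
      syn <- stats::runif(n_obs) < synonym_fraction
      name[syn] <- paste0(name[syn], ".")
      rows[[i]] <- tibble::tibble(
        recordedBy = name,
        eventDate = format(dates, "%Y-%m-%d"),
        gridReference = gr,
        scientificName = species_pool$scientific_name[sp_idx],
        datasetID = dataset_id
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' One-call synthetic dataset
#'
#' Simulates a volunteer cohort and expands it into a raw occurrence table,
#' returning the table together with the planted truth (volunteer
#' archetypes, species pool, landscape) needed for recovery checks.
#'
#' @param n_volunteers Cohort size (default 600).
#' @param seed Integer seed driving every draw.
#' @param archetypes,window_days Passed to [simulate_volunteers()].
#' @param landscape,species_pool,coarse_fraction,synonym_fraction,window_start
#'   Passed to [simulate_records()].
#' @return A list: `raw` (record table), `volunteers`, `species_pool`,
#'   `landscape`, `window` (a [study_window()]).
#' @export
simulate_dataset <- function(n_volunteers = 600, seed = 1,
                             archetypes = default_archetypes(),
                             window_days = 730,
                             landscape = default_landscape(),
                             species_pool = default_species_pool(),
                             coarse_fraction = 0,
                             synonym_fraction = 0,
                             window_start = as.Date("2010-01-01")) {
  vols <- simulate_volunteers(n_volunteers, archetypes = archetypes,
                              window_days = window_days, seed = seed)
  raw <- simulate_records(vols, landscape = landscape,
                          species_pool = species_pool,
                          window_start = window_start,
                          coarse_fraction = coarse_fraction,
                          synonym_fraction = synonym_fraction,
                          seed = seed + 1)
  list(raw = raw, volunteers = vols, species_pool = species_pool,
       landscape = landscape,
       window = study_window(window_start,
                             window_start + window_days - 1))
}

#' Simulate per-species record counts with a planted trait effect
#'
#' Counts with log rate `beta0 + slope * x` for a standard-normal trait x,
#' equidispersed (Poisson) at `dispersion = 1` or overdispersed via a
#' negative binomial with variance `dispersion * mu` otherwise. Used to
#' calibrate and validate the quasipoisson trait screen.
#'
#' @param n_species Number of species rows.
#' @param beta0 Intercept on the log scale.
#' @param slope Planted trait effect (0 for a null simulation).
#' @param dispersion Variance-to-mean ratio (>= 1).
#' @param seed Integer seed.
#' @return A tibble: `species`, `x` (trait), `n_records`.
#' @export
simulate_trait_counts <- function(n_species, beta0 = 1, slope = 0,
                                  dispersion = 1, seed = 1) {
  stopifnot(dispersion >= 1)
  .with_seed(seed, {
    x <- stats::rnorm(n_species)
    mu <- exp(beta0 + slope * x)
    y <- if (dispersion == 1) {
      stats::rpois(n_species, mu)
    } else {
      stats::rnbinom(n_species, mu = mu, size = mu / (dispersion - 1))
    }
    tibble::tibble(species = sprintf("sp%04d", seq_len(n_species)),
                   x = x, n_records = y)
  })
}

#' Expand a simulated cohort into dated per-record rows
#'
#' The minimal record table (recorder and date only) implied by a
#' [simulate_volunteers()] cohort: one row per observation, on the
#' volunteer's active days. Engagement metrics depend on nothing else, so
#' this is the direct route from a cohort to [engagement_table()] when the
#' spatial and taxonomic structure of [simulate_records()] is not needed.
#'
#' @param volunteers A [simulate_volunteers()] cohort.
#' @param window_start First calendar day of the study window.
#' @return A tibble: `recorder_id`, `date`.
#' @export
volunteer_day_records <- function(volunteers,
                                  window_start = as.Date("2010-01-01")) {
  n <- vapply(volunteers$obs_per_day, sum, integer(1))
  tibble::tibble(
    recorder_id = rep(volunteers$recorder_id, n),
    date = window_start +
      unlist(mapply(rep, lapply(volunteers$active_days, function(d) d - 1L),
                    volunteers$obs_per_day, SIMPLIFY = FALSE))
  )
}

#' Species-to-group mapping table for a simulated pool
#'
#' @param species_pool A [default_species_pool()]-style pool.
#' @return A mapping tibble compatible with [assign_groups()].
#' @export
pool_mapping <- function(species_pool) {
  m <- tibble::tibble(
    scientificName = .norm_species(species_pool$scientific_name),
    informalGroup = species_pool$informal_group,
    higherGroup = species_pool$higher_group
  )
  class(m) <- c("group_mapping", class(m))
  m
}
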