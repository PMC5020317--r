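#' Pipeline configuration
#'
#' Collects the inputs and parameters of a full analysis run. Either an
#' `input` CSV path (raw-record schema) or a `simulate` list (arguments for
#' [simulate_dataset()]) must be given.
#'
#' @param out_dir Output directory (created if absent).
#' @param input Optional raw-record CSV path.
#' @param simulate Optional named list passed to [simulate_dataset()].
#' @param mapping Optional species-to-group mapping CSV path; when the input
#'   is simulated the pool's own mapping is used by default.
#' @param checklist Optional checklist CSV path (defaults to the shipped
#'   British-list totals).
#' @param stages Character vector of stages to run, a subset of
#'   `c("engagement", "profiling", "spatial", "taxa")`.
#' @param seed Integer seed recorded in every output.
#' @param k_range,asw_threshold Profiling parameters.
#' @param pairing Spatial correlation pairing policy.
#' @param policy A [record_policy()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, input = NULL, simulate = NULL,
                       mapping = NULL, checklist = NULL,
                       stages = c("engagement", "profiling", "spatial",
                                  "taxa"),
                       seed = 1, k_range = 2:8, asw_threshold = 0.51,
                       pairing = "union", policy = record_policy()) {
  if (is.null(input) && is.null(simulate)) {
    stop("config needs either an input CSV or a simulate spec",
         call. = FALSE)
  }
  if (!is.null(input) && !file.exists(input)) {
    stop("input file does not exist: ", input, call. = FALSE)
  }
  stages <- match.arg(stages, c("engagement", "profiling", "spatial",
                                "taxa"), several.ok = TRUE)
  structure(list(out_dir = out_dir, input = input, simulate = simulate,
                 mapping = mapping, checklist = checklist, stages = stages,
                 seed = seed, k_range = k_range,
                 asw_threshold = asw_threshold, pairing = pairing,
                 policy = policy),
            class = "run_config")
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  ser <- config
  ser$out_dir <- NULL # where outputs land is not part of the analysis
  ser$policy <- unclass(ser$policy)
  jsonlite::write_json(ser, f, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full contribution-analysis pipeline
#'
#' Ingests (or simulates) a raw occurrence table, then runs the enabled
#' stages in dependency order: engagement metrics, profile clustering,
#' spatial cell statistics and hotspots, and taxonomic composition and
#' coverage. Per-stage CSVs, a machine-readable `summary.json` (embedding
#' the seed and a config hash) and the filter audit are written under
#' `config$out_dir`. A stage failure halts the run with the failing stage
#' named; outputs written so far are retained.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed, config_hash = .config_hash(config),
                  stages = config$stages)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ingest
  ing <- run_stage("ingest", {
    if (!is.null(config$input)) {
      list(raw = read_records(config$input), sim = NULL)
    } else {
      sim <- do.call(simulate_dataset,
                     c(config$simulate, list(seed = config$seed)))
      list(raw = sim$raw, sim = sim)
    }
  })
  sim <- ing$sim
  mapping <- if (!is.null(sim)) pool_mapping(sim$species_pool) else NULL
  cleaned <- run_stage("ingest", clean_records(ing$raw, config$policy))
  if (!is.null(config$mapping)) {
    mapping <- run_stage("ingest", load_group_mapping(config$mapping))
  }
  records <- cleaned$records
  if (!is.null(mapping)) records <- assign_groups(records, mapping)
  utils::write.csv(records, file.path(config$out_dir, "clean.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(cleaned$audit),
                       file.path(config$out_dir, "audit.json"),
                       auto_unbox = TRUE)
  summary$audit <- unclass(cleaned$audit)

  window <- if (!is.null(sim)) sim$window else NULL
  eng <- NULL
  if (any(c("engagement", "profiling") %in% config$stages)) {
    eng <- run_stage("engagement",
                     engagement_table(engagement_records(records), window))
    utils::write.csv(eng, file.path(config$out_dir, "engagement.csv"),
                     row.names = FALSE)
    summary$n_volunteers <- nrow(eng)
  }

  if ("profiling" %in% config$stages) {
    model <- run_stage("profiling",
                       fit_profiles(eng, k_range = config$k_range,
                                    asw_threshold = config$asw_threshold,
                                    seed = config$seed))
    ps <- profile_summary(model, eng)
    utils::write.csv(ps, file.path(config$out_dir, "profile_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(model$assignments,
                     file.path(config$out_dir, "profile_assignments.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(k = model$k, accepted = model$accepted, asw = model$asw,
           asw_by_k = as.list(model$asw_by_k),
           wss_by_k = as.list(model$wss_by_k), seed = model$seed),
      file.path(config$out_dir, "profile_diagnostics.json"),
      auto_unbox = TRUE, digits = NA)
    summary$profiles <- list(k = model$k, accepted = model$accepted,
                             asw = model$asw,
                             shares = as.list(table(model$assignments$profile)))
  }

  if ("spatial" %in% config$stages) {
    cells <- run_stage("spatial", aggregate_cells(records))
    utils::write.csv(cells, file.path(config$out_dir, "cells.csv"),
                     row.names = FALSE)
    hs <- run_stage("spatial", hotspots(cells, "n_records", 10))
    utils::write.csv(hs, file.path(config$out_dir, "hotspots.csv"),
                     row.names = FALSE)
    run_stage("spatial",
              cells_geojson(cells, file.path(config$out_dir,
                                             "cells.geojson")))
    summary$spatial <- list(n_cells = nrow(cells),
                            top_hotspots = hs$monad)
  }

  if ("taxa" %in% config$stages) {
    if (is.null(mapping)) {
      stop("pipeline stage 'taxa' failed: no species-to-group mapping",
           call. = FALSE)
    }
    comp <- run_stage("taxa", composition(records, "higher"))
    utils::write.csv(comp, file.path(config$out_dir, "composition.csv"),
                     row.names = FALSE)
    checklist <- if (!is.null(config$checklist)) {
      utils::read.csv(config$checklist, stringsAsFactors = FALSE)
    } else {
      utils::read.csv(volcontrib_extdata("british_list"),
                      stringsAsFactors = FALSE)
    }
    gs <- run_stage("taxa", group_stats(records, checklist))
    utils::write.csv(gs, file.path(config$out_dir, "group_stats.csv"),
                     row.names = FALSE)
    summary$taxa <- list(
      composition = stats::setNames(as.list(comp$percent), comp$group))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(summary)
}
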