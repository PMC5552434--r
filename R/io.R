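RECORD_COLS <- c("subject", "session", "trial_index", "phase", "item_lo",
                 "item_hi", "chosen", "correct", "rt_seconds")

#' Write trial records to CSV
#'
#' The interchange format is a comma-separated, UTF-8, header-required CSV
#' with columns `subject, session, trial_index, phase, item_lo, item_hi,
#' chosen, correct, rt_seconds`. Derived columns (distance, joint rank,
#' pair) are recomputed on read.
#'
#' @param records Trial records.
#' @param path Output path (a `.gz` suffix gives a gzip-compressed file).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  missing_cols <- setdiff(RECORD_COLS, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(records[, RECORD_COLS], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read and validate trial records
#'
#' Reads the CSV interchange format (see [write_records()]), validates
#' every row (phase in 1..3, positive reaction time, chosen item member of
#' its pair, correctness flag consistent with the choice) and attaches the
#' pair coordinates.
#'
#' @param path CSV file (optionally gzip-compressed).
#' @param n_items List length used to recompute coordinates (default 7).
#' @return Validated trial records with `distance`, `joint_rank`, `pair`
#'   columns added.
#' @export
read_records <- function(path, n_items = 7) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- names(utils::read.csv(path, nrows = 1L))
  missing_cols <- setdiff(RECORD_COLS, header)
  if (length(missing_cols))
    stop("header mismatch: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  # item labels such as "F" must never be sniffed as logicals
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(item_lo = "character",
                                      item_hi = "character",
                                      chosen = "character"))
  bad <- function(rows, field, why) {
    if (any(rows))
      stop("invalid record in rows ",
           paste(utils::head(which(rows), 5L), collapse = ", "),
           if (sum(rows) > 5L) " ..." else "",
           ": field '", field, "' ", why, call. = FALSE)
  }
  bad(!d$phase %in% c(1L, 2L, 3L), "phase", "must be 1, 2 or 3")
  bad(!is.finite(d$trial_index) | d$trial_index < 1, "trial_index",
      "must be a positive integer")
  bad(is.na(d$rt_seconds) | d$rt_seconds <= 0, "rt_seconds",
      "must be > 0")
  bad(!(d$chosen == d$item_lo | d$chosen == d$item_hi), "chosen",
      "must be one of the pair's items")
  bad(d$correct != as.integer(d$chosen == d$item_lo), "correct",
      "inconsistent with chosen item")
  items <- ti_items(n_items)
  r_lo <- match(d$item_lo, items$label)
  r_hi <- match(d$item_hi, items$label)
  bad(is.na(r_lo) | is.na(r_hi), "item_lo/item_hi", "unknown item label")
  bad(r_lo >= r_hi, "item_lo", "must rank earlier than item_hi")
  d$distance <- r_hi - r_lo
  d$joint_rank <- r_hi + r_lo
  d$pair <- paste0(d$item_lo, d$item_hi)
  d
}

#' Pipeline run configuration
#'
#' @param species `"monkey"` or `"human"`.
#' @param agent `"representational"`, `"associative"` or an
#'   `agent_config` object.
#' @param n_subjects,sessions_per_subject Cohort size (defaults per
#'   species).
#' @param seed Master seed for the whole run.
#' @param out_dir Output directory (created if missing when
#'   `create_dir = TRUE`).
#' @param create_dir Create `out_dir` if absent (default `TRUE`).
#' @param optimize Tune GP hyperparameters in the analyses (default
#'   `FALSE` for speed; turn on for final runs).
#' @param grid_res Surface grid resolution.
#' @param agent_params,rt_params Optional named lists overriding agent /
#'   RT configuration defaults.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(species = "monkey", agent = "representational",
                       n_subjects = NULL, sessions_per_subject = NULL,
                       seed = 1L, out_dir = tempfile("tigp_run_"),
                       create_dir = TRUE, optimize = FALSE, grid_res = 0.25,
                       agent_params = list(), rt_params = list()) {
  species <- match.arg(species, c("monkey", "human"))
  cfg <- list(species = species, agent = agent, n_subjects = n_subjects,
              sessions_per_subject = sessions_per_subject,
              seed = as.integer(seed), out_dir = out_dir,
              create_dir = isTRUE(create_dir), optimize = isTRUE(optimize),
              grid_res = grid_res, agent_params = agent_params,
              rt_params = rt_params)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from JSON or YAML
#'
#' @param path A `.json`, `.yaml` or `.yml` file whose keys match the
#'   arguments of [run_config()].
#' @return A `"run_config"`.
#' @export
run_config_from_file <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(run_config, vals)
}

resolve_agent <- function(cfg, species) {
  if (inherits(cfg$agent, "agent_config")) return(cfg$agent)
  agent <- match.arg(cfg$agent, c("representational", "associative"))
  if (agent == "representational") {
    base <- default_agent_config(species)
    do.call(representational_config,
            utils::modifyList(unclass(base), cfg$agent_params))
  } else {
    do.call(associative_config, cfg$agent_params)
  }
}

#' Run the simulate-then-analyse pipeline
#'
#' Simulates a cohort under the configuration, runs the four analysis
#' stages (massed-pair accuracy time series, transition profile, phase-2
#' learning rates, joint accuracy surface at the first phase-3 trial),
#' writes each as a CSV table under `out_dir` together with the simulated
#' records and a machine-readable JSON summary of the effect statistics,
#' seeds and package version. The summary is byte-identical across runs of
#' the same configuration; wall-clock timings go to the messages stream
#' only.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `records`, `timeseries`, `transition`,
#'   `rates`, `surface`, `summary` and the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) {
    if (!config$create_dir)
      stop("pipeline stage [setup]: output directory does not exist: ",
           config$out_dir, call. = FALSE)
    dir.create(config$out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  prof <- species_profile(config$species,
                          sessions_per_subject = config$sessions_per_subject)
  agent <- resolve_agent(config, config$species)
  rt_cfg <- do.call(rt_config, c(list(species = config$species),
                                 config$rt_params))

  records <- stage("simulate",
    generate_cohort(prof, agent, rt_cfg, n_subjects = config$n_subjects,
                    seed = config$seed))
  massed <- paste0(LETTERS[prof$n_items - 1L], LETTERS[prof$n_items])
  ts <- stage("timeseries",
    accuracy_timeseries(records, massed, phase = 1,
                        optimize = config$optimize))
  tr <- stage("transition", transition_profile(records))
  lr <- stage("rates",
    learning_rates(records, phase = 2, optimize = config$optimize))
  sf <- stage("surface",
    joint_surface(records, "accuracy", grid_res = config$grid_res,
                  optimize = config$optimize))
  eff <- effect_stats(sf, n_draws = 2000L, seed = config$seed)

  paths <- file.path(config$out_dir,
                     c(records = "records.csv",
                       timeseries = "timeseries_accuracy.csv",
                       transition = "transition_profile.csv",
                       rates = "learning_rates.csv",
                       surface = "surface_pairs.csv",
                       summary = "summary.json"))
  names(paths) <- c("records", "timeseries", "transition", "rates",
                    "surface", "summary")
  write_records(records, paths[["records"]])
  utils::write.csv(as.data.frame(ts), paths[["timeseries"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(tr), paths[["transition"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(lr), paths[["rates"]], row.names = FALSE)
  utils::write.csv(sf$pairs, paths[["surface"]], row.names = FALSE)

  summary <- list(
    package_version = as.character(utils::packageVersion("tigp")),
    config = list(species = config$species,
                  agent = class(agent)[1L],
                  n_subjects = config$n_subjects %||%
                    if (config$species == "monkey") 3L else 33L,
                  sessions_per_subject = prof$sessions_per_subject,
                  seed = config$seed),
    n_records = nrow(records),
    effect_stats = eff,
    first_xf_accuracy = tr$accuracy[tr$segment == "xf" &
                                      tr$presentation == 1L]
  )
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(records = records, timeseries = ts, transition = tr,
                 rates = lr, surface = sf, summary = summary,
                 paths = paths))
}
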