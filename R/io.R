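#' Write and read trajectories
#'
#' Trajectories serialize to RFC-4180-style CSV ("." decimal separator) with
#' one row per recorded time and the column layout of the trajectory frame:
#' `time_d`, biomasses, then all model fluxes (per-symbiont fluxes suffixed
#' with the symbiont label). Values round-trip to 15 significant digits.
#'
#' @param traj A `holo_trajectory` (or its data frame).
#' @param path Output file.
#' @param format `"csv"` or `"json"`.
#' @return `read_trajectory()` returns the data frame.
#' @export
write_trajectory <- function(traj, path, format = c("csv", "json")) {
  format <- match.arg(format)
  fr <- if (inherits(traj, "holo_trajectory")) traj$frame else traj
  if (format == "csv") {
    utils::write.csv(fr, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(fr, path, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

config_schema <- function() list(
  environment = c("light", "din", "prey"),
  init = c("mode", "host0", "symbiont0", "total_symbiont0", "split"),
  sim = c("dt", "duration", "record_every", "engine"),
  experiment = c("vitality_check_day", "dominance_horizon_d",
                 "exclusion_threshold", "exclusion_cap_d",
                 "recovery_horizon_d", "dt", "record_every"),
  host = names(formals(host_params)),
  symbionts = NULL,   # list of symbiont parameter documents
  survey = c("n", "seed", "ranges")
)

#' Load and validate a run configuration
#'
#' Reads a JSON configuration and fills every omitted setting with the
#' package defaults (reference parameterization, default experiment settings,
#' `dt = 0.1`). Unknown keys are rejected with their key path; basic range
#' violations are reported with the offending key.
#'
#' @param path Path to a JSON configuration file, or `NULL` for all-default
#'   configuration. An empty file (or `{}`) likewise yields the defaults.
#' @return A validated configuration list with elements `environment`,
#'   `init`, `sim`, `experiment`, `params` ([holo_params()]), `survey`.
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (nzchar(trimws(txt)))
      raw <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  }
  schema <- config_schema()
  unknown_top <- setdiff(names(raw), names(schema))
  if (length(unknown_top))
    stop("unknown configuration key(s): ",
         paste(unknown_top, collapse = ", "), call. = FALSE)
  for (section in c("environment", "init", "sim", "experiment", "host",
                    "survey")) {
    bad <- setdiff(names(raw[[section]]), schema[[section]])
    if (length(bad))
      stop("unknown configuration key(s): ",
           paste(paste0(section, ".", bad), collapse = ", "), call. = FALSE)
  }

  environment <- utils::modifyList(
    list(light = 30, din = 1e-7, prey = 1e-7), as.list(raw$environment))
  init <- utils::modifyList(
    list(mode = "healthy", host0 = 1, symbiont0 = 0.5,
         total_symbiont0 = 1e-4, split = NULL), as.list(raw$init))
  if (!init$mode %in% c("healthy", "bleached"))
    stop("init.mode must be 'healthy' or 'bleached'", call. = FALSE)
  sim <- utils::modifyList(
    list(dt = 0.1, duration = 365, record_every = 1, engine = "cpp"),
    as.list(raw$sim))
  if (!is.numeric(sim$dt) || sim$dt <= 0)
    stop("sim.dt must be positive", call. = FALSE)
  if (!is.numeric(sim$duration) || sim$duration < 0)
    stop("sim.duration must be nonnegative", call. = FALSE)
  experiment <- do.call(experiment_config, as.list(raw$experiment))

  host <- do.call(host_params, as.list(raw$host))
  symbionts <- if (is.null(raw$symbionts)) list("sensitive", "tolerant")
  else lapply(raw$symbionts, function(s) {
    if (is.character(s)) symbiont_params(s) else do.call(symbiont_params, s)
  })
  params <- holo_params(host, symbionts)

  survey <- utils::modifyList(list(n = 200, seed = 1, ranges = NULL),
                              as.list(raw$survey))
  ranges <- if (is.null(survey$ranges)) env_ranges()
            else do.call(env_ranges, survey$ranges)
  survey$ranges <- ranges

  list(environment = environment, init = init, sim = sim,
       experiment = experiment, params = params, survey = survey)
}

run_manifest <- function(command, config_snapshot, seed, outputs,
                         started, finished) {
  list(command = command,
       package_version = as.character(utils::packageVersion("holodeb")),
       seed = seed,
       started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
       finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
       outputs = outputs,
       config = config_snapshot)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run a single simulation from a configuration
#'
#' Loads (or takes) a configuration, initializes the holobiont in the
#' configured mode, integrates, and writes the trajectory CSV plus a JSON
#' manifest (`<out>.manifest.json`) sufficient to re-run it.
#'
#' @param config A configuration file path, or a list from [load_config()].
#' @param out Output CSV path.
#' @return The trajectory, invisibly.
#' @export
cli_simulate <- function(config = NULL, out = "trajectory.csv") {
  started <- Sys.time()
  cfg <- if (is.list(config)) config else load_config(config)
  env <- do.call(env_conditions, cfg$environment)
  init <- if (cfg$init$mode == "healthy") {
    init_healthy(cfg$params, env, host0 = cfg$init$host0,
                 symbiont0 = cfg$init$symbiont0)
  } else {
    init_bleached(cfg$params, env, host0 = cfg$init$host0,
                  total_symbiont0 = cfg$init$total_symbiont0,
                  split = cfg$init$split)
  }
  traj <- run(init$state, init$fluxes, env, cfg$params,
              duration = cfg$sim$duration, dt = cfg$sim$dt,
              record_every = cfg$sim$record_every,
              engine = cfg$sim$engine)
  write_trajectory(traj, out)
  write_manifest(
    run_manifest("simulate", config_snapshot(cfg), seed = NA,
                 outputs = out, started, Sys.time()),
    paste0(out, ".manifest.json"))
  invisible(traj)
}

#' Run an environmental survey from a configuration
#'
#' Samples environments (seeded), runs one of the three experiments over
#' them, writes the outcome table as CSV and a JSON manifest; optionally fits
#' the outcome LDA and writes its summary as `<out>.lda.json`.
#'
#' @param experiment `"competition"`, `"exclusion"` or `"recovery"`.
#' @param config A configuration file path or list (see [load_config()]).
#' @param out Output CSV path.
#' @param lda If `TRUE`, also fit [fit_lda()] on the outcomes and write the
#'   trace-share summary JSON.
#' @param n,seed Optional overrides of the configured survey size and seed.
#' @return The outcome table, invisibly.
#' @export
cli_survey <- function(experiment, config = NULL, out = "survey.csv",
                       lda = FALSE, n = NULL, seed = NULL) {
  started <- Sys.time()
  cfg <- if (is.list(config)) config else load_config(config)
  n <- n %||% cfg$survey$n
  seed <- seed %||% cfg$survey$seed
  if (n <= 0) stop("survey size must be positive", call. = FALSE)
  envs <- sample_environments(n, cfg$survey$ranges, seed = seed)
  tab <- run_survey(envs, experiment, cfg$params, cfg$experiment)
  utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
  outputs <- out
  if (lda) {
    model <- fit_lda(tab[c("light", "din", "prey")], tab$outcome)
    lda_path <- paste0(out, ".lda.json")
    write_lda_summary(model, lda_path)
    outputs <- c(outputs, lda_path)
  }
  write_manifest(
    run_manifest(paste0("survey:", experiment), config_snapshot(cfg),
                 seed = seed, outputs = outputs, started, Sys.time()),
    paste0(out, ".manifest.json"))
  invisible(tab)
}

config_snapshot <- function(cfg) {
  list(environment = cfg$environment, init = cfg$init, sim = cfg$sim,
       experiment = unclass(cfg$experiment),
       host = unclass(cfg$params$host),
       symbionts = lapply(cfg$params$symbionts, unclass),
       survey = list(n = cfg$survey$n, seed = cfg$survey$seed,
                     ranges = unclass(cfg$survey$ranges)))
}
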