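#' Environmental sampling ranges
#'
#' Uniform sampling ranges for the three environmental drivers. Defaults span
#' benign through stressful light (5--60 mol photons m^-2 d^-1), oligotrophic
#' through enriched dissolved inorganic nitrogen (1e-8--1e-5 mol L^-1) and
#' zooplankton prey from absent to abundant (0--4e-7 C-mol L^-1).
#'
#' @param light,din,prey Length-2 numeric ranges `c(lo, hi)`.
#' @return An object of class `env_ranges`.
#' @export
env_ranges <- function(light = c(5, 60), din = c(1e-8, 1e-5),
                       prey = c(0, 4e-7)) {
  r <- list(light = light, din = din, prey = prey)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (length(v) != 2 || any(!is.finite(v)) || v[1] > v[2] || v[1] < 0)
      stop(sprintf("`%s` must be a nonnegative range c(lo, hi)", nm),
           call. = FALSE)
  }
  structure(r, class = "env_ranges")
}

#' Draw environments uniformly at random
#'
#' Independent uniform draws of light, nitrogen and prey over the given
#' ranges, reproducible under `seed`.
#'
#' @param n Number of environments.
#' @param ranges An [env_ranges()].
#' @param seed Integer seed (optional; when given, set locally for the draw).
#' @return Data frame with columns `light`, `din`, `prey`.
#' @export
sample_environments <- function(n, ranges = env_ranges(), seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    light = stats::runif(n, ranges$light[1], ranges$light[2]),
    din = stats::runif(n, ranges$din[1], ranges$din[2]),
    prey = stats::runif(n, ranges$prey[1], ranges$prey[2])
  )
}

#' Experiment configuration
#'
#' Shared settings for the three simulation experiments.
#'
#' @param vitality_check_day Day of the death check (default 100).
#' @param dominance_horizon_d Horizon for competitive dominance, days
#'   (default 3650, i.e. 10 years).
#' @param exclusion_threshold Share of total symbiont biomass at which the
#'   winner is considered to have excluded the loser (default 0.99).
#' @param exclusion_cap_d Censoring horizon for exclusion runs, days
#'   (default 9125, i.e. 25 years, so that exclusion slower than 20 years is
#'   still resolved rather than censored at the dominance horizon).
#' @param recovery_horizon_d Horizon of the bleaching-recovery experiment,
#'   days (default 1000).
#' @param dt Integration step, days.
#' @param record_every Trajectory recording interval, days.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(vitality_check_day = 100,
                              dominance_horizon_d = 3650,
                              exclusion_threshold = 0.99,
                              exclusion_cap_d = 9125,
                              recovery_horizon_d = 1000,
                              dt = 0.1, record_every = 1) {
  cfg <- list(vitality_check_day = vitality_check_day,
              dominance_horizon_d = dominance_horizon_d,
              exclusion_threshold = exclusion_threshold,
              exclusion_cap_d = exclusion_cap_d,
              recovery_horizon_d = recovery_horizon_d,
              dt = dt, record_every = record_every)
  v <- unlist(cfg)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all experiment settings must be positive", call. = FALSE)
  if (exclusion_threshold <= 0.5 || exclusion_threshold >= 1)
    stop("`exclusion_threshold` must lie in (0.5, 1)", call. = FALSE)
  structure(cfg, class = "experiment_config")
}

final_shares <- function(traj) {
  s <- attr(traj$final_state, "ratios")
  stats::setNames(s / sum(s), traj$labels)
}

#' Within-host competitive dominance in one environment
#'
#' Starts a healthy holobiont (1 C-mol host, 0.5 C-mol of each symbiont) and
#' classifies the outcome: `no_survival` if host growth is nonpositive at the
#' vitality check (day 100), otherwise the label of the symbiont that is
#' numerically more abundant at the dominance horizon (10 years). An exact
#' tie raises an error, surfacing a degenerate configuration.
#'
#' @param env Environmental conditions (named list or [env_conditions()]).
#' @param params A two-symbiont [holo_params()].
#' @param cfg An [experiment_config()].
#' @return List with `outcome` (label or `"no_survival"`), `detail` (winner's
#'   final share of symbiont biomass, NA on no survival) and
#'   `host_limitation` (signed carbon/nitrogen limitation diagnostic of the
#'   host growth synthesizing unit at the end of the run, NA on no survival).
#' @export
competition_outcome <- function(env, params, cfg = experiment_config()) {
  if (n_symbionts(params) != 2)
    stop("competition requires exactly two symbionts", call. = FALSE)
  init <- init_healthy(params, env)
  p1 <- run(init$state, init$fluxes, env, params,
            duration = cfg$vitality_check_day, dt = cfg$dt,
            record_every = cfg$vitality_check_day)
  if (classify_vitality(p1, cfg$vitality_check_day) == "dead")
    return(list(outcome = "no_survival", detail = NA_real_,
                host_limitation = NA_real_))
  p2 <- run(p1$final_state, p1$final_fluxes, env, params,
            duration = cfg$dominance_horizon_d - cfg$vitality_check_day,
            dt = cfg$dt, record_every = cfg$dominance_horizon_d)
  shares <- final_shares(p2)
  if (shares[1] == shares[2])
    stop("exact tie in symbiont abundance at the dominance horizon",
         call. = FALSE)
  lim <- host_limitation(
    structure(list(H = 1, S = attr(p2$final_state, "ratios")),
              class = "holo_state"),
    env, params, p2$final_fluxes)
  list(outcome = names(shares)[which.max(shares)],
       detail = unname(max(shares)), host_limitation = lim)
}

#' Time to competitive exclusion in one environment
#'
#' Starts the eventual winner at 1% of symbiont biomass against the loser at
#' 99% (0.01 and 0.99 C-mol, host 1 C-mol; fluxes at the healthy fixed
#' point), then measures the first time the winner's share reaches the
#' exclusion threshold (99%). Hosts with nonpositive growth at the vitality
#' check are classified `no_survival`; runs that reach the cap without
#' crossing the threshold are `censored`.
#'
#' @param env Environmental conditions.
#' @param params A two-symbiont [holo_params()].
#' @param winner Label of the symbiont started at 1%.
#' @param cfg An [experiment_config()].
#' @return List with `outcome` (`"excluded"`, `"censored"` or
#'   `"no_survival"`) and `time_d` (days to exclusion; NA otherwise).
#' @export
time_to_exclusion <- function(env, params, winner,
                              cfg = experiment_config()) {
  labels <- symbiont_labels(params)
  if (!winner %in% labels)
    stop(sprintf("unknown winner label '%s'", winner), call. = FALSE)
  if (length(labels) != 2)
    stop("exclusion requires exactly two symbionts", call. = FALSE)
  S0 <- ifelse(labels == winner, 0.01, 0.99)
  names(S0) <- labels
  state <- holo_state(1, S0)
  fluxes <- flux_fixed_point(state, env, params, start = "high")
  p1 <- run(state, fluxes, env, params,
            duration = cfg$vitality_check_day, dt = cfg$dt,
            record_every = cfg$vitality_check_day,
            watch_label = winner, watch_share = cfg$exclusion_threshold)
  crossed_early <- !is.na(p1$stopped_time)
  if (crossed_early) {
    # threshold crossed before the vitality check: finish the first 100 days
    # so the death rule of the survey design still applies
    rest <- run(p1$final_state, p1$final_fluxes, env, params,
                duration = cfg$vitality_check_day - p1$stopped_time,
                dt = cfg$dt, record_every = cfg$vitality_check_day)
    vit <- classify_vitality(rest, cfg$vitality_check_day - p1$stopped_time)
  } else {
    vit <- classify_vitality(p1, cfg$vitality_check_day)
  }
  if (vit == "dead")
    return(list(outcome = "no_survival", time_d = NA_real_))
  if (crossed_early)
    return(list(outcome = "excluded", time_d = p1$stopped_time))
  p2 <- run(p1$final_state, p1$final_fluxes, env, params,
            duration = cfg$exclusion_cap_d - cfg$vitality_check_day,
            dt = cfg$dt, record_every = cfg$exclusion_cap_d,
            watch_label = winner, watch_share = cfg$exclusion_threshold)
  if (!is.na(p2$stopped_time))
    list(outcome = "excluded",
         time_d = cfg$vitality_check_day + p2$stopped_time)
  else list(outcome = "censored", time_d = NA_real_)
}

#' Post-bleaching recovery outcome in one environment
#'
#' Two-stage classification of recovery from a bleached start. Stage 1:
#' bleached initialization with the sensitive symbiont alone (1e-4 C-mol
#' total); positive host growth at day 100 gives `recovers_with_sensitive`.
#' Stage 2 (otherwise): bleached initialization with both symbionts (5e-5
#' C-mol each); death at day 100 gives `no_recovery`, else the run continues
#' to the recovery horizon (1000 days) and is labelled by the numerically
#' dominant symbiont: `recovers_with_tolerant` or
#' `recovers_with_sensitive_in_presence_of_tolerant`.
#'
#' @param env Environmental conditions.
#' @param params A [holo_params()] with symbionts labelled `"sensitive"` and
#'   `"tolerant"`.
#' @param cfg An [experiment_config()].
#' @return List with `outcome` (one of the four labels above) and `detail`
#'   (sensitive share of symbiont biomass at the end of the classifying run;
#'   NA for `no_recovery`).
#' @export
recovery_outcome <- function(env, params, cfg = experiment_config()) {
  labels <- symbiont_labels(params)
  if (!all(c("sensitive", "tolerant") %in% labels) || length(labels) != 2)
    stop("recovery requires symbionts labelled 'sensitive' and 'tolerant'",
         call. = FALSE)
  solo <- holo_params(params$host, list(params$symbionts[["sensitive"]]))
  b1 <- init_bleached(solo, env, total_symbiont0 = 1e-4)
  t1 <- run(b1$state, b1$fluxes, env, solo,
            duration = cfg$vitality_check_day, dt = cfg$dt,
            record_every = cfg$vitality_check_day)
  if (classify_vitality(t1, cfg$vitality_check_day) == "alive")
    return(list(outcome = "recovers_with_sensitive", detail = 1))
  b2 <- init_bleached(params, env, total_symbiont0 = 1e-4)
  t2 <- run(b2$state, b2$fluxes, env, params,
            duration = cfg$vitality_check_day, dt = cfg$dt,
            record_every = cfg$vitality_check_day)
  if (classify_vitality(t2, cfg$vitality_check_day) == "dead")
    return(list(outcome = "no_recovery", detail = NA_real_))
  t3 <- run(t2$final_state, t2$final_fluxes, env, params,
            duration = cfg$recovery_horizon_d - cfg$vitality_check_day,
            dt = cfg$dt, record_every = cfg$recovery_horizon_d)
  shares <- final_shares(t3)
  if (shares["sensitive"] == shares["tolerant"])
    stop("exact tie in symbiont abundance at the recovery horizon",
         call. = FALSE)
  out <- if (shares["tolerant"] > shares["sensitive"])
    "recovers_with_tolerant"
  else "recovers_with_sensitive_in_presence_of_tolerant"
  list(outcome = out, detail = unname(shares["sensitive"]))
}

#' Run an experiment over a table of environments
#'
#' Applies one of the three experiments ([competition_outcome()],
#' [time_to_exclusion()] after a dominance run, or [recovery_outcome()]) to
#' every row of an environment table. For the exclusion experiment the
#' eventual winner is determined per environment by a dominance run first,
#' mirroring the survey design.
#'
#' @param envs Data frame with columns `light`, `din`, `prey` (e.g. from
#'   [sample_environments()]).
#' @param experiment One of `"competition"`, `"exclusion"`, `"recovery"`.
#' @param params A [holo_params()].
#' @param cfg An [experiment_config()].
#' @param progress_every Emit a progress message every this many
#'   environments (0 suppresses messages).
#' @return Data frame with columns `light`, `din`, `prey`, `outcome`,
#'   `detail`, plus `host_limitation` (competition) or `winner` (exclusion).
#' @export
run_survey <- function(envs, experiment = c("competition", "exclusion",
                                            "recovery"),
                       params = default_params(),
                       cfg = experiment_config(), progress_every = 100) {
  experiment <- match.arg(experiment)
  n <- nrow(envs)
  out <- data.frame(light = envs$light, din = envs$din, prey = envs$prey,
                    outcome = character(n), detail = rep(NA_real_, n))
  if (experiment == "competition")
    out$host_limitation <- rep(NA_real_, n)
  if (experiment == "exclusion") out$winner <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    env <- list(light = envs$light[i], din = envs$din[i],
                prey = envs$prey[i])
    if (experiment == "competition") {
      r <- competition_outcome(env, params, cfg)
      out$outcome[i] <- r$outcome
      out$detail[i] <- r$detail
      out$host_limitation[i] <- r$host_limitation
    } else if (experiment == "exclusion") {
      dom <- competition_outcome(env, params, cfg)
      if (dom$outcome == "no_survival") {
        out$outcome[i] <- "no_survival"
      } else {
        r <- time_to_exclusion(env, params, winner = dom$outcome, cfg)
        out$outcome[i] <- r$outcome
        out$detail[i] <- r$time_d
        out$winner[i] <- dom$outcome
      }
    } else {
      r <- recovery_outcome(env, params, cfg)
      out$outcome[i] <- r$outcome
      out$detail[i] <- r$detail
    }
    if (progress_every > 0 && i %% progress_every == 0)
      message(sprintf("%s survey: %d / %d environments", experiment, i, n))
  }
  out
}
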