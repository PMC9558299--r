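#' One explicit Euler step of the biomass equations
#'
#' Updates host and symbiont biomasses by the multiplicative Euler rule
#' `S_i' = S_i (1 + (j_SGi - j_STi) dt)` and
#' `H' = H (1 + (j_HG - j_HT) dt)`, flooring biomasses at zero.
#'
#' @param state A [holo_state()].
#' @param fluxes A [flux_state()] evaluated at `state`.
#' @param dt Step size in days; positive.
#' @return The updated state (class `holo_state`). A host biomass driven to
#'   zero marks holobiont death; downstream code treats it as such.
#' @export
euler_step <- function(state, fluxes, dt) {
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  S_new <- pmax(state$S * (1 + (fluxes$sym$j_SG - fluxes$sym$j_ST) * dt), 0)
  H_new <- max(state$H * (1 + (fluxes$host$j_HG - fluxes$host$j_HT) * dt), 0)
  structure(list(H = H_new, S = S_new), class = "holo_state")
}

host_param_order <- c("n_NH", "n_NX", "j_HT0", "sigma_NH", "sigma_CH",
                      "j_Xm", "K_X", "j_Nm", "K_N", "k_CO2", "j_HGm", "y_C")
sym_param_order <- c("n_NS", "j_ST0", "sigma_NS", "sigma_CS", "y_CL",
                     "a_star", "k_NPQ", "k_ROS", "j_CPm", "j_SGm", "b")

host_param_vector <- function(params) {
  unlist(params$host[host_param_order])
}

sym_param_matrix <- function(params) {
  vapply(params$symbionts,
         function(sp) unlist(sp[sym_param_order]),
         numeric(length(sym_param_order)))
}

symf_matrix <- function(fluxes, n) {
  m <- vapply(sym_flux_names, function(f) fluxes$sym[[f]], numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, sym_flux_names))
  m
}

#' Integrate the holobiont model
#'
#' Alternates flux evaluation (with one-step lag, see [compute_fluxes()]) and
#' the explicit Euler biomass update for `duration / dt` steps under constant
#' environmental conditions. Internally the integrator carries the log host
#' biomass and the symbiont:host biomass ratios; since every specific rate of
#' the model depends only on those ratios, this is exactly the multiplicative
#' Euler update of [euler_step()] while remaining finite during years of
#' sustained exponential growth.
#'
#' The recorded fluxes at time `t` are the ones applied over the step ending
#' at `t`; row one holds the initial condition and its initializing fluxes.
#'
#' @param state0 Initial [holo_state()].
#' @param fluxes0 Initializing [flux_state()] (from [init_healthy()],
#'   [init_bleached()], or a previous trajectory's `final_fluxes`).
#' @param env Environmental conditions ([env_conditions()] or named list).
#' @param params A [holo_params()].
#' @param duration Simulated time, days.
#' @param dt Step size, days (default 0.1).
#' @param record_every Recording interval, days (default 1); the final step is
#'   always recorded.
#' @param engine `"cpp"` (compiled loop, default) or `"R"` (pure-R reference
#'   evaluator built on [compute_fluxes()]).
#' @param watch_label Optional symbiont label to monitor; the run stops early
#'   when that symbiont's share of total symbiont biomass first reaches
#'   `watch_share`.
#' @param watch_share Share threshold in (0, 1] for `watch_label`.
#' @return An object of class `holo_trajectory`: list with `frame` (one row
#'   per recorded time: `time_d`, `host_biomass`, `log_host_biomass`,
#'   `symbiont_biomass_<label>`, host fluxes, and per-symbiont fluxes suffixed
#'   by label), `labels`, `dt`, `env`, `stopped_time` (NA unless the watch
#'   tripped), and `final_state` / `final_fluxes` for chaining runs.
#' @export
run <- function(state0, fluxes0, env, params, duration, dt = 0.1,
                record_every = 1, engine = c("cpp", "R"),
                watch_label = NULL, watch_share = NULL) {
  engine <- match.arg(engine)
  env <- as_env_conditions(env)
  if (duration < 0) stop("`duration` must be nonnegative", call. = FALSE)
  if (record_every < dt) record_every <- dt
  n <- n_symbionts(params)
  labels <- symbiont_labels(params)
  if (length(state0$S) != n)
    stop("state has a different number of symbionts than the parameter set",
         call. = FALSE)

  if (!is.null(attr(state0, "log_H"))) {
    lH0 <- attr(state0, "log_H")
    s0 <- attr(state0, "ratios")
  } else {
    lH0 <- log(state0$H)
    s0 <- state0$S / state0$H
  }
  n_steps <- as.integer(round(duration / dt))
  stride <- max(1L, as.integer(round(record_every / dt)))
  watch <- -1L
  wshare <- 1
  if (!is.null(watch_label)) {
    watch <- match(watch_label, labels) - 1L
    if (is.na(watch)) stop("unknown `watch_label`", call. = FALSE)
    stopifnot(is.numeric(watch_share), watch_share > 0, watch_share <= 1)
    wshare <- watch_share
  }

  hostf0 <- unlist(fluxes0$host[host_flux_names])
  symf0 <- symf_matrix(fluxes0, n)

  res <- if (engine == "cpp") {
    .run_loop_cpp(lH0, s0, hostf0, symf0,
                  env$light, env$din, env$prey,
                  host_param_vector(params), sym_param_matrix(params),
                  dt, n_steps, stride, watch, wshare)
  } else {
    run_loop_r(lH0, s0, fluxes0, env, params, dt, n_steps, stride,
               watch, wshare)
  }

  mat <- res$mat
  lH <- mat[, 2]
  s_cols <- mat[, 2 + seq_len(n), drop = FALSE]
  H <- exp(lH)
  frame <- data.frame(time_d = mat[, 1], host_biomass = H,
                      log_host_biomass = lH)
  for (i in seq_len(n))
    frame[[paste0("symbiont_biomass_", labels[i])]] <- s_cols[, i] * H
  off <- 2 + n
  for (f in seq_along(host_flux_names))
    frame[[host_flux_names[f]]] <- mat[, off + f]
  off <- off + length(host_flux_names)
  for (i in seq_len(n))
    for (f in seq_along(sym_flux_names))
      frame[[paste0(sym_flux_names[f], "_", labels[i])]] <-
        mat[, off + (i - 1) * length(sym_flux_names) + f]

  last <- nrow(mat)
  final_s <- s_cols[last, ]
  final_state <- structure(list(H = exp(lH[last]),
                                S = final_s * exp(lH[last])),
                           class = "holo_state",
                           log_H = lH[last], ratios = final_s)
  sym_final <- lapply(seq_along(sym_flux_names), function(f) {
    vapply(seq_len(n), function(i) {
      mat[last, off + (i - 1) * length(sym_flux_names) + f]
    }, numeric(1))
  })
  names(sym_final) <- sym_flux_names
  host_final <- as.list(mat[last, (2 + n) + seq_along(host_flux_names)])
  names(host_final) <- host_flux_names
  final_fluxes <- flux_state(host = host_final, sym = sym_final)

  structure(list(frame = frame, labels = labels, dt = dt, env = env,
                 stopped_time = if (res$stopped_time < 0) NA_real_
                                else res$stopped_time,
                 final_state = final_state, final_fluxes = final_fluxes),
            class = "holo_trajectory")
}

# Pure-R reference loop; mirrors the compiled engine step for step. The model
# is invariant to joint rescaling of biomasses, so fluxes are evaluated at
# host biomass 1 and symbiont biomasses equal to the current ratios.
run_loop_r <- function(lH0, s0, fluxes0, env, params, dt, n_steps, stride,
                       watch, wshare) {
  n <- length(s0)
  ncols <- 2 + n + length(host_flux_names) + length(sym_flux_names) * n
  rows <- vector("list", n_steps %/% stride + 3)
  f <- fluxes0
  lH <- lH0
  s <- s0
  row_of <- function(t) c(t, lH, s, unlist(f$host[host_flux_names]),
                          as.vector(t(symf_matrix(f, n))))
  n_rec <- 1L
  rows[[1]] <- row_of(0)
  stopped_time <- -1
  for (k in seq_len(n_steps)) {
    f <- compute_fluxes(structure(list(H = 1, S = s), class = "holo_state"),
                        env, params, f)
    fH <- 1 + (f$host$j_HG - f$host$j_HT) * dt
    if (fH <= 0)
      stop(sprintf("host biomass became nonpositive at day %g", k * dt),
           call. = FALSE)
    fS <- 1 + (f$sym$j_SG - f$sym$j_ST) * dt
    s <- ifelse(fS > 0, s * fS / fH, 0)
    lH <- lH + log(fH)
    if (any(!is.finite(s)) || is.nan(lH))
      stop(sprintf("state became non-finite at day %g", k * dt),
           call. = FALSE)
    t <- k * dt
    tripped <- watch >= 0 && sum(s) > 0 && s[watch + 1] / sum(s) >= wshare
    if (tripped) stopped_time <- t
    if (tripped || k == n_steps || k %% stride == 0) {
      n_rec <- n_rec + 1L
      rows[[n_rec]] <- row_of(t)
    }
    if (tripped) break
  }
  mat <- do.call(rbind, rows[seq_len(n_rec)])
  dim(mat) <- c(n_rec, ncols)
  list(mat = mat, stopped_time = stopped_time)
}

#' @export
print.holo_trajectory <- function(x, ...) {
  cat(sprintf(
    "<holo_trajectory> %d symbiont(s) [%s], %d records over %.4g d (dt = %g)\n",
    length(x$labels), paste(x$labels, collapse = ", "),
    nrow(x$frame), max(x$frame$time_d), x$dt))
  if (!is.na(x$stopped_time))
    cat(sprintf("  stopped early at day %.4g (share watch)\n",
                x$stopped_time))
  invisible(x)
}

#' @export
as.data.frame.holo_trajectory <- function(x, ...) x$frame

#' Host vitality at a checkpoint
#'
#' A holobiont is classified dead when the host specific growth rate
#' `j_HG - j_HT` is zero or negative at the recorded time nearest the
#' checkpoint (default day 100).
#'
#' @param traj A `holo_trajectory`.
#' @param t_check Checkpoint time in days.
#' @return `"alive"` or `"dead"`.
#' @export
classify_vitality <- function(traj, t_check = 100) {
  fr <- traj$frame
  if (t_check > max(fr$time_d) + traj$dt / 2)
    stop("`t_check` lies beyond the trajectory", call. = FALSE)
  i <- which.min(abs(fr$time_d - t_check))
  if (fr$j_HG[i] - fr$j_HT[i] <= 0) "dead" else "alive"
}

#' Healthy initialization
#'
#' Initializes the holobiont in the healthy, unbleached basin: biomasses from
#' the arguments (defaults: host 1 C-mol, 0.5 C-mol per symbiont) and fluxes
#' set to the self-consistent fixed point of [compute_fluxes()] at that state
#' under the run's own environment, approached from the healthy branch (see
#' [flux_fixed_point()]).
#'
#' @param params A [holo_params()].
#' @param env Environmental conditions.
#' @param host0 Initial host biomass, C-mol.
#' @param symbiont0 Initial biomass per symbiont, C-mol (scalar recycled or
#'   vector, one per symbiont).
#' @return List with components `state` and `fluxes`.
#' @export
init_healthy <- function(params, env, host0 = 1, symbiont0 = 0.5) {
  n <- n_symbionts(params)
  S <- rep_len(symbiont0, n)
  names(S) <- symbiont_labels(params)
  state <- holo_state(host0, S)
  fluxes <- flux_fixed_point(state, env, params, start = "high")
  list(state = state, fluxes = fluxes)
}

#' Bleached initialization
#'
#' Initializes the holobiont in the bleached basin by the slow--fast
#' anchoring scheme: a very small total symbiont biomass (default 1e-4 C-mol
#' against 1 C-mol of host) and fluxes derived in dependency order with the
#' host biomass formation rate and symbiont photosynthesis rate pinned to
#' zero. With those anchors the symbiont growth and carbon-sharing fluxes are
#' zero, all absorbed light is in excess (`j_eL = j_L`), surplus prey carbon
#' powers the CCM (`j_eC = j_X`), and the remaining fluxes follow directly.
#'
#' @param params A [holo_params()].
#' @param env Environmental conditions.
#' @param host0 Initial host biomass, C-mol.
#' @param total_symbiont0 Total initial symbiont biomass, C-mol.
#' @param split Proportions of `total_symbiont0` per symbiont (sums to 1);
#'   default equal shares.
#' @return List with components `state` and `fluxes`.
#' @export
init_bleached <- function(params, env, host0 = 1, total_symbiont0 = 1e-4,
                          split = NULL) {
  env <- as_env_conditions(env)
  n <- n_symbionts(params)
  if (is.null(split)) split <- rep(1 / n, n)
  if (length(split) != n || abs(sum(split) - 1) > 1e-12 || any(split < 0))
    stop("`split` must be nonnegative proportions summing to 1",
         call. = FALSE)
  if (total_symbiont0 <= 0)
    stop("`total_symbiont0` must be positive", call. = FALSE)
  S <- split * total_symbiont0
  names(S) <- symbiont_labels(params)
  state <- holo_state(host0, S)
  hp <- params$host

  j_X <- hp$j_Xm * env$prey / (env$prey + hp$K_X)
  j_N <- hp$j_Nm * env$din / (env$din + hp$K_N)
  A <- light_amplification(sum(S), host0)
  j_HT <- hp$j_HT0
  r_NH <- hp$sigma_NH * hp$n_NH * j_HT
  j_HG <- 0
  rho_N <- j_N + hp$n_NX * j_X + r_NH
  j_eC <- j_X
  j_CO2 <- hp$k_CO2 * j_eC
  r_CH <- hp$sigma_CH * j_HT

  syms <- params$symbionts
  j_L <- A * env$light * unname(vapply(syms, `[[`, numeric(1), "a_star"))
  r_CS <- j_NPQ <- c_ROS <- r_NS <- j_ST <- numeric(n)
  for (i in seq_len(n)) {
    sp <- syms[[i]]
    r_CS[i] <- sp$sigma_CS * sp$j_ST0
    j_NPQ[i] <- su_single(sp$k_NPQ, j_L[i])
    c_ROS[i] <- 1 + max(j_L[i] - j_NPQ[i], 0) / sp$k_ROS
    r_NS[i] <- sp$sigma_NS * sp$n_NS * sp$j_ST0
    j_ST[i] <- sp$j_ST0 * (1 + sp$b * (c_ROS[i] - 1))
  }
  fluxes <- flux_state(
    host = list(j_X = j_X, j_N = j_N, j_HG = j_HG, j_HT = j_HT, r_NH = r_NH,
                rho_N = rho_N, j_eC = j_eC, j_CO2 = j_CO2, r_CH = r_CH,
                A = A),
    sym = list(j_L = j_L, r_CS = r_CS, j_CP = numeric(n), j_eL = j_L,
               j_NPQ = j_NPQ, c_ROS = c_ROS, r_NS = r_NS,
               j_SG = numeric(n), rho_C = numeric(n), j_ST = j_ST)
  )
  list(state = state, fluxes = fluxes)
}
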