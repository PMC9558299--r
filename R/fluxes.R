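#' Holobiont state
#'
#' The slow variables of the model: host biomass and per-symbiont biomass.
#'
#' @param host_biomass Host biomass H, C-mol; strictly positive.
#' @param symbiont_biomass Numeric vector of symbiont biomasses S_i, C-mol;
#'   nonnegative, named by symbiont label (names optional, filled from the
#'   parameter set where needed).
#' @return An object of class `holo_state`.
#' @export
holo_state <- function(host_biomass, symbiont_biomass) {
  if (!is.finite(host_biomass) || host_biomass <= 0)
    stop("`host_biomass` must be finite and positive", call. = FALSE)
  if (any(!is.finite(symbiont_biomass)) || any(symbiont_biomass < 0))
    stop("`symbiont_biomass` must be finite and nonnegative", call. = FALSE)
  structure(list(H = host_biomass, S = symbiont_biomass),
            class = "holo_state")
}

host_flux_names <- c("j_X", "j_N", "j_HG", "j_HT", "r_NH", "rho_N",
                     "j_eC", "j_CO2", "r_CH", "A")
sym_flux_names <- c("j_L", "r_CS", "j_CP", "j_eL", "j_NPQ", "c_ROS",
                    "r_NS", "j_SG", "rho_C", "j_ST")

#' Construct a flux state
#'
#' Container for all specific rates of the model: ten host-level fluxes and
#' ten per-symbiont fluxes. Used both as the model output at a time point and
#' as the lagged ("fast variable") input that breaks the algebraic loops of
#' the synthesizing-unit network.
#'
#' @param host Named list/vector of host-level fluxes
#'   (`j_X, j_N, j_HG, j_HT, r_NH, rho_N, j_eC, j_CO2, r_CH, A`).
#' @param sym Named list of numeric vectors (one entry per symbiont) for
#'   `j_L, r_CS, j_CP, j_eL, j_NPQ, c_ROS, r_NS, j_SG, rho_C, j_ST`.
#' @return An object of class `flux_state`.
#' @export
flux_state <- function(host, sym) {
  host <- as.list(host)[host_flux_names]
  sym <- as.list(sym)[sym_flux_names]
  if (any(vapply(host, is.null, logical(1))) ||
      any(vapply(sym, is.null, logical(1))))
    stop("flux state is missing required components", call. = FALSE)
  structure(list(host = host, sym = sym), class = "flux_state")
}

flux_vector <- function(fluxes) {
  c(unlist(fluxes$host), unlist(fluxes$sym))
}

#' Evaluate all model fluxes at a state
#'
#' Evaluates the full synthesizing-unit network in dependency order. The
#' network is cyclic (shared carbon feeds host growth, which sets the shared
#' nitrogen that feeds symbiont growth, which sets the shared carbon; and
#' photosynthesis depends on ROS, which depends on excess light, which depends
#' on photosynthesis), so a `lagged` flux state supplies the previous step's
#' `rho_C`, `j_SG` and `c_ROS` where a cycle would otherwise occur. All other
#' fluxes are computed fresh from the current state and environment.
#'
#' Conventions: the CCM flux `j_eC` and the excess-light flux `j_eL` are
#' clamped at zero (neither mechanism runs in reverse; transient negatives
#' only arise from the lag). With zero total symbiont biomass the per-C-mol
#' shares of host nitrogen and CO2 are defined as zero.
#'
#' @param state A [holo_state()].
#' @param env An [env_conditions()] (or named list with `light`, `din`,
#'   `prey`).
#' @param params A [holo_params()].
#' @param lagged A [flux_state()] carrying the previous step's fluxes.
#' @return A [flux_state()].
#' @export
compute_fluxes <- function(state, env, params, lagged) {
  env <- as_env_conditions(env)
  hp <- params$host
  syms <- params$symbionts
  n <- length(syms)
  H <- state$H
  S <- state$S
  if (length(S) != n)
    stop("state has a different number of symbionts than the parameter set",
         call. = FALSE)
  lag_rho_C <- lagged$sym$rho_C
  lag_j_SG <- lagged$sym$j_SG
  lag_c_ROS <- lagged$sym$c_ROS
  if (any(c(lag_rho_C, lag_j_SG) < 0) || any(lag_c_ROS < 1))
    stop("lagged fluxes must be nonnegative (and c_ROS >= 1)", call. = FALSE)

  Stot <- sum(S)
  s <- S / H

  # host uptake (Michaelis-Menten)
  j_X <- hp$j_Xm * env$prey / (env$prey + hp$K_X)
  j_N <- hp$j_Nm * env$din / (env$din + hp$K_N)

  # light field
  A <- light_amplification(Stot, H)
  a_star <- unname(vapply(syms, `[[`, numeric(1), "a_star"))
  j_L <- A * env$light * a_star

  # host maintenance and nitrogen recycling
  j_HT <- hp$j_HT0
  r_NH <- hp$sigma_NH * hp$n_NH * j_HT

  # host growth from shared carbon (lagged) + prey carbon, and nitrogen
  carbon_in <- hp$y_C * (sum(lag_rho_C * s) + j_X)
  nitrogen_in <- (j_N + hp$n_NX * j_X + r_NH) / hp$n_NH
  j_HG <- if (carbon_in > 0 && nitrogen_in > 0)
    su_parallel(hp$j_HGm, carbon_in, nitrogen_in) else 0

  # surplus nitrogen shared with symbionts; surplus carbon powers the CCM
  rho_N <- max(j_N + hp$n_NX * j_X + r_NH - hp$n_NH * j_HG, 0)
  j_eC <- max(j_X + sum(lag_rho_C * s) - j_HG / hp$y_C, 0)
  j_CO2 <- hp$k_CO2 * j_eC
  r_CH <- hp$sigma_CH * (j_HT + (1 - hp$y_C) * j_HG / hp$y_C)

  co2_share <- if (Stot > 0) (j_CO2 + r_CH) * H / Stot else 0
  rhoN_share <- if (Stot > 0) rho_N * H / Stot else 0

  r_CS <- j_CP <- j_eL <- j_NPQ <- c_ROS <- r_NS <- j_SG <- rho_C <-
    j_ST <- numeric(n)
  for (i in seq_len(n)) {
    sp <- syms[[i]]
    r_CS[i] <- sp$sigma_CS * (sp$j_ST0 + (1 - hp$y_C) * lag_j_SG[i] / hp$y_C)
    light_in <- sp$y_CL * j_L[i]
    co2_in <- co2_share + r_CS[i]
    jcp_raw <- if (light_in > 0 && co2_in > 0)
      su_parallel(sp$j_CPm, light_in, co2_in) else 0
    j_CP[i] <- jcp_raw / lag_c_ROS[i]
    j_eL[i] <- max(j_L[i] - j_CP[i] / sp$y_CL, 0)
    j_NPQ[i] <- su_single(sp$k_NPQ, j_eL[i])
    c_ROS[i] <- 1 + max(j_eL[i] - j_NPQ[i], 0) / sp$k_ROS
    r_NS[i] <- sp$sigma_NS * sp$n_NS * sp$j_ST0
    n_in <- (rhoN_share + r_NS[i]) / sp$n_NS
    c_in <- hp$y_C * j_CP[i]
    j_SG[i] <- if (c_in > 0 && n_in > 0)
      su_parallel(sp$j_SGm, c_in, n_in) else 0
    rho_C[i] <- j_CP[i] - j_SG[i] / hp$y_C
    j_ST[i] <- sp$j_ST0 * (1 + sp$b * (c_ROS[i] - 1))
  }

  flux_state(
    host = list(j_X = j_X, j_N = j_N, j_HG = j_HG, j_HT = j_HT, r_NH = r_NH,
                rho_N = rho_N, j_eC = j_eC, j_CO2 = j_CO2, r_CH = r_CH,
                A = A),
    sym = list(j_L = j_L, r_CS = r_CS, j_CP = j_CP, j_eL = j_eL,
               j_NPQ = j_NPQ, c_ROS = c_ROS, r_NS = r_NS, j_SG = j_SG,
               rho_C = rho_C, j_ST = j_ST)
  )
}

#' Self-consistent fluxes at a frozen state
#'
#' Iterates [compute_fluxes()] at a fixed biomass state until the fluxes stop
#' changing, yielding the quasi-steady ("fast subsystem") flux values. Because
#' the flux network is bistable in many environments, the starting point
#' selects the branch: the default `"high"` start (maximal carbon sharing, no
#' ROS) converges to the healthy branch. If plain iteration fails to converge
#' the iteration is retried once with 0.5 damping.
#'
#' @param state A [holo_state()].
#' @param env Environmental conditions.
#' @param params A [holo_params()].
#' @param start Either `"high"` or a [flux_state()] to start from.
#' @param tol Convergence tolerance on the maximum relative flux change.
#' @param max_iter Iteration cap (per attempt).
#' @return A converged [flux_state()].
#' @export
flux_fixed_point <- function(state, env, params, start = "high",
                             tol = 1e-9, max_iter = 100) {
  n <- n_symbionts(params)
  if (identical(start, "high")) {
    j_CPm <- vapply(params$symbionts, `[[`, numeric(1), "j_CPm")
    j_SGm <- vapply(params$symbionts, `[[`, numeric(1), "j_SGm")
    f <- flux_state(
      host = as.list(stats::setNames(rep(0, 10), host_flux_names)),
      sym = list(j_L = rep(0, n), r_CS = rep(0, n), j_CP = j_CPm,
                 j_eL = rep(0, n), j_NPQ = rep(0, n), c_ROS = rep(1, n),
                 r_NS = rep(0, n), j_SG = j_SGm, rho_C = j_CPm,
                 j_ST = rep(0, n))
    )
  } else {
    f <- start
  }
  iterate <- function(f, damping) {
    for (k in seq_len(max_iter)) {
      f_new <- compute_fluxes(state, env, params, f)
      if (damping < 1) {
        v_old <- flux_vector(f); v_new <- flux_vector(f_new)
        v_mix <- damping * v_new + (1 - damping) * v_old
        f_new <- unflatten_fluxes(v_mix, n)
      }
      delta <- max(abs(flux_vector(f_new) - flux_vector(f)) /
                     pmax(abs(flux_vector(f)), 1e-12))
      f <- f_new
      if (delta < tol) return(f)
    }
    NULL
  }
  out <- iterate(f, 1)
  if (is.null(out)) out <- iterate(f, 0.5)
  if (is.null(out))
    stop("flux fixed-point iteration failed to converge", call. = FALSE)
  out
}

unflatten_fluxes <- function(v, n) {
  host <- as.list(v[seq_along(host_flux_names)])
  names(host) <- host_flux_names
  rest <- v[-seq_along(host_flux_names)]
  sym <- lapply(seq_along(sym_flux_names), function(i) {
    unname(rest[((i - 1) * n + 1):(i * n)])
  })
  names(sym) <- sym_flux_names
  flux_state(host = host, sym = sym)
}

#' Host carbon/nitrogen limitation diagnostic
#'
#' Applies the substrate [limitation_index()] to the host growth synthesizing
#' unit: substrate 1 is the carbon input, substrate 2 the nitrogen input.
#' Positive values mean the host is nitrogen-limited, negative values
#' carbon-limited.
#'
#' @param state A [holo_state()].
#' @param env Environmental conditions.
#' @param params A [holo_params()].
#' @param fluxes A self-consistent [flux_state()] at the state.
#' @return Signed limitation index (NA when an input flux is zero).
#' @export
host_limitation <- function(state, env, params, fluxes) {
  env <- as_env_conditions(env)
  hp <- params$host
  s <- state$S / state$H
  carbon_in <- hp$y_C * (sum(fluxes$sym$rho_C * s) + fluxes$host$j_X)
  nitrogen_in <- (fluxes$host$j_N + hp$n_NX * fluxes$host$j_X +
                    fluxes$host$r_NH) / hp$n_NH
  if (carbon_in <= 0 || nitrogen_in <= 0) return(NA_real_)
  limitation_index(carbon_in, nitrogen_in, hp$j_HGm)
}
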