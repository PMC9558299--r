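# Independent oracles, coded straight from the model equations without
# reusing package internals.

# One-symbiont flux evaluation, straight-line transcription of the flux
# network (lagged rho_C, j_SG, c_ROS supplied explicitly).
oracle_fluxes_one <- function(H, S, L, N, X, lag_rho_C, lag_j_SG, lag_c_ROS,
                              hp = list(n_NH = 0.18, n_NX = 0.2,
                                        j_HT0 = 0.03, sigma_NH = 0.9,
                                        sigma_CH = 0.1, j_Xm = 0.13,
                                        K_X = 1e-6, j_Nm = 0.035,
                                        K_N = 1.5e-6, k_CO2 = 10,
                                        j_HGm = 1, y_C = 0.8),
                              sp = list(n_NS = 0.13, j_ST0 = 0.03,
                                        sigma_NS = 0.9, sigma_CS = 0.9,
                                        y_CL = 0.1, a_star = 1.34,
                                        k_NPQ = 112, k_ROS = 80,
                                        j_CPm = 2.8, j_SGm = 0.25, b = 5)) {
  su1 <- function(m, x) if (x <= 0) 0 else 1 / (1 / m + 1 / x)
  su2 <- function(m, x, y) {
    if (x <= 0 || y <= 0) 0 else 1 / (1 / m + 1 / x + 1 / y - 1 / (x + y))
  }
  j_X <- hp$j_Xm * X / (X + hp$K_X)
  j_N <- hp$j_Nm * N / (N + hp$K_N)
  A <- 1.26 + 1.39 * exp(-6.48 * S / H)
  j_L <- A * L * sp$a_star
  j_HT <- hp$j_HT0
  r_NH <- hp$sigma_NH * hp$n_NH * j_HT
  j_HG <- su2(hp$j_HGm, hp$y_C * (lag_rho_C * S / H + j_X),
              (j_N + hp$n_NX * j_X + r_NH) / hp$n_NH)
  rho_N <- max(j_N + hp$n_NX * j_X + r_NH - hp$n_NH * j_HG, 0)
  j_eC <- max(j_X + lag_rho_C * S / H - j_HG / hp$y_C, 0)
  j_CO2 <- hp$k_CO2 * j_eC
  r_CH <- hp$sigma_CH * (j_HT + (1 - hp$y_C) * j_HG / hp$y_C)
  r_CS <- sp$sigma_CS * (sp$j_ST0 + (1 - hp$y_C) * lag_j_SG / hp$y_C)
  j_CP <- su2(sp$j_CPm, sp$y_CL * j_L,
              (j_CO2 + r_CH) * H / S + r_CS) / lag_c_ROS
  j_eL <- max(j_L - j_CP / sp$y_CL, 0)
  j_NPQ <- su1(sp$k_NPQ, j_eL)
  c_ROS <- 1 + max(j_eL - j_NPQ, 0) / sp$k_ROS
  r_NS <- sp$sigma_NS * sp$n_NS * sp$j_ST0
  j_SG <- su2(sp$j_SGm, hp$y_C * j_CP,
              (rho_N * H / S + r_NS) / sp$n_NS)
  rho_C <- j_CP - j_SG / hp$y_C
  j_ST <- sp$j_ST0 * (1 + sp$b * (c_ROS - 1))
  list(j_X = j_X, j_N = j_N, j_HG = j_HG, j_HT = j_HT, r_NH = r_NH,
       rho_N = rho_N, j_eC = j_eC, j_CO2 = j_CO2, r_CH = r_CH, A = A,
       j_L = j_L, r_CS = r_CS, j_CP = j_CP, j_eL = j_eL, j_NPQ = j_NPQ,
       c_ROS = c_ROS, r_NS = r_NS, j_SG = j_SG, rho_C = rho_C, j_ST = j_ST)
}

# One-symbiont lagged-flux Euler integration built on the oracle above;
# returns host and symbiont biomass plus last fluxes. Independent of the
# package's integrator.
oracle_run_one <- function(H0, S0, L, N, X, f0, dt, n_steps) {
  H <- H0; S <- S0
  lag <- f0
  for (k in seq_len(n_steps)) {
    f <- oracle_fluxes_one(H, S, L, N, X,
                           lag_rho_C = lag$rho_C, lag_j_SG = lag$j_SG,
                           lag_c_ROS = lag$c_ROS)
    S <- max(S * (1 + (f$j_SG - f$j_ST) * dt), 0)
    H <- max(H * (1 + (f$j_HG - f$j_HT) * dt), 0)
    lag <- f
  }
  list(H = H, S = S, fluxes = lag)
}

# Brute-force linear discriminant axes: eigen-decomposition of W^-1 B where
# W is the pooled within-class scatter and B the between-class scatter.
oracle_lda <- function(x, labels) {
  x <- as.matrix(x)
  # condition the scatter matrices by working on unit-sd columns; the
  # generalized eigenproblem transforms back exactly (v = v_scaled / sd)
  d <- apply(x, 2, stats::sd)
  xs <- sweep(x, 2, d, "/")
  labels <- factor(labels)
  grand <- colMeans(xs)
  W <- matrix(0, ncol(xs), ncol(xs))
  B <- matrix(0, ncol(xs), ncol(xs))
  for (lv in levels(labels)) {
    xi <- xs[labels == lv, , drop = FALSE]
    mi <- colMeans(xi)
    W <- W + crossprod(sweep(xi, 2, mi))
    B <- B + nrow(xi) * tcrossprod(mi - grand)
  }
  e <- eigen(solve(W) %*% B)
  keep <- seq_len(min(nlevels(labels) - 1, ncol(x)))
  vals <- Re(e$values[keep])
  vecs <- Re(e$vectors[, keep, drop = FALSE]) / d
  list(values = vals, vectors = vecs,
       proportion_of_trace = vals / sum(vals))
}

default_env <- function(light = 30, din = 1e-7, prey = 1e-7) {
  list(light = light, din = din, prey = prey)
}

flux_as_vector <- function(f) {
  c(unlist(f$host), unlist(f$sym))
}
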