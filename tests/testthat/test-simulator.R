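params2 <- default_params()

test_that("euler_step applies the multiplicative biomass update", {
  env <- default_env()
  init <- init_healthy(params2, env)
  # zero net growth leaves the state unchanged
  f <- init$fluxes
  f$host$j_HG <- f$host$j_HT
  f$sym$j_SG <- f$sym$j_ST
  st <- euler_step(init$state, f, 0.1)
  expect_equal(st$H, init$state$H)
  expect_equal(st$S, init$state$S)
  # one-step arithmetic
  f$host$j_HG <- 0.13
  f$host$j_HT <- 0.03
  expect_equal(euler_step(holo_state(1, c(0.5, 0.5)), f, 0.1)$H, 1.01)
  expect_error(euler_step(init$state, f, -1), "positive")
})

test_that("halving dt shows first-order consistency (Richardson)", {
  env <- default_env(25, 5e-7, 2e-7)
  init <- init_healthy(params2, env)
  end_H <- function(dt) {
    tr <- run(init$state, init$fluxes, env, params2, duration = 10,
              dt = dt, record_every = 10)
    log(tr$final_state$H)
  }
  e1 <- abs(end_H(0.1) - end_H(0.025))
  e2 <- abs(end_H(0.05) - end_H(0.025))
  # halving the step roughly halves the distance to a refined solution
  expect_lt(e2, 0.8 * e1)
  expect_lt(e1, 1e-2)
})

test_that("zero-duration runs return only the initial condition", {
  env <- default_env()
  init <- init_healthy(params2, env)
  tr <- run(init$state, init$fluxes, env, params2, duration = 0)
  expect_equal(nrow(tr$frame), 1L)
  expect_equal(tr$frame$time_d, 0)
  expect_equal(tr$frame$host_biomass, 1)
})

test_that("compiled and pure-R engines agree step for step", {
  env <- default_env(35, 1e-6, 2e-7)
  init <- init_healthy(params2, env)
  a <- run(init$state, init$fluxes, env, params2, duration = 30,
           engine = "cpp")
  b <- run(init$state, init$fluxes, env, params2, duration = 30,
           engine = "R")
  expect_equal(a$frame, b$frame, tolerance = 1e-13)
})

test_that("trajectories are deterministic and biomasses stay nonnegative", {
  env <- default_env(45, 1e-6, 3e-7)
  init <- init_healthy(params2, env)
  a <- run(init$state, init$fluxes, env, params2, duration = 200)
  b <- run(init$state, init$fluxes, env, params2, duration = 200)
  expect_identical(a$frame, b$frame)
  expect_true(all(a$frame$host_biomass > 0))
  expect_true(all(a$frame$symbiont_biomass_sensitive >= 0))
  expect_true(all(a$frame$symbiont_biomass_tolerant >= 0))
})

test_that("splitting a symbiont population does not change the dynamics", {
  # two identical-parameter symbionts at biomass s each behave as one
  # symbiont at biomass 2s
  twin <- holo_params(host_params(),
                      list(symbiont_params("sensitive"),
                           symbiont_params("s2", k_ROS = 80, j_CPm = 2.8,
                                           j_SGm = 0.25)))
  single <- holo_params(host_params(), list("sensitive"))
  env <- default_env(30, 5e-7, 2e-7)
  i2 <- init_healthy(twin, env, symbiont0 = 0.25)
  i1 <- init_healthy(single, env, symbiont0 = 0.5)
  t2 <- run(i2$state, i2$fluxes, env, twin, duration = 150)
  t1 <- run(i1$state, i1$fluxes, env, single, duration = 150)
  expect_equal(t2$frame$host_biomass, t1$frame$host_biomass,
               tolerance = 1e-10)
  tot2 <- t2$frame$symbiont_biomass_sensitive +
    t2$frame$symbiont_biomass_s2
  expect_equal(tot2, t1$frame$symbiont_biomass_sensitive,
               tolerance = 1e-10)
})

test_that("multi-symbiont integrator reduces to an independently coded
           one-symbiont evaluator", {
  single <- holo_params(host_params(), list("sensitive"))
  env <- default_env(30, 1e-7, 1e-7)
  init <- init_healthy(single, env, host0 = 1, symbiont0 = 0.5)
  tr <- run(init$state, init$fluxes, env, single, duration = 50,
            record_every = 50)
  f0 <- list(rho_C = init$fluxes$sym$rho_C, j_SG = init$fluxes$sym$j_SG,
             c_ROS = init$fluxes$sym$c_ROS)
  o <- oracle_run_one(1, 0.5, 30, 1e-7, 1e-7, f0, dt = 0.1, n_steps = 500)
  expect_equal(tr$final_state$H, o$H, tolerance = 1e-10)
  expect_equal(unname(tr$final_state$S), o$S, tolerance = 1e-10)
  expect_equal(tr$final_fluxes$sym$j_CP, o$fluxes$j_CP, tolerance = 1e-10)
})

test_that("a symbiont started at zero biomass leaves the rest unchanged", {
  env <- default_env(20, 1e-6, 2e-7)
  single <- holo_params(host_params(), list("sensitive"))
  i1 <- init_healthy(single, env, symbiont0 = 0.5)
  st2 <- holo_state(1, c(sensitive = 0.5, tolerant = 0))
  f1 <- i1$fluxes
  # extend the one-symbiont fluxes with zeros for the absent symbiont
  sym2 <- lapply(f1$sym, function(v) c(v, 0))
  sym2$c_ROS[2] <- 1   # lagged c_ROS has baseline 1 even for absent symbionts
  f2 <- flux_state(host = f1$host, sym = sym2)
  t2 <- run(st2, f2, env, params2, duration = 100)
  t1 <- run(i1$state, f1, env, single, duration = 100)
  expect_equal(t2$frame$host_biomass, t1$frame$host_biomass,
               tolerance = 1e-9)
  expect_equal(t2$frame$symbiont_biomass_sensitive,
               t1$frame$symbiont_biomass_sensitive, tolerance = 1e-9)
  expect_true(all(t2$frame$symbiont_biomass_tolerant == 0))
})

test_that("healthy initialization is a self-consistent healthy state", {
  env <- default_env(20, 1e-7, 1e-7)
  init <- init_healthy(params2, env)
  expect_equal(init$state$H, 1)
  expect_equal(unname(init$state$S), c(0.5, 0.5))
  f2 <- compute_fluxes(init$state, env, params2, init$fluxes)
  rel <- abs(flux_as_vector(f2) - flux_as_vector(init$fluxes)) /
    pmax(abs(flux_as_vector(init$fluxes)), 1e-12)
  expect_lt(max(rel), 1e-7)
  # healthy means positive growth from the start
  tr <- run(init$state, init$fluxes, env, params2, duration = 1)
  expect_gt(tr$frame$j_HG[2] - tr$frame$j_HT[2], 0)
})

test_that("bleached initialization pins growth and photosynthesis to zero", {
  env <- default_env(30, 1e-7, 1e-7)
  b <- init_bleached(params2, env)
  expect_equal(b$fluxes$host$j_HG, 0)
  expect_equal(unname(b$fluxes$sym$j_CP), c(0, 0))
  expect_equal(unname(b$state$S), c(5e-5, 5e-5))
  expect_equal(sum(b$state$S), 1e-4)
  # derived fluxes follow the dependency order
  hp <- params2$host
  j_X <- hp$j_Xm * env$prey / (env$prey + hp$K_X)
  expect_equal(b$fluxes$host$j_eC, j_X)
  expect_equal(b$fluxes$host$j_CO2, hp$k_CO2 * j_X)
  expect_equal(unname(b$fluxes$sym$rho_C), c(0, 0))
  expect_equal(unname(b$fluxes$sym$j_eL), unname(b$fluxes$sym$j_L))
  expect_error(init_bleached(params2, env, split = c(0.7, 0.7)), "sum")
})

test_that("vitality is read from the growth rate at the checkpoint", {
  env <- default_env(20, 1e-7, 2e-7)
  init <- init_healthy(params2, env)
  tr <- run(init$state, init$fluxes, env, params2, duration = 100)
  expect_equal(classify_vitality(tr, 100), "alive")
  # bleached start in a hostile environment stays in decline
  hostile <- default_env(55, 1e-5, 0)
  b <- init_bleached(params2, hostile)
  trb <- run(b$state, b$fluxes, hostile, params2, duration = 100)
  expect_equal(classify_vitality(trb, 100), "dead")
  expect_error(classify_vitality(tr, 500), "beyond")
})
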