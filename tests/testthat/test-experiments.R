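params2 <- default_params()

test_that("environment sampling is uniform within ranges and reproducible", {
  r <- env_ranges()
  a <- sample_environments(200, r, seed = 11)
  b <- sample_environments(200, r, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$light >= 5 & a$light <= 60))
  expect_true(all(a$din >= 1e-8 & a$din <= 1e-5))
  expect_true(all(a$prey >= 0 & a$prey <= 4e-7))
  expect_equal(nrow(sample_environments(0)), 0L)
  expect_error(env_ranges(light = c(10, 5)), "range")
})

test_that("competitive dominance follows the known light/nutrient structure", {
  # low-to-moderate light favors the sensitive symbiont
  expect_equal(
    competition_outcome(default_env(10, 1e-7, 2e-7), params2)$outcome,
    "sensitive")
  # high light with low nitrogen and high prey keeps a tolerant symbiosis
  expect_equal(
    competition_outcome(default_env(55, 1e-8, 3.5e-7), params2)$outcome,
    "tolerant")
  # extreme light with high nitrogen and no prey kills the host
  expect_equal(
    competition_outcome(default_env(60, 1e-5, 0), params2)$outcome,
    "no_survival")
})

test_that("dominance switches from sensitive to tolerant exactly once along
           a light transect", {
  lights <- seq(20, 60, by = 4)
  outs <- vapply(lights, function(L)
    competition_outcome(default_env(L, 1e-6, 3e-7), params2)$outcome,
    character(1))
  # pattern: sensitive+, then tolerant+, then possibly no_survival
  runs <- rle(outs)
  expect_true(identical(runs$values, c("sensitive", "tolerant")) ||
                identical(runs$values,
                          c("sensitive", "tolerant", "no_survival")))
})

test_that("time to exclusion honors the threshold, censoring and death
           rules", {
  # winner already at the threshold reaches it immediately
  cfg <- experiment_config()
  env <- default_env(10, 5e-6, 3e-7)
  r <- time_to_exclusion(env, params2, winner = "sensitive", cfg)
  expect_equal(r$outcome, "excluded")
  expect_gt(r$time_d, 100)
  # a lethal environment is excluded from the statistic
  r2 <- time_to_exclusion(default_env(60, 1e-5, 0), params2, "sensitive",
                          cfg)
  expect_equal(r2$outcome, "no_survival")
  expect_error(time_to_exclusion(env, params2, "nope", cfg), "unknown")
  # near the dominance switch, exclusion outlasts a short cap
  slow <- default_env(42, 1e-6, 3e-7)
  cfg_short <- experiment_config(exclusion_cap_d = 2000)
  d <- competition_outcome(slow, params2)$outcome
  r3 <- time_to_exclusion(slow, params2, winner = d, cfg_short)
  expect_equal(r3$outcome, "censored")
})

test_that("exclusion is slowest near the dominance switch along the
           transect", {
  lights <- c(30, 36, 42, 48, 54)
  cfg <- experiment_config(exclusion_cap_d = 9125)
  times <- vapply(lights, function(L) {
    env <- default_env(L, 1e-6, 3e-7)
    d <- competition_outcome(env, params2)$outcome
    if (d == "no_survival") return(NA_real_)
    r <- time_to_exclusion(env, params2, winner = d, cfg)
    if (r$outcome == "censored") cfg$exclusion_cap_d else r$time_d
  }, numeric(1))
  peak <- which.max(times)
  expect_equal(lights[peak], 42)
  expect_true(all(times[peak] >= times, na.rm = TRUE))
})

test_that("recovery classification reproduces the four-way outcome set", {
  # mild light, low nitrogen, abundant prey: the sensitive symbiont alone
  # is enough
  expect_equal(
    recovery_outcome(default_env(10, 1e-8, 3.5e-7), params2)$outcome,
    "recovers_with_sensitive")
  # hostile extreme: no recovery at all
  expect_equal(
    recovery_outcome(default_env(60, 1e-5, 0), params2)$outcome,
    "no_recovery")
  # scanning light along the recovery boundary finds tolerant-assisted
  # recovery just past the sensitive-alone limit
  f <- function(L)
    recovery_outcome(default_env(L, 1e-6, 4e-7), params2)$outcome
  a <- 5; b <- 60
  for (k in 1:16) {
    m <- (a + b) / 2
    if (f(m) == "recovers_with_sensitive") a <- m else b <- m
  }
  above <- f(b + 0.05)
  expect_true(above %in%
                c("recovers_with_tolerant",
                  "recovers_with_sensitive_in_presence_of_tolerant"))
})

test_that("holobionts that die in competition also fail the healthy
           vitality check", {
  env <- default_env(60, 1e-5, 0)
  expect_equal(competition_outcome(env, params2)$outcome, "no_survival")
  init <- init_healthy(params2, env)
  tr <- run(init$state, init$fluxes, env, params2, duration = 100)
  expect_equal(classify_vitality(tr, 100), "dead")
})

test_that("surveys are deterministic, closed-label and carry diagnostics", {
  envs <- sample_environments(12, seed = 3)
  a <- suppressMessages(run_survey(envs, "competition", params2))
  b <- suppressMessages(run_survey(envs, "competition", params2))
  expect_identical(a, b)
  expect_named(a, c("light", "din", "prey", "outcome", "detail",
                    "host_limitation"))
  expect_true(all(a$outcome %in% c("sensitive", "tolerant", "no_survival")))
  expect_equal(nrow(a), 12L)
  expect_true(all(is.na(a$host_limitation[a$outcome == "no_survival"])))
  rec <- suppressMessages(run_survey(envs, "recovery", params2))
  expect_true(all(rec$outcome %in%
                    c("recovers_with_sensitive", "recovers_with_tolerant",
                      "recovers_with_sensitive_in_presence_of_tolerant",
                      "no_recovery")))
  empty <- suppressMessages(run_survey(envs[0, ], "competition", params2))
  expect_equal(nrow(empty), 0L)
})
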