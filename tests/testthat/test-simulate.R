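test_that("default schedule is 180 days over 7 years, 1260 steps", {
  cfg <- simulation_config()
  expect_equal(cfg$total_steps, 1260L)
  expect_error(simulate_agent(list(exposure_pattern = "101",
                                   desert_history = "0000000",
                                   alpha = 0.01), cfg),
               "7 digits")
})

test_that("a daily step consumes healthy food per the situation protocol", {
  cfg <- simulation_config()
  s <- preference_state(v_hat_h = 0.3, alpha = 0.05)
  set.seed(11)
  out <- step_agent(s, gamma = 1, cfg)
  expect_identical(out$record$situation, "healthy_only")
  expect_true(out$record$consumed_healthy)
  expect_equal(out$state$v_hat_h, 0.3 + 0.05 * 0.7)

  out0 <- step_agent(preference_state(alpha = 0.05), gamma = 0, cfg)
  expect_identical(out0$record$situation, "choice")
  expect_false(out0$record$consumed_healthy)
  expect_equal(out0$state$v_hat_h, 0)
  expect_identical(out0$record$servings, integer(1))

  # law of total probability: P(consume) = gamma + (1 - gamma) * v/(1+v)
  v <- 0.8; gamma <- 0.5
  p_expected <- gamma + (1 - gamma) * v / (1 + v)
  set.seed(12)
  consumed <- vapply(1:20000, function(i) {
    step_agent(preference_state(v_hat_h = v, alpha = 0.05), gamma,
               cfg)$record$consumed_healthy
  }, logical(1))
  expect_equal(mean(consumed), p_expected, tolerance = 0.015)
})

test_that("forced-gamma runs match the TD closed form exactly", {
  agent <- list(exposure_pattern = "1111111", desert_history = "0000000",
                alpha = 0.05)
  cfg <- simulation_config(record_every = 1260L)
  traj <- simulate_agent(agent, cfg, seed = 21, gamma_override = 1)
  expect_equal(attr(traj, "v_final"), 1 - 0.95^1260, tolerance = 1e-12)
  expect_lt(attr(traj, "v_final"), 1)

  traj0 <- simulate_agent(agent, cfg, seed = 21, gamma_override = 0)
  expect_equal(attr(traj0, "v_final"), 0)
  expect_equal(attr(traj0, "mean_servings"), 0)
})

test_that("compiled simulation reproduces R-level stepping draw for draw", {
  env <- environment_params(p1 = 0.15, p2 = 0.65, a = 0.25)
  cfg <- simulation_config(days_per_year = 30L, n_years = 7L, env = env,
                           model = serving_model(2.7), record_every = 1L)
  agent <- list(exposure_pattern = "1010001", desert_history = "0110011",
                alpha = 0.05)
  traj <- simulate_agent(agent, cfg, seed = 31)

  set.seed(31)
  s <- preference_state(alpha = 0.05)
  v_seq <- numeric(0); serv_seq <- integer(0); cons_seq <- logical(0)
  ffvp <- strsplit(agent$exposure_pattern, "")[[1]] == "1"
  desert <- strsplit(agent$desert_history, "")[[1]] == "1"
  for (y in 1:7) {
    gamma <- draw_gamma(desert[y], ffvp[y], env)
    for (d in 1:30) {
      out <- step_agent(s, gamma, cfg)
      s <- out$state
      v_seq <- c(v_seq, s$v_hat_h)
      serv_seq <- c(serv_seq, out$record$servings)
      cons_seq <- c(cons_seq, out$record$consumed_healthy)
    }
  }
  expect_equal(traj$v_hat_h, v_seq)
  expect_equal(traj$servings, serv_seq)
  expect_equal(traj$consumed_healthy, cons_seq)
})

test_that("trajectories are monotone in preference with increasing steps", {
  cfg <- simulation_config(record_every = 7L)
  set.seed(41)
  for (i in 1:5) {
    agent <- list(exposure_pattern = paste(rbinom(7, 1, 0.4), collapse = ""),
                  desert_history = paste(rbinom(7, 1, 0.6), collapse = ""),
                  alpha = runif(1, 0.002, 0.05))
    traj <- simulate_agent(agent, cfg, seed = 100 + i)
    expect_true(all(diff(traj$v_hat_h) >= 0))
    expect_true(all(diff(traj$step) > 0))
    expect_lt(attr(traj, "v_final"), 1)
  }
})

test_that("cohort simulation is deterministic and order-independent", {
  cohort <- generate_cohort(cohort_config(
    cell_counts = c(nd_nf = 5L, nd_f = 5L, d_nf = 5L, d_f = 5L), seed = 3))
  cfg <- simulation_config(record_every = 90L, seed = 77)
  full <- simulate_cohort(cohort, cfg)
  again <- simulate_cohort(cohort, cfg)
  expect_identical(full, again)
  # a subset simulated in isolation reproduces its rows of the full run
  sub <- simulate_cohort(cohort[c(8, 2, 15), ], cfg)
  expect_equal(sub$final_states,
               full$final_states[c(8, 2, 15), ], ignore_attr = "row.names")
  # identical agents on the same substream give identical trajectories
  twins <- make_agents("1100000", "1111111", 2)
  twins$agent_id <- c(5L, 5L)
  tw <- simulate_cohort(twins, cfg)
  expect_equal(tw$final_states$v_hat_final[1], tw$final_states$v_hat_final[2])

  empty <- simulate_cohort(cohort[0, ], cfg)
  expect_equal(nrow(empty$final_states), 0L)
  expect_null(empty$trajectories)
})

test_that("larger healthy-situation probability accelerates preference formation", {
  # non-desert never-exposed agents dominate desert never-exposed agents
  nd <- mean_final("0000000", "0000000", n = 500, seed = 42)
  d <- mean_final("0000000", "1111111", n = 500, seed = 42)
  expect_gt(nd["v"], d["v"])

  # early exposure beats the same exposure late (one year, kindergarten vs grade 6)
  early <- mean_final("1000000", "1111111", n = 500)
  late <- mean_final("0000001", "1111111", n = 500)
  expect_gt(early["v"], late["v"])

  # servings rise with the number of exposure years
  s0 <- mean_final("0000000", "1111111", n = 500)["serv"]
  s2 <- mean_final("0001100", "1111111", n = 500)["serv"]
  s7 <- mean_final("1111111", "1111111", n = 500)["serv"]
  expect_lt(s0, s2)
  expect_lt(s2, s7)
})

test_that("daily gamma redraw preserves the yearly interval structure", {
  env <- environment_params(p1 = 0.15, p2 = 0.65, a = 0.25)
  cfg <- simulation_config(days_per_year = 60L, env = env,
                           gamma_redraw = "daily", record_every = 60L)
  agent <- list(exposure_pattern = "1111111", desert_history = "0000000",
                alpha = 0.01)
  traj <- simulate_agent(agent, cfg, seed = 51)
  expect_true(all(diff(traj$v_hat_h) >= 0))
  g <- attr(traj, "gammas")
  expect_true(all(g > 0.15 + 0.25 & g <= 1))
})
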