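test_that("Welch t from summary cells agrees with t.test on raw data", {
  expect_equal(welch_t(50, 3, 1, 60, 3, 2)$t, 0)
  set.seed(61)
  x <- rnorm(40, 2, 0.5); y <- rnorm(75, 2.4, 1.3)
  ours <- welch_t(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
  ref <- t.test(x, y)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(welch_t(10, 1, 0, 10, 2, 0), "both standard deviations")
  expect_error(welch_t(1, 1, 1, 10, 2, 1), "n1")
})

test_that("Welch t reproduces the published group-contrast statistics", {
  for (cell in printed_cells) {
    res <- welch_t(cell$n1, cell$m1, cell$s1, cell$n2, cell$m2, cell$s2)
    expect_lt(abs(res$t - cell$t), 0.5)
    expect_lt(res$p, 0.001)
  }
})

test_that("the effect table partitions the cohort and computes cell contrasts", {
  # hand-built final states with known group means
  fs <- data.frame(
    agent_id = 1:12,
    exposure_pattern = rep(c("0000000", "1100000"), 6),
    desert_history = rep(c("0000000", "1111111"), each = 6),
    mean_servings = c(2, 3, 2, 3, 2.2, 3.2,   1, 2, 1, 2, 1.3, 2.3),
    stringsAsFactors = FALSE)
  tab <- effect_table(fs)
  expect_identical(tab$group, c("never_desert", "ever_desert", "total"))
  expect_equal(tab$n_unexposed + tab$n_exposed, c(6, 6, 12))
  nd <- tab[tab$group == "never_desert", ]
  expect_equal(nd$effect, mean(c(3, 3, 3.2)) - mean(c(2, 2, 2.2)))
  expect_true(all(is.finite(tab$t)))

  # all agents in one cell: other cells empty, no crash
  one <- fs[fs$desert_history == "0000000" & fs$exposure_pattern == "0000000", ]
  tab1 <- effect_table(one)
  expect_equal(tab1$n_exposed, c(0, 0, 0))
  expect_true(all(is.na(tab1$effect)))
})

test_that("simulated FFVP effect is larger inside food deserts", {
  cells <- c(nd_nf = 300L, nd_f = 300L, d_nf = 300L, d_f = 300L)
  cohort <- generate_cohort(cohort_config(cell_counts = cells, seed = 5))
  cfg <- simulation_config(record_every = 100000L, seed = 6)
  fs <- simulate_cohort(cohort, cfg, return_trajectories = FALSE)$final_states
  tab <- effect_table(fs)
  eff <- setNames(tab$effect, tab$group)
  expect_gt(eff["ever_desert"], eff["never_desert"])
  expect_gt(eff["never_desert"], 0)
  expect_true(all(tab$p < 0.001))
})

test_that("pattern summaries order by exposure years and track servings", {
  fs <- data.frame(agent_id = 1:4,
                   exposure_pattern = c("0000000", "0000000", "1110000", "0000001"),
                   desert_history = "0000000",
                   v_hat_final = c(0.5, 0.6, 0.9, 0.7),
                   mean_servings = c(2, 2.2, 3, 2.5),
                   stringsAsFactors = FALSE)
  ps <- pattern_summary(fs)
  expect_identical(ps$exposure_pattern, c("0000000", "0000001", "1110000"))
  expect_equal(ps$n, c(2L, 1L, 1L))
  expect_equal(ps$mean_servings[1], 2.1)

  # positive association between exposure years and servings at defaults
  cells <- c(nd_nf = 0L, nd_f = 400L, d_nf = 100L, d_f = 400L)
  cohort <- generate_cohort(cohort_config(cell_counts = cells, seed = 15))
  cfg <- simulation_config(record_every = 100000L, seed = 16)
  fs2 <- simulate_cohort(cohort, cfg, return_trajectories = FALSE)$final_states
  ps2 <- pattern_summary(fs2)
  rho <- cor(ps2$n_years_exposed, ps2$mean_servings, method = "spearman")
  expect_gt(rho, 0)
})

test_that("trajectory panels average the requested patterns with references", {
  cohort <- rbind(make_agents("1111111", "1111111", 40),
                  make_agents("0000000", "1111111", 40),
                  make_agents("1000000", "1111111", 40))
  cohort$agent_id <- seq_len(nrow(cohort))
  cfg <- simulation_config(record_every = 63L, seed = 8)
  sim <- simulate_cohort(cohort, cfg)
  panel <- trajectory_panel(sim$trajectories, cohort, "1000000")
  expect_setequal(unique(panel$exposure_pattern),
                  c("0000000", "1000000", "1111111"))
  # full exposure dominates no exposure at every recorded step
  full <- panel$mean_v_hat[panel$exposure_pattern == "1111111"]
  none <- panel$mean_v_hat[panel$exposure_pattern == "0000000"]
  expect_true(all(full >= none))
  expect_error(trajectory_panel(sim$trajectories, cohort, "0101010"),
               "not present in cohort")

  # single-agent panel equals that agent's own trajectory
  solo <- cohort[1, ]
  sim1 <- simulate_cohort(solo, cfg)
  p1 <- trajectory_panel(sim1$trajectories, solo)
  expect_equal(p1$mean_v_hat, sim1$trajectories$v_hat_h)
})
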