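test_that("TD update moves preference toward palatability and never back", {
  s <- preference_state(alpha = 0.1)
  expect_equal(tdl_update(s)$v_hat_h, 0.1)

  # fixed point: once perceived valuation equals palatability it stays there
  s <- preference_state(v_hat_h = 0.5, alpha = 0.5)
  expect_equal(tdl_update(s, palatability(beta_h = 0.5))$v_hat_h, 0.5)

  # closed form after n consecutive updates: beta_h * (1 - (1 - alpha)^n)
  for (alpha in c(0.05, 0.0042, 0.3)) {
    s <- preference_state(alpha = alpha)
    for (i in 1:45) s <- tdl_update(s)
    expect_equal(s$v_hat_h, 1 - (1 - alpha)^45, tolerance = 1e-12)
  }

  # monotone and bounded over a random update sequence
  set.seed(1)
  s <- preference_state(alpha = 0.2)
  prev <- s$v_hat_h
  for (i in 1:200) {
    if (runif(1) < 0.5) s <- tdl_update(s)
    expect_gte(s$v_hat_h, prev)
    expect_lte(s$v_hat_h, 1)
    prev <- s$v_hat_h
  }

  expect_error(preference_state(alpha = 0), "alpha")
  expect_error(preference_state(alpha = 1.2), "alpha")
  expect_error(preference_state(v_hat_h = 1, alpha = 0.5), "v_hat_h")
})

test_that("Luce choice probability is v/(1+v), bounded by one half", {
  expect_equal(choice_prob(preference_state(alpha = 0.1)), 0)
  expect_equal(choice_prob(preference_state(v_hat_h = 0.889, alpha = 0.1)),
               0.889 / 1.889)
  set.seed(2)
  for (v in runif(50)) {
    p <- choice_prob(preference_state(v_hat_h = v, alpha = 0.1))
    expect_gte(p, 0)
    expect_lte(p, 0.5)
  }
})

test_that("gamma draws stay in the environment interval, augmented under FFVP", {
  env <- environment_params(p1 = 0.2, p2 = 0.6, a = 0.3)
  set.seed(3)
  g_desert <- draw_gamma(TRUE, FALSE, env, n = 1e4)
  expect_true(all(g_desert > 0 & g_desert < 0.2))
  g_healthy <- draw_gamma(FALSE, FALSE, env, n = 1e4)
  expect_true(all(g_healthy > 0.2 & g_healthy < 0.6))
  g_ffvp <- draw_gamma(TRUE, TRUE, env, n = 1e4)
  expect_true(all(g_ffvp > 0.3 & g_ffvp < 0.5))
  # near-saturating augmentation clips at 1
  env_hi <- environment_params(p1 = 0.2, p2 = 0.6, a = 0.9)
  expect_true(all(draw_gamma(FALSE, TRUE, env_hi, n = 1e4) <= 1))
  # zero augmentation: FFVP draw identical to no-FFVP draw, seed-matched
  env0 <- environment_params(p1 = 0.2, p2 = 0.6, a = 0)
  set.seed(4); g_off <- draw_gamma(TRUE, FALSE, env0, n = 100)
  set.seed(4); g_on <- draw_gamma(TRUE, TRUE, env0, n = 100)
  expect_identical(g_on, g_off)
  expect_error(environment_params(p1 = 0.6, p2 = 0.2, a = 0), "p2")
})

test_that("Poisson quantile matches a brute-force CDF oracle", {
  expect_identical(poisson_quantile(0, 2.5), 0L)
  expect_identical(poisson_quantile(0.5, 1), 1L)
  expect_identical(poisson_quantile(0.9, 2.5), 5L)
  u <- (1:99) / 100
  for (lam in c(0.5, 1, 2.5, 5))
    expect_identical(poisson_quantile(u, lam), poisson_quantile_oracle(u, lam))
  expect_error(poisson_quantile(1, 2.5), "\\[0, 1\\)")
  expect_error(poisson_quantile(-0.1, 2.5), "\\[0, 1\\)")
})

test_that("servings draws are zero at unformed preference and increase with it", {
  model <- serving_model(lam = 2.5)
  s0 <- preference_state(alpha = 0.1)
  expect_identical(draw_servings(s0, model, n = 10), integer(10))
  # unformed preference consumes no random numbers
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(draw_servings(s0, model)); after <- runif(1)
  expect_identical(before, after)

  set.seed(6)
  hi <- draw_servings(preference_state(v_hat_h = 0.9, alpha = 0.1), model, 1e4)
  lo <- draw_servings(preference_state(v_hat_h = 0.4, alpha = 0.1), model, 1e4)
  expect_gt(mean(hi), mean(lo))
})

test_that("Monte-Carlo servings mean matches the direct expectation sum", {
  v <- 0.999999; lam <- 2
  set.seed(7)
  mc <- mean(draw_servings(preference_state(v_hat_h = v, alpha = 0.1),
                           serving_model(lam), n = 1e5))
  k <- 0:60
  p_k <- (pmin(ppois(k, lam), v) - pmin(ppois(k - 1, lam), v)) / v
  direct <- sum(k * p_k)
  expect_equal(mc, direct, tolerance = 0.02)
})
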