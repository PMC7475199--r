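# Small cohort builders used across test files.

make_agents <- function(pattern, desert, n, alpha = ffvp_defaults()$alpha) {
  data.frame(agent_id = seq_len(n),
             exposure_pattern = rep_len(pattern, n),
             desert_history = rep_len(desert, n),
             alpha = alpha,
             stringsAsFactors = FALSE)
}

# Desert histories drawn from the generator's yearly flip chain at the
# default cohort mix (70.7% ever-desert), for property checks that should
# hold under cohort-typical environments.
cohort_mix_histories <- function(n, seed = 99,
                                 ever_frac = 0.707, init = 0.9, flip = 0.05) {
  set.seed(seed)
  replicate(n, {
    if (runif(1) >= ever_frac) return("0000000")
    repeat {
      bits <- logical(7)
      bits[1] <- runif(1) < init
      for (y in 2:7) bits[y] <- xor(bits[y - 1], runif(1) < flip)
      if (any(bits)) return(paste(as.integer(bits), collapse = ""))
    }
  })
}

# Mean final perceived valuation / servings for one exposure pattern.
mean_final <- function(pattern, desert, n, seed = 42,
                       cfg = simulation_config(record_every = 100000L)) {
  cohort <- make_agents(pattern, desert, n)
  fs <- simulate_cohort(cohort, cfg, return_trajectories = FALSE)$final_states
  c(v = mean(fs$v_hat_final), serv = mean(fs$mean_servings))
}

# Brute-force Poisson quantile: cumulative summation of the pmf.
poisson_quantile_oracle <- function(u, lam) {
  vapply(u, function(ui) {
    k <- 0L
    cdf <- dpois(0, lam)
    while (cdf < ui) {
      k <- k + 1L
      cdf <- cdf + dpois(k, lam)
    }
    k
  }, integer(1))
}

# Printed summary cells of the group-contrast table the reporting module
# rebuilds (never-FFVP vs ever-FFVP, by food-desert stratum).
printed_cells <- list(
  never_desert = list(n1 = 7942, m1 = 2.493, s1 = 0.500,
                      n2 = 2591, m2 = 2.924, s2 = 0.269, t = -55.928),
  ever_desert  = list(n1 = 17598, m1 = 2.079, s1 = 0.472,
                      n2 = 7850, m2 = 2.716, s2 = 0.461, t = -100.97),
  total        = list(n1 = 25540, m1 = 2.208, s1 = 0.518,
                      n2 = 10441, m2 = 2.767, s2 = 0.431, t = -105.200))
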