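#' Simulation configuration
#'
#' The default schedule is 180 school days per academic year over 7 years
#' (kindergarten through grade 6), i.e. 1260 daily steps; summers and
#' weekends are not simulated. The healthy-situation probability gamma is
#' drawn once per agent-year by default (FFVP receipt and food-desert status
#' are yearly attributes); a per-day redraw is available via
#' `gamma_redraw = "daily"`.
#'
#' @param days_per_year School days per academic year. Default 180.
#' @param n_years Number of academic years; exposure patterns and desert
#'   histories must have this many digits. Default 7.
#' @param env An [environment_params()]. Default: calibrated values from
#'   [ffvp_defaults()].
#' @param pal A [palatability()]. Default: both foods normalized to 1.
#' @param model A [serving_model()]. Default: calibrated mean from
#'   [ffvp_defaults()].
#' @param record_every Stride (in steps) at which trajectory rows are stored;
#'   the final step is always recorded. Default 10.
#' @param gamma_redraw `"yearly"` (default) or `"daily"`.
#' @param servings_mode How end-of-study servings are summarized:
#'   `"final_year_mean"` (default) averages the daily servings draws over the
#'   last `days_per_year` steps, reducing single-draw noise; `"final_draw"`
#'   reports the last day's single draw.
#' @param seed Master seed; per-agent substreams are derived from it and the
#'   agent id, so cohort results do not depend on iteration order.
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config()
#' cfg$total_steps  # 1260
#' @export
simulation_config <- function(days_per_year = 180L, n_years = 7L,
                              env = NULL, pal = palatability(),
                              model = NULL, record_every = 10L,
                              gamma_redraw = c("yearly", "daily"),
                              servings_mode = c("final_year_mean", "final_draw"),
                              seed = 1L) {
  defs <- ffvp_defaults()
  if (is.null(env))
    env <- environment_params(p1 = defs$p1, p2 = defs$p2, a = defs$a)
  if (is.null(model)) model <- serving_model(lam = defs$lam)
  gamma_redraw <- match.arg(gamma_redraw)
  servings_mode <- match.arg(servings_mode)
  stopifnot(is_scalar_count(days_per_year), days_per_year >= 1,
            is_scalar_count(n_years), n_years >= 1,
            is_scalar_count(record_every), record_every >= 1,
            is_scalar_count(seed),
            inherits(env, "environment_params"),
            inherits(pal, "palatability"),
            inherits(model, "serving_model"))
  structure(list(days_per_year = as.integer(days_per_year),
                 n_years = as.integer(n_years),
                 total_steps = as.integer(days_per_year * n_years),
                 env = env, pal = pal, model = model,
                 record_every = as.integer(record_every),
                 gamma_redraw = gamma_redraw,
                 servings_mode = servings_mode,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Advance one agent by one daily step
#'
#' With probability `gamma` the day is a healthy-only situation and the agent
#' consumes healthy food; otherwise the agent is in a choice situation and
#' picks the healthy food with probability [choice_prob()]. Consuming healthy
#' food triggers the temporal-difference update; choosing unhealthy food
#' leaves the state unchanged. The daily servings count is then drawn from
#' the (updated) preference. Pure-R reference step; [simulate_agent()] runs
#' the identical draw sequence in compiled code.
#'
#' @param state A [preference_state()].
#' @param gamma Healthy-situation probability for this day, in \[0, 1\].
#' @param cfg A [simulation_config()] (palatability and serving model used).
#' @return List with elements `state` (updated [preference_state()]) and
#'   `record` (situation, consumed-healthy flag, choice probability,
#'   servings draw).
#' @export
step_agent <- function(state, gamma, cfg = simulation_config()) {
  stopifnot(inherits(state, "preference_state"),
            inherits(cfg, "simulation_config"),
            is_scalar_number(gamma), gamma >= 0, gamma <= 1)
  healthy_only <- stats::runif(1) < gamma
  consumed <- if (healthy_only) TRUE
              else if (state$v_hat_h > 0) stats::runif(1) < choice_prob(state)
              else FALSE
  if (consumed) state <- tdl_update(state, cfg$pal)
  servings <- draw_servings(state, cfg$model, 1)
  list(state = state,
       record = list(situation = if (healthy_only) "healthy_only" else "choice",
                     consumed_healthy = consumed,
                     p_choice = choice_prob(state),
                     servings = servings))
}

as_year_bits <- function(bits, n_years, what) {
  check_bits(bits, what, n_bits = n_years)
  as.integer(bits_to_logical(bits))
}

# Thin wrapper over the compiled kernel; no validation, no trajectory
# data frame. `gfix` is the per-year gamma override (NA = draw).
sim_agent_raw <- function(ffvp, desert, alpha, v0, cfg, gfix) {
  sim_agent_cpp(v0, alpha, cfg$pal$beta_h, 1.0, ffvp, desert,
                cfg$env$p1, cfg$env$p2, cfg$env$a,
                cfg$days_per_year, cfg$model$lam,
                cfg$record_every, cfg$gamma_redraw == "daily", gfix)
}

#' Simulate one agent over the full schedule
#'
#' Runs `n_years` blocks of `days_per_year` daily steps. At the start of each
#' year one gamma is drawn via [draw_gamma()] from that year's desert and
#' FFVP bits (unless `gamma_redraw = "daily"` or `gamma_override` fixes it).
#' The trajectory records every `record_every`-th step plus the final step.
#'
#' @param agent A list or one-row data frame with fields `exposure_pattern`,
#'   `desert_history` (binary strings of `n_years` digits) and `alpha`;
#'   optional `v0` (initial perceived valuation, default 0).
#' @param cfg A [simulation_config()].
#' @param seed Optional integer seed applied before simulation; if `NULL`
#'   the current RNG state is used.
#' @param gamma_override Optional numeric vector of length `n_years` (or a
#'   scalar, recycled): fixes gamma for the years where it is non-`NA`.
#' @return A data frame of class `ffvp_trajectory` with columns `step`,
#'   `v_hat_h`, `p_choice`, `situation`, `consumed_healthy`, `servings`, and
#'   attributes `v_final`, `p_final`, `mean_servings`, `gammas`.
#' @examples
#' agent <- list(exposure_pattern = "1110000", desert_history = "0000000",
#'               alpha = 0.02)
#' traj <- simulate_agent(agent, simulation_config(), seed = 7)
#' attr(traj, "v_final")
#' @export
simulate_agent <- function(agent, cfg = simulation_config(), seed = NULL,
                           gamma_override = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  ffvp <- as_year_bits(agent$exposure_pattern, cfg$n_years, "exposure pattern")
  desert <- as_year_bits(agent$desert_history, cfg$n_years, "desert history")
  alpha <- agent$alpha
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha > 1)
    stop("agent `alpha` must lie in (0, 1]", call. = FALSE)
  v0 <- if (!is.null(agent$v0)) agent$v0 else 0
  if (is.null(gamma_override)) {
    gfix <- rep(NA_real_, cfg$n_years)
  } else {
    gfix <- rep_len(as.numeric(gamma_override), cfg$n_years)
    if (any(!is.na(gfix) & (gfix < 0 | gfix > 1)))
      stop("`gamma_override` values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  res <- sim_agent_raw(ffvp, desert, alpha, v0, cfg, gfix)
  m <- res$trajectory
  traj <- data.frame(step = as.integer(m[, 1]),
                     v_hat_h = m[, 2],
                     p_choice = m[, 3],
                     situation = ifelse(m[, 4] == 1, "healthy_only", "choice"),
                     consumed_healthy = m[, 5] == 1,
                     servings = as.integer(m[, 6]),
                     stringsAsFactors = FALSE)
  attr(traj, "v_final") <- res$v_final
  attr(traj, "p_final") <- res$v_final / (1 + res$v_final)
  attr(traj, "mean_servings") <-
    if (cfg$servings_mode == "final_year_mean") mean(res$servings_final_year)
    else res$servings_final_year[cfg$days_per_year]
  attr(traj, "gammas") <- res$gammas
  class(traj) <- c("ffvp_trajectory", "data.frame")
  traj
}

#' Simulate a whole cohort
#'
#' Each agent runs on an independent RNG substream derived from
#' `cfg$seed` and the agent id, so results are bit-for-bit reproducible and
#' independent of iteration order (a subset of agents re-simulated in
#' isolation reproduces its rows of the full run).
#'
#' @param cohort Cohort data frame (see [generate_cohort()]).
#' @param cfg A [simulation_config()].
#' @param return_trajectories Keep per-agent trajectories? Set `FALSE` for
#'   large cohorts where only final states are needed. Default `TRUE`.
#' @return List with `final_states` (data frame: `agent_id`,
#'   `exposure_pattern`, `desert_history`, `v_hat_final`, `p_final`,
#'   `mean_servings`) and `trajectories` (one long data frame with an
#'   `agent_id` column, or `NULL`).
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   cell_counts = c(nd_nf = 5L, nd_f = 5L, d_nf = 5L, d_f = 5L)))
#' out <- simulate_cohort(cohort, simulation_config(record_every = 180L))
#' head(out$final_states)
#' @export
simulate_cohort <- function(cohort, cfg = simulation_config(),
                            return_trajectories = TRUE) {
  stopifnot(is.data.frame(cohort), inherits(cfg, "simulation_config"))
  n <- nrow(cohort)
  if (n == 0L)
    return(list(final_states = data.frame(agent_id = integer(0),
                                          exposure_pattern = character(0),
                                          desert_history = character(0),
                                          v_hat_final = numeric(0),
                                          p_final = numeric(0),
                                          mean_servings = numeric(0),
                                          stringsAsFactors = FALSE),
                trajectories = NULL))
  v_final <- numeric(n); p_final <- numeric(n); mean_serv <- numeric(n)
  trajs <- if (return_trajectories) vector("list", n) else NULL
  seeds <- derive_seed(cfg$seed, cohort$agent_id)
  if (return_trajectories) {
    for (i in seq_len(n)) {
      ag <- list(exposure_pattern = cohort$exposure_pattern[i],
                 desert_history = cohort$desert_history[i],
                 alpha = cohort$alpha[i])
      traj <- simulate_agent(ag, cfg, seed = seeds[i])
      v_final[i] <- attr(traj, "v_final")
      p_final[i] <- attr(traj, "p_final")
      mean_serv[i] <- attr(traj, "mean_servings")
      traj$agent_id <- cohort$agent_id[i]
      trajs[[i]] <- as.data.frame(traj)
    }
  } else {
    gfix <- rep(NA_real_, cfg$n_years)
    final_day <- cfg$days_per_year
    for (i in seq_len(n)) {
      ffvp <- as_year_bits(cohort$exposure_pattern[i], cfg$n_years,
                           "exposure pattern")
      desert <- as_year_bits(cohort$desert_history[i], cfg$n_years,
                             "desert history")
      set.seed(seeds[i])
      res <- sim_agent_raw(ffvp, desert, cohort$alpha[i], 0, cfg, gfix)
      v_final[i] <- res$v_final
      p_final[i] <- res$v_final / (1 + res$v_final)
      mean_serv[i] <- if (cfg$servings_mode == "final_year_mean")
        mean(res$servings_final_year) else res$servings_final_year[final_day]
    }
  }
  final_states <- data.frame(agent_id = cohort$agent_id,
                             exposure_pattern = cohort$exposure_pattern,
                             desert_history = cohort$desert_history,
                             v_hat_final = v_final,
                             p_final = p_final,
                             mean_servings = mean_serv,
                             stringsAsFactors = FALSE)
  trajectories <- if (return_trajectories) {
    out <- do.call(rbind, trajs)
    out[, c("agent_id", "step", "v_hat_h", "p_choice", "situation",
            "consumed_healthy", "servings")]
  } else NULL
  list(final_states = final_states, trajectories = trajectories)
}

#' Write simulation outputs as CSV
#'
#' @param x `final_states` or `trajectories` data frame from
#'   [simulate_cohort()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_sim_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  # serialize doubles at 17 significant digits so a read-back recomputation
  # is bit-identical to one done in memory
  for (col in names(x))
    if (is.double(x[[col]])) x[[col]] <- sprintf("%.17g", x[[col]])
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
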