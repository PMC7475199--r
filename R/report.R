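#' Welch two-sample t test from summary statistics
#'
#' Mean comparison assuming independence but not equal variances, with
#' Welch–Satterthwaite degrees of freedom; computable directly from group
#' n/mean/SD cells as printed in a summary table.
#'
#' @param n1,n2 Group sizes (>= 2).
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations (>= 0, not both 0).
#' @return An object of class `welch_result`: `t`, `df`, `p` (two-sided).
#' @examples
#' welch_t(7942, 2.493, 0.500, 2591, 2.924, 0.269)
#' @export
welch_t <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(is_scalar_count(n1), n1 >= 2, is_scalar_count(n2), n2 >= 2,
            is_scalar_number(mean1), is_scalar_number(mean2),
            is_scalar_number(sd1), sd1 >= 0,
            is_scalar_number(sd2), sd2 >= 0)
  if (sd1 == 0 && sd2 == 0)
    stop("both standard deviations are zero: t statistic undefined",
         call. = FALSE)
  se1 <- sd1^2 / n1
  se2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se1 + se2)
  df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.3f, df = %.1f, p = %.3g\n",
              x$t, x$df, x$p))
  invisible(x)
}

ever_flags <- function(final_states) {
  data.frame(agent_id = final_states$agent_id,
             ever_ffvp = grepl("1", final_states$exposure_pattern),
             ever_desert = grepl("1", final_states$desert_history),
             mean_servings = final_states$mean_servings,
             stringsAsFactors = FALSE)
}

summ_cell <- function(x) {
  c(n = length(x),
    mean = if (length(x)) mean(x) else NA_real_,
    sd = if (length(x) >= 2) stats::sd(x) else NA_real_)
}

#' FFVP-by-food-environment effect table
#'
#' Rebuilds the headline group contrast: end-of-study mean servings by
#' (ever in a food desert) x (ever received FFVP), with the FFVP effect per
#' environment (exposed mean minus unexposed mean) and a Welch t test for
#' each contrast. "Ever" means at least one 1-bit over the seven grades.
#' Cells with fewer than two agents yield `NA` statistics rather than an
#' error.
#'
#' @param final_states Final-state table from [simulate_cohort()] (must
#'   carry `exposure_pattern`, `desert_history`, `mean_servings`).
#' @return Data frame with one row per environment group (`never_desert`,
#'   `ever_desert`, `total`): unexposed and exposed n/mean/SD, `effect`,
#'   `t`, `df`, `p`.
#' @export
effect_table <- function(final_states) {
  stopifnot(is.data.frame(final_states),
            all(c("agent_id", "exposure_pattern", "desert_history",
                  "mean_servings") %in% names(final_states)))
  fl <- ever_flags(final_states)
  groups <- list(never_desert = !fl$ever_desert,
                 ever_desert = fl$ever_desert,
                 total = rep(TRUE, nrow(fl)))
  rows <- lapply(names(groups), function(g) {
    sub <- fl[groups[[g]], ]
    un <- summ_cell(sub$mean_servings[!sub$ever_ffvp])
    ex <- summ_cell(sub$mean_servings[sub$ever_ffvp])
    ok <- un["n"] >= 2 && ex["n"] >= 2 && !is.na(un["sd"]) && !is.na(ex["sd"]) &&
          (un["sd"] > 0 || ex["sd"] > 0)
    wt <- if (ok) welch_t(un["n"], un["mean"], un["sd"],
                          ex["n"], ex["mean"], ex["sd"])
          else list(t = NA_real_, df = NA_real_, p = NA_real_)
    data.frame(group = g,
               n_unexposed = un["n"], mean_unexposed = un["mean"],
               sd_unexposed = un["sd"],
               n_exposed = ex["n"], mean_exposed = ex["mean"],
               sd_exposed = ex["sd"],
               effect = ex["mean"] - un["mean"],
               t = wt$t, df = wt$df, p = wt$p,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-exposure-pattern servings summary
#'
#' One row per exposure pattern observed in the cohort: agent count, mean
#' end-of-study servings and the number of exposure years; sorted by
#' exposure-year count then pattern. This is the table behind the
#' pattern-bubble figure (bubble size = agent count).
#'
#' @param final_states Final-state table from [simulate_cohort()].
#' @return Data frame with columns `exposure_pattern`, `n_years_exposed`,
#'   `n`, `mean_servings`, `mean_v_hat`.
#' @export
pattern_summary <- function(final_states) {
  stopifnot(is.data.frame(final_states), nrow(final_states) > 0,
            all(c("exposure_pattern", "mean_servings", "v_hat_final") %in%
                  names(final_states)))
  sp <- split(final_states, final_states$exposure_pattern)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(exposure_pattern = d$exposure_pattern[1],
               n_years_exposed = sum(bits_to_logical(d$exposure_pattern[1])),
               n = nrow(d),
               mean_servings = mean(d$mean_servings),
               mean_v_hat = mean(d$v_hat_final),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$n_years_exposed, out$exposure_pattern), ]
  rownames(out) <- NULL
  out
}

#' Mean preference trajectories by exposure pattern
#'
#' Step-indexed mean perceived-valuation curves for the requested exposure
#' patterns, always including the never-exposed (`"0000000"`) and
#' fully-exposed (`"1111111"`) reference patterns when present in the cohort.
#' Requesting a pattern absent from the cohort is an error.
#'
#' @param trajectories Long trajectory table from [simulate_cohort()].
#' @param cohort Cohort data frame (maps `agent_id` to `exposure_pattern`).
#' @param patterns Character vector of exposure patterns of interest.
#' @return Data frame with columns `exposure_pattern`, `step`, `mean_v_hat`,
#'   `n_agents`.
#' @export
trajectory_panel <- function(trajectories, cohort, patterns = character(0)) {
  stopifnot(is.data.frame(trajectories), is.data.frame(cohort))
  present <- unique(cohort$exposure_pattern)
  missing <- setdiff(patterns, present)
  if (length(missing))
    stop(sprintf("pattern(s) not present in cohort: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  wanted <- union(patterns, intersect(c("0000000", "1111111"), present))
  tr <- merge(trajectories,
              cohort[, c("agent_id", "exposure_pattern")], by = "agent_id")
  tr <- tr[tr$exposure_pattern %in% wanted, ]
  agg <- stats::aggregate(v_hat_h ~ exposure_pattern + step, data = tr, mean)
  cnt <- stats::aggregate(agent_id ~ exposure_pattern + step, data = tr,
                          function(x) length(unique(x)))
  out <- merge(agg, cnt, by = c("exposure_pattern", "step"))
  names(out) <- c("exposure_pattern", "step", "mean_v_hat", "n_agents")
  out <- out[order(out$exposure_pattern, out$step), ]
  rownames(out) <- NULL
  out
}

#' Plot helpers for the standard report tables
#'
#' Optional ggplot2 renderings of the CSV-backed report tables:
#' `plot_pattern_summary` draws the pattern bubble chart (mean servings vs
#' years of exposure, bubble area = agent count); `plot_trajectory_panel`
#' draws the mean preference-evolution curves.
#'
#' @param x A [pattern_summary()] or [trajectory_panel()] table.
#' @return A ggplot object.
#' @export
plot_pattern_summary <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(x, ggplot2::aes(x = n_years_exposed, y = mean_servings,
                                  size = n)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Years of FFVP exposure (K-6)",
                  y = "Mean servings by grade 6", size = "Agents") +
    ggplot2::theme_minimal()
}

#' @rdname plot_pattern_summary
#' @export
plot_trajectory_panel <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(x, ggplot2::aes(x = step, y = mean_v_hat,
                                  colour = exposure_pattern)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "School day", y = "Mean perceived valuation of healthy food",
                  colour = "Exposure pattern") +
    ggplot2::theme_minimal()
}
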