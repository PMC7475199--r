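---
title: "An agent-based model of healthy-food preference learning under a school fruit and vegetable program"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of healthy-food preference learning under a school fruit and vegetable program}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffvpsim)
```

## The model

`ffvpsim` simulates how elementary-school children (kindergarten through
grade 6) form preferences for healthy food — fruits and vegetables — under
the USDA Fresh Fruit and Vegetable Program (FFVP), which provides free
fruit and vegetable snacks in qualifying schools. The scientific question
the model addresses is allocational: given that program grants move between
schools from year to year, how do the *timing* and *duration* of a child's
exposure, and the child's residential food environment, shape the
preferences and intake they carry into adolescence?

Each agent $i$ holds a perceived valuation $\hat V_{iH}(t)$ of healthy food,
starting completely unformed at $\hat V_{iH}(0) = 0$, and a fully formed
valuation of unhealthy food fixed at $\hat V_{iU} = 1$. Whenever the agent
consumes healthy food, the perceived valuation moves toward the food's
intrinsic palatability $\beta_H$ (normalized to 1) by temporal-difference
learning:

$$\hat V_{iH}(t+1) = \hat V_{iH}(t) + \alpha_i\,[\beta_H - \hat V_{iH}(t)],$$

where $\alpha_i \in (0,1]$ is the agent's learning speed. Preferences are
learned but never forgotten: $\hat V_{iH}$ is non-decreasing, converges
geometrically toward $\beta_H$, and after $n$ consecutive updates from zero
equals $\beta_H\,[1-(1-\alpha_i)^n]$ exactly. This asymmetry — one food
learned, the other fully known — is what produces the model's lock-in
behaviour: early exposure compounds, because a partly formed preference
raises the chance of choosing healthy food later, which itself accelerates
learning.

Each school day puts the agent in one of two situations. With probability
$\gamma$ only healthy food is available (a *healthy situation*: an FFVP
snack, a home without alternatives) and the agent consumes it. Otherwise
the agent faces a *choice situation* and picks healthy food with the Luce
choice probability

$$P_{iH}(t) = \frac{\hat V_{iH}(t)}{\hat V_{iU} + \hat V_{iH}(t)},$$

which under the normalization $\hat V_{iU} = \beta_H = 1$ is bounded by
$1/2$: even a fully learned preference yields at best a coin flip against
an equally palatable unhealthy option. An agent with $\hat V_{iH} = 0$
never chooses healthy food in a choice situation.

$\gamma$ is drawn once per agent-year from the food environment: uniformly
on $(0, p_1)$ for agents living in a food desert that year, on $(p_1, p_2)$
otherwise, and augmented additively by a constant $a$ (clipped at 1) in
years the agent receives FFVP. We read the augmentation as additive because
the program supplies healthy-only eating occasions directly, an effect that
should not vanish for the agents with the worst baseline environments (a
multiplicative boost would shrink to nothing as $p_1 \to 0$). A per-day
redraw of $\gamma$ is available (`gamma_redraw = "daily"`), but the yearly
draw is the default since both FFVP receipt and desert status are yearly
attributes.

Because preferences are not directly observable, they are converted to a
daily servings count by drawing $u \sim \mathrm{Uniform}(0, \hat V_{iH}]$
and returning the Poisson quantile $Q(u; \lambda)$ — the smallest integer
$k$ whose Poisson CDF reaches $u$. The servings distribution is therefore
stochastically increasing in preference, equals a full Poisson($\lambda$)
draw in the limit $\hat V_{iH} \to 1$, and is degenerate at zero for an
unformed preference. This construction is also why the model requires
$\hat V_{iH} < 1$ strictly: the quantile diverges at $u = 1$. The strict
bound holds automatically, since the geometric update never reaches its
ceiling in finite time. We note the phrase "inverse Poisson" admits other
readings (a deterministic quantile at $\hat V$ itself, or an
inverse-Poisson-family distribution); we chose the randomized quantile
because it is stochastic, respects the stated support requirement, and
makes intake rise smoothly with preference.

## Schedule and cohort

The simulated schedule is 180 school days per academic year over 7 years
(1260 steps); summers and weekends are not modelled. Exposure is encoded as
a 7-digit binary pattern over grades K–6 (`"1010000"` = FFVP in
kindergarten and grade 2; 128 possible patterns), and food-desert residence
as a 7-digit yearly history.

The real cohort behind the model — two kindergarten cohorts of Arkansas
public-school students, 35,981 agents, with FFVP award records and
food-access classifications — is not publicly available. The
`generate_cohort()` module emulates its structure instead: agents are
stratified *exactly* into the four (ever-desert × ever-FFVP) cells, whose
default counts (7,942 / 2,591 / 17,598 / 7,850) reproduce the published
cross and hence the published marginals (70.7% ever in a food desert,
29.0% ever exposed to FFVP). We note the source text elsewhere states 45%
for the ever-exposed share; the tabulated value 0.290, which agrees with
the cell counts, is the one we match, and we surface the discrepancy here
rather than reconcile it silently.

Two features of the real data are *not* published and are therefore
modelled parametrically, configurable in `cohort_config()`:

* **Exposure patterns within ever-FFVP agents.** Schools hold or lose
  grants across consecutive years, so the default support is the 28
  contiguous-run patterns, with run length $L$ weighted by a truncated
  geometric $0.55^{L-1}$ and the start grade uniform. At this decay the
  all-seven pattern has probability ≈ 0.013, matching its rarity in the
  real cohort (104 of 10,441). The real cohort exhibits 40 of the 128
  patterns, including non-contiguous ones; restricting to an explicit
  admissible set is supported via `pattern_weights`.
* **Desert dynamics.** Census areas can change desert status year to year,
  but no rates are published. Histories follow a symmetric yearly flip
  chain (default flip probability 0.05, initial desert probability 0.9 for
  ever-desert agents), conditioned so ever-desert agents have at least one
  desert year.

These are structural stand-ins, not estimates: passing tests on this
synthetic cohort shows the pipeline reproduces the model's *mechanisms*
(orderings, interactions, calibration), not that it predicts any real
child's consumption.

## Parameters and calibration

| Parameter | Meaning | Default | Origin |
|---|---|---|---|
| $p_1$ | upper bound of desert-year $\gamma$ draw | 0.15 | fixed design choice |
| $p_2$ | upper bound of non-desert $\gamma$ draw | 0.65 | fixed design choice |
| $a$ | FFVP augmentation of $\gamma$ | 0.2734 | calibrated |
| $\alpha$ | learning speed (constant across agents) | 0.0042 | anchored |
| $\lambda$ | Poisson servings mean (servings/day) | 2.7 | anchored |

The empirical anchor is a regression-discontinuity finding that one school
year of FFVP raises intake by about 1/3 cup of fruits and vegetables; the
cup-to-serving equivalence (one cup = one serving difference) is declared
in `calibration_target()`, not hard-coded. `one_year_effect()` measures the
model's analogue: two arms of kindergarten agents over one 180-day year —
FFVP on versus off, identical environment mix (70.7% desert) and identical
per-agent random substreams — compared on mean daily servings. Common
random numbers make the contrast exact at $a = 0$ and low-noise elsewhere.

A single scalar target cannot identify three free parameters: a full
$(a, \alpha, \lambda)$ grid fit has a ridge of near-zero loss and lands
wherever the grid happens to touch it, including regimes where every agent
saturates by grade 6. The default calibration is therefore structured as an
identified fit:

1. $\alpha$ and $\lambda$ are **anchored to the scales the model is
   documented to operate at**: with $\alpha = 0.0042$ the simulated cohort's
   mean perceived valuation by grade 6 is ≈ 0.88 (reported scale ≈ 0.889,
   with preferences "almost fully formed" but not saturated, min ≈ 0.5,
   max ≈ 0.99), and with $\lambda = 2.7$ never-exposed agents average
   ≈ 2.21 daily servings (reported scale 2.208).
2. $a$ alone is then **calibrated to the one-year effect** by coarse grid
   search (5 points on $[0.05, 0.6]$) plus three local refinement rounds,
   minimizing squared deviation; the fitted $a = 0.2734$ achieves an effect
   of 0.330, stable to ±0.003 across seeds at 2,000 agents per arm.

`calibrate()` still accepts bounds for any of $a, \alpha, \lambda, p_1,
p_2$, so the under-determined joint fits remain available for exploration;
freeing $p_1$ or $p_2$ additionally warns, since the environment bounds and
the augmentation trade off almost perfectly in the one-year contrast.

## Numerical and implementation choices

* **Daily loop.** The per-day simulation runs in compiled code with a fixed
  per-day draw order (situation uniform; choice uniform only in a choice
  situation with formed preference; servings uniform only when preference
  is positive). The pure-R `step_agent()` performs the identical sequence,
  and a test reproduces a compiled 7-year trajectory draw-for-draw from R.
* **Servings quantile.** Inside the loop the Poisson quantile is read from
  a precomputed CDF table (identical smallest-$k$ definition, built to
  $1 - 10^{-13}$ mass) with a fallback to `qpois` in the far upper tail.
* **RNG discipline.** One master seed; each agent's substream seed is a
  splitmix-style integer mix of the master seed and the agent id, kept
  below $2^{31}$. Results are order-independent: any subset of agents
  re-simulated in isolation reproduces its rows of the full run, and the
  pipeline stages rerun standalone are byte-identical to the full pipeline
  (simulation tables serialize doubles at 17 significant digits so file
  round trips are lossless).
* **End-of-study servings.** Reported as the mean of the daily servings
  draws over the final 180 days (default), which matches the dispersion of
  an averaged quantity; a single final-day draw is available via
  `servings_mode = "final_draw"`.
* **Degenerate inputs.** $\hat V = 0$ is absorbing under $\gamma = 0$ (the
  unhealthy food is always chosen, by convention); empty cohorts and empty
  contrast cells return empty/NA outputs rather than errors; configuration
  files are schema-validated with all problems aggregated into one error.

## Problem sizes used in the test suite

Monte-Carlo checks run at 500–1,000 agents per exposure pattern for the
ordering and saturation properties, 2,000 agents per arm for calibration
checks, and the full 35,981-agent cell structure for the cohort-marginal
check (generation only). These sizes hold the Monte-Carlo standard error of
group means well below the margins being asserted while keeping the suite
fast.

## What the model does and does not show

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_config(seed = 1))
sim <- simulate_cohort(cohort, simulation_config(seed = 1),
                       return_trajectories = FALSE)
effect_table(sim$final_states)
```

At the calibrated defaults the simulation reproduces the model's
qualitative findings: early exposure dominates late exposure of the same
duration (kindergarten-only beats grade-6-only), three consecutive early
years are nearly as effective as all seven (within 0.02 in mean final
valuation under the cohort environment mix), and the FFVP effect on
servings is larger for food-desert agents than for non-desert agents.
These are *model* predictions — testable hypotheses about program
allocation — not causal estimates. The magnitudes of the simulated
grade-6 group contrasts depend on the unpublished joint distribution of
exposure patterns and desert histories, so only their orderings, the
one-year calibrated effect, and the published-table recomputations are
meaningful points of comparison. Known limitations: two foods only, no
forgetting, no social influence between agents, no within-day eating
occasions, no school-level clustering of exposure, and a servings scale
tied to a single empirical anchor.
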