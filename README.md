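# ffvpsim

An agent-based model of how elementary-school children form preferences for
healthy food under the USDA **Fresh Fruit and Vegetable Program (FFVP)**, a
federal grant that provides free fruit and vegetable snacks in qualifying
elementary schools. Grants move between schools from year to year, so
children accumulate different *exposure patterns* across grades K–6. The
package is for researchers in nutrition policy and computational
epidemiology who want to explore how the timing and duration of such an
intervention, and a child's residential food environment, shape long-run
dietary preference — and to generate testable allocation hypotheses (e.g.
"front-load grants into the earliest grades").

## The model

Each agent carries a perceived valuation of healthy food,
$\hat V_H \in [0, 1)$, starting unformed at 0, against a fully formed
unhealthy-food valuation fixed at 1. Consuming healthy food triggers a
temporal-difference update toward the intrinsic palatability $\beta_H = 1$:

$$\hat V_H \leftarrow \hat V_H + \alpha\,(\beta_H - \hat V_H)$$

Each of 1260 school days (180 days × 7 years) is either a *healthy-only
situation* (probability $\gamma$, drawn yearly from the food environment:
uniform on $(0, p_1)$ in a food desert, $(p_1, p_2)$ otherwise, plus an
additive program boost $a$ in FFVP years) or a *choice situation*, where the
agent picks healthy food with Luce probability
$\hat V_H / (1 + \hat V_H) \le 1/2$. Daily servings are the Poisson
quantile $Q(u; \lambda)$ at $u \sim \mathrm{U}(0, \hat V_H]$, so intake
rises stochastically with learned preference. Learning compounds: early
exposure raises the chance of choosing healthy food later, which
accelerates further learning (the lock-in effect).

The environment boost $a$ is calibrated so that one year of FFVP raises
mean daily servings by 1/3, the empirical benchmark for the program;
$\alpha$ and $\lambda$ are anchored to the cohort-level preference and
servings scales. See `vignette("preference-learning-model")` for the full
account, including what the synthetic cohort generator does and does not
emulate about the original 35,981-student Arkansas cohort.

## Worked example

```r
library(ffvpsim)

# synthetic cohort, 1/10-scale cells of the emulated administrative cross
cohort <- generate_cohort(cohort_config(
  cell_counts = c(nd_nf = 794L, nd_f = 259L, d_nf = 1760L, d_f = 785L),
  seed = 1))
sim <- simulate_cohort(cohort, simulation_config(seed = 1),
                       return_trajectories = FALSE)
effect_table(sim$final_states)
#>          group n_unexposed mean_unexposed sd_unexposed n_exposed mean_exposed
#> 1 never_desert         794          2.502       0.1184       259        2.536
#> 2  ever_desert        1760          2.080       0.2062       785        2.247
#> 3        total        2554          2.211       0.2682      1044        2.319
#>   sd_exposed  effect       t     df         p
#> 1     0.1080 0.03337  -4.215  476.3 2.990e-05
#> 2     0.1747 0.16749 -21.101 1758.5 2.775e-88
#> 3     0.2034 0.10768 -13.080 2530.6 7.025e-38
```

The table is the model's headline contrast: grade-6 mean daily servings by
(ever in a food desert) × (ever received FFVP), with the FFVP effect per
environment and a Welch unequal-variance t test. Here the program effect is
five times larger for food-desert agents (0.167 vs 0.033 servings) — the
model's central allocation finding: children with the worst baseline food
access benefit most. Mean grade-6 perceived valuation in this run is 0.883
and mean choice probability 0.468, i.e. preferences nearly but not fully
formed by age 12.

Welch t statistics can also be recomputed directly from any published
n/mean/SD cells:

```r
welch_t(7942, 2.493, 0.500, 2591, 2.924, 0.269)
#> <welch_result> t = -55.919, df = 8285.7, p = 0
```

A YAML-configured pipeline (`run_pipeline()`, or
`inst/cli/ffvpsim.R <pipeline|cohort|simulate|calibrate|report>`) runs
cohort generation → simulation → reporting with a provenance manifest and
byte-reproducible outputs under a single master seed.

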