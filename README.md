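# loadctrl

Personalized training-load control for competitive sport, as a testable
simulation + reinforcement-learning toolkit in R. The package is aimed at
sport scientists and methodologists who want to study *closed-loop* load
prescription — a controller that reads an athlete's daily monitoring data
(HRV, RPE, soreness, sleep, recent load) and prescribes the next day's
session — without running a human trial: athletes are simulated from a
fitness–fatigue–recovery model, and policies are compared under paired,
seeded conditions.

## The model and the controller

Each simulated athlete follows an impulse-response performance model with a
saturating dose–response and a fatigue penalty,

    P[t+1] = P[t] + f(Φ) · η · (1 − exp(−λ · TL[t])) − δ · F[t]

fatigue dynamics `dF/dt = k1·TL − k2·F − k3·R` (forward Euler, 1-day step,
clamped at zero), and multi-compartment recovery
`R_total(t) = Σ_j r_max,j (1 − exp(−t/τ_j))`.

Daily decisions form an MDP over a 16-week (112-day) macrocycle: factored
actions (intensity × volume × session type × recovery protocol, |A| = 60),
min–max-scaled state features including a 7-day load window and the
acute:chronic workload ratio, a logistic injury hazard in fatigue and ACWR,
and a four-component reward

    R = α·P_gain + β·(1 − risk) + γ·adherence + δ·recovery_quality,
    (α, β, γ, δ) = (0.4, 0.3, 0.2, 0.1)

calibrated by a constrained grid search (0.05 grid on the admissible ranges,
simplex-filtered to 55 candidates, athlete-level 5-fold CV) with a ±20%
sensitivity analysis. The controller is a DQN — a ReLU multilayer perceptron
trained by temporal-difference learning with prioritized experience replay
(`P(i) ∝ p_i^0.6`), importance-weighted regularized TD loss, soft target
updates (`θ⁻ ← 0.001·θ + 0.999·θ⁻`), ε-greedy exploration decaying 0.3 → 0.05,
gradient clipping and plateau learning-rate scheduling. Baselines: linear
periodization, threshold rules (HRV < 60 ms, RPE > 7/10, soreness > 6/10),
and regression-based prescription. Evaluation uses the sport-weighted
improvement `PI = (P_post − P_base)/P_base × 100 × W_sport`, discounted
long-term effectiveness, injuries per 100 training hours, and paired
bootstrap/Cohen's-d comparisons.

See `vignettes/training-load-control.Rmd` for the full methods account,
including which component definitions are constructions and what the
synthetic cohort does not emulate.

## Worked example

```r
library(loadctrl)

cohort <- generate_cohort(cohort_spec(n_athletes = 6, seed = 42))
envs   <- lapply(cohort, training_env)
agent  <- train_agent(envs, episodes = 600, reduced_agent_config(), seed = 7)

report <- compare_policies(
  list(periodization = policy_periodization(),
       dqn           = policy_agent(agent),
       rules         = policy_rule_based()),
  cohort, seed = 1)
glance(report)
#> # A tibble: 3 × 5
#>   policy        mean_pi injury_rate_per_100h mean_efficiency mean_return
#>   <chr>           <dbl>                <dbl>           <dbl>       <dbl>
#> 1 dqn              27.1                0               0.796        85.4
#> 2 periodization    27.4                0.747           0.614        75.4
#> 3 rules            31.0                0.354           0.660        79.2
```

Reading the output: over six simulated athletes under identical seeds, the
600-episode DQN attains performance gains comparable to the baselines while
driving the simulated injury rate to zero and achieving the best efficiency
(gain per unit load) and the highest episode return (the reward actually
optimized, which also prices injury safety, adherence and recovery). `mean_pi`
is the mean relative performance improvement in percent over the 16 weeks;
`injury_rate_per_100h` counts simulated injuries per 100 training hours at a
nominal 2 h per unit daily load. Longer training (the bundled experiments use
2,000 episodes) strengthens the DQN column; `report$comparisons` adds paired
bootstrap CIs and Cohen's d against the first-listed policy.

A command-line interface wraps the same functions
(`inst/cli/loadctrl.R simulate|train|calibrate|evaluate|report`), writing CSV
outputs plus a manifest with settings, seed and versions.

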