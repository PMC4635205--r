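# behavdyn

Tools for modeling **behavior contagion**: how a behavior — a stress
response in a classroom, a habit, a panic reaction in a crowd — spreads
through a population, and how the spreading parameters can be estimated
from psychophysiological measurements taken in controlled (e.g. virtual
reality) stress-induction experiments.

The package is aimed at computational behavioral scientists and
epidemiological modelers. It provides four connected layers:

1. **Aggregate diffusion models.** The Bass-type recurrence
   `S(t) = S(t−1) + α(1−S(t−1)) + β(1−S(t−1))S(t−1)` (α: spontaneous
   adoption rate, β: social/imitation rate), its continuous closed form
   `S(t) = (1 − e^{−(α+β)t}) / (1 + (β/α)e^{−(α+β)t})`, a
   stock-and-flow adoption model driven by `AdoptionFraction` and
   `ImitationEffectiveness`, and the SIR compartment model
   `dS/dt = −ρSI`, `dI/dt = ρSI − aI`, `dR/dt = aI`.
2. **Network models.** Poisson, preferential-attachment and
   configuration-model contact graphs; percolation analytics with
   immune-node removal (giant-component emergence at `p(1−α)n = 1`,
   outbreak size from `r = 1 − e^{−r(1−α)np}`, connectivity bound,
   configuration-model threshold `⟨d²⟩ = 2⟨d⟩`); homogeneous and
   degree-based mean-field spreading (relaxation time
   `τ = ⟨k²⟩/(λ(⟨k²⟩−⟨k⟩))`); and an agent-based contagion simulator
   with heterogeneous `behavioral_degree`.
3. **Information-theoretic contagion between two individuals.**
   `I(p) = log(1/p)`, entropy as expected contagion, Kraft–McMillan and
   source-coding bounds, mutual contagion `I(F;G) = S(F) − S(F|G)`,
   channel capacity (Blahut–Arimoto), maximum-entropy distributions.
4. **Calibration from physiology.** Heart-rate-variability time and
   frequency indexes (AVNN, SDNN, RMSSD, pNN50; VLF/LF/HF band powers
   and normalised units), EMG RMS envelopes, respiration features, EEG
   alpha asymmetry; baseline-relative deltas; a configurable
   stress-threshold rule that flags stressed subjects per condition; and
   per-group estimation of `AdoptionFraction` (cognitive-task condition)
   and `ImitationEffectiveness` (media conditions VR/AUDIO/TEXT/VIDEO) —
   plus a synthetic cohort generator with known ground truth so the
   whole pipeline is testable end to end.

## Worked example

Generate a synthetic cohort shaped like the reference study (26 female
and 16 male subjects; responder probabilities 0.8 and 0.4), calibrate it
with a stress threshold of 0.2, and simulate the two-group adoption
scenario:

```r
library(behavdyn)

gen <- generate_index_table(cohort_spec(seed = 42))
est <- calibrate_cohort(gen$records, stress_rule_config(st = 0.2))
est
#>    group n_subjects adoption_fraction imitation_effectiveness
#> 1 female         26         0.8846154               0.7980769
#> 2   male         16         0.5000000               0.4375000

pars <- scenario_from_calibration(est, total_population = 1e6,
                                  contact_rate = 100)
for (g in names(pars)) {
  tr <- simulate_sd_adoption(pars[[g]], horizon = 6, dt = 0.05)
  tr$fraction <- tr$adopters / 1e6
  cat(sprintf("%s: time to 90%% adoption = %.2f\n",
              g, time_to_adoption(tr, 0.9)))
}
#> female: time to 90% adoption = 0.09
#> male: time to 90% adoption = 0.14
```

The estimated adoption fraction (0.88, 0.50) is the proportion of each
group flagged as stressed by the rule in the cognitive task, close to
the planted responder shares (0.8, 0.4); the imitation effectiveness is
the mean flagged proportion across the four media conditions. Fed into
the stock-and-flow model with one million agents and a contact rate of
100 per time unit, the group with the larger propensities reaches 90%
adoption in roughly two thirds of the other group's time — the
qualitative group-difference pattern the calibration is designed to
expose.

Network-side quantities follow the printed relations:

```r
solve_outbreak_fraction(2)
#> [1] 0.7968121   # root of r = 1 - exp(-2 r)

estimate_percolation_threshold(n = 2000, alpha_immune = 0.3,
                               reps = 30, seed = 1)$product
#> [1] 0.9         # giant component emerges near p (1 - alpha) n = 1
```

A thin command-line wrapper lives at `inst/cli/behavdyn`
(`behavdyn simulate|calibrate|synth|sweep|analyze-network --config
cfg.yaml [--seed N] [--out DIR]`); scenario configs are YAML, outputs
are CSV trajectories plus JSON summaries and a re-run manifest (see
`?run_scenario`).

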