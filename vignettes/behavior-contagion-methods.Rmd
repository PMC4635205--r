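---
title: "Modeling behavior contagion: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling behavior contagion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavdyn)
```

behavdyn studies how a behavior — a stress response, a habit, a panic
reaction — spreads through a population. It combines three modeling
layers (aggregate, networked, dyadic/information-theoretic) with a
calibration engine that turns psychophysiological measurements into the
two propensities the aggregate model needs. This vignette explains the
models, the assumptions behind them, and the design decisions that were
genuinely open.

## Aggregate adoption models

The simplest description tracks the adopted fraction $S(t)$ through the
recurrence

$$S(t) = S(t-1) + \alpha\,(1 - S(t-1)) + \beta\,(1 - S(t-1))\,S(t-1),$$

a Bass-type diffusion: $\alpha$ is the per-period rate of spontaneous or
environmentally driven adoption, $\beta$ the rate driven by social
contact and imitation. Its continuous counterpart
$dS/dt = (\alpha + \beta S)(1 - S)$ has, for $\alpha > 0$ and $S(0) = 0$,
the closed form

$$S(t) = \frac{1 - e^{-(\alpha+\beta)t}}{1 + (\beta/\alpha)\,e^{-(\alpha+\beta)t}}.$$

Two numerical choices here. First, the raw recurrence can overshoot 1
when $\alpha + \beta$ is large, so each step is clipped to $[0,1]$:
the model's state is a fraction. Second, `adoption_closed_form()`
rejects $\alpha = 0$ rather than evaluating a limit: the closed form is
derived under $\alpha > 0$, and the $\alpha = 0$ case (pure imitation
with no seed) is degenerate — the ODE path handles it, as it does any
starting fraction other than zero.

The stock-and-flow version (`simulate_sd_adoption()`) works on counts:
`AdoptionFromImitation = PotentialAdopters * ImitationEffectiveness` and
`AdoptionFromWOM = Adopters * PotentialAdopters * ContactRate *
AdoptionFraction / TotalPopulation`. The naming is kept exactly as in
the stock-and-flow formulation even though the roles mirror the Bass
innovation/imitation terms inversely — `ImitationEffectiveness`
multiplies the contact-free flow and `AdoptionFraction` sits in the
word-of-mouth term. In per-capita form the model reduces to the
continuous recurrence with $\alpha =$ `ImitationEffectiveness` and
$\beta =$ `ContactRate * AdoptionFraction`, which is tested directly.
Counts are the primary output; a fraction column is added where
downstream utilities need it.

The SIR layer uses the standard compartments
$dS/dt = -\rho S I$, $dI/dt = \rho S I - a I$, $dR/dt = a I$ with
$S + I + R = 1$, accepting either the normalised rates or the
stock-and-flow factors ($\rho = c \cdot i$, $a = 1/d$).

All ODEs are integrated with deSolve's adaptive `lsoda` at tight
tolerances (`rtol = 1e-10`); these models are non-stiff at any parameter
values a behavioral scenario uses, and the output step `dt` is a
sampling choice, not an accuracy choice. Conservation ($S+I+R$, or
potential + adopters) holds to ~1e-10 and is asserted in the tests at
1e-8.

## Network models

Aggregate models ignore who is connected to whom. The network layer
represents the population as a graph (igraph objects throughout):
Poisson random graphs with link probability $p$, preferential-attachment
trees (one edge per arriving node, $P(k) \sim k^{-\gamma}$ with
$2 \le \gamma \le 3$), and configuration-model graphs from a prescribed
degree sequence (stub matching, then removal of self-loops and
multi-edges — standard practice, and the degree distortion is a handful
of edges at the sizes used).

A fraction $\alpha$ of individuals is *immune* — never adopts, removed
from the graph. After removal, a giant component of susceptibles emerges
at $p\,(1-\alpha)\,n = 1$; the expected outbreak reach on the
supercritical side solves $r = 1 - e^{-r(1-\alpha)np}$
(`solve_outbreak_fraction()`, bisection; the rearranged form
$(1-\alpha)np = -\ln(1-r)/r$ is `outbreak_mean_degree()`). Above
$p = \log((1-\alpha)n)/((1-\alpha)n)$ the susceptible network is
asymptotically fully connected. `estimate_percolation_threshold()`
verifies the emergence point by simulation: it sweeps $p$ over a grid
spanning products 0.5–1.5 (step 0.05), averages the largest-component
fraction over replicates, and reports the first grid point crossing an
emergence cutoff of 0.05 of nodes. The cutoff is a finite-size choice —
the theory gives only the asymptotic relation — and is configurable. At
$n = 2000$ the crossing lands near product 0.9: at criticality the
largest component already holds $\sim n^{2/3}$ nodes, so a fixed cutoff
crosses slightly *below* the asymptotic threshold. For a general degree
sequence, the configuration-model threshold is
$\langle d^2\rangle = 2\langle d\rangle$
(`config_supercritical_margin()`); when immune removal is in play the
moments are computed on the residual (post-removal) degree sequence — the
alternative (original moments scaled by $1-\alpha$) is not what the
removal process produces.

### Mean-field spreading

On a roughly homogeneous network the informed density follows the
logistic $di/dt = \lambda i \langle k\rangle (1-i)$. On heterogeneous
(scale-free) networks the mean degree is not informative, so the density
is tracked per degree class $k$, with the early-time closed form

$$i_k(t) = i_0\left[1 + \frac{k\langle k\rangle}
{\langle k^2\rangle - \langle k\rangle}\left(e^{t/\tau}-1\right)\right],
\qquad
\tau = \frac{\langle k^2\rangle}
{\lambda\,(\langle k^2\rangle - \langle k\rangle)}.$$

We implement $\tau$ as printed above. Note that parts of the mean-field
literature normalise the neighbor density by $\langle k\rangle$ rather
than $\langle k^2\rangle$, which yields
$\tau = \langle k\rangle/(\lambda(\langle k^2\rangle - \langle k\rangle))$
instead; the two differ by the factor
$\langle k^2\rangle/\langle k\rangle$. For internal consistency the
comparison ODE integrated by `meanfield_degree_based()` uses the
neighbor density
$\theta(t) = \sum_{k'} (k'-1) P(k') i_{k'}(t) / \langle k^2\rangle$,
the unique uncorrelated-network normalisation whose linearised growth
rate equals the $1/\tau$ above. Both routes are returned; they agree to
within 5% for $t \lesssim 0.1\tau$ and then diverge — the closed form is
an early-time approximation and is additionally capped at density 1.

### Agent-based contagion

`simulate_network_contagion()` runs the process the analytics
approximate: synchronous discrete-time updates in which every adopter
tries to transmit to each susceptible, non-immune neighbor with
probability `transmit_prob * behavioral_degree`, plus spontaneous
adoption. Synchronous updating was chosen because the process
description names no scheduler and synchronous steps are reproducible
and match the mean-field comparisons; there is no recovery in this
process (adoption counts are monotone), so the correspondence with the
SIS-style mean-field equations is early-time only — documented, not
resolved. `behavioral_degree` (the agent's normalised decision strength
to diffuse) defaults to 1 for every agent; the model introduces the
variable without a distribution, so heterogeneous values are accepted
as per-node input rather than invented. When comparing simulated
outbreaks with the analytic $r$, runs are conditioned on an outbreak
(>1% adopted): $r$ describes the giant-outbreak branch only, and the
unconditioned mean mixes in runs whose seed landed in a small component.

## Dyadic behavior contagion as information

Between two individuals, the "contagion" of an event with probability
$p$ is $I(p) = \log(1/p)$ — non-negative, additive over independent
events, zero for a sure event. Its expectation over a distribution is
the entropy $S(P) = \sum_i p_i \log(1/p_i)$ (with $0\log(1/0) := 0$).
The module provides the Kraft–McMillan feasibility sum, the
source-coding bound $S(B) \le L\log\beta$, mutual contagion
$I(F;G) = S(F) - S(F|G)$ with all identities computed by direct
summation, channel capacity $C = \max_{P(f)} I(F;G)$ via the
Blahut–Arimoto alternating maximisation (monotone lower bound; stops
when the upper/lower gap is below tolerance), and maximum-entropy
distributions $f_i = \exp(-\lambda - \sum_r \lambda_r s_i^{(r)})$ with
multipliers found by minimising the convex dual (BFGS plus a damped
Newton polish on the constraint residuals; $\lambda = \ln H$ with $H$
the partition sum). Internally everything is computed in nats and
converted at the interface — the measure is defined for any base (bits,
trits, nats, Hartleys), so no base is privileged. The channel is
accepted in the forward orientation $P(g|f)$, since capacity is
conventionally a maximum over input distributions; a backward
characterisation $\{P(f|g)\}$ plus output marginal can be converted with
`channel_from_backward()`. Deterministic rows are handled by the
$0\log 0$ convention. What the symbols $f_i, g_j$ are empirically — how
a dyadic behavior stream is discretised — is deliberately left open;
this module stays at the probabilistic layer.

## Calibrating the adoption parameters from physiology

The link between measurement and simulation is a stress-threshold rule
over baseline-relative index changes. For each subject, each
physiological index (HRV time- and frequency-domain measures, facial
EMG, skin conductance, respiration, EEG band powers and frontal alpha
asymmetry) is measured at rest (Baseline) and under five conditions:
four media-based stress-imitation inductions (VR, AUDIO, TEXT, VIDEO)
and a time-pressure COGNITIVE_TASK. The delta is
$\Delta = (x_{cond} - x_{base})/|x_{base}|$ — a *relative* change, so a
threshold "ST, %" is comparable across indexes with wildly different
units (ms², µS, dimensionless ratios); the rule's source declares ST a
percentage but never fixes the normalisation, and this is our choice.
Self-report scales (SUS presence, PMQ anxiety/relaxation) use raw
post-minus-pre differences on their own scales.

A subject is flagged as stressed in a condition when any of five clause
blocks fires (see `apply_stress_rule()`), with three resolved
ambiguities worth recording:

* The printed rule writes decrease clauses as "$\Delta < ST$", which
  would fire almost always for $ST \ge 0$; they are implemented as a
  decrease beyond the threshold, $\Delta < -ST$, consistent with the
  physiology (e.g. zygomatic activity and vagal HRV indexes fall under
  stress). The full direction table is configurable.
* The brace nesting of the facial block is read as
  ({EMG-Z down OR EMG-CS up} AND skin conductance up): electrodermal
  arousal is the conjunctive gate.
* The "n-tuple (couple, triple, ...)" combination block is a
  configurable minimum count (default 2) over the autonomic-plus-EEG
  sub-rules; the tuple size is not fixed by the source. EEG indexes
  participate only in this block.

The SUS clause ($\Delta(\mathrm{SUS}) > 0$) is kept as printed but
switchable: a presence questionnaire marks that the induction *worked*,
not that the subject is stressed, and because it ignores ST it breaks
strict flag monotonicity in the threshold — the monotonicity property is
verified with the clause off. The HF band's upper bound defaults to
0.4 Hz with an override, since both 0.4 and 0.5 Hz appear in standard
definitions. `TOTPWR` is total spectral power up to the HF upper bound.

Per group, `adoption_fraction` is the proportion of subjects flagged in
the cognitive task (direct stress propensity) and
`imitation_effectiveness` the mean over the four media conditions of the
proportion flagged (propensity to acquire stress from depicted others).
The mapping from flags to parameter magnitudes is not specified beyond
"positive"; the proportion-of-flagged-subjects estimator is this
package's documented choice — it is bounded in $[0,1]$, unbiased for the
responder probability, and monotone in ST. RSA is accepted as a
precomputed index only (peak-valley vs. spectral computation is not
specified). `threshold_sweep()` exposes the dependence of both
parameters on ST, which is a substantive modeling dial: the simulated
dynamics describe diffusion *of stress at that severity*.

## The synthetic cohort: what it emulates and what it does not

No deposited data exist for this design, so `generate_index_table()`
emulates a cohort at the index level with known ground truth. The fixed
study conditions are: two groups of 26 (female) and 16 (male) subjects;
responder probabilities 0.8 and 0.4 per condition; responder effect size
0.25 (a 25% baseline-relative shift in each index's stress direction —
an ordinary magnitude for autonomic stress reactivity) over relative
noise of sd 0.05, i.e. effects five times the noise; baselines drawn
around plausible resting magnitudes (850 ms mean NN, SDNN 50 ms, LF/HF
1.5, ...) listed in `default_index_profiles()` with 15% between-subject
variability — the source prints none, so these are code constants chosen
once. Self-report deltas are emitted already differenced: responders
shift in the stress direction; non-responders drift mildly the other way
(habituation over a session), so the self-report clauses have a low
false-alarm rate. SUS rows exist only for the four media conditions — a
presence questionnaire does not apply to a cognitive task — which keeps
the presence clause from contaminating the adoption-fraction estimate.

The generator also produces NN-interval series with sinusoidal
modulation at the LF/HF band centers (0.10/0.30 Hz — clean band
separation for spectral tests) and Gaussian noise, with a 200 ms
physiological floor.

What passing tests show: the calibration pipeline recovers planted
responder shares within binomial error, the rule's clauses fire exactly
as specified, and the spectral indexes land in the band that was
modulated. What they do not show: realism of waveform morphology,
artifacts, non-stationarity, correlated index noise within subjects, or
any property of real human data — the generator is index-level only, and
real cohorts will have messier delta distributions than
Gaussian-around-baseline.

## The integrated policy model

`run_integrated_model()` reconstructs the integrated
agents + system-dynamics + discrete-event architecture in simplified
form: each agent's "SD output" is an exponentially smoothed function of
its adoption state (smoothing constant configurable; 1 makes it the raw
state) — the original names this coupling without giving block
equations, so this layer is an explicit reconstruction, not a
reproduction. Agents above the output threshold enqueue one
behavior-change request (no duplicates while queued); a FIFO queue with
per-step service capacity models the public policy; each served request
reverts the agent with a success probability. FIFO with one pending
request per agent is the simplest discrete-event discipline consistent
with a single service block.

## Problem sizes and determinism

Every stochastic routine takes a `seed` and restores the caller's RNG
state, so identical configuration and seed give identical results, and
the scenario runner writes a manifest sufficient to re-run a scenario
exactly. The simulation sizes used in the test-suite and in
`scripts/acceptance.R` — percolation sweeps at $n = 2000$ with 30
replicates per grid point, outbreak Monte Carlo at $n = 5000$ with 200
replicates, 100 calibration replicates of the 42-subject cohort — are
the package's reference problem sizes: large enough that binomial and
finite-size errors sit well inside the tolerances asserted, small enough
to run routinely.

## Known limitations

* The closed-form degree-based mean field is early-time only, and its
  relaxation time follows the printed
  $\langle k^2\rangle$-normalisation (see above); users comparing
  against the $\langle k\rangle$-normalised literature must rescale.
* The agent contagion process has no recovery, so it is an SI process on
  a finite graph; SIS/SIR agent dynamics are out of scope.
* The calibration estimator equates flagged proportion with propensity;
  any monotone transformation of flag counts would also be consistent
  with the source.
* The empirical figures of the original study print no numeric
  parameters, so no attempt is made to reproduce them; all quantitative
  claims here are property-based or derived from printed relations.
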