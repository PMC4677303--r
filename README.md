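# agdyn — stochastic evolutionary dynamics of the Anticipation Game

Behavioural experiments show that dictators in a Dictator Game (DG) become
markedly more generous when a partner-acceptance phase is added: before each
round, the receiver may inspect the dictator's recent donations and refuse to
play, in which case both earn nothing. `agdyn` implements the evolutionary
analysis of this *Anticipation Game* (AG) for researchers in evolutionary
game theory and experimental economics: it explains *where the generosity
comes from* — dictators anticipating that a low donation today lowers their
probability of being accepted tomorrow.

## The model

Two finite populations of *N* individuals each (dictators, receivers)
interact across populations and evolve within their own. A dictator's
strategy is an integer donation *p* ∈ {1, …, X} out of an endowment of
*X* = 10 ECU; a receiver's strategy is a minimum expectation *q*: she accepts
when *p* ≥ *q* (in the restricted model *q* ≤ 5 — receivers do not demand
more than half the endowment). With probability ω the receiver knows the
dictator's action (ω = 1: AG; ω = 0.5: noisy AG); when uninformed she falls
back on a baseline expectation *q₀*.

Strategies spread by pairwise comparison: a learner imitates a random role
model with the Fermi probability [1 + e^(−β Δf)]⁻¹, where β is the intensity
of selection. In the rare-mutation limit the dynamics reduce to a Markov
chain over homogeneous states (*p*, *q*) whose transitions are single-mutant
fixation probabilities; the stationary distribution π is the eigenvector of
Mᵀ at eigenvalue 1 and its mean donation is a decreasing function of β, which
is what calibration against the experimental averages exploits.

The package's core extension couples the dictator's fitness to the
receiver population's *acceptance curve* A(p) — the probability that a
randomly drawn receiver accepts a donation *p*:

```
f_D(p) = (1 − δ) (X − p) a_now + δ (X − p) A(p)
```

with zero on rejection. The future-importance weight δ ∈ [0, 1] makes
anticipation explicit: δ = 0 recovers the basic stochastic model, δ = 1 makes
success depend solely on anticipated future acceptance. Since A(p) is
generated by the evolving receivers, the coupled system is solved as a damped
fixed point.

A forward Monte Carlo simulator (explicit mutation rate μ, Rcpp core) verifies
the embedded chain, and a synthetic-session generator emulates the
experimental protocol (30 rounds, 3 initiation rounds, 3-round reputation
history, random re-matching, information coin-flips) for testing the
summary-statistics pipeline.

## Worked example

```r
library(agdyn)

## restricted Anticipation Game, basic model (delta = 0)
cfg <- game_config("AG", q_max = 5)
sp  <- population_spec(cfg, N = 100)

## which selection intensity reproduces the observed 4.2 ECU average?
calibrate_beta(sp, cfg, target = 4.2)
#> <calibration_result> AG (delta=0, omega=1): beta* = 0.005233 in [0.003652, 0.007499]
#>   mean donation 4.1831 (target 4.20)

## anticipatory model: high future importance at stronger selection
cfg75 <- game_config("AG", q_max = 5, delta = 0.75)
fp <- solve_self_consistent(population_spec(cfg75), cfg75, beta = 0.05)
fp
#> <fixed_point_result> beta=0.05 delta=0.75: mean p = 3.0052, mean q = 2.0026 (33 iterations, residual 7.21e-09)
fp$curve
#> <acceptance_curve>
#>      1      2      3      4      5      6      7      8      9     10
#> 0.3333 0.6666 0.9975 1.0000 1.0000 1.0000 1.0000 1.0000 1.0000 1.0000
```

The calibration result says a selection intensity β ≈ 0.005 reproduces the
observed treatment average, with the bracket giving the β region that fits;
the same region also fits the DG target (2.2 ECU), which is the model's
predictive-transfer property. The fixed-point solve shows the anticipatory
model at work: with δ = 0.75 the dictator population concentrates around
3 ECU donations, and the acceptance curve saturates at 1 for every donation
≥ 5, matching the behaviour of experimental receivers.

A command-line wrapper exposes the same machinery
(`inst/scripts/agdyn-cli.R` with subcommands `sweep`, `solve`, `scan`,
`calibrate`, `simulate`, `sessions`), writing CSV tables plus a provenance
JSON per run.

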