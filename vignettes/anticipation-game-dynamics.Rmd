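---
title: "Evolutionary dynamics of anticipation in the Dictator Game with partner acceptance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary dynamics of anticipation in the Dictator Game with partner acceptance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agdyn)
```

## The games and their strategy spaces

The Dictator Game (DG) gives a dictator an endowment of $X = 10$ ECU; she
donates an integer $p \in \{1,\dots,10\}$ and keeps $X - p$. The minimum
donation of 1 avoids a second subgame perfect equilibrium at zero and makes
the receiver strictly prefer playing. The Anticipation Game (AG) prepends a
matching phase: the receiver may refuse the proposed dictator based on the
dictator's past donations, and refusal leaves both with zero payoff. In the
model the receiver's strategy is an integer threshold $q$ — the minimum
donation she expects — and receivers are assumed to infer the dictator's
donation perfectly, so acceptance depends on the current $p$ rather than on a
stored history. Ties accept: "expects at least $q$" means $p \ge q$.

Three design choices deserve comment:

* **DG is a separate variant, not the $\omega = 0$ limit of AG.** The DG
  receiver has no action at all; an uninformed AG receiver still applies the
  baseline expectation $q_0$ and would reject donations below it.
* **Restricted receiver space.** The basic model lets $q$ range over
  $1,\dots,10$, but experimental receivers essentially always accept
  donations of at least half the endowment. The restricted model caps
  $q \le 5$; all headline analyses use it.
* **Baseline expectation $q_0 = 2$.** When uninformed, receivers are taken
  to expect no more than the average DG donation ($\approx 2.2$ ECU),
  rounded to the nearest feasible integer donation. It is a configurable
  field of `game_config()`.

Partial information ($\omega < 1$) admits two acceptance semantics, both
implemented behind `acceptance_mode`:

* `THRESHOLD_MIX` (default): the receiver's effective expectation is the
  convex combination $\omega q + (1-\omega) q_0$ and acceptance is the
  deterministic threshold rule against it;
* `BERNOULLI_MIX`: a per-round information coin-flip,
  $A = \omega\,\mathbf{1}[p \ge q] + (1-\omega)\,\mathbf{1}[p \ge q_0]$.

They agree exactly at $\omega \in \{0, 1\}$, which is asserted in the test
suite. The default follows the "weighted combination of expectations"
reading; the Bernoulli mode mirrors what the session generator does round by
round.

## Imitation dynamics and the embedded chain

Each population holds $N = 100$ individuals (a `population_spec()` field).
Strategies spread by pairwise comparison: a learner imitates a random role
model of its own population with the Fermi probability
$[1 + e^{-\beta(f_{\mathrm{other}} - f_{\mathrm{self}})}]^{-1}$. Payoffs are
averages against the opposite population's composition, which has a useful
consequence: during the fixation of a single mutant the payoffs of mutant
and resident do not depend on the mutant count, so the fixation probability
collapses to the geometric closed form
$\rho = (1-\gamma)/(1-\gamma^N)$ with
$\gamma = e^{-\beta(f_A - f_B)}$. The implementation evaluates it via
`expm1`, switching to log-domain arithmetic for disfavoured mutants so that
$\beta|\Delta f|$ of several hundred remains finite; the general
sum-of-products formula is retained in the test suite as an independent
oracle and agrees to $10^{-12}$ over randomised grids. At $\gamma = 1$ the
neutral value $1/N$ is returned exactly.

In the rare-mutation regime ($\mu \ll 1/N$) at most one mutant lineage
segregates at a time, and the long-run dynamics reduce to a Markov chain
over homogeneous states $(p, q)$. A mutant arises in either population with
probability $1/2$, uniformly among the other strategies of that population;
scaling both weights by a common factor merely makes the chain lazier and
leaves the stationary distribution unchanged (asserted in a test), whereas
asymmetric reweighting would change it — the symmetric split is a modelling
choice, not a free normalisation. The stationary distribution is the eigenvector of $M^\top$ at
eigenvalue 1. If the eigensolver reports more than one eigenvalue within
$10^{-9}$ of 1 the solver stops with an error rather than choosing
arbitrarily; a power-iteration fallback covers poorly conditioned solves,
and any result with residual $\lVert \pi M - \pi \rVert_\infty > 10^{-8}$ is
treated as a failure. In practice residuals are at rounding level
($< 10^{-10}$, asserted).

Mean donation and mean expectation are decreasing in $\beta$, which makes
calibration a bisection problem: `calibrate_beta()` halves a logarithmic
bracket until the achieved mean donation is within 0.05 ECU of the target
(the experimental averages are printed to one decimal) or the bracket is
relatively narrower than $10^{-3}$. Sweeps default to a 60-point logarithmic
$\beta$ grid from $10^{-4}$ to $10$, which covers neutral drift through
effectively deterministic selection.

## Anticipation: the acceptance curve and the $\delta$-fitness

The acceptance curve of a receiver population with marginal $m(q)$ is
$A(p) = \sum_q m(q)\, a(p, q)$, with $a$ the acceptance rule. It is computed
in complement form, $1 - \sum_q m(q)(1 - a(p,q))$, so that saturation at 1
is exact in floating point — in the restricted model with $\omega = 1$,
$A(p) = 1$ for all $p \ge 5$ identically, not approximately.

The anticipatory dictator fitness weighs the current payoff against the
payoff of the next round, scaled by the probability that the *next* receiver
accepts the current donation:

$$f_D(p) = (1-\delta)(X-p)\,a_{\mathrm{now}} + \delta\,(X-p)\,A(p),$$

zero when the matched receiver rejects (present and future are both lost).
The current-round term uses the matched resident receiver's decision, the
$\delta$-term uses $A(p)$: this separates "now" (the matched partner) from
"future" (a random re-match), mirroring the game's per-round random
matching. Receiver fitness stays the plain stage payoff — anticipation is a
dictator-side trait.

Which receiver distribution generates $A(p)$ is genuinely open in a
monomorphic-resident model: with residents only, $A(p) \in \{0,1\}$ at
$\omega = 1$ and $\delta$ would be inert. The package therefore takes $A(p)$
from the receiver marginal of the coupled stationary distribution and solves
the pair self-consistently: build the chain under the current curve, compute
$\pi$, recompute the curve from the receiver marginal, and update with
damping $1/2$ (plain iteration can oscillate between curve/distribution
pairs; damping is the standard remedy). Iteration stops when the sup-norm
change of the curve drops below $10^{-8}$, with a 200-iteration cap; on the
default scan grid convergence takes some tens of iterations per cell
(asserted in the tests). Uniqueness of the fixed point is not claimed: the
solver reports the fixed point reached from the uniform-receiver start, and
`check_fixed_point_multistart()` re-solves from five random monotone initial
curves under a fixed seed and reports the maximum discrepancy (at the tested
parameters, $< 10^{-6}$). A `one_shot` flag keeps the uniform-receiver
baseline for comparison. At $\delta = 0$ the curve does not enter the
fitness and the solve is bit-identical to the basic chain, which the tests
assert.

Two qualitative properties anchor the extension: at fixed $\beta$ the mean
donation is nondecreasing in $\delta$, and for a fixed donation target the
best-fitting $\beta$ shifts upward as $\delta$ grows. Both are asserted on
computed scan tables rather than stated. Two edge cases are worth knowing.
At $\delta = 1$ the mean donation is *not* monotone in $\beta$: once only
the future matters, strong selection maximises $(X-p)A(p)$, which lands on
$p = q_{\max} = 5$ (every receiver then accepts, making receivers neutral
and their marginal uniform — a self-consistent fixed point), so the
donation-versus-$\beta$ curve dips and comes back up. And in the noisy AG
the strong-selection donation is 2, not 1: an uninformed receiver applies
the baseline $q_0 = 2$, so 1-ECU donations are rejected whenever the
history is missing and the minimum viable donation is the baseline itself.

## Monte Carlo verification

`monte_carlo()` simulates the full process with explicit mutation: per
update, a population is chosen with probability $1/2$ (only the dictator
population in DG), a learner uniformly; with probability $\mu$ it adopts a
uniformly random strategy of its set (including possibly its current one, so
$\mu$ is comparable across strategy-set sizes), otherwise it imitates a
random role model via the Fermi rule. The compiled core exploits an exact
event-skipping identity: while both populations are homogeneous, imitation
cannot change anything, so the waiting time to the next mutation is
geometric and can be drawn in one step with the occupancy credited in bulk.
This is distributionally identical to the naive loop and makes multi-billion
update runs feasible. All randomness flows through R's RNG, so a fixed seed
reproduces trajectories bit for bit.

The empirical counterpart of the embedded chain's stationary distribution is
the occupancy of homogeneous states (time spent while both populations are
monomorphic, $>90\%$ of updates at $\mu = 10^{-4}$). The verification runs
compare this occupancy to $\pi$ in total variation at three $\beta$ values
spanning weak, fitted and strong selection, at $\mu = 10^{-4}$: the DG
comparison uses $N = 50$ and $2\times10^9$ updates, the AG comparison
$N = 25$ and $4\times10^9$ updates. These sizes give roughly $10^4$
fixation events — enough to resolve total variation well below the 0.05
agreement threshold — while keeping the whole comparison to a few minutes;
$\mu \ll 1/N$ holds throughout, and each Monte Carlo run is compared to the
embedded chain at its own $N$.

## The synthetic-session generator

`generate_sessions()` emulates the behavioural protocol: 9
dictator–receiver pairs per session (18 subjects), 30 rounds, the first 3 a
forced-play DG initiation that seeds each dictator's 3-round history, random
re-matching every round, per-round information coin-flips at rate $\omega$,
acceptance against the mean of the 3-round history (the experiment shows
receivers three amounts; a `"last"` mode is provided since the model text
speaks of the last *or* average action), history updates only on accepted
rounds, and optionally a final round at the dictator's plain-DG donation —
the experimental signature that AG generosity is strategic. Strategies are
drawn from a user-supplied source, e.g. a model stationary distribution.

The generator is a test harness for the summary-statistics pipeline
(`session_summaries()`: per-session and pooled mean donation, acceptance
rate, per-round series, donation histogram, informed/uninformed split). It
emulates the protocol, not the subjects: strategies are fixed for a session
(no within-session learning), receivers use exact thresholds (no noisy
choice), and payoff-to-currency conversion is ignored. Passing tests
therefore validate the bookkeeping and the model-to-protocol interface, not
behavioural realism of individual subjects.

## Limitations

* $\delta$ is a system-level parameter, not an evolving individual trait;
  making it part of the behaviour is explicitly future work.
* The refusal-count information of the third experimental treatment is not
  modelled; the model does not distinguish treatments 2 and 3.
* Analytic stationary distributions are available only in the small-mutation
  limit; non-vanishing mutation rates are covered by the Monte Carlo
  simulator alone.
* The experimental averages (2.2 / 4.2 / 3.5 ECU; 83% / 89% acceptance) are
  human-subject data packaged as calibration targets via
  `calibration_targets()`; the package fits to them but cannot re-derive
  them.
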