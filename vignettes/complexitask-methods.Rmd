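---
title: "A complexity-rewarded choice task: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A complexity-rewarded choice task: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the deterministic reward rule, the learning agents, the variability
statistics, the fitting machinery, and — importantly — the places where the
design was genuinely open and a choice had to be made.

## The task

A subject moves between three reward locations $\{A, B, C\}$ and may never
choose the location it currently occupies, so behavior is a sequence of
binary choices. Three reward regimes are implemented:

* **training** — every choice is rewarded;
* **complexity** — at each trial the window of the nine past choices plus
  each candidate option (10 symbols in total) is scored with Lempel–Ziv
  complexity; the option(s) achieving the weakly highest score are the
  rewarded ones. The rule is fully deterministic;
* **p75** — every choice is rewarded with probability 0.75 regardless of
  the sequence, matching the success level a uniform random chooser attains
  under the complexity rule.

Because a length-9 no-repeat history has $3 \times 2^8 = 768$ possible
values and each has exactly two extensions, the complexity rule is a finite
decision tree. `enumerate_tree()` scores all of it: every history offers
either a tie (both options rewarded; probability 1 of reward under a coin
flip) or a single winner (probability 0.5). Exactly half the histories tie,
which forces the overall uniform-choice success rate
$1 \cdot \tfrac12 + 0.5 \cdot \tfrac12 = 0.75$. Three consequences anchor
everything else: a greedy complexity-following policy is rewarded on every
scored trial, a uniform random policy earns 75%, and the circular pattern
$A,B,C,A,B,C,\dots$ earns nothing.

### The LZ76 convention

Lempel–Ziv complexity counts the components of the exhaustive production
history of a string. Conventions differ on the terminal component: some add
one for a tail that is fully reproducible from its prefix, some do not.
`lz_complexity()` counts **only innovation-terminated components**: the
periodic window `ABCABCABCA` parses to 3 (`A·B·C` + a reproducible tail)
while `ABCABCABCB` parses to 4 (the tail ends with an innovation). Under
the "+1 for the tail" alternative both windows would score 4, the rule
could no longer penalize the circular pattern, and none of the three
anchors above would hold. The chosen convention is validated in the test
suite by brute-force re-parsing of every 3-letter string up to length 10
and by the three anchors themselves.

### Warm-up

The first nine trials of a session have no full window. The reward rule for
them is not derivable from the task definition, so both plausible behaviors
are implemented: `reward_all` (default — these trials are rewarded, which
mirrors the preceding 100%-reward training and keeps session success rates
simple) and `skip` (the rule is applied to the shorter available window).
Post-warm-up rewards are identical under both. Success rates of re-scored
sequences (`evaluate_sequence()`) are always computed over post-warm-up
trials only.

## The agent

The agent is Rescorla–Wagner learning with a softmax policy over the two
legal actions:

$$\Delta Q(s_t, a_t) = \alpha\,(U_{t+1} - Q(s_t, a_t)), \qquad
P(a \mid s_t) = \frac{e^{Q(s_t,a)/\tau}}{\sum_{a'} e^{Q(s_t,a')/\tau}}$$

with a utility that discounts rewarded U-turns (returns to the location of
two steps ago): $U_{t+1} = (1-\kappa)\,r_{t+1}$ on a U-turn, $r_{t+1}$
otherwise. The state $s_t = [S_t, S_{t-1}, \dots, S_{t-m}]$ carries a
memory of $m$ past locations; with representation ambiguity $n > 1$ each
location is replaced by one of $n$ interchangeable codes, redrawn
independently at every encoding event (the simplest reading of an ambiguous
state; a fixed random code map per run is the plausible alternative and was
not chosen).

Parameters, units and defaults:

| parameter | meaning | range | notes |
|---|---|---|---|
| $\alpha$ | learning rate | $(0,1]$ | fixed at 0.1 in session-wise fitting |
| $\tau$ | softmax temperature | $>0$ | utility units |
| $\kappa$ | U-turn cost | $[0,1]$ | multiplicative on reward |
| $m$ | memory size | $0..9$ | the window bounds useful memory |
| $n$ | ambiguity | $\ge 1$ | codes per location |
| $\rho=\tau/\kappa$ | randomness | $>0$ | the effective stochasticity |

Numerical choices: softmax is computed after subtracting the maximal value;
Q-values initialize at 0 — utilities live in $[0,1]$, so this is
*pessimistic* initialization, chosen deliberately so that structure is
discovered through the reward stream rather than forced by optimistic
exploration. Each session starts at a uniformly drawn location, the first
move is never a U-turn, and the task history buffer (not the value table)
resets at session boundaries.

### The two regimes of randomness

Randomness $\rho$ has opposite effects depending on memory. Small-memory
agents cannot tell rewarded from unrewarded situations apart, drift into
poorly rewarded stereotyped cycles at low $\rho$, and are rescued by
randomness toward the 75% of a uniform chooser. Large-memory agents can
resolve the deterministic tree and exceed 75% at low $\rho$; randomness
only dilutes that. `memory_regime_sweep()` measures the boundary — the
largest $m$ at which the high-$\rho$ run still beats the low-$\rho$ run —
and finds it at $m = 3$ with the default pair $\tau_{low} = 0.2$,
$\tau_{high} = 2.5$ at $\kappa = 0.5$ ($\rho$ 0.4 vs 5).

The low temperature deserves a comment, because it was a real choice. Near
the zero-temperature limit the softmax entrenches whatever the first
rewards single out, and we observed that even 2-step-memory agents then
lock into fully rewarded cycles ($\hat S = 1$): the task is solvable by
soft-greedy lock-in with surprisingly little memory. In that limit the
sweep no longer measures the memory dependence of interest. $\tau_{low} =
0.2$ sits above the lock-in regime while still being clearly
exploitation-dominated; the boundary at 3 is then stable across seeds.

## Variability statistics

* **NLZcomp** — LZ complexity divided by the mean LZ complexity of 1000
  random sequences of the same length that respect the no-repeat
  constraint. Close to 1 for uncorrelated choice, far below 1 for
  repetitive behavior. The surrogate ensemble is drawn from its own
  fixed-seed stream and cached by (length, count, seed): sessions of equal
  length share one normalizer, so values are comparable across sessions and
  deterministic.
* **RQA ENT** — Shannon entropy (natural log) of the distribution of
  diagonal-line lengths in the symbolic recurrence plot (recurrence =
  equal locations, line of identity excluded, upper triangle, minimal line
  length 2). Diagonals are recurring patterns, so the entropy is *high*
  for structured sequences (a period-3 circle of length 30 has nine
  distinct diagonal lengths: entropy $\ln 9$) and lower for random ones.
  The settings mirror the defaults of standard recurrence-analysis
  software; the log base is a declared choice, not an inference.
* **U-turn rate** — fraction of trials 3..T that return to the location of
  two steps back. (The first two trials have no defined U-turn; the
  denominator is $T-2$.)
* **Surrogate test** — two-sided empirical rank of the raw LZ count within
  the surrogate ensemble, with the $(r+1)/(B+1)$ correction; sequences with
  $p > 0.05$ are flagged indistinguishable from random. The raw count is
  used rather than NLZcomp (they differ by a fixed factor, so the test is
  identical); statistic and sidedness are declared choices.
* **Pattern histogram** — counts of the length-10 windows starting at A,
  in decision-tree (lexicographic) order so neighboring branches share
  prefixes, plus the ranked cumulative distribution.

## Fitting and model comparison

The session-wise fit asks which $(\tau, \kappa, m)$ make the converged
agent behave like a given session, scoring candidates with
$\mathrm{fitness} = 1 - \tfrac12(|\hat S - \bar S| + |\hat C - \bar C|)$
(U-turn rate replaces success rate for training sessions, where everything
is rewarded). Candidates come from random search: $\tau$ and $\alpha$
log-uniform, $\kappa$ uniform, $m$ a uniform integer, with $\alpha$ fixed
at 0.1 in session-wise mode. Since a converged run's statistics do not
depend on which session they are compared against, one simulated pool is
scored against every session target, making per-session leaderboards
directly comparable. Default search ranges ($\alpha \in [0.01,1]$,
$\tau \in [0.01,10]$, $\kappa \in [0.01,1]$, $m \in 0..9$) are declared
defaults, overridable.

The continuous mode simulates the whole trajectory (10 training then
complexity sessions of 200 trials) and averages fitness over the last
training session and the complexity sessions, each parameter set over
several runs; `grid_search()` applies the same scoring to an explicit grid
so that values stay comparable across ambiguity levels.

`bayes_factor()` compares the two modes by approximate Bayesian
computation: each model's likelihood is the fraction of its retained best
fits (15 by default) whose $(\hat S, \hat C)$ fall inside the 95%
confidence intervals of the data, averaged per session when several are
given; the Bayes factor is the ratio, with $B > 3$ read as substantial. A
zero denominator is reported as $+\infty$ with a flag — no smoothing is
applied, because none is defined for the procedure. A simulated
$\hat C$ can exceed 1 by sampling noise, so complexity terms are clamped
into $[0,1]$ before the distance.

## The synthetic cohort

`generate_cohort()` stands in for behavioral data. It generates each
subject with the package's own agent — not by resampling any recorded data
— which makes parameter recovery a well-posed test: the generating
randomness schedule is known exactly. Defaults: 27 subjects, 10 training +
10 complexity sessions, 100–200 trials per session, $\kappa = 0.5$ fixed,
$\tau$ at 0.15 in training and rising geometrically 0.15 → 0.5 across
complexity sessions ($\rho$ 0.3 → 1), value tables carried across
sessions. Group G1 continues into the probabilistic condition after the
complexity phase; group G2 enters it directly after training; each group
keeps its preceding parameters there, since a reward that ignores behavior
provides no gradient to change them.

Two generator choices matter and are worth stating plainly:

* **Memory 1, not 0.** A memory-free agent cannot represent U-turn
  aversion — its state lacks the previous location — so at low temperature
  it entrenches an arbitrary transition graph, most often a two-location
  ping-pong with a U-turn rate near 0.9. The circular, U-turn-free
  training behavior the cohort must emulate is only representable with
  $m \ge 1$. With $m = 1$ the training sessions converge to U-turn rates
  below 0.02.
* **Training temperature 0.15.** Cold enough that the converged circular
  pattern is nearly deterministic, warm enough that the forward action is
  sampled everywhere before the U-turn value entrenches.

With these defaults the cohort reproduces the intended group-level
trajectory: training success 1 with U-turn rate → 0.01; complexity success
rising from ≈0.48 to ≈0.74 (inside the 0.70–0.78 band around the 75%
random-choice ceiling), NLZcomp rising from ≈0.62 to ≈0.99, U-turn rate
rising from ≈0.18 to ≈0.36; and the G1/G2 contrast in the probabilistic
condition (G1 keeps complexity ≈0.95 and U-turn ≈0.34; G2 stays at ≈0.36
and ≈0.06).

What the generator does **not** emulate: locomotion timing, inter-trial
intervals, spatial trajectories, per-subject parameter heterogeneity
beyond seed variation, session-to-session forgetting, and trials whose
reward attribution is uncertain (the session format carries a validity
mask for the latter, but the generator never sets it). Passing tests on
this cohort show that the pipeline recovers what the model class planted;
they cannot show that real animals are described by this model class.

## Problem sizes and runtime choices

Simulation-heavy checks run at sizes chosen to make their statistics
stable: reference policies at $10^4$–$10^5$ trials, the regime sweep at
$2 \times 10^5$ trials per run (the fitting default; the original
convergence scale of $2 \times 10^6$ is configurable), random-search
budgets of 40–100 with $2\times10^4$–$4\times10^4$ trials per candidate,
cohorts of 8–27 subjects. The exhaustive oracle comparisons (all
$\le$ length-10 strings for LZ, random sequences to length 25 for the
recurrence entropy) are complete, not sampled, where the space is
enumerable.

## Known limitations

* The recovered randomness $\rho$ saturates once behavior is close to
  uniform: sessions past the complexity plateau constrain $\rho$ only from
  below, so recovery is asserted as a rank correlation, not a value match.
* `fitness_score()` compares two statistics; parameter sets differing only
  in ways those statistics ignore (e.g. large memory at high randomness)
  tie, and leaderboard order among ties is seed-dependent.
* The first trial of a session is a placement, not a choice; it is stored
  with reward 1 (or the Bernoulli draw under p75) and excluded from
  U-turn and direction analyses by construction.
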