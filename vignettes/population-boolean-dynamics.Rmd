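---
title: "Modeling interacting cell populations with stochastic Boolean networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling interacting cell populations with stochastic Boolean networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`boolpop` simulates signalling networks as continuous-time Markov processes
on Boolean states, and couples those simulations to a simple synchronous
model of population turnover and cell--cell communication.

**Within a cell.** A network of $n$ Boolean nodes has state
$S \in \{0,1\}^n$. Each node $i$ carries three expressions: a logic rule
$B_i(S)$ and two transition rates, `rate_up` for the $0\to1$ flip and
`rate_down` for the $1\to0$ flip. In state $S$, every node at 0 whose
`rate_up` evaluates positive, and every node at 1 whose `rate_down`
evaluates positive, defines an enabled transition; with total rate $\rho(S)$
the waiting time to the next jump is $\mathrm{Exponential}(\rho)$ and a
single node flips, chosen with probability proportional to its rate
(exact-jump stochastic simulation). When only a logic rule is given, the
package synthesizes the conventional defaults
`rate_up = @logic ? 1.0 : 0.0` and `rate_down = @logic ? 0.0 : 1.0`, i.e.
unit rate for every flip the logic permits. States with $\rho = 0$ are
absorbing.

**Across cells.** An ensemble of `sample_count` trajectories approximates the
distribution $P_t(S)$, read at the population level as

$$\text{cells in state } S \;=\; \text{total cells} \times P_t(S).$$

A run of length `max_time` ends in a *population update*: every state $S$ of
the end-of-run distribution $q(S)$ receives a weight

$$w(S) = \begin{cases}
0 & \text{death node active in } S\\
2 & \text{division node active (death inactive)}\\
1 & \text{otherwise,}
\end{cases}$$

the step's population ratio is $r = \sum_S q(S)\,w(S) = 1 - P(\text{death})
+ P(\text{division} \wedge \neg\text{death})$, and the relative population
size evolves as $N_k = N_{k-1} r_k$ with $N_0 = 1$. The reweighted
distribution (division flags reset in daughters) is renormalized and seeds
the next run, and the update formulas of the `upp` file refresh external
variables from its joint probabilities -- for example
`$outerL u= 5 * p[(L) = (1)];` makes a receptor's activation rate track the
population-wide ligand level, closing a paracrine loop. Total simulated
time is `steps` $\times$ `max_time`.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `rate_up`, `rate_down` | 1/h | 1.0 via `@logic` | kinetics of each flip; fast vs slow biology |
| `max_time` | h | 1 | window between population updates; must keep the system transient within a window |
| `steps` | -- | model file | number of windows; total time = steps x max_time |
| `time_tick` | h | 0.1 | probability reporting grid (occupancy windows) |
| `sample_count` | -- | 10000 | trajectories per window; Monte-Carlo error $\propto n^{-1/2}$ |
| istate | probability | all nodes 0 | initial Boolean assignment distribution |

The update interval `max_time` is a *modeling* choice, not a numerical
tolerance: death, division and receptor refresh are synchronous events, so
coarser intervals let each window run further toward its internal
equilibrium before the population reacts. In the bundled toy model the
plateau composition shifts by a few percentage points when the interval is
halved or doubled. The package follows the convention of updating hourly
(`max_time = 1`) and documents fixture step counts large enough to reach
their plateaus (20 for the toy model).

## What the fixtures emulate

The fixture builders generate every model the test-suite uses, so the
package is testable without downloads:

* `build_toy_model()` -- a six-node differentiation decision (trigger I,
  signal A, ligand L, receptor R, fates T1/T2) whose receptor either sees
  the cell's own ligand (`innerOn = 1`, independent cells) or an external
  rate refreshed from the population ligand level (`innerOn = 0`,
  interacting cells). The two fates are irreversible and mutually
  exclusive: T2 requires the receptor while A is still off, T1 requires A
  in cells not already committed to T2. Only the interacting variant can
  produce T2 cells; the independent variant provably cannot, because its
  receptor needs the ligand, which needs A.
* `build_telegraph()`, `build_iffl()` -- one-node and four-node motifs with
  closed-form or matrix-exponential solutions, used as analytic oracles.
* `build_random_network()` -- seeded random two-input logic over up to 8
  nodes, the corpus for generator-matrix cross-checks.
* `build_population_motif()` -- a toggle wired to Death and Division
  phenotypes, exercising both update weights.

These fixtures emulate the *mechanisms* (stochastic commitment, paracrine
feedback, census turnover), not real signalling biology: rates are uniform,
networks are small, and no parameter was fit to data. Passing tests show
the machinery is correct, not that any particular pathway model is.

## Numerical choices

* **Vectorised ensemble engine.** All trajectories advance in lock-step;
  per-state transition tables (enabled flips, total rate, cumulative flip
  probabilities) are memoised lazily, which is valid because external
  variables are constant within a window. This is what makes a pure-R
  implementation fast enough for $10^4$--$10^5$ trajectories.
* **Occupancy-weighted reporting.** Window probabilities are time-weighted
  occupancies (lower variance than point sampling); each window's
  distribution is normalized by its realized occupancy total, so it sums to
  1 exactly. The end-of-run distribution is the *point* sample at
  `t = max_time`, because the next window must start from a bona fide state
  distribution at the handoff instant.
* **Residual resampling between windows.** Each window's initial states are
  drawn by residual (stratified) sampling: $\lfloor n p \rfloor$
  trajectories per state outright, the remainder multinomially. The loop is
  a sequential Monte Carlo scheme, and plain multinomial resampling would
  compound noise step after step; residual resampling is unbiased and keeps
  the final composition estimates tight (empirically ~3x smaller standard
  deviation on the toy model's final fate split).
* **Seeding.** One seed drives the whole run; consecutive windows consume a
  single RNG stream. Identical (model, config, seed) gives bit-identical
  results, which the suite asserts.
* **Degenerate cases.** Zero total rate means absorbing (no discrete-time
  fallback); negative evaluated rates are an error; death wins over
  division when both flags are set (a dying cell cannot divide); a step
  ratio below $10^{-12}$ is treated as extinction, the loop stops, and later
  steps record $N_k = 0$ with a truncation flag.
* **Update-formula timing.** Formulas are evaluated on the *post-update*
  normalized distribution -- after dead states are removed and daughters
  added -- so ligand produced by removed cells does not signal into the next
  window. The alternative (pre-update) convention is one isolated function
  call away (`refresh_variables` takes any distribution) and can be tested
  directly; the package commits to the post-update reading.

## Design decisions taken where the design was open

* The file dialect (semicolon-terminated statements, `//` comments,
  `$name u= expr;` update lines, both `[A].istate` and `[A]. istate`
  spellings) is normative for this package and documented in the README;
  the writers emit a canonical form that round-trips structurally.
* `@logic` may be used as a *numeric* rate (e.g. the toy receptor's
  `rate_up = @logic` with logic `$innerOn ? L : $outerL`), so a conditional
  rule can switch between a Boolean drive and a real-valued
  population-dependent rate with one expression.
* Knockdown/knockin perturbations force the initial state as well as the
  rate, so mutants are effective from $t = 0$ regardless of the configured
  istate.
* Division weight is fixed at 2 (two identical daughters); other weights
  are not supported.
* Treatment phases re-apply their edits from the base (possibly mutant)
  model, so each phase states its condition explicitly rather than
  inheriting the previous phase's overrides; a transient ligand pulse is
  expressed as istate 1 plus a degradation rate (e.g. 1/4 per hour for a
  4 h half-life), a constitutive treatment as a ligand knockin.

## Problem sizes used by the checks

The test-suite verifies the simulator against independent oracles: exact
enumeration for the update algebra, closed forms for birth/telegraph
processes (10000 trajectories, 3--4 standard-error bands), matrix
exponentials of the generator for 25 random 2--4-node networks (20000
trajectories at three time points, 4 standard errors), and a splicing check
that a stepped run without census events matches one long run. The
end-to-end toy-model check runs 10000 trajectories over 20 hourly windows
and asserts the final T1/T2 composition within three percentage points of
the 87%/13% plateau; `scripts/acceptance.R` recomputes that composition
from scratch at any seed.

## Known limitations

* No spatial dimension: cells interact only through population-averaged
  probabilities (a well-mixed assumption).
* Boolean abstraction: no dose--response within a node; multilevel species
  need multiple nodes.
* Metabolic networks (reactions consuming reactants) are out of scope.
* The synchronous census update makes results mildly dependent on
  `max_time`; choose it against the fastest population-relevant process and
  check sensitivity.
* Double mutants are available by composing `apply_perturbation()` calls
  but are not enumerated by the sweep by default.
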