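# boolpop

Stochastic simulation of Boolean signalling networks as continuous-time
Markov processes, alternated with synchronous population updates for cell
death, cell division and ligand--receptor communication.

## The problem

Logical (Boolean) models are the workhorse for signalling pathways whose
kinetics are poorly quantified: each gene, protein, complex or phenotype is
a 0/1 node updated by a logic rule. Stochastic continuous-time semantics
(MaBoSS-style) turn such a model into a Markov jump process: a node at 0
whose `rate_up` expression evaluates positive may flip up after an
exponential waiting time, a node at 1 may flip down at its `rate_down`, and
an ensemble of Gillespie-style trajectories yields time-dependent state
probabilities.

A single-cell ensemble, however, describes a population of *independent*
cells. Real populations die, divide, and talk to each other through
ligands and receptors. `boolpop` adds that layer: simulation windows of
length `max_time` alternate with synchronous census updates in which each
state `S` of the end-of-window distribution `q(S)` is weighted

    w(S) = 0  if the death node is active in S        (cell removed)
           2  if the division node is active, death inactive
           1  otherwise

giving the step's population ratio `r = sum_S q(S) w(S)` and the relative
population size `N_k = N_{k-1} * r_k` (`N_0 = 1`). The reweighted
distribution (division flags reset in daughters) is renormalized and starts
the next window, and update formulas refresh external variables from its
joint probabilities -- e.g.

    $outerL u= 5 * p[(L) = (1)];

makes a receptor's activation rate track the population-wide ligand level:
a paracrine feedback loop, with no spatial dimension. The population is
interpreted through `cells in state S = total cells x P(S)`.

Models are plain text in three files: a network definition (`.bnd`: node
blocks with `logic`, `rate_up`, `rate_down` expressions), a configuration
(`.cfg`: `$variable` values, `[A].istate = 0.2 [0], 0.8 [1];` initial
states, `max_time`, `time_tick`, `sample_count`, `seed`) and a population
update file (`.upp`: `death = ...;`, `division = ...;`, `steps = ...;` and
`$var u= formula;` lines). Statements end with `;`, `//` starts a comment,
and two-column `bnet` files can be imported as a starting point
(`import_bnet()`). Genetic screens (`apply_perturbation()`,
`mutant_sweep()`) and sequential treatment schedules (`schedule_phase()`,
`run_schedule()`) run on top of the population loop.

## Worked example

The bundled toy model is a six-node differentiation decision: a trigger `I`
activates `A`; `A` drives the `T1` fate and the ligand `L`; `L` activates
the receptor `R`, which drives the irreversible `T2` fate only while `A` is
still off. The receptor rule `$innerOn ? L : $outerL` switches between
independent cells (`innerOn = 1`: the receptor sees only the cell's own
ligand, and `T2` is unreachable because `R` needs `L` needs `A`) and an
interacting population (`innerOn = 0`: the receptor rate is refreshed each
hour from the population ligand level, so receptors fire in cells whose own
`A` is still off).

```r
library(boolpop)
fx <- build_toy_model(inner_on = 0)
traj <- run_population(fx$model, fx$config, fx$spec, seed = 1)
print(traj)
#> Population trajectory: 20 step(s) x max_time 1 (10000 trajectories/window)
#>   final relative population size: 1
#>   final node marginals:
#>     I            1.0000
#>     A            1.0000
#>     L            1.0000
#>     R            1.0000
#>     T1           0.8952
#>     T2           0.1048
```

About 89% of cells end in the `T1` fate and 11% in `T2` -- the `T2` branch
exists *only* because of the population coupling (with `inner_on = 1` its
probability is exactly 0 at every step). The census stays at 1 because
this model has no death or division nodes. `write_results()` exports the
per-step node probabilities, state distributions, population sizes and a
JSON manifest.

The same runs are available from the shell via the installed script:

```sh
inst/cli/boolpop uprun toy.bnd toy.cfg toy.upp --seed 1 --out results/
inst/cli/boolpop sweep toy.bnd toy.cfg toy.upp --seed 1   # WT + knockdowns
```

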