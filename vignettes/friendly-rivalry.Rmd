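---
title: "Friendly rivalry in the repeated prisoner's dilemma: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Friendly rivalry in the repeated prisoner's dilemma: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(friendlyrival)
```

## The problem

Two players repeatedly face the prisoner's dilemma with payoffs
$T > R > P > S$ and $2R > T + S$ (every result in this package in fact only
needs $R > P$, $2R > T+S$ and $T > S$, which also covers the snowdrift and
stag-hunt orderings).  Classic strategies divide into *partners*, which
secure mutual cooperation and make unilateral deviation unprofitable, and
*rivals*, which guarantee they are never outperformed by the co-player.
Under rare implementation error ($e > 0$, an intended action is flipped
independently with probability $e$) these two roles pull in opposite
directions: a partner must forgive an erroneous defection that a rival must
punish.  This package provides the machinery to decide, for deterministic
strategies that condition on the last $m$ rounds of both players, whether a
strategy manages to be both — a *friendly rival* — and to study the
evolutionary consequences.

A memory-$m$ strategy is a map from joint states
$(A_{t-m}\dots A_{t-1},\,B_{t-m}\dots B_{t-1})$ to an action.  We pack a
joint state into the integer $(h_A \ll m)\,|\,h_B$ with $c = 0$, $d = 1$ and
the oldest action in the most significant bit, so full cooperation is always
state 0; a strategy's integer id has bit $i$ equal to 1 iff it defects at
state $i$.  There are $2^{4^m}$ such strategies: 16 at $m=1$, 65,536 at
$m=2$, and $\approx 1.8\times 10^{19}$ at $m=3$, which is why the package
enumerates $m \le 2$ exhaustively and only samples or certifies individual
strategies at $m = 3$.

## The three criteria

**Efficiency.**  In self-play, mutual cooperation must be reached with
probability one as $e \to 0^+$.  Error-free self-play of a deterministic
strategy is a deterministic map on joint states whose recurrent classes are
the cycles of its functional graph.  The noisy chain is a small random
perturbation of this map, and its stationary distribution concentrates, as
$e \to 0$, on the classes minimising the Freidlin–Wentzell weight $W$: for
each recurrent class, $W$ is the minimal total number of action flips over
spanning in-arborescences of the class graph, where the cost of an edge
between classes is the least number of flipped actions along any state path
that does not pass through a third recurrent class (deterministic moves are
free, a single flip costs 1, a simultaneous double flip 2).  Costs are
computed by Dijkstra runs seeded at each class; $W$ by the Chu–Liu/Edmonds
minimum-arborescence algorithm (one shared C++ implementation serves both
the R reference path and the bulk scanner).  A strategy is efficient iff
every weight-minimising class consists solely of mutual-cooperation rounds —
for a memory strategy, exactly the full-cooperation fixed point.
Probabilistic strategies (e.g. generous TFT) are assessed numerically
instead: stationary mass above 0.99 on the full-cooperation state at
$e = 10^{-6}$.

**Defensibility.**  Against *any* co-player and from *any* initial state,
error-free play must never leave the strategy behind in long-run payoff.
Whatever the co-player does, the play traces a walk on the graph whose nodes
are the strategy's own $4^m$ information states, with the strategy's action
fixed by its table and one edge per co-player action.  Weighting each edge
by $\mathrm{sign}(\pi_A - \pi_B)$ of its realized pair ($+1$ for $(d,c)$,
$-1$ for $(c,d)$, 0 otherwise — the sign alone suffices because $T > S$, so
the verdict is payoff-free), the co-player can gain in the long run iff this
graph contains a negative-weight cycle.  The check is a Floyd–Warshall pass;
because any opponent play, of arbitrary memory, induces a walk on this
graph, the verdict covers opponents of any memory length.  The adversarial
co-simulation oracle in the test suite exercises exactly this claim, and
`find_negative_cycle()` / `verify_exploit()` turn a negative verdict into a
concrete scripted opponent realizing the gain.

**Distinguishability.**  Against unconditional cooperation (AllC) the
strategy's limit payoff must be strictly higher, so that neutral drift
cannot flood a resident population with cooperators.  Against AllC the
error-free cycles contain no $(c,d)$ rounds, so the strategy is strictly
ahead iff the weight-minimising classes of the pair's zero-error limit
contain at least one of its defections.  In the rare case where tied
minimal classes disagree, the verdict defers to numerical stationary
payoffs at $e \in \{10^{-5}, 10^{-6}\}$, requiring a gap above
$10\,e\,(T-S)$.

A strategy that is efficient *and* defensible is a friendly rival (it is
then both a partner and a rival); adding distinguishability makes it
*successful*.

## CAPRI, TFT-ATFT, and the memory-two census

The exhaustive memory-two scan (seconds of compute; `enumerate_strategies(2)`)
finds 7,639 efficient and 2,144 defensible strategies whose intersection
holds exactly 8 friendly rivals, 4 of them successful.  All four successful
strategies recover from a single erroneous defection through the same
four-round pattern (defect twice, then re-converge), and the canonical
member returned by `tft_atft()` is selected by a documented tie-break:
among the four, take those agreeing with TFT at every state whose own
recent history is clean (`cc`), then the smallest id.  This is the
TFT-with-anti-TFT-repair strategy of the literature; the other three differ
only at rarely visited states and are asserted via their properties, since
no closed-form table exists for them.

`capri()` is the memory-three friendly rival defined by five rules —
cooperate at mutual cooperation, accept punishment for an erroneous
defection, punish a defection once, recover from mutual defection, and
otherwise defect.  Its recovery path is the shortest possible
(punish once, then cooperate: two time steps; one defection is unavoidable
for defensibility).  `capri_two()` shows why memory three is necessary: a
memory-two version must cooperate at $(cd,dc)$ and $(dc,cd)$ to recover
from error, and those prescriptions open a negative cycle in which an
alternating co-player recoups every punishment, gaining $T - S$ once per
four rounds.

## Joint chains and payoffs

`build_chain()` constructs the Markov chain of joint play: strategies of
different memory are embedded into the larger memory; Moore automata
(needed for grim trigger, which is not memory-$m$ for any finite $m$) are
paired over reachable product states augmented with the last realized pair.
Payoffs attribute to each state the payoff of its most recent realized
action pair.  Stationary vectors come from a dense LU solve with a
normalisation row, falling back to damped power iteration when the solve is
singular (reducible chains at $e = 0$ with a probabilistic co-player); a
fully deterministic pair at $e = 0$ is refused and routed to
`zero_error_limit()`.  The memory-one five-tuple $(p_0, p_R, p_S, p_T,
p_P)$ maps payoffs to realized pairs from the focal player's view
($R \leftrightarrow (c,c)$, $S \leftrightarrow (c,d)$,
$T \leftrightarrow (d,c)$, $P \leftrightarrow (d,d)$); $p_0$ is stored but
ignored by all long-run computations, which are initial-condition-free
stationary averages at $e > 0$.

`sample_payoff_cloud()` draws co-players uniformly from the
64-dimensional unit hypercube of probabilistic memory-three strategies.
The default error rate for the cloud is 0: the interior co-player makes the
chain ergodic almost surely, and defensibility then guarantees
$\pi_A \ge \pi_B$ in every sample for a defensible focal strategy — the
experiment reproduces CAPRI's strict dominance and TFT-ATFT's
payoff-equalising diagonal.

## Evolutionary dynamics

The evolutionary model is the donation game ($R = b-1$, $T = b$, $S = -1$,
$P = 0$) in a well-mixed population of size $N$ with Fermi imitation of
strength $\sigma$ and mutation rate low enough that the population is
monomorphic between mutation events.  A single mutant $X$ in a resident
population $Y$ fixes with the closed-form probability
$$\rho = \Big[\sum_{i=0}^{N-1}\prod_{j=1}^{i}
  e^{\sigma[(N-j-1)s_{yy} + j s_{yx} - (N-j)s_{xy} - (j-1)s_{xx}]}\Big]^{-1},$$
evaluated in log space (cumulative sums plus log-sum-exp) so that large
$\sigma N$ cannot overflow; equal payoffs give exactly $1/N$.  The pair
payoffs $s_{xy}$ are exact stationary chain averages at the configured
error rate, cached in a payoff table over the mutant set.

`run_moran()` simulates the induced resident random walk: mutants come
uniformly from the $11 \times 11$ reactive grid
($p_c, p_d \in \{0, 0.1, \dots, 1\}$), or, with probability $\mu$,
uniformly from the special set (so with two specials each appears with
$\mu/2$ — the natural reading of a rare informed mutant; configurable).
The initial resident is drawn uniformly from the grid, and abundance is the
time fraction of resident identity per mutant-introduction step, averaged
over independent runs.  Reactive strategies classify as rivals
($p_d = 0$; the boundary point $p_c = 1, p_d = 0$ counts as a rival),
partners ($p_c = 1$ and
$p_d < p_d^* = \min\{1-(T-R)/(R-S),\,(R-P)/(T-P)\}$, which is $2/3$ at
$b = 3$), or other.  Default study conditions are $b = 3$, $N = 50$,
$e = 10^{-3}$, $N\sigma = 10$, $\mu = 0.01$; the package's default run
length is $10^5$ mutant introductions averaged over 3 runs, a desk-scale
problem size whose qualitative rankings (partners over rivals; CAPRI the
single most abundant strategy once available; CAPRI over TFT-ATFT
head-to-head) are decisive and stable across seeds — full-scale runs
($10^7$ introductions, 10 runs) are reachable through the configuration.

**Robustness is a limit statement.**  A friendly rival $Y$ satisfies
$s_{yy} \ge s_{xy}$, $s_{yy} \ge s_{xx}$ and $s_{yx} \ge s_{xy}$ for every
mutant $X$, which by Jensen's inequality forces $\rho \le 1/N$ for all $N$
and $\sigma$.  These inequalities hold in the $e \to 0^+$ limit.  At any
finite error rate they are perturbed at order $e$: a friendly rival's own
recovery rule occasionally donates a round of cooperation to an
unconditional defector, so at $e = 10^{-3}$ an AllD-type mutant is a few
$e$ ahead in the pair payoff, and at $N = 2$ (where only $s_{yx} - s_{xy}$
enters) its fixation probability exceeds $1/2$ by order $\sigma e$ — a
fact confirmed here both by the chain solve and by an independent
Monte-Carlo simulation.  `robustness_certificate()` therefore evaluates
payoffs at $e = 10^{-8}$ by default, a numerical stand-in for the limit,
with a $10^{-6}$ tolerance on each inequality and on the $1/N$ bound; at
$e = 10^{-3}$ the bound still holds comfortably for $N \ge 10$, where the
resident's self-play advantage dominates the exponent.  The same
finite-$e$ reasoning applies to `check_defensible_empirical()`, the
empirical rival check used for probabilistic strategies such as
extortionate ZD, whose exact payoff relation holds at $e = 0$ only.

## What the generators emulate, and what they do not

The random co-players of the payoff cloud (uniform on $[0,1]^{64}$) and the
reactive mutant grid are the two synthetic populations used throughout:
the former probes worst-case payoff dominance against unstructured
opponents, the latter reproduces a standard evolutionary setting where
mutants explore a low-dimensional, behaviourally interpretable slice of
strategy space.  Neither emulates discounted games, finite horizons,
population structure, concurrent polymorphism (high mutation), $n$-player
interactions, or opponents that condition on more than the last three
rounds; conclusions from passing tests are claims about the
infinitely-repeated, well-mixed, low-mutation model only.  The full
memory-three census (trillions of friendly rivals among $2^{64}$
strategies) is outside desk scale by design; `sample_m3()` documents the
base rate rather than searching.

## Numerical choices

* Ties in the arborescence weights are resolved with an absolute
  $10^{-9}$ slack; unreachable classes carry infinite weight (grim
  trigger's cooperative class is the canonical example).
* Stationary solves switch to damped (lazy-chain) power iteration only on
  singular systems; the two routes are cross-checked against each other on
  random pairs in the tests.
* The distinguishability fallback threshold $10\,e\,(T-S)$ separates a
  genuine $O(1)$ payoff gap from the $O(e)$ noise floor at the two
  evaluation error rates.
* The bulk scanner and the readable R implementations are independent
  routes to the same verdicts and are tested for agreement on random
  strategies; the efficiency verdict is additionally validated against the
  numerical stationary mass at $e = 10^{-6}$ over the entire memory-two
  space, and defensibility against adversarial co-simulation.
* Automaton minimisation treats all four realized pairs as possible inputs
  (one's own action can be flipped by error), so minimised machines remain
  correct under noisy play.

## Limitations

Defensibility certifies a weak inequality at $e = 0$; it does not bound
finite-$e$ payoff gaps, which is precisely why robustness certification at
finite $e$ needs care (above).  Efficiency for probabilistic strategies is
a numerical verdict with a 0.99 mass threshold, not an exact limit
computation.  The package does not attempt the supercomputer-scale
memory-three census, and reports about memory-three strategies other than
explicitly constructed ones (CAPRI and its variants) are sampling
statements.
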