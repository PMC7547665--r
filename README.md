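# friendlyrival

Tools for the axiomatic analysis of strategies in the infinitely repeated
prisoner's dilemma under rare implementation error, aimed at researchers in
evolutionary game theory and the evolution of cooperation.

In the repeated prisoner's dilemma (payoffs $T > R > P > S$, $2R > T+S$;
actions are misimplemented independently with probability $e$), classic
strategies act either as **partners** — achieving the mutual-cooperation
payoff $R$ in self-play and making unilateral deviation unprofitable — or as
**rivals** — guaranteeing $\pi_A \ge \pi_B$ against any co-player.  A
**friendly rival** is both at once.  The package decides, exactly, the three
axioms that characterise them for deterministic memory-$m$ strategies
(rules conditioning on the last $m$ moves of both players):

1. **Efficiency** — self-play reaches mutual cooperation with probability
   one as $e \to 0^+$; decided by the Freidlin–Wentzell zero-noise limit of
   the joint play chain (recurrent classes of the error-free map, minimal
   action-flip costs, minimum spanning arborescences).
2. **Defensibility** — never outperformed at $e = 0$ by any co-player of any
   memory, from any state; equivalent to the absence of a negative cycle in
   the adversarial state graph with edge weights
   $\mathrm{sign}(\pi_A-\pi_B) \in \{-1, 0, +1\}$, hence independent of the
   payoff values.
3. **Distinguishability** — strictly higher limit payoff than an
   unconditional cooperator, blocking neutral drift toward AllC.

On top of this sit an exhaustive census of the memory-one and memory-two
spaces, the memory-three strategy **CAPRI** ("cooperate, accept punishment,
punish, recover, in all other cases defect") and the memory-two
**TFT-ATFT** recovered by search, explicit exploit witnesses for
non-defensible strategies, payoff sampling against random memory-three
co-players, and a low-mutation Moran simulation with closed-form fixation
probabilities in which friendly rivals are evolutionarily robust
($\rho \le 1/N$ for every mutant in the zero-error limit).

## Worked example

```r
library(friendlyrival)

classify_strategy(capri())
#> <classification of CAPRI>
#>   efficient:        TRUE
#>   defensible:       TRUE
#>   distinguishable:  TRUE
#>   friendly rival:   TRUE   successful: TRUE
#>   recovery steps:   2

recovery_path(capri())
#> <recovery path after co-player's error>
#>   Alice: c d c
#>   Bob:   d c c
#>   recovered in 2 time steps
```

After the co-player's single erroneous defection, CAPRI punishes once and
both players are back at mutual cooperation two time steps later — the
shortest recovery compatible with defensibility.

```r
enumerate_strategies(2)   # exhaustive scan of all memory-two strategies
#> <memory-2 enumeration: 65536 strategies>
#>   efficient:        7639
#>   defensible:       2144
#>   friendly rivals:  8
#>   successful:       4
#>   successful ids:   37530, 37562, 38554, 38586
```

Of 65,536 memory-two strategies, 7,639 are efficient and 2,144 defensible,
but only 8 are both, and 4 pass all three axioms (TFT-ATFT and three
variants).  With memory one the intersection is empty.

```r
cloud <- sample_payoff_cloud(capri(), n = 1000, e = 0, seed = 2024)
mean(cloud$pi_A >= cloud$pi_B - 1e-9)
#> [1] 1
```

CAPRI is never outperformed by any of 1,000 random probabilistic
memory-three co-players, as defensibility guarantees.

```r
cfg <- evolution_config(mu = 0.01,
                        special = list(CAPRI = capri(), `TFT-ATFT` = tft_atft()),
                        steps = 1e5, runs = 3, seed = 2025)
run_moran(cfg)
#> <abundance: b=3 N=50 e=0.001 sigma=0.2 mu=0.01, 100000 steps x 3 runs>
#>   per class: partner=0.059  rival=0.006  other=0.003  special=0.933
#>   top strategies: CAPRI=0.914  R(1,0.2)=0.019  TFT-ATFT=0.019  R(1,0.5)=0.015  R(1,0.3)=0.010
```

When rare informed mutants can adopt either friendly rival, CAPRI ends up
as resident 91% of the time, an order of magnitude ahead of TFT-ATFT —
the head-to-head evolutionary comparison of the two.

A thin command-line front end ships in `exec/rival`
(`rival classify --name CAPRI`, `rival enumerate --m 2`,
`rival sample-payoffs --name CAPRI --n 1000`, `rival evolve --mu 0.01
--special CAPRI`).

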