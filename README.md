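# groupchase

Agent-based simulation of group chase and escape in a two-dimensional disk
habitat, for studying when cooperative hunting survives a social dilemma.

Predators ("chasers") pursue faster prey ("targets") using one of two
rules. The **direct chasing strategy (DCS)** is selfish: move straight at
the nearest target at speed $v_D$,

$$\hat v_{C_i} = \frac{r_{T_j} - r_{C_i}}{\lvert r_{T_j} - r_{C_i}\rvert}.$$

The **group chasing strategy (GCS)** is cooperative: move — at a reduced
speed $v_G < v_D$, the cost of the extra cognition — so that the nearest
target $T_k$ would sit at the centroid of all chasers at least as close to
it. With $\Gamma_i$ the set of other chasers not farther from $T_k$ than
the focal chaser, the aim point is

$$X_{C_i} = (n_i+1)\,r_{T_k} - \textstyle\sum_{j\in\Gamma_i} r_{C_j},
\qquad n_i = \lvert\Gamma_i\rvert,$$

and a GCS chaser may move *away* from the target to close the ring.
Targets move fastest of all ($v_G < v_D < v_T$) and flee the nearest
hazard — a chaser or the habitat boundary — within their recognition range;
chasers alternate between hunting and resting with linearly ramping switch
probabilities. Captures happen when a hunting chaser overlaps a target;
the target is replaced at random, keeping populations constant.

The package provides the full per-step engine (compiled, with a pure-R
reference implementation that is bitwise identical from the same seed),
ensemble runners, and the observables of interest:

* windowed **hunting performance** `h(t)` (captures per chaser per
  window), optionally stratified by strategy and by homogeneous vs
  heterogeneous pursuing sets;
* **set-resolved fitness** `f_G(n_G, n_D)`, `f_D(n_G, n_D)` — each
  strategy's share of captures in sets of composition `(n_G, n_D)`
  normalized by its share of chaser observations there;
* **Nash-arrow analysis** of the fitness table (which compositions reward
  a unilateral strategy switch, which cells are equilibria);
* **fixation probabilities** under spatial imitation learning (model C:
  after each capture, chasers within `r_learn` of the capture site adopt
  the capturer's strategy).

Model variants: `A_DCS` / `A_GCS` (single-strategy populations), `B`
(mixed 50:50, no learning), `C` (mixed with learning).

## A worked example

A single learning run in the slow-defector regime (`v_D = 0.072`), at a
reduced horizon:

```r
library(groupchase)
cfg <- chase_config(model = "C", v_D = 0.072, T_max = 1e5,
                    ss_window = c(5e4, 1e5))
run <- run_simulation(cfg, seed = 42)
print(run)
#> <chase_run> model C, seed 42, t=100000
#>   39 captures; final 100 GCS / 0 DCS
#>   fixation: GCS at t=89913
```

The population of 50 cooperators and 50 defectors is absorbed into an
all-GCS state at `t = 89913`: imitation of successful neighbours spreads
the cooperative rule even though defectors out-earn cooperators inside
mixed pursuing sets. The capture log and summaries are tibbles:

```r
head(tidy(run), 3)    # one row per capture event
#>       t chaser_id strategy target_id     x      y   n_G   n_D in_set
#> 1   806        53 GCS             17  263.   98.4     1     1 TRUE
#> 2 10450        62 GCS             45  247. -434.      1     3 TRUE
#> 3 11049        63 GCS             31  119. -321.      5     1 TRUE

hunting_performance(run)   # captures per chaser per 2e4-step window
#>       t     h
#> 1 10000  0.06
#> 2 30000  0.04
#> 3 50000  0.08
#> 4 70000  0.11
#> 5 90000  0.1
```

`h(t)` rises as the population turns cooperative — the group benefit of
encirclement. `autoplot(run)` draws the strategy counts over time,
`fitness_table()` and `nash_arrows()` analyse set-resolved payoffs from
model-B ensembles, and `run_ensemble()` + `fixation_probability()`
estimate `P_fix` across seeds. A thin command-line front end is installed
at `inst/cli/groupchase.R` (`run`, `ensemble`, `analyze` subcommands).

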