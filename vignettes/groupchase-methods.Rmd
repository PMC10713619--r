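---
title: "Methods: group chase and escape with strategy learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group chase and escape with strategy learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`groupchase` simulates foraging predators ("chasers") and prey ("targets")
in a two-dimensional disk of radius $R$ in continuous space. The disk is
used rather than a square because corners trap prey; the boundary is
otherwise inert. Populations are fixed: $N_C$ chasers and $N_T$ targets,
with every captured target immediately replaced at a random location at
least $r_{\min}$ from every agent.

**Targets** move at speed $v_T$. A target treats any chaser, and the
habitat boundary, as a hazard when it is within the recognition range
$r_{haz}$. It flees straight away from the *nearest* hazard,

$$\hat v_{T_i} = \frac{r_{T_i} - r_{H_i}}{\lvert r_{T_i} - r_{H_i}\rvert},$$

where $r_{H_i}$ is the nearest hazard position (for the boundary, the
radial projection of the target onto the bounding circle). With no hazard
in range it performs a random walk with straight steps of length
$v_T\,\delta t$.

**Chasers** carry one of two strategies.

* *Direct chasing strategy (DCS)* — move straight at the nearest target at
  speed $v_D$: $\hat v_{C_i} = (r_{T_j} - r_{C_i}) / \lvert r_{T_j} -
  r_{C_i}\rvert$. This is the selfish rule.
* *Group chasing strategy (GCS)* — move at the reduced speed $v_G < v_D$
  (the cost of the extra cognition) so that the nearest target $T_k$ would
  sit at the centroid of all chasers at least as close to it. With
  $\Gamma_i$ the set of other chasers $j$ satisfying $\lvert r_{T_k} -
  r_{C_j}\rvert \le d_{C_i}$, the aim point is

  $$X_{C_i} = (n_i + 1)\, r_{T_k} - \sum_{j \in \Gamma_i} r_{C_j},
  \qquad n_i = \lvert\Gamma_i\rvert,$$

  and the chaser moves along $(X_{C_i} - r_{C_i}) /
  \lvert X_{C_i} - r_{C_i}\rvert$ — possibly *away* from the target. With
  $\Gamma_i = \emptyset$ the rule reduces exactly to the direct rule.

Speeds obey $v_G < v_D < v_T$: prey outrun any individual predator, so
captures require cornering at the boundary or genuine encirclement.

**Hunt and rest.** A chaser alternates between a hunting mode (pursuit as
above) and a rest mode (random walk at its strategy's speed). After a time
$t$ in the current mode the per-step switch probability is
$\min(t/T_{hunt}, 1)$ or $\min(t/T_{rest}, 1)$; spells therefore have mean
length $\approx \sqrt{\pi T/2}$ ($\approx 40$ steps for $T = 10^3$) and can
never exceed $T + \delta t$.

**Learning (model C).** When a chaser captures a target, every chaser
within $r_{learn}$ of the capture location adopts the capturer's strategy.
The strategy mix then drifts until *fixation* — an all-GCS or all-DCS
population, which is absorbing.

Model variants: `A_DCS` / `A_GCS` are single-strategy populations, `B`
mixes both (half and half by default) without learning, `C` adds learning.

## The per-step update

Each step of length $\delta t$ executes, in order:

1. one mode draw per chaser (id order), timer bookkeeping after the draw;
2. set decomposition: each hunting chaser is assigned to its nearest
   target (used by the observables and for classifying captures);
3. chaser move proposals: a hunting chaser whose nearest target lies
   within $v_C\,\delta t$ *snaps* exactly onto the target's position,
   otherwise one straight step along the strategy rule; resting chasers
   step randomly;
4. target move proposals (flight rule above);
5. chaser commits in a uniformly random order: a move is rejected if any
   other chaser — at its position current at that moment of the sweep — is
   within $r_{\min}$ of the attempted position;
6. target commits in a uniformly random order: a target with an updated
   chaser within `eps_capture` of its pre-move position is captured,
   removed, credited to the nearest such chaser, and replaced at random
   (at least $r_{\min}$ from every agent); survivors move under the same
   exclusion rule;
7. learning (model C), processing same-step captures sequentially in the
   order they occurred — a capturer converted by an earlier event
   propagates its *new* strategy;
8. $t \mathrel{+}= \delta t$.

## Reference conditions

The package defaults are the study conditions and are not tuned per
experiment:

| parameter | default | meaning |
|---|---|---|
| $R$ | 500 | disk radius (length units) |
| $N_C$, $N_T$ | 100, 50 | population sizes |
| $v_G$, $v_D$, $v_T$ | 0.07, 0.082 (range 0.072–0.098), 0.1 | speeds |
| $\delta t$ | 1 | step length (time unit) |
| $r_{\min}$ | 0.15 | same-species exclusion distance |
| $r_{haz}$ | 50 | hazard recognition range |
| $r_{learn}$ | 200 | learning radius (model C) |
| $T_{hunt}$, $T_{rest}$ | $10^3$ | spell caps |
| $T_{\max}$ | $10^6$ | horizon |

## Observables

* **Hunting performance** $h(t)$: captures per chaser in non-overlapping
  windows of width $\Delta t = 2\times 10^4$ centred at $\Delta t/2,
  3\Delta t/2, \dots$ In mixed populations it is stratified by the
  capturer's strategy and by whether the pursuing set was homogeneous or
  heterogeneous, each divided by the time-averaged number of chasers of
  that strategy in sets of that category (windows with empty denominators
  are `NA`, never zero).
* **Set-resolved fitness.** Sets are classified by composition
  $(n_G, n_D)$; $N(n_G,n_D)$ counts set observations once per set per step
  inside the steady-state window, $H_G$/$H_D$ count captures. Fitness is
  the relative performance
  $f_G = (H_G/H^{tot}) / (n_G N / N_C^{tot})$ and symmetrically for
  $f_D$. The table obeys the exact identity
  $\sum [n_G N f_G + n_D N f_D] = N_C^{tot}$, which the tests assert on
  every accumulated table.
* **Nash arrows.** A `G2D` arrow at $(n_G,n_D)$ marks
  $f_G(n_G,n_D) < f_D(n_G{-}1,n_D{+}1)$ (defection pays); `D2G`
  symmetrically. Cells where no occupant benefits from switching are
  equilibrium cells. Comparisons touching undefined fitness are skipped
  and reported, never coerced to 0 or 1.
* **Fixation probability**: fraction of ensemble runs absorbed at each
  strategy; unfixed runs count in the denominator only.

## Design choices where the rules were open

* **Boundary overshoot** is radially clamped onto the circle. Targets
  already flee the boundary inside $r_{haz}$, so the clamp is a rare
  safety net. The projection is iterated (with a forced strict shrink
  after two passes) so that it is exactly idempotent in floating point.
* **"Within distance $x$"** is closed ($\le x$) for every predicate —
  hazard and learning ranges, snap distance, $\Gamma$ membership
  ("not farther than"), capture coincidence, and move exclusion. Ties are
  measure-zero; uniformity beats case-by-case conventions.
* **Nearest-entity ties** break to the lowest agent id, and the boundary
  loses ties against a chaser. This makes replays deterministic.
* **Degenerate directions** (a target exactly on its hazard, a GCS aim
  point coinciding with the chaser) fall back to a random unit vector; any
  fixed choice would bias the symmetric case.
* **$\Gamma$ membership and hazards** include resting chasers and both
  strategies (the rules name "chasers" with no qualifier, and
  heterogeneous sets require cross-strategy membership). Both inclusions
  are exposed as configuration switches (`resting_in_gamma`,
  `resting_are_hazards`) for sensitivity analysis.
* **Sets contain only hunting chasers** — a resting chaser is not
  pursuing. Consequently only hunting chasers capture: the snap rule is
  the only capture mechanism and it fires in hunting mode.
* **Set decomposition timing.** Classes are computed after the mode draw
  and before movement. This guarantees the capturer is a member of the
  captured target's set (a snap requires hunting mode and the same
  nearest-target assignment), which is what makes the fitness identity
  exact. A defensive branch excludes from the fitness accumulators any
  capture whose capturer was somehow outside the decomposition (it cannot
  occur under this timing) and counts it separately (`n_unclassed`).
* **Capture predicate**: distance $\le 10^{-6}$ length units. The snap
  copies coordinates bit-for-bit, so the tolerance only absorbs transport
  rounding; it is ten-thousand-fold below $r_{\min}$, so false captures
  cannot occur.
* **Capture does not reset the hunting timer**, and all chasers start in
  hunting mode with zero timers; transients are excluded by the
  steady-state window in any case.
* **Capture events are stamped** with the time of the state they produce
  ($t + \delta t$).
* **Mode draw before movement**, with the timer incremented after the
  draw, so a fresh spell always survives its first draw.

## Implementation and its verification

The production step loop is compiled (Rcpp) with two exact accelerations:
SIMD minimum reductions over squared distances, and cell-list spatial
indices (a coarse grid at the hazard range, fine grids at a few length
units for exclusion, capture, and replacement queries). Both preserve
results bit-for-bit: minima are associative, candidate sets provably
contain every agent that can satisfy the corresponding predicate, and
candidate minima resolve ties by lowest id exactly as a linear scan does.

The package also ships `reference_step()`, a deliberately slow pure-R
implementation built from the exported per-phase operations. Both
implementations draw from R's global RNG in the same order (including an
explicit Fisher–Yates shuffle, since `base::sample()` consumes the stream
differently), so from any seed the two produce *bitwise identical* world
states; the test suite asserts this over 100 steps for ten seeds, plus
capture-heavy scenarios that exercise replacement and learning.

## Scale of the shipped experiments

Full-scale reproduction (ensembles of 1000–5000 runs of $10^6$ steps) is
out of desk scope. The shipped tests and the acceptance script run reduced
protocols, chosen as the largest sizes that keep a complete check-out
under half an hour on one core; they are estimates of the same quantities
with honest sampling error, not new conditions:

* population comparison: 5 runs per population of $4\times10^5$ steps,
  steady-state window $[2\times10^5, 4\times10^5]$ (the transient is over
  by $t \approx 2\times10^5$; the population gap is an order of magnitude,
  so few runs suffice);
* mixed-population fitness and stratified performance: 50 runs of
  $4\times10^5$ steps, same window;
* fixation: 20 runs of $2\times10^5$ steps at $v_D = 0.072$;
* the acceptance script uses slightly smaller ensembles of the same shape.

At these sizes a capture-rate of order $2.5\times10^{-4}$ per step yields
a few thousand classified captures, so per-cell fitness values for small
sets carry standard errors of roughly 0.1–0.3. The orderings (group
benefit of GCS, individual advantage of DCS in mixed sets, GCS-biased
fixation) are stable; individual cell values fluctuate accordingly.

## What the equal-speed null does and does not show

Setting $v_D = v_G$ (allowed via `enforce_speed_order = FALSE`) removes
the speed penalty but *not* the behavioural difference: paired GCS chasers
still encircle while DCS chasers still chase directly, and singleton sets
of either strategy still out-earn large sets per capita (a lone chaser
adjacent to a wandering target is the most frequent capture geometry at
these densities). Equal speeds therefore do not make every $f$ equal to
one; the fitness index only collapses to unity under the stronger
hypothesis that every chaser has the same capture rate in every set. In
this implementation the observed equal-speed table shows mirrored
singleton cells agreeing between strategies while multi-chaser GCS cells
sit above their DCS mirrors — cooperation is genuinely profitable even
without a speed edge. The identity
$\sum[n_G N f_G + n_D N f_D] = N_C^{tot}$, which *is* an algebraic
property of the index, is tested exactly instead.

## Known limitations

* Chasers are omniscient about target positions (no perception range on
  the predator side); only targets have limited recognition.
* Cross-species overlap is resolved solely by capture; there are no
  predator–prey collisions.
* The learning rule transmits strategies instantaneously and equally fast
  in both directions; no cost of learning, no mutation, no birth–death
  turnover.
* Single-strategy speeds only: all DCS chasers share $v_D$, all GCS
  chasers share $v_G$.
* Ensemble runners are serial; members are independent by construction
  (seed $s_0 + k$), so external parallelisation is safe.
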