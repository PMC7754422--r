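---
title: "Planning conservation interventions on social networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning conservation interventions on social networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netreserve)
```

## The decision problem

`netreserve` addresses a conservation planning setting in which each node of
a social network is an actor (a landholder, a fisher group) with exclusive
management rights over one site, and each site carries part of a species
pool. Sites are in one of three states — available (`A`), developed (`D`),
or reserved (`R`) — and the two terminal states are absorbing. Species
persist at available and reserved sites and are lost from developed ones;
only reserved sites count toward the conservation objective. A decision
maker can target one actor per time step with an intervention (a land
purchase offer, an incentive payment, a co-management program) that enables
the reserve transition. The question the package quantifies: how much
better are these interventions when the planner knows the social network
through which behaviors spread, compared with planning as if actors were
independent?

## Behavior spread model

Per time step, an available actor develops with hazard

$$q_d = 1 - (1 - p_d) \prod_{j \in \mathcal{N}_D(i)} (1 - u_{d,ij}),$$

where `p_d` is the intrinsic development propensity and the product runs
over developed neighbors: intrinsic choice and each neighbor influence act
as independent triggers, as in independent-cascade and
susceptible–infected spread models. Reservation is only possible while an
intervention targets the actor; its hazard is the analogous
$q_r = 1 - (1 - p_r)\prod_{j \in \mathcal{N}_R(i)}(1 - u_{r,ij})$, and it
is zero otherwise (`p_r = 0`, `u_r = 0` without an intervention). With
homogeneous strengths the products collapse to $(1-u_d)^{n_d}$ and
$(1-u_r)^{n_r}$.

Two points in this kernel are genuine modeling choices rather than
consequences of the verbal description, and both are isolated in
`node_transition_distribution()`:

* **Competing hazards under an intervention.** When both latent events
  fire in the same step, reservation wins: $P(A \to R) = q_r$,
  $P(A \to D) = (1 - q_r)\,q_d$. The rationale is that an intervention
  actively facilitates reservation — the facilitated transition should not
  be pre-empted by the very behavior the intervention is meant to avert.
  An alternative reading, in which an intervention also suspends the
  actor's intrinsic development for that step, is equally defensible; the
  precedence rule used here is the more conservative of the two, and the
  choice is confined to this one function so it can be swapped.
* **Synchronous updates.** All nodes draw their next state from kernels
  conditioned on the same pre-step joint state, the standard convention in
  cascade models. Asynchronous schemes are out of scope.

All nodes share `p_d` and `p_r` (default 0.2 each); link strengths may be
homogeneous (the motif experiments) or heterogeneous per link (the fishery
case study).

## Network motifs and metrics

Five 6-node motifs span a gradient of Freeman closeness centralization:
ring (0), line (0.291), ring-star (0.340), wheel (0.643) and star (1).
Closeness of a node is $(n-1)/\sum_j d_{ij}$ with unweighted hop-count
distances (link strengths affect dynamics, never distances); the network
centralization is $\sum_i (c_{\max} - c_i)$ normalized by the star's
value, $(n-1)(n-2)/(2n-3)$.

The ring-star motif is defined here as a 5-cycle rim with a pendant hub
attached to one rim node. A plausible alternative — hub attached to two
adjacent rim nodes — turns out to have centralization 0.223, *below* the
line's 0.291, which would break the intended monotone gradient; the
single-attachment variant (density 0.4, equal to the ring's) preserves it.
All motif edge sets live in one constants table (`motif_edge_table()`) so
any of them can be revised in a single place.

Disconnected nodes (the fishery has one) get closeness computed within
their connected component, an isolated node has closeness 0, and
centralization uses these values unchanged. This is one deterministic
convention among several in use; it is documented rather than claimed
canonical.

## Species distributions and nestedness

Species pools are generated over the network's sites with a controlled
degree of nestedness. Range sizes are drawn uniformly on
`{1, ..., n_sites}` — the pool spans narrow endemics to ubiquitous
species; nothing finer is assumed about the occupancy model. Nestedness is
measured by the Brualdi–Sanderson discrepancy `d`: with species ranked by
overall incidence (ties broken by original index, deterministically — no
search over orderings), `d` counts presences outside the maximally packed
matrix with the same row sums. The generator's working scale is the
normalized score `1 - d / F` (`F` = total presences), which is 1 exactly
for perfectly nested matrices and decreases as the pool becomes un-nested.

`generate_species_distribution()` starts from the perfectly nested
arrangement and applies range-preserving single-presence moves, greedily
accepted when they bring the score closer to the target `phi`
(tolerance 0.02, proposal cap 10,000, and a stall rule of 500 consecutive
rejections, since greedy acceptance cannot escape a local optimum). Two
properties deserve emphasis:

* For 6-site, 20-species pools the attainable score has a floor around
  0.6–0.75: the discrepancy cannot exceed roughly
  $\sum_i \min(r_i, m - r_i)$. Low targets (`phi` ≲ 0.6) therefore return
  the most un-nested configuration achievable, flagged `feasible = FALSE`.
  In the experiments, "low nestedness" consequently means "maximally
  un-nested attainable", which is exactly the anti-nested regime the
  design calls for.
* The finished matrix has its site rows randomly permuted. The nested seed
  arrangement is built on sites in index order, and without the relabeling
  site 1 — the hub of the star and wheel motifs — would be the richest site
  in almost every draw, confounding nestedness rank with node identity and
  biasing the network-blind baseline. Nestedness is a property of the
  pool; which node is species-rich must be random.

A permutation test accompanies the index: sequential checkerboard swaps
(2×2 submatrix swaps `10/01 <-> 01/10`) preserve both marginals exactly and
yield a null distribution for `d`. A perfectly nested matrix contains no
checkerboard unit at all (nestedness implies subset structure between all
species pairs), so its null ensemble is the singleton {observed}; this
degenerate case is detected explicitly and reported with `p = 1` rather
than silently.

## Exact planning

The joint system is a factored Markov decision process over $3^n$ states
(base-3 encoding, node 1 least significant). The reward of `(state,
action)` is the number of species with at least one presence at a reserved
node — species counted once — minus an intervention cost `c` when the
action is not the no-op; rewards accrue on the pre-transition state.
Defaults: discount $\gamma = 0.95$, `c = 0.1` species-units, both exposed
in every constructor and config. These two values are not identifiable
from the problem description ("a notional cost"); they were fixed once up
front and exposed everywhere precisely so that their influence can be
explored. VoI magnitudes depend on them; the qualitative contrasts the
test suite asserts do not rely on fine-tuning either.

Transition matrices are materialized per action as dense $3^n \times 3^n$
arrays built by vectorized column gathers from per-node kernels — at
$n = 6$ that is seven 4 MB matrices, cheaper to build and multiply than
sparse equivalents at this size. Models with more than 8 nodes are refused
with a clear message: exact planning is exponential and approximate
methods are out of scope. Two solvers are provided:

* `value_iteration()` — Bellman sweeps to a sup-norm residual `tol`
  (default `1e-6`), with non-convergence an explicit error;
* `solve_decision_model()` — Howard policy iteration (exact evaluation via
  a direct linear solve plus a tie-aware improvement step that changes an
  action only when strictly better by `1e-9`), which terminates at an
  exactly optimal policy. Tie-aware improvement matters: with naive
  argmax improvement, equal-valued actions cause policy cycling.

Greedy tie-breaks go to the no-op, then the lowest node index. Targeting a
non-available node is legal, has no dynamic effect, and still pays `c`, so
it is never optimal; this keeps the action space uniform across states.

## Value of network information

`compute_voi()` solves the model twice: informed (true network) and
network-blind (`uninformed_model()`, every link strength zeroed — the
planner that assumes independent actors). Both policies are then evaluated
**under the true dynamics** by exact linear solves, and values are read at
the all-available state. The value of information is
$100\,(V_I - V_U)/V_U$. Because the informed policy is optimal under the
true dynamics, VoI is nonnegative up to linear-solve roundoff, and it is
exactly zero when both strengths are zero. The blind planner keeps full
state observability — it re-plans from what it sees, it just does not
believe in influence. The alternative (also evaluating it under blind
dynamics) would conflate the value of network *information* with the value
of network *effects* and is not used.

Per-instance VoI is fully deterministic given the species pool: randomness
enters the experiment grid only through replicate pools. Pool seeds derive
from `(phi, replicate)` alone, so the same pools recur across strength
cells and motifs — comparisons are paired, and the blind planner (which
depends only on the pool) is solved once per pool.

## The experiment grid and its scale

`run_voi_grid()` crosses motifs × nestedness targets × `u_r` × `u_d` ×
replicates; `summarize_voi_grid()` reports per-motif means with percentile
bootstrap intervals and the fractions of instances whose first action
targets a most species-rich site and a maximum-closeness node (ties count
as satisfied). Mixed-model summaries are deliberately replaced by these
direct empirical statistics.

The package's reference experiment (see `scripts/acceptance.R`) runs, per
motif, 10 nestedness levels × 6 × 6 strength levels × 2 replicate pools of
20 species over 6 nodes with `p_d = p_r = 0.2` — 3,600 exact
double-solves, a few minutes on one CPU. The reduced grid used by the test
suite is 3 × 3 × 3 × 3 per motif. These sizes are the package's chosen
desk scale for a reproducible, deterministic study; the full 11-level
strength grid changes none of the qualitative conclusions, only the
resolution of the surfaces.

What the synthetic study does and does not emulate: pools are binary
incidence with uniform range sizes (no abundances, no detection error, no
spatial autocorrelation beyond nestedness); motifs are homogeneous-strength
6-node graphs (real networks are larger and heterogeneous); actors share
one behavioral parameter set. Passing tests certify the solver and the
qualitative structure of the VoI surface under these conditions, not
predictions for any specific real system.

## Fishery-style case study

`make_fishery_fixture()` constructs a *synthetic* 6-node system in the
style of a gear-based territorial-user-rights fishery: one isolated group
(speargun), heterogeneous link strengths with the seine-net–handline tie
strongest, the seine-net group the strictly richest site and the network
hub, and a species pool whose nestedness is not significantly different
from random (checkerboard test, `p > 0.1`). It is a stand-in built to
reproduce qualitative features, not real data. `case_study()` reports VoI
and projects both policies into deterministic intervention sequences under
the convention that each intervention succeeds and nothing else transitions
— the modal "first do X, then Y" plan used for narrative summaries.

## Known limitations

* Exact planning stops at 8 nodes by design.
* The nestedness score `1 - d/F` is a monotone working proxy, not
  calibrated to any published nestedness scale; its attainable range
  depends on the drawn range sizes (see above).
* The blind baseline is one defensible formalization of "no network
  information"; open-loop or evaluation-blind baselines would give
  different VoI magnitudes.
* VoI magnitudes depend on the discount and intervention cost, which are
  not identifiable from the problem description; the test suite asserts
  the qualitative contrasts (centralization raises VoI, nestedness
  suppresses it) at the default settings only.
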