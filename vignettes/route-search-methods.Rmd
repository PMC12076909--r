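---
title: "Proof-number route search and diversity scoring: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proof-number route search and diversity scoring: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrodiv)
```

## The game model and its assumptions

Retrosynthesis is modelled as a two-player game on a directed bipartite
graph. Molecule nodes are OR positions: the molecule player picks one of
the reactions producing the molecule. Reaction nodes are AND positions:
the reaction player may demand any reactant. The molecule player wins on
reaching a building block; the reaction player wins on reaching a dead end
(a childless, unbuyable molecule) or when a molecule is visited a second
time on the current play path. The repetition rule is what makes the game
well-defined on cyclic networks, and it is deliberately *path-local*: a
molecule may legitimately recur on disjoint branches of a synthesis tree
(two branches may buy or make the same intermediate independently), so the
package tracks only the set of molecules on the root-to-node path.
Reaction nodes are not tracked separately: a reaction can only recur after
its product molecule recurs one ply later, so the molecule set is
sufficient state and the settled value is the same.

A target that is itself purchasable is solved by the empty route, whose
viability is 1 (empty-product convention). A reaction with no reactants is
vacuously proved for the same reason.

## Proof numbers, thresholds, and the two failure modes on cycles

`pn(v)`/`dn(v)` estimate how many frontier settlements are still needed to
prove/disprove `v`; unexpanded nodes start at (1, 1), a proved node is
(0, Inf), a disproved node (Inf, 0). Aggregation is min/sum at molecule
nodes and sum/min at reaction nodes, with sums saturating at `Inf` (the
package never does `Inf - Inf` arithmetic; thresholds use explicit
saturating helpers).

DFPN explores depth-first under two thresholds and backtracks as soon as
`pn >= th_pn` or `dn >= th_dn`. At a molecule node the chosen child's pn
threshold is capped by the second-best child's proof number plus one; at a
reaction node it is the parent's surplus `th_pn - pn(v) + pn(child)`; dn
is symmetric; a single child inherits the thresholds unchanged. Two
distinct things go wrong on cyclic graphs:

* **Graph history interaction (GHI).** A (dis)proof found through one
  path need not hold through another, because the repetition rule is
  path-dependent. Caching results per node is therefore unsound.
* **Incompleteness.** Even with sound caching, stale stored values and
  threshold interplay can trap plain DFPN in an infinite loop while a
  solution exists.

`dfpn()` exposes both reinforcements separately:

* `ghi_safe = TRUE` stores every settled result keyed by the set of path
  molecules it actually depended on. A cached *proof* carries the
  molecules of its proof subtree and is valid only for query paths
  disjoint from them; a cached *disproof* carries the path molecules its
  repetition arguments used (minus the node itself) and is valid only for
  paths containing them. Stored numeric values that look settled but have
  no valid cache entry under the current path are reset to (1, 1) before
  use, so path-dependent results can never leak; they cost re-search, not
  correctness. In this mode an on-path repeat contributes a certain
  path-keyed disproof, exactly as the game rules demand.
* With `ghi_safe = FALSE` (the classic, unsafe configuration) an on-path
  repeat instead contributes a saturating "blocked" value
  `(pn, dn) = (Inf, Inf)`: the search cannot prove or disprove through the
  cycle and stores nothing path-dependent. This conservative treatment is
  common in practice, and it is visibly incomplete: on the bundled 7-node
  counterexample (`dfpn_counterexample()`) the blocked values meet the
  saturated thresholds everywhere, the search churns without ever
  expanding the escape reaction `v5`, and any step budget is exhausted.
* `use_tca = TRUE` enables the threshold controlling algorithm: `md(v)`
  tracks the minimum explored root distance, and whenever a node about to
  backtrack has an unproved *old* child (`md(child) <= md(v)`, the
  signature of a cycle), its thresholds are raised to `pn(v) + 1` and
  `dn(v) + 1` — the minimal values restoring the strict inequalities — so
  the search continues until an expansion or a closed cycle makes
  progress.

`ghi_safe` defaults to `use_tca`, so `dfpn(g)` is the plain incomplete
algorithm and `dfpn(g, use_tca = TRUE)` the reinforced one. The
completeness claim is empirical here: the test suite checks that the
reinforced configuration settles 200 seeded cyclic graphs (up to 30 nodes)
within 50 visits per node and always agrees with an exhaustive game
solver. The brute-force solver (`solve_brute_force()`) and an independent
memoised evaluator (for acyclic graphs, in the test helpers) are kept as
two separate oracles.

The search budget is counted in *node visits* (one per search step), not
first-time expansions: first-time expansions are bounded by the graph
size, so they could never witness non-termination, which is precisely what
the budget must be able to report. `expansions_used` in a `game_outcome`
reports the visits consumed.

### The counterexample fixture

The published minimal counterexample is described textually; the bundled
fixture is the completion of those constraints: `v0 -> {v1, v2}` with
near-symmetric cyclic branches `v1 -> v4 -> v1` and `v2 -> v3 -> v2`, one
escape `v3 -> v5 -> v6` with `v6` the only building block, hence exactly
one winning strategy, and `v3`'s child `v2` an old child
(`md(v2) = 1 <= md(v3) = 2`), the TCA trigger. The behavioural contract —
plain DFPN exhausts a 10,000-step budget without expanding `v5`, the
reinforced search proves the root through `v6` — is asserted by tests and
recomputed by `scripts/acceptance.R`; the exact visit sequence of the
original description is not part of the contract.

## Multi-solution search

`find_route_set()` turns the decision procedure into a route-set
generator. After each proof:

1. the route is recorded;
2. its *deepest* reaction (longest path from the target, traversal-order
   ties) is force-disproved, keyed by the molecules of the branch that
   reached it — the same route cannot recur, while other paths to the
   reaction stay usable;
3. `p_reac` is added to the proof number of every reaction on that branch
   (`p_mol`, default 0, to molecules — disproving a molecule disproves a
   reaction anyway, which is also why a reaction is the forced target);
4. cached proofs are purged (the forced disproof invalidates them;
   disproofs remain valid because forcing only removes options) and the
   search restarts with all other state intact.

Design choices the interface does not show: penalties persist cumulatively
across iterations (resetting them would re-find near-identical routes);
the step budget is global across the whole run, mirroring a wall-clock
budget; route distinctness is tree equality after canonical child
ordering. One subtlety is worth recording: a proof cached *after* some
forced disproof may still hide the forced reaction behind a different
partial path, so every cached proof carries, besides its molecule
dependency set, the *residual* part of each forced key not already inside
its own subtree; a proof is only reused on paths that do not complete any
residual. Without this the extracted strategy could step onto a reaction
that the forcing has disproved on exactly that path.

With edge costs enabled (`edge_costs = TRUE`), molecule-node aggregation
becomes `pn = min(pn(child) + cost)` and the chosen child's pn threshold
is reduced by its edge cost; costs are taken from the graph, or derived
from a reaction score `s` as `round(-log(s))` capped at 10, or 0. Costs
bias the search among unproved children only: a node with a certainly
proved child keeps `pn = 0`, so the game value is never distorted. Whether
the original edge-cost variant also modifies threshold propagation beyond
this is not specified by its description; the symmetric treatment here is
the simplification adopted.

## The MCTS baseline

`mcts_search()` plays the one-player formulation: a state is the set of
molecules still to be made, an action resolves the first open molecule by
one of its reactions, building-block reactants are absorbed, a reactant
already resolved on the line loses it (cycle cut), and a line wins when
nothing is open. Selection is UCB1 with a per-visit penalty (so long runs
spread over distinct lines), expansion adds all children at once, rollouts
choose reactions with probability proportional to their one-step scores —
the bias toward high-scoring reactions that characterises planners built
on learned policies — and rewards are 0/1. Routes are read off the tree's
winning lines only; rollouts estimate values. Reading routes out of random
rollouts would hand the baseline a diversity mechanism no such planner
has, and with it the comparison below would measure the rollout policy,
not the search.

## Chemical diversity score

`cds()` implements the disconnection-based score. Each route maps to the
set of bonds its reactions form, keyed canonically
(`canonical_bond()`; bond type is ignored — a disconnection is a
connectivity change). The retained family `C_M` deduplicates the sets,
drops empty ones and removes any set that a strictly smaller input set
represents (`build_cm()`; strict-subset reading by default, the
"covered by a union of smaller sets" reading is available via
`minimality = "cover"`). The score is `1 + (1/|C_M|)` times the full
ordered double sum of Jaccard distances, diagonal included (it contributes
zero): this normalisation makes `n` pairwise-disjoint ideas score exactly
`n`, matching the score's reading as a count of chemical ideas, and makes
the score invariant under route duplication, route order, and the
addition of routes whose disconnections are supersets of existing ones.
An empty family yields score 0 with a warning flag rather than an error.

## Synthetic networks: what they emulate, and what they do not

`generate_network()` stands in for the neural one-step model and the
building-block catalog. Molecules sit on layers below the target;
reactions connect a molecule to one or two strictly deeper molecules (the
base network is acyclic and planted routes always terminate), a fraction
of molecules is purchasable, and `cycle_fraction` of the non-planted
reactions gains an extra non-deeper reactant, creating directed cycles.
Planted routes use fresh reaction nodes so later random edges cannot
corrupt them. Each molecule owns one or two "disconnection ideas" (small
bond sets in the target's frame) and every reaction producing it draws its
formed bonds from that pool — the synthetic analogue of many named
reactions forming the same bond, which is the reason the diversity score
works at the level of disconnections rather than reactions. Reaction
scores are Beta(4, 1.5): mostly plausible reactions with a thin tail of
poor ones, so viability products and cost-guided search are exercised.

The study conditions for the diversity comparison are fixed at: 50
networks (seed block 7000 + 1..50) of 35 molecules, up to 4 reactions per
molecule, buyable fraction 0.3, cycle fraction 0.1, depth 5, two planted
routes; DFPN\* runs with a 6,000-step budget and at most 10 routes, at
`p_reac` 0 versus 20; MCTS runs 600 iterations (an iteration does a
descent plus a rollout of up to 30 steps, roughly matching the node work
of ten search steps) with its first 10 routes kept. The asserted claims
are trends on means with a 0.05 tolerance — higher penalties do not
decrease mean CDS, and the penalised multi-solution search is not less
diverse than the MCTS baseline — not per-instance dominance.

What the generator does not emulate: real chemistry distributions (ring
systems, functional groups, protecting-group logic), atom-mapped
structures (bond labels are abstract), branching factors of tens as a
learned model would produce, or failure correlations between reactions.
Passing tests therefore show the algorithms and the score behave as
designed on networks with controlled structure; they do not certify
performance on a real catalog and model, where the published full-scale
experiments (which require a proprietary one-step model and a
building-block catalog) remain the reference.

## Numerical and engineering choices

* `Inf` is a first-class saturating value; all pn/dn sums and threshold
  surpluses saturate rather than overflow or produce `NaN`.
* Ties everywhere (child selection, proved-child choice at extraction,
  deepest-reaction selection) break to the first element in stored order;
  all searches are deterministic given their seed, and DFPN uses no
  randomness at all.
* Stored search state lives in environments (`new_search_records()`);
  record stores can be passed back in to continue a search.
* The brute-force oracle's depth cap defaults to twice the node count plus
  slack, which the repetition rule makes unreachable; it exists to turn
  malformed inputs into flagged truncation instead of hangs.
* Test problem sizes — graphs of 5 to 45 nodes, 200-seed equivalence
  sweeps, 50-network trend blocks — keep the full suite under a minute
  of compute while every behavioural claim stays at the scale stated
  above.

## Known limitations

* The completeness of the reinforced search is demonstrated empirically,
  not proved, and the path-keyed cache is conservative: results that
  cannot be validated under the current path are re-searched, which costs
  time on heavily transposed graphs.
* The multi-solution loop purges cached proofs after every forced
  disproof; on large graphs an incremental invalidation would be cheaper.
* `p_mol` is exposed but defaults to 0 and is untested beyond its
  arithmetic, matching its role as a secondary knob.
* The MCTS baseline is a faithful simple planner, not a reimplementation
  of any specific published tool; published MCTS planners differ in
  unreported details.
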