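# retrodiv

Diversity-oriented retrosynthetic route search on AND/OR reaction networks.

## The problem

Computer-assisted synthesis planning assembles one-step reaction
predictions into full synthesis plans: starting from purchasable building
blocks, produce a given target molecule. A single "best" plan is rarely
what a chemist wants — quality criteria (safety, yield, equipment,
regulations) are context-specific — so a practical planner should return a
*diverse set* of plans and let the chemist choose. `retrodiv` implements a
search stack built around that idea:

* **The game model.** Retrosynthesis is a two-player game on a bipartite
  AND/OR graph: molecule nodes (OR) belong to the molecule player, who
  picks a reaction producing the molecule; reaction nodes (AND) belong to
  the reaction player, who may demand any reactant. The molecule player
  wins on reaching a building block; the reaction player wins at a dead
  end or when a molecule repeats on the play path. A winning strategy for
  the molecule player *is* a synthesis route.
* **Proof-number search.** `pns()` (best-first) and `dfpn()` (depth-first
  with thresholds) solve the game guided by proof numbers `pn` and
  disproof numbers `dn`: at a molecule node `pn = min` / `dn = sum` over
  children, at a reaction node `pn = sum` / `dn = min`. Plain DFPN is
  incomplete on cyclic graphs — the package ships a 7-node counterexample
  (`dfpn_counterexample()`) on which it loops forever — and becomes
  empirically complete when reinforced with the threshold controlling
  algorithm (TCA, raising thresholds at nodes with *old* children,
  `md(child) <= md(node)`) and path-keyed proof caching that handles the
  graph-history-interaction problem.
* **Multi-solution search (DFPN\*).** `find_route_set()` iterates DFPN:
  after each proof it force-disproves the deepest reaction of the found
  route *under the path that reached it* (so the route cannot recur while
  the reaction stays usable elsewhere) and adds a penalty `p_reac` to the
  proof numbers along the branch. Higher penalties push the search toward
  different branches, i.e. more diverse routes.
* **Chemical diversity score (CDS).** For a route set, each route is
  reduced to its *disconnection set* — the bonds formed in the forward
  direction, keyed in the target's atom frame. After dropping sets that a
  strictly smaller set already represents (the retained family `C_M`),

  ```
  CDS = 1 + (1/|C_M|) * sum over ordered pairs (T, T') in C_M of d_J(T, T')
  ```

  with `d_J` the Jaccard distance. One route scores 1; `n` pairwise
  disjoint disconnection ideas score exactly `n` — the score reads as the
  number of distinct chemical ideas in the set.
* **Baselines and harness.** A one-player MCTS baseline
  (`mcts_search()`, UCB1 selection with a visit penalty and score-weighted
  rollouts), seeded generators for synthetic reaction networks with
  planted routes (`generate_network()`, `generate_route_set()`), and a
  small benchmark harness (`run_bench()`).

## Worked example

```r
library(retrodiv)

net <- generate_network(n_molecules = 35, max_reactions_per_molecule = 4,
                        buyable_fraction = 0.3, cycle_fraction = 0.1,
                        planted_routes = 2, depth = 5, seed = 7001)
g <- net$graph

routes <- find_route_set(g, max_solutions = 10, p_reac = 20,
                         max_expansions = 6000)
length(routes)
#> [1] 9
cds(routes)
#> <cds_result> score 3.749 over 5 retained disconnection sets
round(sapply(routes, route_viability), 3)
#> [1] 0.713 0.524 0.914 0.772 0.255 0.776 0.185 0.124 0.216
```

Nine distinct routes were found for this target; their disconnection sets
collapse into five retained ideas, and the score 3.75 says the set carries
nearly four genuinely different chemical ideas once overlap is accounted
for. The viability of each route is the product of its per-reaction
scores — the probability the whole route works if reactions fail
independently.

The cyclic counterexample, in one screenful:

```r
g <- dfpn_counterexample()
dfpn(g, 10000, use_tca = FALSE)
#> <game_outcome> unproved (10000 search steps)
dfpn(g, 10000, use_tca = TRUE)
#> <game_outcome> proved (8 search steps)
```

A command-line front end with the same functionality is installed at
`system.file("cli", "retrodiv", package = "retrodiv")` (subcommands
`search`, `diversify`, `score-cds`, `simulate`, `bench`).

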