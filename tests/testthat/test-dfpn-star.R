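test_that("deepest reaction selection is maximal-depth with traversal-order ties", {
  r3 <- chain_graph()
  route <- enumerate_routes(r3)[[1]]
  expect_equal(deepest_reaction(route)$rxn, "R2")   # last step of the chain

  # branched: depth 1 vs depth 2
  branched <- synthesis_route(
    "A", rxn = "Rtop", reactants = list(
      synthesis_route("B"),
      synthesis_route("C", rxn = "Rdeep",
                      reactants = list(synthesis_route("D")))))
  expect_equal(deepest_reaction(branched)$rxn, "Rdeep")
  expect_equal(deepest_reaction(branched)$path_molecules, c("A", "C"))

  # two reactions tied at depth 2: traversal-first wins
  tied <- synthesis_route(
    "A", rxn = "R0", reactants = list(
      synthesis_route("B", rxn = "Rb",
                      reactants = list(synthesis_route("E"))),
      synthesis_route("C", rxn = "Rc",
                      reactants = list(synthesis_route("F")))))
  expect_equal(deepest_reaction(tied)$rxn, "Rb")

  expect_error(deepest_reaction(synthesis_route("A")), "no reactions")
})

test_that("forced disproofs are path-keyed and idempotent", {
  st <- new_search_records()
  force_disprove(st, "R5", c("A", "B", "D"))
  expect_equal(ghi_lookup(st, "R5", ctx = c("A", "B", "D")), "disproved")
  expect_equal(ghi_lookup(st, "R5", ctx = c("A", "C", "D")), "unknown")
  n0 <- length(st$ghi[["R5"]])
  force_disprove(st, "R5", c("A", "B", "D"))
  expect_length(st$ghi[["R5"]], n0)
})

test_that("penalties add to pn, respect the molecule default, and saturate", {
  g <- diamond_graph()
  st <- new_search_records()
  retrodiv:::set_rec(st, "R1", list(pn = 3, dn = 1, expanded = TRUE, md = 1))
  retrodiv:::set_rec(st, "B", list(pn = 2, dn = 1, expanded = TRUE, md = 2))
  retrodiv:::set_rec(st, "R3", list(pn = Inf, dn = 0, expanded = TRUE,
                                    md = 3))
  apply_penalties(g, st, c("A", "R1", "B", "R3"), p_reac = 5, p_mol = 0)
  expect_equal(st$rec[["R1"]]$pn, 8)
  expect_equal(st$rec[["B"]]$pn, 2)        # p_mol = 0 leaves molecules alone
  expect_equal(st$rec[["R3"]]$pn, Inf)     # saturation
  expect_equal(retrodiv:::get_pen(st, "R1"), 5)
})

test_that("a force-disproved reaction stays usable through a second path", {
  g <- diamond_graph()
  expect_length(enumerate_routes(g), 2)
  routes <- find_route_set(g, max_solutions = 5, p_reac = 5,
                           max_expansions = 5000)
  expect_length(routes, 2)   # R5 is re-used via the other diamond arm
  expect_true(all(vapply(routes, function(r) route_is_valid(g, r),
                         logical(1))))
  rxns <- lapply(routes, route_reactions)
  expect_true(all(vapply(rxns, function(x) "R5" %in% x, logical(1))))
})

test_that("multi-solution search returns exact counts on hand-checked graphs", {
  expect_length(find_route_set(two_route_graph(), max_solutions = 5), 2)
  expect_length(find_route_set(dfpn_counterexample(), max_solutions = 5), 1)
  expect_length(find_route_set(dead_chain_graph(), max_solutions = 5), 0)
})

test_that("route sets are valid, distinct and deterministic on synthetic networks", {
  for (s in 1:12) {
    net <- generate_network(n_molecules = 16,
                            max_reactions_per_molecule = 3,
                            buyable_fraction = 0.3, cycle_fraction = 0.2,
                            planted_routes = 1 + s %% 2, depth = 4,
                            seed = 300 + s)
    g <- net$graph
    rs <- find_route_set(g, max_solutions = 10, p_reac = 5,
                         max_expansions = 8000)
    expect_true(all(vapply(rs, function(r) route_is_valid(g, r),
                           logical(1))), info = paste("seed", s))
    keys <- vapply(rs, retrodiv:::route_key, character(1))
    expect_false(anyDuplicated(keys) > 0, info = paste("seed", s))
    if (solve_brute_force(g)$status == "proved") {
      expect_gte(length(rs), 1)
    }
    rs2 <- find_route_set(g, max_solutions = 10, p_reac = 5,
                          max_expansions = 8000)
    expect_identical(lapply(rs, unclass), lapply(rs2, unclass),
                     info = paste("determinism seed", s))
  }
})

test_that("edge-cost search still matches the game value", {
  for (s in 1:15) {
    g <- dag_net(s)$graph
    truth <- solve_brute_force(g)$status
    out <- dfpn(g, 10000, use_tca = TRUE, edge_costs = TRUE)
    expect_equal(out$status, truth, info = paste("seed", s))
    if (truth == "proved") expect_true(route_is_valid(g, out$strategy))
  }
})

test_that("route viability multiplies reaction scores", {
  r <- synthesis_route(
    "A", rxn = "R1", score = 0.9, reactants = list(
      synthesis_route("B", rxn = "R2", score = 0.8,
                      reactants = list(synthesis_route("C")))))
  expect_equal(route_viability(r), 0.72)
  expect_equal(route_viability(synthesis_route("A")), 1)
  r$via$score <- 0
  expect_equal(route_viability(r), 0)
  r$via$score <- NULL
  expect_error(route_viability(r), "R1")
})
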