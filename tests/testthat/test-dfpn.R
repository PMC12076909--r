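test_that("search handles terminal roots and trivial graphs", {
  bb <- and_or_graph(c(A = "molecule"), NULL, root = "A",
                     terminal = c(A = "building_block"))
  for (res in list(pns(bb), dfpn(bb))) {
    expect_equal(res$status, "proved")
    expect_equal(res$expansions_used, 0)
    expect_true(is_route_leaf(res$strategy))
  }
  expect_equal(dfpn(dead_chain_graph())$status, "disproved")
  expect_equal(pns(dead_chain_graph())$status, "disproved")
  expect_equal(dfpn(chain_graph())$status, "proved")
})

test_that("plain DFPN loops on the cyclic counterexample without touching the escape", {
  g <- dfpn_counterexample()
  out <- dfpn(g, max_expansions = 10000, use_tca = FALSE)
  expect_equal(out$status, "unproved")
  expect_equal(out$expansions_used, 10000)
  expect_false(isTRUE(out$records$rec[["v5"]]$expanded))
})

test_that("DFPN with TCA proves the counterexample through the building block", {
  g <- dfpn_counterexample()
  out <- dfpn(g, max_expansions = 10000, use_tca = TRUE)
  expect_equal(out$status, "proved")
  expect_true("v6" %in% route_leaves(out$strategy))
  expect_true(route_is_valid(g, out$strategy))
  expect_lt(out$expansions_used, 100)
})

test_that("all searches agree with the oracle on random DAGs", {
  for (s in 1:60) {
    g <- dag_net(s)$graph
    truth <- solve_brute_force(g)$status
    expect_equal(pns(g, 10000)$status, truth, info = paste("pns seed", s))
    expect_equal(dfpn(g, 10000, use_tca = FALSE)$status, truth,
                 info = paste("dfpn seed", s))
    expect_equal(dfpn(g, 10000, use_tca = TRUE)$status, truth,
                 info = paste("dfpn-tca seed", s))
  }
})

test_that("TCA + path-keyed caching settles cyclic graphs within 50 visits per node", {
  for (s in 1:60) {
    g <- cyclic_net(s)$graph
    n <- length(g$role)
    out <- dfpn(g, max_expansions = 50 * n, use_tca = TRUE, ghi_safe = TRUE)
    expect_false(out$status == "unproved", info = paste("seed", s))
    expect_equal(out$status, solve_brute_force(g)$status,
                 info = paste("seed", s))
    expect_lte(out$expansions_used, 50 * n)
  }
})

test_that("settled pn/dn values agree with a fresh bottom-up aggregation on DAGs", {
  n_checked <- 0
  for (s in c(3, 7, 11)) {
    g <- dag_net(s)$graph
    out <- dfpn(g, 10000, use_tca = TRUE)
    st <- out$records
    for (v in ls(st$rec)) {
      rec <- st$rec[[v]]
      if (!rec$expanded) next
      if (length(retrodiv:::node_children(g, v)) == 0) next
      ctx <- if (retrodiv:::node_role(g, v) == "molecule") v else character(0)
      agg <- retrodiv:::aggregate_node(g, st, v, ctx, ghi_safe = TRUE,
                                       edge_costs = FALSE)
      n_checked <- n_checked + 1
      # pn = 0 iff proved, dn = 0 iff disproved, never both
      expect_equal(rec$pn == 0, agg$pn == 0, info = paste(s, v))
      expect_equal(rec$dn == 0, agg$dn == 0, info = paste(s, v))
      expect_false(agg$pn == 0 && agg$dn == 0, info = paste(s, v))
    }
  }
  expect_gt(n_checked, 0)
})

test_that("md never increases and budgets are respected", {
  g <- dfpn_counterexample()
  out <- dfpn(g, max_expansions = 50, use_tca = FALSE)
  expect_lte(out$expansions_used, 50)
  st <- out$records
  # md equals the true minimum explored root distance for the fixture
  expect_equal(st$rec[["v0"]]$md, 0)
  expect_equal(st$rec[["v1"]]$md, 1)
  expect_equal(st$rec[["v4"]]$md, 2)
})

test_that("strategy extraction breaks ties by child order and rejects unproved roots", {
  g <- two_route_graph()
  out <- dfpn(g, 1000, use_tca = TRUE)
  expect_equal(out$status, "proved")
  # both reactions are proved; the first in child order must be picked
  expect_equal(out$strategy$via$rxn, "R1")

  st <- new_search_records()
  expect_error(extract_strategy(dead_chain_graph(), st), "unproved")
})

test_that("search outcomes are deterministic", {
  g <- cyclic_net(5)$graph
  a <- dfpn(g, 5000, use_tca = TRUE)
  b <- dfpn(g, 5000, use_tca = TRUE)
  expect_identical(a$status, b$status)
  expect_identical(a$expansions_used, b$expansions_used)
  if (a$status == "proved") {
    expect_identical(unclass(a$strategy), unclass(b$strategy))
  }
})
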