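test_that("pn/dn aggregation follows the OR/AND update rules", {
  expect_equal(update_numbers("molecule", c(2, 3), c(1, 4)), c(2, 5))
  expect_equal(update_numbers("reaction", c(2, 3), c(1, 4)), c(5, 1))
  expect_equal(update_numbers("molecule", c(0, 7), c(Inf, 2)), c(0, Inf))
  expect_equal(update_numbers("reaction", c(Inf, 1), c(0, 5)), c(Inf, 0))
  expect_error(update_numbers("molecule", numeric(0), numeric(0)),
               "non-empty")
})

test_that("threshold propagation matches the DFPN rules", {
  # molecule node: pn threshold capped by second-best + 1
  expect_equal(
    child_thresholds("molecule", Inf, Inf, 1, 5, chosen = c(1, 2),
                     second_best = c(4, 3))[1], 5)
  # single child passes thresholds unchanged
  expect_equal(
    child_thresholds("reaction", 7, 9, 1, 1, chosen = c(1, 1),
                     single_child = TRUE), c(7, 9))
  # reaction node: pn surplus th - pn(v) + pn(child)
  expect_equal(
    child_thresholds("reaction", 10, Inf, 6, 1, chosen = c(2, 1),
                     second_best = c(3, 4))[1], 6)
  # saturation
  expect_equal(
    child_thresholds("molecule", Inf, Inf, 1, Inf, chosen = c(1, Inf),
                     second_best = c(Inf, Inf)), c(Inf, Inf))
})

test_that("TCA raises thresholds exactly at nodes with old unproved children", {
  g <- dfpn_counterexample()
  st <- new_search_records()
  # state after the search has walked v0 -> v2 -> v3 and expanded the cycle
  retrodiv:::set_rec(st, "v0",
                     list(pn = 1, dn = 2, expanded = TRUE, md = 0))
  retrodiv:::set_rec(st, "v2",
                     list(pn = 1, dn = 1, expanded = TRUE, md = 1))
  retrodiv:::set_rec(st, "v3",
                     list(pn = 1, dn = 2, expanded = TRUE, md = 2))
  adj <- tca_adjust(g, st, "v3", ctx = "v0")
  expect_true(adj$raised)   # md(v2) = 1 <= md(v3) = 2 and v2 unproved
  expect_equal(adj$th_pn, 2)  # pn(v3) + 1
  expect_equal(adj$th_dn, 3)  # dn(v3) + 1

  # children all strictly deeper: no raise
  adj0 <- tca_adjust(g, st, "v0", ctx = character(0))
  expect_false(adj0$raised)

  # an already-proved old child does not trigger a raise
  ghi_store(st, "v2", "proved")
  adj2 <- tca_adjust(g, st, "v3", ctx = "v0")
  expect_false(adj2$raised)
})

test_that("path-keyed proof cache validates contexts correctly", {
  st <- new_search_records()
  expect_equal(ghi_lookup(st, "v"), "unknown")

  ghi_store(st, "v", "proved", dep = c("v", "m2"))
  expect_equal(ghi_lookup(st, "v", ctx = "root"), "proved")
  # a proof is invalid when a proof-subtree molecule is already on the path
  expect_equal(ghi_lookup(st, "v", ctx = c("root", "m2")), "unknown")

  # a repetition-based disproof applies only to paths containing its
  # dependency (hand-built cyclic situation: w disproved while m3 on path)
  ghi_store(st, "w", "disproved", dep = "m3")
  expect_equal(ghi_lookup(st, "w", ctx = c("root", "m3")), "disproved")
  expect_equal(ghi_lookup(st, "w", ctx = "root"), "unknown")

  # storing is idempotent / dominated entries are dropped
  n0 <- length(st$ghi[["w"]])
  ghi_store(st, "w", "disproved", dep = "m3")
  ghi_store(st, "w", "disproved", dep = c("m3", "m4"))
  expect_length(st$ghi[["w"]], n0)
})

test_that("reusing a repetition disproof on a wrong path is prevented end to end", {
  # 6-node cyclic graph: B is disproved when reached through A (its only
  # continuation loops back), but provable through the direct reaction R2.
  g <- and_or_graph(
    c(A = "molecule", R1 = "reaction", B = "molecule", R2 = "reaction",
      C = "molecule", R3 = "reaction"),
    data.frame(from = c("A", "R1", "B", "R3", "B", "R2"),
               to   = c("R1", "B", "R3", "A", "R2", "C")),
    root = "A", terminal = c(C = "building_block"))
  expect_equal(solve_brute_force(g)$status, "proved")
  out <- dfpn(g, 5000, use_tca = TRUE, ghi_safe = TRUE)
  expect_equal(out$status, "proved")
})
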