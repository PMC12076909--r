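test_that("formed bonds are the product-minus-reactant difference", {
  expect_equal(formed_bonds(list(c("1", "2"), c("2", "3")),
                            list(c("2", "3"))), "1|2")
  expect_length(formed_bonds(list(c("1", "2")), list(c("1", "2"))), 0)
  expect_equal(formed_bonds(list(c("1", "2"), c("3", "4")), list()),
               c("1|2", "3|4"))
  # order normalisation: (b,a) and (a,b) are the same bond
  expect_length(formed_bonds(list(c("b", "a")), list(c("a", "b"))), 0)
})

test_that("disconnection extraction unions bond keys with set semantics", {
  r <- synthesis_route(
    "A", rxn = "R1", bonds = c("a1|a2"), score = 1, reactants = list(
      synthesis_route("B", rxn = "R2", bonds = c("a3|a4", "a1|a2"),
                      score = 1,
                      reactants = list(synthesis_route("C")))))
  expect_equal(extract_disconnections(r), c("a1|a2", "a3|a4"))
  r$via$bonds <- character(0)
  expect_error(extract_disconnections(r), "R1")
})

test_that("Jaccard distance is a metric on hand fixtures", {
  expect_equal(jaccard_distance("x", "x"), 0)
  expect_equal(jaccard_distance("x", "y"), 1)
  expect_equal(jaccard_distance(c("a", "b"), c("a", "c")), 2 / 3)
  expect_equal(jaccard_distance(character(0), character(0)), 0)
  # symmetry and triangle inequality spot checks
  A <- c("a", "b"); B <- c("b", "c"); C <- c("c", "d")
  expect_equal(jaccard_distance(A, B), jaccard_distance(B, A))
  expect_lte(jaccard_distance(A, C),
             jaccard_distance(A, B) + jaccard_distance(B, C))
})

test_that("the retained family keeps inclusion-minimal, deduplicated sets", {
  expect_equal(build_cm(list("a", c("a", "b"))), list("a"))
  expect_equal(build_cm(list("a", "b")), list("a", "b"))
  expect_equal(build_cm(list("a", "a")), list("a"))
  expect_length(build_cm(list(character(0), "a")), 1)
  # minimality is judged against the full family
  expect_equal(build_cm(list(c("a", "b", "c"), c("a", "b"), "a")),
               list("a"))
})

test_that("CDS matches its closed forms", {
  expect_equal(cds(list("a|b"))$score, 1)
  for (n in 2:6) {
    sets <- lapply(seq_len(n), function(i) paste0("x", i, "|y", i))
    expect_equal(cds(sets)$score, n)
  }
  expect_equal(cds(list(c("a|b", "a|c"), c("a|b", "a|d")))$score, 5 / 3)
})

test_that("CDS is invariant under permutation, duplication and supersets", {
  sets <- list(c("a|b", "c|d"), c("e|f", "g|h"), c("a|b", "i|j"))
  base <- cds(sets)$score
  expect_equal(cds(rev(sets))$score, base)
  expect_equal(cds(c(sets, sets[2]))$score, base)
  # a superset of an existing disconnection set is absorbed
  expect_equal(cds(c(sets, list(c("a|b", "c|d", "z|w"))))$score, base)
  m <- cds(sets)$distance_matrix
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  expect_gte(base, 1)
  expect_lte(base, length(cds(sets)$c_m))
})

test_that("empty input yields the flagged zero score", {
  expect_warning(res <- cds(list()), "undefined")
  expect_equal(res$score, 0)
  expect_true(res$empty)
})

test_that("unique molecule counts and route-length statistics", {
  r <- synthesis_route(
    "T", rxn = "R1", score = 1, bonds = "a|b", reactants = list(
      synthesis_route("I1", rxn = "R2", score = 1, bonds = "c|d",
                      reactants = list(
        synthesis_route("I2", rxn = "R3", score = 1, bonds = "e|f",
                        reactants = list(synthesis_route("L1"),
                                         synthesis_route("L2")))))))
  counts <- unique_molecule_counts(list(r))
  expect_equal(counts$unique_intermediates, 2)
  expect_equal(counts$unique_building_blocks, 2)
  expect_equal(unique_molecule_counts(list(r, r)), counts)
  expect_equal(unique_molecule_counts(list()),
               list(unique_intermediates = 0, unique_building_blocks = 0))

  two <- generate_route_set(2, 2, seed = 1)
  stats <- route_length_stats(list(t1 = two))
  expect_equal(stats$mean_reactions, 2)
  expect_equal(stats$iqr, 0)
  lens <- list(t1 = list(r),                       # 3 reactions
               t2 = generate_route_set(1, 1, seed = 2))  # 2 reactions
  st <- route_length_stats(lens)
  expect_equal(st$mean_reactions, 2.5)
  expect_equal(st$median, 2.5)
  expect_error(route_length_stats(list()), "empty")
})
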