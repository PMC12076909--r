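#' The 7-node cyclic graph on which plain DFPN is incomplete
#'
#' A minimal AND/OR game graph exhibiting the incompleteness of plain DFPN:
#' the root molecule `v0` has two near-symmetric reactions `v1`/`v2` leading
#' to molecules `v4`/`v3`, both of which fall back into their cycle
#' (`v4 -> v1`, `v3 -> v2`); only `v3` has an escape through reaction `v5`
#' to the sole building block `v6`, so the game has exactly one winning
#' strategy and it includes `v6`. Without reinforcements DFPN keeps churning
#' on the cyclic branches -- the on-path repeats contribute saturated
#' values, the thresholds are met and the search never expands `v5` --
#' while DFPN with the threshold-controlling adjustment and path-keyed
#' proof caching proves the root through `v6`. The cycle also illustrates
#' the TCA trigger: `v3`'s child `v2` is an old child
#' (`md(v2) = 1 <= md(v3) = 2`).
#'
#' @return An [and_or_graph()] with 7 nodes.
#' @export
dfpn_counterexample <- function() {
  nodes <- c(v0 = "molecule", v1 = "reaction", v2 = "reaction",
             v3 = "molecule", v4 = "molecule", v5 = "reaction",
             v6 = "molecule")
  edges <- data.frame(
    from = c("v0", "v0", "v1", "v2", "v3", "v3", "v4", "v5"),
    to   = c("v1", "v2", "v4", "v3", "v2", "v5", "v1", "v6"),
    stringsAsFactors = FALSE
  )
  and_or_graph(nodes, edges, root = "v0",
               terminal = c(v6 = "building_block"))
}

#' Generate a synthetic AND/OR reaction network with planted routes
#'
#' Emulates the branching reaction networks a one-step prediction model
#' would induce: molecules are placed on layers below the target, reactions
#' connect a molecule to 1..`max_reactants` molecules on strictly deeper
#' layers (so the base network is acyclic), a fraction of molecules is
#' purchasable, and `cycle_fraction` of the non-planted reactions gain one
#' extra reactant on a non-deeper layer, creating directed cycles. A given
#' number of solution routes is planted first through fresh reaction nodes,
#' so they remain valid whatever else is added. Reactions carry viability
#' scores (Beta(4, 1.5) on the molecule-to-reaction edge) and random bond
#' labels in the target's atom frame, so diversity scoring and cost-guided
#' search are exercisable.
#'
#' @param n_molecules total number of molecule nodes (>= 4).
#' @param max_reactions_per_molecule cap on reactions per molecule.
#' @param max_reactants cap on reactants per reaction.
#' @param buyable_fraction probability that a non-root molecule is a
#'   building block (1 makes every molecule purchasable, the target
#'   included).
#' @param cycle_fraction probability that a random reaction receives a
#'   cycle-creating extra reactant.
#' @param planted_routes number of solution routes planted (>= 0).
#' @param depth number of layers below the target.
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return List with `graph` (an [and_or_graph()]) and `planted` (list of
#'   [synthesis_route()] objects, valid in `graph`).
#' @export
generate_network <- function(n_molecules = 30,
                             max_reactions_per_molecule = 2,
                             max_reactants = 2, buyable_fraction = 0.3,
                             cycle_fraction = 0, planted_routes = 1,
                             depth = 4, seed = 1) {
  if (n_molecules < 4) stop("need at least 4 molecules")
  if (depth < 2) stop("depth must be at least 2")
  with_seed(seed, {
    mols <- paste0("m", seq_len(n_molecules))
    layer <- c(0, sample(seq_len(depth), n_molecules - 1, replace = TRUE))
    names(layer) <- mols
    # make sure every layer is populated
    for (l in seq_len(depth)) {
      if (!any(layer[-1] == l)) {
        layer[1 + ((l - 1) %% (n_molecules - 1)) + 1] <- l
      }
    }
    buyable <- layer == depth |
      (layer > 0 & stats::runif(n_molecules) < buyable_fraction)
    if (buyable_fraction >= 1) buyable[] <- TRUE
    names(buyable) <- mols

    rxn_n <- 0L
    edges_from <- character(0); edges_to <- character(0)
    edge_sc <- numeric(0)
    rxn_ids <- character(0)
    bonds <- list()
    atom_pool <- paste0("a", seq_len(2 * depth + 6))
    n_react_of <- stats::setNames(integer(n_molecules), mols)

    # Each molecule owns a small pool of disconnection ideas (bond sets);
    # competing reactions making the same molecule frequently realise the
    # same idea, as named-reaction variants do in real chemistry, so route
    # variations that merely swap such reactions add no diversity.
    idea_pool <- lapply(mols, function(m) {
      n_ideas <- sample(1:2, 1)
      lapply(seq_len(n_ideas), function(i) {
        nb <- sample(1:2, 1)
        unique(vapply(seq_len(nb), function(j) {
          p <- sample(atom_pool, 2)
          canonical_bond(p[1], p[2])
        }, character(1)))
      })
    })
    names(idea_pool) <- mols

    new_rxn <- function(parent, reactants) {
      rxn_n <<- rxn_n + 1L
      rid <- paste0("r", rxn_n)
      rxn_ids <<- c(rxn_ids, rid)
      edges_from <<- c(edges_from, parent, rep(rid, length(reactants)))
      edges_to <<- c(edges_to, rid, reactants)
      edge_sc <<- c(edge_sc, stats::rbeta(1, 4, 1.5),
                    rep(NA_real_, length(reactants)))
      pool <- idea_pool[[parent]]
      bonds[[rid]] <<- pool[[sample.int(length(pool), 1)]]
      n_react_of[parent] <<- n_react_of[parent] + 1L
      rid
    }

    # Plant solution routes: fresh reactions, reactants strictly deeper,
    # recursion bottoms out at building blocks.
    plant <- function(m) {
      l <- layer[m]
      deeper_bb <- mols[buyable & layer > l]
      deeper_open <- mols[!buyable & layer > l & layer < depth]
      if (length(deeper_bb) == 0) {
        stop("infeasible generator settings: no building block below layer ",
             l)
      }
      k <- sample(seq_len(max_reactants), 1)
      reactants <- character(0)
      for (i in seq_len(k)) {
        go_open <- length(deeper_open) > 0 && l < depth - 1 &&
          stats::runif(1) < 0.6
        pool <- if (go_open) deeper_open else deeper_bb
        pool <- setdiff(pool, reactants)
        if (length(pool) == 0) next
        reactants <- c(reactants, pool[sample.int(length(pool), 1)])
      }
      if (length(reactants) == 0) reactants <- deeper_bb[1]
      rid <- new_rxn(m, reactants)
      subs <- lapply(reactants, function(q) {
        if (buyable[q]) list(mol = q) else plant(q)
      })
      list(mol = m, rxn = rid, reactants = subs)
    }

    planted_skel <- list()
    if (!buyable["m1"] && planted_routes > 0) {
      planted_skel <- lapply(seq_len(planted_routes), function(i) plant("m1"))
    }

    # Random extra reactions on non-buyable molecules.
    for (m in mols) {
      if (buyable[m]) next
      l <- layer[m]
      deeper <- mols[layer > l]
      if (length(deeper) == 0) next
      extra <- max_reactions_per_molecule - n_react_of[m]
      if (extra <= 0) next
      n_extra <- sample(0:extra, 1)
      for (i in seq_len(n_extra)) {
        k <- min(sample(seq_len(max_reactants), 1), length(deeper))
        reactants <- deeper[sample.int(length(deeper), k)]
        if (stats::runif(1) < cycle_fraction) {
          shallow <- mols[!buyable & layer <= l]
          if (length(shallow) > 0) {
            reactants <- unique(c(
              reactants, shallow[sample.int(length(shallow), 1)]))
          }
        }
        new_rxn(m, reactants)
      }
    }

    roles <- stats::setNames(c(rep("molecule", n_molecules),
                               rep("reaction", length(rxn_ids))),
                             c(mols, rxn_ids))
    term <- stats::setNames(ifelse(buyable, "building_block", "none"), mols)
    g <- and_or_graph(
      roles,
      data.frame(from = edges_from, to = edges_to, score = edge_sc,
                 stringsAsFactors = FALSE),
      root = "m1", terminal = term, bonds = bonds)

    to_route <- function(sk) {
      if (is.null(sk$rxn)) return(synthesis_route(sk$mol))
      synthesis_route(sk$mol, rxn = sk$rxn,
                      reactants = lapply(sk$reactants, to_route),
                      bonds = g$bonds[[sk$rxn]] %||% character(0),
                      score = edge_score(g, sk$mol, sk$rxn))
    }
    planted <- lapply(planted_skel, to_route)
    if (buyable["m1"]) planted <- list(synthesis_route("m1"))
    list(graph = g, planted = planted)
  })
}

#' Generate synthetic routes with controlled disconnection overlap
#'
#' Builds `n_routes` two-step linear routes whose disconnection sets fall
#' into `n_ideas` groups ("chemical ideas"). Each idea owns a pool of bond
#' labels; `overlap` is the fraction of each idea's bonds drawn from a pool
#' shared by all ideas, so `overlap = 0` gives pairwise-disjoint,
#' equal-sized (hence inclusion-minimal) sets and [cds()] equals `n_ideas`
#' exactly, while larger overlaps pull the score down continuously.
#'
#' @param n_routes number of routes (>= `n_ideas`).
#' @param n_ideas number of distinct disconnection groups.
#' @param overlap number in `[0, 1)`: shared fraction of each idea's bonds.
#' @param seed RNG seed (scores are random; the bond structure is
#'   deterministic by construction).
#' @param bonds_per_idea size of each idea's disconnection set.
#' @return List of [synthesis_route()] objects.
#' @export
generate_route_set <- function(n_routes, n_ideas, overlap = 0, seed = 1,
                               bonds_per_idea = 4) {
  if (n_ideas > n_routes) stop("n_ideas must not exceed n_routes")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  n_shared <- round(overlap * bonds_per_idea)
  shared <- vapply(seq_len(max(n_shared, 1)), function(i)
    canonical_bond(paste0("s", i), paste0("s", i + 1)), character(1))
  idea_sets <- lapply(seq_len(n_ideas), function(i) {
    own <- vapply(seq_len(bonds_per_idea - n_shared), function(j)
      canonical_bond(paste0("i", i, "x", j), paste0("i", i, "y", j)),
      character(1))
    sort(c(own, if (n_shared > 0) shared[seq_len(n_shared)]))
  })
  with_seed(seed, {
    lapply(seq_len(n_routes), function(j) {
      idea <- ((j - 1) %% n_ideas) + 1
      bb <- idea_sets[[idea]]
      half <- ceiling(length(bb) / 2)
      sc <- stats::rbeta(2, 4, 1.5)
      leaf1 <- synthesis_route(paste0("bb", idea, "a"))
      leaf2 <- synthesis_route(paste0("bb", idea, "b"))
      inner <- synthesis_route(
        paste0("int", idea), rxn = paste0("x", idea, "b"),
        reactants = list(leaf1, leaf2),
        bonds = bb[seq(half + 1, length(bb))], score = sc[2])
      synthesis_route(
        "target", rxn = paste0("x", idea, "a"),
        reactants = list(inner), bonds = bb[seq_len(half)], score = sc[1])
    })
  })
}
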