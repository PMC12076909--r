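#' Force a path-keyed disproof of a reaction
#'
#' Marks a reaction as disproved whenever it is reached through a path
#' containing all molecules of `ctx` (the route branch it sat on). Under
#' any other path the reaction remains usable, so routes reaching it
#' differently can still be found. Forced entries persist across proof-cache
#' purges and are idempotent.
#'
#' @param records a [new_search_records()] store.
#' @param v reaction node id.
#' @param ctx molecule ids of the branch from the target down to the
#'   reaction's product (the disproof key).
#' @return The records, invisibly.
#' @export
force_disprove <- function(records, v, ctx) {
  ghi_store(records, v, "disproved", unique(ctx), forced = TRUE)
  rec <- get_rec(records, v)
  if (rec$pn == 0 || rec$dn == 0) {
    set_rec(records, v, modifyList(rec, list(pn = 1, dn = 1)))
  }
  invisible(records)
}

#' Apply proof-number penalties along a disproved branch
#'
#' Adds `p_reac` to the proof number of every reaction node and `p_mol` to
#' every molecule node on the branch (the path from the target to the node
#' just force-disproved). Penalties accumulate across iterations of the
#' multi-solution loop and re-enter every subsequent aggregation, steering
#' the search away from already-used reactions; `Inf` saturates. Ancestor
#' pn/dn values are refreshed on the next search pass, which recomputes
#' every visited node from its children.
#'
#' @param g an [and_or_graph()].
#' @param records a [new_search_records()] store.
#' @param path_nodes node ids on the branch (molecules and reactions).
#' @param p_reac,p_mol non-negative integer penalties; the default
#'   `p_mol = 0` penalizes reactions only, since disproving a molecule
#'   disproves a reaction anyway.
#' @return The records, invisibly.
#' @export
apply_penalties <- function(g, records, path_nodes, p_reac, p_mol = 0) {
  for (v in unique(path_nodes)) {
    p <- if (node_role(g, v) == "reaction") p_reac else p_mol
    if (p <= 0) next
    assign(v, get_pen(records, v) + p, envir = records$pen)
    rec <- records$rec[[v]]
    if (!is.null(rec) && rec$pn > 0 && is.finite(rec$pn)) {
      set_rec(records, v, modifyList(rec, list(pn = rec$pn + p)))
    }
  }
  invisible(records)
}

route_branch_nodes <- function(r, target_rxn) {
  # molecules and reactions from the route root down to target_rxn
  found <- NULL
  walk <- function(s, acc) {
    if (is_route_leaf(s)) return(invisible())
    acc <- c(acc, s$mol, s$via$rxn)
    if (s$via$rxn == target_rxn && is.null(found)) {
      found <<- acc
      return(invisible())
    }
    for (sub in s$via$reactants) walk(sub, acc)
  }
  walk(r, character(0))
  found
}

#' Multi-solution diversity-driven search (DFPN*)
#'
#' Iterates DFPN to produce a set of distinct synthesis routes with an
#' explicit push towards diversity. After each proof the route is recorded,
#' its deepest reaction is force-disproved under the path that reached it
#' (see [force_disprove()]) so the same route cannot be found again while
#' routes sharing the reaction via other paths remain reachable, and
#' proof-number penalties are added along the branch (see
#' [apply_penalties()]). Cached proofs are then purged (the forced disproof
#' invalidates them), and the search restarts with the accumulated state
#' until the solution or search budget is exhausted or the root becomes
#' disproved. Deterministic: no randomness is involved.
#'
#' @param g an [and_or_graph()].
#' @param max_solutions maximum number of routes to return.
#' @param p_reac,p_mol proof-number penalties per disproved branch node;
#'   higher `p_reac` yields more diverse route sets at higher search cost.
#' @param max_expansions global search-step budget across all iterations.
#' @param use_tca,edge_costs passed to [dfpn()] (`ghi_safe` is always on:
#'   the multi-solution bookkeeping is built on path-keyed disproofs).
#' @return List of valid, pairwise-distinct [synthesis_route()] objects
#'   (empty when the target is unsolvable).
#' @export
find_route_set <- function(g, max_solutions = 10, p_reac = 5, p_mol = 0,
                           max_expansions = 10000, use_tca = TRUE,
                           edge_costs = FALSE) {
  st <- new_search_records()
  routes <- list()
  keys <- character(0)
  budget_left <- max_expansions
  repeat {
    if (length(routes) >= max_solutions || budget_left <= 0) break
    out <- dfpn(g, max_expansions = budget_left, use_tca = use_tca,
                ghi_safe = TRUE, records = st, edge_costs = edge_costs)
    budget_left <- budget_left - max(out$expansions_used, 1)
    if (out$status != "proved") break
    r <- out$strategy
    key <- route_key(r)
    if (key %in% keys) break   # forced disproof failed to separate; stop
    routes[[length(routes) + 1]] <- r
    keys <- c(keys, key)
    if (is_route_leaf(r)) break   # target itself purchasable: unique route
    d <- deepest_reaction(r)
    force_disprove(st, d$rxn, d$path_molecules)
    branch <- route_branch_nodes(r, d$rxn)
    apply_penalties(g, st, branch, p_reac = p_reac, p_mol = p_mol)
    purge_proofs(st)
  }
  routes
}
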