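# Child-status evaluation under a path context.
#
# Certainty discipline: a child's status is "proved"/"disproved" (certain)
# only when it follows from a terminal rule, a repetition on the current
# path, or a cached entry valid under this context. Anything else is
# "unknown" and its stored pn/dn are heuristics; stale settled-looking
# stored values without a valid cache entry are reset to (1, 1) so that a
# path-dependent result can never leak into a context where it is invalid.
#
# In GHI-unsafe mode an on-path repeat is "blocked": it contributes
# saturating (Inf, Inf) instead of a disproof. This conservative treatment
# never stores path-dependent results but cannot disprove by repetition,
# which is what makes plain DFPN incomplete on cyclic graphs.
child_status <- function(g, st, v, ctx, ghi_safe) {
  role <- node_role(g, v)
  if (role == "molecule") {
    if (v %in% ctx) {
      if (ghi_safe) {
        return(list(pn = Inf, dn = 0, status = "disproved", certain = TRUE,
                    dep = v))
      }
      return(list(pn = Inf, dn = Inf, status = "blocked", certain = FALSE,
                  dep = character(0)))
    }
    if (is_building_block(g, v)) {
      return(list(pn = 0, dn = Inf, status = "proved", certain = TRUE,
                  dep = character(0)))
    }
    if (length(node_children(g, v)) == 0) {
      return(list(pn = Inf, dn = 0, status = "disproved", certain = TRUE,
                  dep = character(0)))
    }
  } else if (length(node_children(g, v)) == 0) {
    return(list(pn = 0, dn = Inf, status = "proved", certain = TRUE,
                dep = character(0)))
  }
  e <- ghi_lookup_dep(st, v, ctx)
  if (!is.null(e)) {
    if (e$status == "proved") {
      return(list(pn = 0, dn = Inf, status = "proved", certain = TRUE,
                  dep = e$dep, res = e$res %||% list()))
    }
    return(list(pn = Inf, dn = 0, status = "disproved", certain = TRUE,
                dep = e$dep))
  }
  rec <- get_rec(st, v)
  pn <- rec$pn; dn <- rec$dn
  if (pn == 0 || dn == 0) { pn <- 1; dn <- 1 }   # stale settled value
  pn <- sat_add(pn, get_pen(st, v))
  list(pn = pn, dn = dn, status = "unknown", certain = FALSE,
       dep = character(0))
}

# Aggregate a node's pn/dn from its children under a path context.
# `newpath` must already include `v` when v is a molecule node.
aggregate_node <- function(g, st, v, newpath, ghi_safe, edge_costs) {
  kids <- node_children(g, v)
  if (length(kids) == 0) stop("aggregate_node called on a terminal node")
  role <- node_role(g, v)
  stats <- lapply(kids, function(k) child_status(g, st, k, newpath, ghi_safe))
  pns <- vapply(stats, `[[`, numeric(1), "pn")
  dns <- vapply(stats, `[[`, numeric(1), "dn")
  status <- vapply(stats, `[[`, character(1), "status")
  certain <- vapply(stats, `[[`, logical(1), "certain")
  eff <- pns
  if (role == "molecule" && edge_costs) {
    costs <- vapply(kids, function(k) edge_cost(g, v, k), numeric(1))
    eff <- ifelse(status == "proved", 0,
                  vapply(seq_along(pns), function(i)
                    sat_add(pns[i], costs[i]), numeric(1)))
  }
  nums <- update_numbers(role, eff, dns)
  pn_v <- nums[1]; dn_v <- nums[2]
  pen <- get_pen(st, v)
  if (pen > 0 && pn_v > 0 && is.finite(pn_v)) pn_v <- pn_v + pen
  list(pn = pn_v, dn = dn_v, ids = kids, pns = pns, dns = dns, eff = eff,
       certain = certain, status = status,
       deps = lapply(stats, `[[`, "dep"),
       res = lapply(stats, function(s) s$res %||% list()))
}

# Cache a certain result. Dependency propagation: a proof depends on every
# molecule inside the proof subtree (re-entered when the strategy is
# replayed); a disproof depends on the path molecules its repetition
# arguments used, minus the node itself (which rejoins the path whenever
# the node is queried). Proofs additionally inherit residual forced-key
# constraints: a forced disproof of a reaction inside the proof subtree
# invalidates the proof on any path completing the key, and the part of the
# key that lies inside the subtree is stripped off molecule by molecule on
# the way up.
settle_node <- function(g, st, v, agg, ghi_safe, forced = FALSE) {
  role <- node_role(g, v)
  if (agg$pn == 0) {
    if (role == "molecule") {
      i <- which(agg$certain & agg$status == "proved")[1]
      dep <- c(v, agg$deps[[i]])
      res <- lapply(agg$res[[i]], function(R) setdiff(R, v))
    } else {
      dep <- unique(unlist(agg$deps))
      res <- c(do.call(c, agg$res) %||% list(), forced_keys(st, v))
    }
    if (!ghi_safe) dep <- character(0)
    ghi_store(st, v, "proved", unique(dep %||% character(0)), res = res)
    set_rec(st, v, modifyList(get_rec(st, v), list(pn = 0, dn = Inf)))
  } else {
    dep <- if (role == "molecule") {
      setdiff(unique(unlist(agg$deps)), v)
    } else {
      i <- which(agg$certain & agg$status == "disproved")[1]
      agg$deps[[i]]
    }
    if (!ghi_safe) dep <- character(0)
    ghi_store(st, v, "disproved", unique(dep %||% character(0)),
              forced = forced)
    set_rec(st, v, modifyList(get_rec(st, v), list(pn = Inf, dn = 0)))
  }
  invisible(st)
}

new_game_outcome <- function(status, strategy = NULL, expansions_used = 0,
                             records = NULL) {
  out <- list(status = status, strategy = strategy,
              expansions_used = expansions_used, records = records)
  class(out) <- "game_outcome"
  out
}

#' Depth-first proof-number search
#'
#' DFPN explores the AND/OR game graph depth-first, carrying proof- and
#' disproof-number thresholds that delimit how long a branch may be pursued
#' before the search would be better spent elsewhere; it continues below a
#' node while `pn < th_pn` and `dn < th_dn` and backtracks otherwise. Plain
#' DFPN is incomplete on cyclic graphs: stale stored values can trap it in
#' an infinite loop. Two optional reinforcements address this:
#' `use_tca` enables the threshold controlling algorithm (see
#' [tca_adjust()]), which raises thresholds at nodes with *old* children so
#' the loop is eventually broken, and `ghi_safe` enables path-keyed
#' (dis)proof caching (see [ghi_store()]) with repetition treated as a
#' context-dependent disproof. With both enabled the search is empirically
#' complete on cyclic graphs; with neither it reproduces the classic
#' incomplete behaviour.
#'
#' @param g an [and_or_graph()].
#' @param max_expansions budget on search steps (node visits). The search
#'   returns an `"unproved"` outcome when the budget is exhausted.
#' @param use_tca enable the threshold controlling algorithm.
#' @param ghi_safe enable path-keyed proof caching; defaults to `use_tca`
#'   so that the plain and reinforced configurations are each coherent.
#' @param records optionally a pre-populated [new_search_records()] store
#'   (used by the multi-solution driver to carry state across restarts).
#' @param edge_costs apply [edge_cost()] values to molecule-to-reaction
#'   edges in the pn aggregation and thresholds (the DFPN-E heuristic).
#' @param trace print a line per search event (node, pn, dn, thresholds,
#'   md) for debugging.
#' @return A `game_outcome`: `status` (`"proved"`, `"disproved"`,
#'   `"unproved"`), `strategy` (a [synthesis_route()] iff proved),
#'   `expansions_used`, and the `records` store.
#' @export
dfpn <- function(g, max_expansions = 10000, use_tca = FALSE,
                 ghi_safe = use_tca, records = NULL, edge_costs = FALSE,
                 trace = FALSE) {
  root <- g$root
  ts <- terminal_status(g, root, character(0))
  if (ts == "proved") {
    return(new_game_outcome("proved", synthesis_route(root), 0,
                            records %||% new_search_records()))
  }
  if (ts == "disproved") {
    return(new_game_outcome("disproved", NULL, 0,
                            records %||% new_search_records()))
  }
  st <- records %||% new_search_records()
  sst <- new.env(parent = emptyenv())
  sst$visits <- 0L
  sst$exhausted <- FALSE

  mid <- function(v, thp, thd, path, depth) {
    if (sst$visits >= max_expansions) { sst$exhausted <- TRUE; return() }
    sst$visits <- sst$visits + 1L
    rec <- get_rec(st, v)
    rec$md <- min(rec$md, depth)
    rec$expanded <- TRUE
    set_rec(st, v, rec)
    role <- node_role(g, v)
    newpath <- if (role == "molecule") c(path, v) else path
    repeat {
      agg <- aggregate_node(g, st, v, newpath, ghi_safe, edge_costs)
      set_rec(st, v, modifyList(get_rec(st, v),
                                list(pn = agg$pn, dn = agg$dn)))
      if (trace) {
        cat(sprintf("visit %s pn=%s dn=%s th=(%s,%s) md=%s\n", v,
                    agg$pn, agg$dn, thp, thd, get_rec(st, v)$md))
      }
      if (agg$pn == 0 || agg$dn == 0) {
        settle_node(g, st, v, agg, ghi_safe)
        return()
      }
      sel <- which(agg$status == "unknown")
      if (agg$pn >= thp || agg$dn >= thd) {
        raised <- FALSE
        if (use_tca && length(sel) > 0 &&
            has_old_unproved_child(st, v, agg)) {
          thp <- sat_add(agg$pn, 1)
          thd <- sat_add(agg$dn, 1)
          raised <- TRUE
          if (trace) cat(sprintf("  tca raise at %s -> (%s,%s)\n",
                                 v, thp, thd))
        }
        if (!raised) return()
      }
      if (length(sel) == 0) return()
      if (role == "molecule") {
        ci <- sel[which.min(agg$eff[sel])]
      } else {
        ci <- sel[which.min(agg$dns[sel])]
      }
      others <- seq_along(agg$ids)[-ci]
      second <- if (length(others) == 0) c(Inf, Inf) else {
        c(min(agg$eff[others]), min(agg$dns[others]))
      }
      chosen <- c(agg$eff[ci], agg$dns[ci])
      single <- length(agg$ids) == 1
      # v's penalty enters pn(v); the molecule min-rule compares on the
      # child scale, so the pn threshold is lowered by the penalty there.
      # The reaction surplus rule already cancels it through pn(v).
      thp_eff <- if (role == "molecule") sat_sub(thp, get_pen(st, v)) else thp
      th_c <- child_thresholds(role, thp_eff, thd,
                               agg$pn, agg$dn, chosen, second, single)
      if (role == "molecule" && edge_costs && !single) {
        cost_c <- edge_cost(g, v, agg$ids[ci])
        th_c[1] <- if (is.infinite(th_c[1])) Inf else
          max(th_c[1] - cost_c, 0)
      }
      if (sst$visits >= max_expansions) { sst$exhausted <- TRUE; return() }
      mid(agg$ids[ci], th_c[1], th_c[2], newpath, depth + 1)
      if (sst$exhausted) return()
    }
  }

  repeat {
    e <- ghi_lookup_dep(st, root, character(0))
    if (!is.null(e)) break
    if (sst$visits >= max_expansions) break
    mid(root, Inf, Inf, character(0), 0)
  }
  e <- ghi_lookup_dep(st, root, character(0))
  if (is.null(e)) {
    return(new_game_outcome("unproved", NULL, sst$visits, st))
  }
  if (e$status == "proved") {
    new_game_outcome("proved", extract_strategy(g, st, root), sst$visits, st)
  } else {
    new_game_outcome("disproved", NULL, sst$visits, st)
  }
}

sat_sub <- function(a, b) if (is.infinite(a)) Inf else max(a - b, 0)

#' Proof-number search (best-first)
#'
#' The best-first ancestor of DFPN: repeatedly descends from the root --
#' picking the minimum-pn child at molecule nodes and the minimum-dn child
#' at reaction nodes -- to a most promising unexpanded node, expands it, and
#' propagates updated proof/disproof numbers back along the descent path.
#' Uses the same path-aware repetition handling and proof cache as the
#' GHI-safe DFPN.
#'
#' @inheritParams dfpn
#' @param max_expansions budget on node expansions.
#' @return A `game_outcome` (see [dfpn()]); `expansions_used` counts
#'   first-time node expansions.
#' @export
pns <- function(g, max_expansions = 10000, records = NULL) {
  root <- g$root
  ts <- terminal_status(g, root, character(0))
  if (ts == "proved") {
    return(new_game_outcome("proved", synthesis_route(root), 0,
                            records %||% new_search_records()))
  }
  if (ts == "disproved") {
    return(new_game_outcome("disproved", NULL, 0,
                            records %||% new_search_records()))
  }
  st <- records %||% new_search_records()
  expansions <- 0L
  n_nodes <- length(node_ids(g))

  repeat {
    if (!is.null(ghi_lookup_dep(st, root, character(0)))) break
    if (expansions >= max_expansions) break
    progress <- FALSE
    v <- root
    path <- character(0)
    stack <- list()
    depth <- 0
    for (step in seq_len(2 * n_nodes + 4)) {
      role <- node_role(g, v)
      newpath <- if (role == "molecule") c(path, v) else path
      rec <- get_rec(st, v)
      rec$md <- min(rec$md, depth)
      stack[[length(stack) + 1]] <- list(v = v, ctx = newpath)
      if (!rec$expanded) {
        rec$expanded <- TRUE
        set_rec(st, v, rec)
        expansions <- expansions + 1L
        progress <- TRUE
        break
      }
      set_rec(st, v, rec)
      agg <- aggregate_node(g, st, v, newpath, ghi_safe = TRUE,
                            edge_costs = FALSE)
      if (agg$pn == 0 || agg$dn == 0) {
        settle_node(g, st, v, agg, ghi_safe = TRUE)
        progress <- TRUE
        break
      }
      sel <- which(agg$status == "unknown")
      if (length(sel) == 0) break
      ci <- if (role == "molecule") sel[which.min(agg$eff[sel])] else
        sel[which.min(agg$dns[sel])]
      v <- agg$ids[ci]
      path <- newpath
      depth <- depth + 1
    }
    # back up pn/dn (and settles) along the descent path
    for (i in rev(seq_along(stack))) {
      fr <- stack[[i]]
      if (length(node_children(g, fr$v)) == 0) next
      agg <- aggregate_node(g, st, fr$v, fr$ctx, ghi_safe = TRUE,
                            edge_costs = FALSE)
      set_rec(st, fr$v, modifyList(get_rec(st, fr$v),
                                   list(pn = agg$pn, dn = agg$dn)))
      if ((agg$pn == 0 || agg$dn == 0) &&
          is.null(ghi_lookup_dep(st, fr$v, fr$ctx))) {
        settle_node(g, st, fr$v, agg, ghi_safe = TRUE)
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  e <- ghi_lookup_dep(st, root, character(0))
  if (is.null(e)) return(new_game_outcome("unproved", NULL, expansions, st))
  if (e$status == "proved") {
    new_game_outcome("proved", extract_strategy(g, st, root), expansions, st)
  } else {
    new_game_outcome("disproved", NULL, expansions, st)
  }
}

#' Read off the winning strategy after a proof
#'
#' Walks the explored graph from a proved molecule node, at each molecule
#' picking the first child (in the graph's stored order) whose cached proof
#' is valid under the current path, and taking all reactants at reaction
#' nodes. Bond labels and reaction scores stored on the graph are copied
#' onto the route.
#'
#' @param g an [and_or_graph()].
#' @param records a [new_search_records()] store holding the proof.
#' @param root molecule node to extract from.
#' @return A [synthesis_route()].
#' @export
extract_strategy <- function(g, records, root = g$root) {
  build <- function(m, ctx) {
    if (is_building_block(g, m)) return(synthesis_route(m))
    ctx2 <- c(ctx, m)
    for (rx in node_children(g, m)) {
      ok <- child_status(g, records, rx, ctx2, ghi_safe = TRUE)
      if (ok$status != "proved") next
      subs <- lapply(node_children(g, rx), build, ctx = ctx2)
      return(synthesis_route(m, rxn = rx, reactants = subs,
                             bonds = g$bonds[[rx]] %||% character(0),
                             score = edge_score(g, m, rx)))
    }
    stop(sprintf("no proved reaction for molecule '%s': %s", m,
                 "extract_strategy requires a proved root"))
  }
  st0 <- child_status(g, records, root, character(0), ghi_safe = TRUE)
  if (st0$status != "proved") {
    stop("extract_strategy called on an unproved root")
  }
  build(root, character(0))
}
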