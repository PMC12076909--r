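#' Exhaustive game solver (test oracle)
#'
#' Solves the retrosynthesis game exactly by full minimax with the path-set
#' repetition rule: molecule nodes are OR positions, reaction nodes AND
#' positions, a repeated molecule on the play path loses for the molecule
#' player. Exponential in the worst case; intended as ground truth on small
#' graphs (tens of nodes), not as a search algorithm.
#'
#' @param g an [and_or_graph()].
#' @param v node to solve (default the root; must be a molecule node).
#' @param ctx molecule ids already on the path above `v`.
#' @param depth_cap maximum number of plies to explore. Because the
#'   repetition rule bounds simple paths, the default (two plies per node
#'   plus slack) can never truncate a sound result.
#' @return A `game_outcome`: list with `status` (`"proved"`, `"disproved"`
#'   or `"unproved"`), `strategy` (a [synthesis_route()] when proved),
#'   `expansions_used` (number of positions evaluated) and `capped`
#'   (`TRUE` when the depth cap truncated the search).
#' @export
solve_brute_force <- function(g, v = g$root, ctx = character(0),
                              depth_cap = 2 * length(node_ids(g)) + 2) {
  n_eval <- 0L
  capped <- FALSE

  solve_mol <- function(m, path, depth) {
    n_eval <<- n_eval + 1L
    ts <- terminal_status(g, m, path)
    if (ts == "proved") return(list(status = "proved",
                                    route = synthesis_route(m)))
    if (ts == "disproved") return(list(status = "disproved"))
    if (depth <= 0) { capped <<- TRUE; return(list(status = "unproved")) }
    any_open <- FALSE
    for (rx in node_children(g, m)) {
      res <- solve_rxn(rx, c(path, m), depth - 1)
      if (res$status == "proved") {
        sc <- edge_score(g, m, rx)
        return(list(status = "proved", route = synthesis_route(
          m, rxn = rx, reactants = res$routes,
          bonds = g$bonds[[rx]] %||% character(0), score = sc)))
      }
      if (res$status == "unproved") any_open <- TRUE
    }
    list(status = if (any_open) "unproved" else "disproved")
  }

  solve_rxn <- function(rx, path, depth) {
    n_eval <<- n_eval + 1L
    kids <- node_children(g, rx)
    if (length(kids) == 0) return(list(status = "proved", routes = list()))
    if (depth <= 0) { capped <<- TRUE; return(list(status = "unproved")) }
    routes <- vector("list", length(kids))
    any_open <- FALSE
    for (i in seq_along(kids)) {
      res <- solve_mol(kids[i], path, depth - 1)
      if (res$status == "disproved") return(list(status = "disproved"))
      if (res$status == "unproved") { any_open <- TRUE; next }
      routes[[i]] <- res$route
    }
    if (any_open) return(list(status = "unproved"))
    list(status = "proved", routes = routes)
  }

  if (!has_node(g, v)) stop(sprintf("unknown node id '%s'", v))
  if (node_role(g, v) != "molecule") stop("oracle solves molecule nodes")
  res <- solve_mol(v, ctx, depth_cap)
  out <- list(status = res$status, strategy = res$route,
              expansions_used = n_eval, capped = capped)
  class(out) <- "game_outcome"
  out
}

#' @export
print.game_outcome <- function(x, ...) {
  cat(sprintf("<game_outcome> %s (%d search steps)\n", x$status,
              x$expansions_used))
  invisible(x)
}

#' Enumerate all synthesis routes of a graph
#'
#' Depth-first enumeration of every distinct winning strategy (as unordered
#' trees), in deterministic child order; truncates at `max_routes`. Used as
#' the counting oracle for the multi-solution search and as a fixture
#' generator for diversity scoring.
#'
#' @param g an [and_or_graph()].
#' @param max_routes maximum number of routes to return.
#' @param max_depth maximum molecule depth per branch.
#' @return List of [synthesis_route()] objects (possibly empty).
#' @export
enumerate_routes <- function(g, max_routes = 100,
                             max_depth = length(node_ids(g)) + 1) {

  enum_mol <- function(m, path, depth, limit) {
    if (limit <= 0) return(list())
    ts <- terminal_status(g, m, path)
    if (ts == "proved") return(list(synthesis_route(m)))
    if (ts == "disproved" || depth <= 0) return(list())
    out <- list()
    for (rx in node_children(g, m)) {
      if (length(out) >= limit) break
      combos <- enum_rxn(rx, c(path, m), depth - 1, limit - length(out))
      sc <- edge_score(g, m, rx)
      for (cb in combos) {
        out[[length(out) + 1]] <- synthesis_route(
          m, rxn = rx, reactants = cb,
          bonds = g$bonds[[rx]] %||% character(0), score = sc)
      }
    }
    out
  }

  # Cartesian product of per-reactant route lists, capped at `limit`.
  enum_rxn <- function(rx, path, depth, limit) {
    kids <- node_children(g, rx)
    combos <- list(list())
    for (m in kids) {
      subs <- enum_mol(m, path, depth, limit)
      if (length(subs) == 0) return(list())
      nxt <- list()
      for (cb in combos) {
        for (s in subs) {
          if (length(nxt) >= limit) break
          nxt[[length(nxt) + 1]] <- c(cb, list(s))
        }
        if (length(nxt) >= limit) break
      }
      combos <- nxt
    }
    combos
  }

  routes <- enum_mol(g$root, character(0), max_depth, max_routes)
  keys <- vapply(routes, route_key, character(1))
  routes[!duplicated(keys)]
}
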