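#' Construct an AND/OR reaction network
#'
#' An AND/OR graph is the standard game encoding of retrosynthesis: molecule
#' nodes (OR) are positions of the molecule player, who picks one reaction
#' producing the molecule; reaction nodes (AND) are positions of the reaction
#' player, who may demand any reactant. A molecule is a `building_block`
#' terminal (win for the molecule player) or a `dead_end` (childless,
#' unbuyable; win for the reaction player). Revisiting a molecule on the
#' current play path is also a win for the reaction player, which makes the
#' game well-defined on cyclic networks.
#'
#' @param nodes named character vector or data.frame with columns `id`,
#'   `role` (`"molecule"` or `"reaction"`) and optional `terminal`
#'   (`"building_block"`, `"dead_end"` or `"none"`). A named character
#'   vector is interpreted as `id = role`.
#' @param edges data.frame with columns `from`, `to` and optional `cost`
#'   (non-negative number) and `score` (reaction viability in `[0, 1]`).
#'   Child order within a parent is the row order and is the tie-breaking
#'   order used by every search routine.
#' @param root id of the target molecule.
#' @param terminal optional named character vector `id = terminal` used when
#'   `nodes` is a character vector.
#' @param bonds optional named list: reaction id -> character vector of
#'   canonical bond keys (see [canonical_bond()]) formed by that reaction in
#'   the target's atom frame. Carried onto routes extracted from the graph.
#' @return An object of class `and_or_graph`.
#' @seealso [validate_graph()], [read_graph()], [generate_network()]
#' @export
and_or_graph <- function(nodes, edges = NULL, root, terminal = NULL,
                         bonds = NULL) {
  if (is.data.frame(nodes)) {
    ids <- as.character(nodes$id)
    role <- stats::setNames(as.character(nodes$role), ids)
    term <- if ("terminal" %in% names(nodes)) {
      stats::setNames(as.character(nodes$terminal), ids)
    } else {
      stats::setNames(rep("none", length(ids)), ids)
    }
  } else {
    ids <- names(nodes)
    role <- stats::setNames(as.character(nodes), ids)
    term <- stats::setNames(rep("none", length(ids)), ids)
    if (!is.null(terminal)) term[names(terminal)] <- terminal
  }
  term[is.na(term)] <- "none"

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) children[[i]] <- character(0)
  edge_cost <- list()
  edge_score <- list()
  if (!is.null(edges) && nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      fr <- as.character(edges$from[i]); to <- as.character(edges$to[i])
      children[[fr]] <- c(children[[fr]], to)
      key <- paste0(fr, " -> ", to)
      if ("cost" %in% names(edges) && !is.na(edges$cost[i])) {
        edge_cost[[key]] <- as.numeric(edges$cost[i])
      }
      if ("score" %in% names(edges) && !is.na(edges$score[i])) {
        edge_score[[key]] <- as.numeric(edges$score[i])
      }
    }
  }
  g <- list(
    role = role, terminal = term, children = children,
    edge_cost = edge_cost, edge_score = edge_score,
    bonds = bonds %||% list(), root = as.character(root)
  )
  class(g) <- "and_or_graph"
  g
}

#' @export
print.and_or_graph <- function(x, ...) {
  n_mol <- sum(x$role == "molecule")
  n_rxn <- sum(x$role == "reaction")
  cat(sprintf(
    "<and_or_graph> %d molecule + %d reaction nodes, %d edges, root '%s'\n",
    n_mol, n_rxn, sum(lengths(x$children)), x$root))
  cat(sprintf("  building blocks: %d, dead ends: %d\n",
              sum(x$terminal == "building_block"),
              sum(x$terminal == "dead_end")))
  invisible(x)
}

node_ids <- function(g) names(g$role)

node_role <- function(g, v) unname(g$role[[v]])

node_children <- function(g, v) g$children[[v]]

has_node <- function(g, v) v %in% names(g$role)

is_building_block <- function(g, v) {
  identical(unname(g$terminal[[v]]), "building_block")
}

is_dead_end <- function(g, v) {
  node_role(g, v) == "molecule" && !is_building_block(g, v) &&
    length(node_children(g, v)) == 0
}

#' Check the structural invariants of an AND/OR graph
#'
#' Reports violations instead of throwing, so that malformed inputs read
#' from files can be diagnosed in one pass.
#'
#' @param g an [and_or_graph()].
#' @return Character vector of human-readable violation descriptions;
#'   empty when the graph is valid.
#' @export
validate_graph <- function(g) {
  bad <- character(0)
  ids <- node_ids(g)
  if (!g$root %in% ids) {
    bad <- c(bad, sprintf("root '%s' is not a node", g$root))
  } else if (node_role(g, g$root) != "molecule") {
    bad <- c(bad, sprintf("root '%s' is not a molecule node", g$root))
  }
  for (v in ids) {
    rv <- node_role(g, v)
    if (!rv %in% c("molecule", "reaction")) {
      bad <- c(bad, sprintf("node '%s' has unknown role '%s'", v, rv))
      next
    }
    tv <- unname(g$terminal[[v]])
    if (!tv %in% c("building_block", "dead_end", "none")) {
      bad <- c(bad, sprintf("node '%s' has unknown terminal tag '%s'", v, tv))
    }
    if (tv == "building_block" && rv != "molecule") {
      bad <- c(bad, sprintf("reaction node '%s' marked building_block", v))
    }
    if (tv == "building_block" && length(node_children(g, v)) > 0) {
      bad <- c(bad, sprintf("building block '%s' has outgoing edges", v))
    }
    if (tv == "dead_end" &&
        (rv != "molecule" || length(node_children(g, v)) > 0)) {
      bad <- c(bad, sprintf(
        "dead_end tag on '%s' requires a childless molecule node", v))
    }
    for (w in node_children(g, v)) {
      if (!w %in% ids) {
        bad <- c(bad, sprintf("edge %s -> %s points outside the graph", v, w))
      } else if (node_role(g, w) == rv) {
        bad <- c(bad, sprintf(
          "edge %s -> %s violates bipartiteness (both are %s nodes)",
          v, w, rv))
      }
    }
  }
  for (key in names(g$edge_cost)) {
    if (g$edge_cost[[key]] < 0) {
      bad <- c(bad, sprintf("edge %s has negative cost", key))
    }
  }
  for (key in names(g$edge_score)) {
    s <- g$edge_score[[key]]
    if (s < 0 || s > 1) {
      bad <- c(bad, sprintf("edge %s has score outside [0, 1]", key))
    }
  }
  bad
}

#' Terminal status of a node under a path context
#'
#' Encodes the win/lose rules of the retrosynthesis game: a building block is
#' a win for the molecule player (`"proved"`); a dead end, or a molecule
#' already visited on the current root-to-node path, is a win for the
#' reaction player (`"disproved"`); anything else is `"open"`. A reaction
#' node with no reactants is vacuously `"proved"` (empty-product convention).
#'
#' @param g an [and_or_graph()].
#' @param v node id.
#' @param ctx character vector of molecule ids on the root-to-`v` path
#'   (exclusive of `v`; a repeat is detected when `v` itself appears).
#' @return `"proved"`, `"disproved"` or `"open"`.
#' @export
terminal_status <- function(g, v, ctx = character(0)) {
  if (!has_node(g, v)) stop(sprintf("unknown node id '%s'", v))
  if (node_role(g, v) == "molecule") {
    if (is_building_block(g, v)) return("proved")
    if (v %in% ctx) return("disproved")
    if (length(node_children(g, v)) == 0) return("disproved")
  } else {
    if (length(node_children(g, v)) == 0) return("proved")
  }
  "open"
}

#' Look up the cost of a molecule -> reaction edge
#'
#' Edge costs drive the DFPN-E variant: the proof number of a molecule node
#' becomes the minimum over children of `pn(child) + cost(edge)`. When the
#' graph stores no explicit cost but the edge carries a reaction score
#' `s` in `(0, 1]`, the cost defaults to `round(-log(s))` capped at
#' `max_cost`; with neither, the cost is 0 (plain DFPN).
#'
#' @param g an [and_or_graph()].
#' @param parent molecule node id.
#' @param child reaction node id (a child of `parent`).
#' @param max_cost cap applied to score-derived costs.
#' @return Non-negative number.
#' @export
edge_cost <- function(g, parent, child, max_cost = 10) {
  if (!child %in% node_children(g, parent)) {
    stop(sprintf("no edge %s -> %s in graph", parent, child))
  }
  key <- paste0(parent, " -> ", child)
  if (!is.null(g$edge_cost[[key]])) return(g$edge_cost[[key]])
  s <- g$edge_score[[key]]
  if (!is.null(s) && s > 0) return(min(round(-log(s)), max_cost))
  0
}

edge_score <- function(g, parent, child) {
  g$edge_score[[paste0(parent, " -> ", child)]]
}
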