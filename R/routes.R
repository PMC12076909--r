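#' Construct a synthesis route
#'
#' A route is a rooted alternating tree from the target molecule down to
#' building-block leaves: each non-leaf molecule is made by exactly one
#' reaction, and each reaction lists all of its reactants. Reactions may
#' carry the set of bonds they form (canonical keys in the target's atom
#' frame, see [canonical_bond()]) and a viability score in `[0, 1]`.
#'
#' @param mol molecule id at this position of the tree.
#' @param rxn reaction id making `mol`, or `NULL` for a leaf
#'   (building block) or for a target that is itself purchasable.
#' @param reactants list of `synthesis_route` subtrees, one per reactant.
#' @param bonds character vector of canonical bond keys formed by `rxn`.
#' @param score viability score of `rxn` in `[0, 1]`, or `NULL`.
#' @return An object of class `synthesis_route`.
#' @export
synthesis_route <- function(mol, rxn = NULL, reactants = list(),
                            bonds = character(0), score = NULL) {
  r <- list(mol = as.character(mol))
  if (!is.null(rxn)) {
    r$via <- list(rxn = as.character(rxn), bonds = as.character(bonds),
                  score = score, reactants = reactants)
  }
  class(r) <- "synthesis_route"
  r
}

is_route_leaf <- function(r) is.null(r$via)

#' @export
print.synthesis_route <- function(x, ...) {
  cat(sprintf("<synthesis_route> target '%s', %d reactions, %d leaves\n",
              x$mol, length(route_reactions(x)), length(route_leaves(x))))
  show_route <- function(r, indent) {
    cat(strrep("  ", indent), r$mol, if (is_route_leaf(r)) "  [leaf]" else "",
        "\n", sep = "")
    if (!is_route_leaf(r)) {
      sc <- if (is.null(r$via$score)) "" else sprintf(" (score %.3g)",
                                                      r$via$score)
      cat(strrep("  ", indent + 1), "via ", r$via$rxn, sc, "\n", sep = "")
      for (sub in r$via$reactants) show_route(sub, indent + 1)
    }
  }
  show_route(x, 0)
  invisible(x)
}

# Depth-first walk collecting f(subroute, depth) over all positions.
route_walk <- function(r, f, depth = 0) {
  out <- list(f(r, depth))
  if (!is_route_leaf(r)) {
    for (sub in r$via$reactants) {
      out <- c(out, route_walk(sub, f, depth + 1))
    }
  }
  out
}

#' Reaction ids used by a route (traversal order)
#' @param r a [synthesis_route()].
#' @return Character vector of reaction ids, root-first depth-first order.
#' @export
route_reactions <- function(r) {
  unlist(route_walk(r, function(s, d) if (is_route_leaf(s)) NULL else
    s$via$rxn))
}

#' Leaf (building-block) molecule ids of a route
#' @param r a [synthesis_route()].
#' @return Character vector of leaf molecule ids.
#' @export
route_leaves <- function(r) {
  unlist(route_walk(r, function(s, d) if (is_route_leaf(s)) s$mol))
}

# Molecule ids appearing at non-root, non-leaf positions.
route_intermediates <- function(r) {
  ids <- unlist(route_walk(r, function(s, d) {
    if (d > 0 && !is_route_leaf(s)) s$mol
  }))
  unique(ids %||% character(0))
}

#' Validate a route against an AND/OR graph
#'
#' A route is valid when every molecule -> reaction and reaction -> reactant
#' edge it uses exists in the graph, every leaf is a building block, and
#' every reaction carries all of its reactant children from the graph.
#'
#' @param g an [and_or_graph()].
#' @param r a [synthesis_route()].
#' @return `TRUE` or `FALSE`.
#' @export
route_is_valid <- function(g, r) {
  check <- function(s) {
    if (!has_node(g, s$mol) || node_role(g, s$mol) != "molecule") return(FALSE)
    if (is_route_leaf(s)) return(is_building_block(g, s$mol))
    rxn <- s$via$rxn
    if (!rxn %in% node_children(g, s$mol)) return(FALSE)
    need <- node_children(g, rxn)
    got <- vapply(s$via$reactants, function(x) x$mol, character(1))
    if (!identical(sort(need), sort(got))) return(FALSE)
    all(vapply(s$via$reactants, check, logical(1)))
  }
  isTRUE(check(r))
}

# Canonical string key for tree-distinctness: child subtrees are sorted,
# so two routes are equal iff they are equal as unordered trees.
route_key <- function(r) {
  if (is_route_leaf(r)) return(paste0("(", r$mol, ")"))
  subs <- sort(vapply(r$via$reactants, route_key, character(1)))
  paste0("(", r$mol, ":", r$via$rxn, "[", paste(subs, collapse = ","), "])")
}

#' Deepest reaction of a route
#'
#' Returns a reaction at maximal depth, i.e. one reached through a longest
#' molecule/reaction path from the target; ties are broken by depth-first
#' traversal order. This is the node the multi-solution search disproves to
#' force the next route to differ (disproving a deep reaction invalidates
#' the route while destroying as few other routes as possible).
#'
#' @param r a [synthesis_route()].
#' @return List with `rxn` (reaction id), `depth` (number of reactions on
#'   the branch) and `path_molecules` (molecule ids from the target down to
#'   the reaction's product, inclusive).
#' @export
deepest_reaction <- function(r) {
  if (is_route_leaf(r)) {
    stop("route has no reactions (target is a building block)")
  }
  best <- NULL
  walk <- function(s, depth, mols) {
    if (is_route_leaf(s)) return(invisible())
    mols <- c(mols, s$mol)
    if (is.null(best) || depth > best$depth) {
      best <<- list(rxn = s$via$rxn, depth = depth, path_molecules = mols)
    }
    for (sub in s$via$reactants) walk(sub, depth + 1, mols)
  }
  walk(r, 1, character(0))
  best
}

#' Multiplicative route viability
#'
#' The viability of a route is the product of the per-reaction viability
#' scores, interpretable as the probability that the whole route works in
#' the lab when reactions fail independently. The empty route (a target
#' that is itself a building block) has viability 1.
#'
#' @param r a [synthesis_route()].
#' @return Number in `[0, 1]`.
#' @export
route_viability <- function(r) {
  scores <- route_walk(r, function(s, d) {
    if (is_route_leaf(s)) return(NULL)
    if (is.null(s$via$score)) {
      stop(sprintf("reaction '%s' carries no viability score", s$via$rxn))
    }
    s$via$score
  })
  prod(unlist(scores) %||% numeric(0))
}
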