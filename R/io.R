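FORMAT_VERSION <- "1"

#' Write / read an AND/OR graph as JSON
#'
#' The dialect is
#' `{"format_version", "nodes":[{"id","role","terminal","bonds"}],`
#' `"edges":[{"from","to","cost","score"}], "root"}`; `terminal`, `cost`,
#' `score` and `bonds` are optional. `bonds` on a reaction node lists the
#' bond keys the reaction forms, each as a pair of atom labels.
#' Writing then reading is the identity on valid graphs.
#'
#' @param g an [and_or_graph()].
#' @param path file path.
#' @return `read_graph` returns an [and_or_graph()]; `write_graph` returns
#'   `path` invisibly.
#' @export
write_graph <- function(g, path) {
  nodes <- lapply(node_ids(g), function(v) {
    nd <- list(id = v, role = node_role(g, v))
    tv <- unname(g$terminal[[v]])
    if (tv != "none") nd$terminal <- tv
    if (!is.null(g$bonds[[v]])) {
      nd$bonds <- lapply(g$bonds[[v]], bond_key_atoms)
    }
    nd
  })
  edges <- list()
  for (v in node_ids(g)) {
    for (w in node_children(g, v)) {
      e <- list(from = v, to = w)
      key <- paste0(v, " -> ", w)
      if (!is.null(g$edge_cost[[key]])) e$cost <- g$edge_cost[[key]]
      if (!is.null(g$edge_score[[key]])) e$score <- g$edge_score[[key]]
      edges[[length(edges) + 1]] <- e
    }
  }
  obj <- list(format_version = FORMAT_VERSION, nodes = nodes, edges = edges,
              root = g$root)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$nodes) || is.null(obj$root)) {
    stop("graph JSON must have 'nodes' and 'root' fields")
  }
  ids <- vapply(obj$nodes, function(n) as.character(n$id), character(1))
  role <- vapply(obj$nodes, function(n) as.character(n$role), character(1))
  bad_role <- !role %in% c("molecule", "reaction")
  if (any(bad_role)) {
    stop(sprintf("node '%s': unknown role '%s'", ids[bad_role][1],
                 role[bad_role][1]))
  }
  term <- vapply(obj$nodes, function(n) {
    tv <- n$terminal %||% "none"
    as.character(tv)
  }, character(1))
  bad_term <- !term %in% c("building_block", "dead_end", "none")
  if (any(bad_term)) {
    stop(sprintf("node '%s': unknown terminal '%s'", ids[bad_term][1],
                 term[bad_term][1]))
  }
  bonds <- list()
  for (n in obj$nodes) {
    if (!is.null(n$bonds)) {
      bonds[[as.character(n$id)]] <- vapply(n$bonds, function(b) {
        canonical_bond(b[[1]], b[[2]])
      }, character(1))
    }
  }
  edges <- NULL
  if (length(obj$edges %||% list()) > 0) {
    edges <- data.frame(
      from = vapply(obj$edges, function(e) as.character(e$from), character(1)),
      to = vapply(obj$edges, function(e) as.character(e$to), character(1)),
      cost = vapply(obj$edges, function(e) as.numeric(e$cost %||% NA_real_),
                    numeric(1)),
      score = vapply(obj$edges, function(e) as.numeric(e$score %||% NA_real_),
                     numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  and_or_graph(stats::setNames(role, ids), edges, root = obj$root,
               terminal = stats::setNames(term, ids), bonds = bonds)
}

route_to_json_obj <- function(r) {
  obj <- list(mol = r$mol)
  if (!is_route_leaf(r)) {
    obj$via <- list(
      rxn = r$via$rxn,
      bonds = lapply(r$via$bonds, bond_key_atoms),
      reactants = lapply(r$via$reactants, route_to_json_obj)
    )
    if (!is.null(r$via$score)) obj$via$score <- r$via$score
  }
  obj
}

route_from_json_obj <- function(obj) {
  if (is.null(obj$mol)) stop("route JSON entry lacks 'mol' field")
  if (is.null(obj$via)) return(synthesis_route(obj$mol))
  bonds <- vapply(obj$via$bonds %||% list(), function(b) {
    canonical_bond(b[[1]], b[[2]])
  }, character(1))
  synthesis_route(
    obj$mol, rxn = obj$via$rxn,
    reactants = lapply(obj$via$reactants %||% list(), route_from_json_obj),
    bonds = bonds, score = obj$via$score
  )
}

#' Write / read synthesis routes as JSON
#'
#' Routes are stored as nested
#' `{"mol", "via": {"rxn", "bonds": [["a3","a7"], ...], "score",`
#' `"reactants": [...]}}` trees under a top-level `routes` array; bond keys
#' round-trip exactly.
#'
#' @param routes list of [synthesis_route()] objects.
#' @param path file path.
#' @return `read_routes` returns a list of routes; `write_routes` returns
#'   `path` invisibly.
#' @export
write_routes <- function(routes, path) {
  obj <- list(format_version = FORMAT_VERSION,
              routes = lapply(routes, route_to_json_obj))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_routes
#' @export
read_routes <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$routes)) stop("route JSON must have a 'routes' field")
  lapply(obj$routes, route_from_json_obj)
}
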