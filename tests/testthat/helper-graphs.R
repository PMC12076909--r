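# Shared fixtures and an independent evaluator used as a second oracle.

# Linear chain: target -> r -> intermediate -> r2 -> building block.
chain_graph <- function() {
  and_or_graph(
    c(A = "molecule", R1 = "reaction", B = "molecule", R2 = "reaction",
      C = "molecule"),
    data.frame(from = c("A", "R1", "B", "R2"), to = c("R1", "B", "R2", "C")),
    root = "A", terminal = c(C = "building_block"))
}

# Chain ending in a dead end: unsolvable.
dead_chain_graph <- function() {
  and_or_graph(
    c(A = "molecule", R1 = "reaction", B = "molecule"),
    data.frame(from = c("A", "R1"), to = c("R1", "B")),
    root = "A")
}

# Two independent one-step reactions for the root.
two_route_graph <- function() {
  and_or_graph(
    c(A = "molecule", R1 = "reaction", R2 = "reaction", B = "molecule",
      C = "molecule"),
    data.frame(from = c("A", "A", "R1", "R2"), to = c("R1", "R2", "B", "C")),
    root = "A",
    terminal = c(B = "building_block", C = "building_block"))
}

# Diamond: the final reaction R5 is reachable through two different paths.
diamond_graph <- function() {
  and_or_graph(
    c(A = "molecule", R1 = "reaction", R2 = "reaction", B = "molecule",
      C = "molecule", R3 = "reaction", R4 = "reaction", D = "molecule",
      R5 = "reaction", E = "molecule"),
    data.frame(from = c("A", "A", "R1", "R2", "B", "C", "R3", "R4", "D",
                        "R5"),
               to = c("R1", "R2", "B", "C", "R3", "R4", "D", "D", "R5",
                      "E")),
    root = "A", terminal = c(E = "building_block"))
}

# Independent second oracle for acyclic graphs: memoised AND/OR evaluation
# ignoring path context (sound on DAGs, where repetition cannot occur).
dag_value <- function(g) {
  memo <- new.env(parent = emptyenv())
  eval_node <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    role <- retrodiv:::node_role(g, v)
    kids <- retrodiv:::node_children(g, v)
    val <- if (role == "molecule") {
      if (retrodiv:::is_building_block(g, v)) TRUE
      else if (length(kids) == 0) FALSE
      else any(vapply(kids, eval_node, logical(1)))
    } else {
      if (length(kids) == 0) TRUE
      else all(vapply(kids, eval_node, logical(1)))
    }
    assign(v, val, envir = memo)
    val
  }
  if (eval_node(g$root)) "proved" else "disproved"
}

# Reverse every child list (a deterministic order permutation).
permute_children <- function(g) {
  g$children <- lapply(g$children, rev)
  g
}

has_directed_cycle <- function(g) {
  state <- new.env(parent = emptyenv())
  visit <- function(v) {
    s <- state[[v]] %||% 0L
    if (s == 1L) return(TRUE)
    if (s == 2L) return(FALSE)
    assign(v, 1L, envir = state)
    for (w in retrodiv:::node_children(g, v)) if (visit(w)) return(TRUE)
    assign(v, 2L, envir = state)
    FALSE
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  any(vapply(names(g$role), visit, logical(1)))
}

dag_net <- function(s) {
  generate_network(n_molecules = 5 + (s %% 14),
                   max_reactions_per_molecule = 3, buyable_fraction = 0.25,
                   cycle_fraction = 0, planted_routes = s %% 2,
                   depth = 3 + (s %% 3), seed = s)
}

cyclic_net <- function(s) {
  generate_network(n_molecules = 5 + (s %% 10),
                   max_reactions_per_molecule = 3, buyable_fraction = 0.2,
                   cycle_fraction = 0.5, planted_routes = s %% 2,
                   depth = 3, seed = 1000 + s)
}
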