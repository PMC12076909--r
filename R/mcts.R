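#' UCB1 selection score with visit penalty
#'
#' Standard upper-confidence-bound score -- mean value plus an exploration
#' bonus shrinking with visits -- minus a penalty proportional to the visit
#' count, so that already-visited lines are progressively discouraged and
#' long runs surface multiple distinct solutions. Unvisited children score
#' `Inf` and are tried first.
#'
#' @param node list with `visits` and `value_sum` counters.
#' @param parent_visits visit count of the parent (>= 1).
#' @param exploration_c exploration constant (> 0).
#' @param visit_penalty per-visit penalty subtracted from the score.
#' @return A number (possibly `Inf`).
#' @export
uct_score <- function(node, parent_visits, exploration_c = sqrt(2),
                      visit_penalty = 0) {
  if (node$visits == 0) return(Inf)
  node$value_sum / node$visits +
    exploration_c * sqrt(log(parent_visits) / (1 + node$visits)) -
    visit_penalty * node$visits
}

# One-player state: molecules still to be made (sorted; the first is the
# one resolved next) and molecules already resolved on this line (used to
# cut cycles: a reactant that was already resolved loses the line).
mcts_apply <- function(g, open, used, rxn) {
  m <- open[1]
  used <- c(used, m)
  rest <- open[-1]
  for (q in node_children(g, rxn)) {
    if (is_building_block(g, q)) next
    if (q %in% used || q %in% rest) {
      return(list(status = "loss", open = rest, used = used))
    }
    if (length(node_children(g, q)) == 0) {
      return(list(status = "loss", open = rest, used = used))
    }
    rest <- c(rest, q)
  }
  rest <- sort(rest)
  list(status = if (length(rest) == 0) "win" else "open",
       open = rest, used = used)
}

mcts_route_from_choices <- function(g, choices) {
  build <- function(m) {
    if (is_building_block(g, m)) return(synthesis_route(m))
    rx <- choices[[m]]
    synthesis_route(m, rxn = rx,
                    reactants = lapply(node_children(g, rx), build),
                    bonds = g$bonds[[rx]] %||% character(0),
                    score = edge_score(g, m, rx))
  }
  build(g$root)
}

#' Monte-Carlo tree search baseline
#'
#' One-player MCTS over sets of open molecules: a state is the set of
#' molecules still to be synthesised, an action resolves the first open
#' molecule by one of its reactions, building-block reactants are absorbed,
#' and a line wins when no open molecule remains. Each iteration runs the
#' four standard phases (selection by [uct_score()], expansion of all
#' children at once, uniformly random rollout to `rollout_depth`, and
#' backpropagation of the 0/1 reward). Every distinct winning line
#' encountered -- in the tree or during a rollout -- is recorded as a route.
#'
#' @param g an [and_or_graph()].
#' @param iterations number of MCTS iterations.
#' @param exploration_c UCB exploration constant.
#' @param rollout_depth maximum reactions resolved in a random rollout.
#' @param visit_penalty per-visit penalty in the selection score.
#' @param seed RNG seed (the run is reproducible given the seed).
#' @return List of distinct, valid [synthesis_route()] objects in order of
#'   first discovery (empty when no winning line was found).
#' @export
mcts_search <- function(g, iterations = 1000, exploration_c = sqrt(2),
                        rollout_depth = 30, visit_penalty = 0.01,
                        seed = 1) {
  root_id <- g$root
  if (is_building_block(g, root_id)) {
    return(list(synthesis_route(root_id)))
  }
  if (length(node_children(g, root_id)) == 0) return(list())

  nodes <- list(list(state = list(open = root_id, used = character(0)),
                     choices = list(), status = "open",
                     visits = 0, value_sum = 0, children = integer(0),
                     expanded = FALSE, parent = 0L))
  routes <- list()
  keys <- character(0)

  record_win <- function(choices) {
    r <- mcts_route_from_choices(g, choices)
    k <- route_key(r)
    if (!k %in% keys) {
      keys <<- c(keys, k)
      routes[[length(routes) + 1]] <<- r
    }
  }

  rxn_weights <- function(m, rxns) {
    w <- vapply(rxns, function(rx) edge_score(g, m, rx) %||% NA_real_,
                numeric(1))
    if (anyNA(w) || sum(w) == 0) rep(1, length(rxns)) else w
  }

  # Rollouts estimate values only; routes are read off the tree's winning
  # lines, as a planner would materialise them.
  rollout <- function(open, used) {
    for (step in seq_len(rollout_depth)) {
      if (length(open) == 0) return(1)
      m <- open[1]
      rxns <- node_children(g, m)
      if (length(rxns) == 0) return(0)
      rx <- rxns[[sample.int(length(rxns), 1,
                             prob = rxn_weights(m, rxns))]]
      res <- mcts_apply(g, open, used, rx)
      if (res$status == "loss") return(0)
      if (res$status == "win") return(1)
      open <- res$open; used <- res$used
    }
    0
  }

  with_seed(seed, {
    for (it in seq_len(iterations)) {
      # selection
      ni <- 1L
      path <- ni
      while (nodes[[ni]]$expanded && length(nodes[[ni]]$children) > 0 &&
             nodes[[ni]]$status == "open") {
        kids <- nodes[[ni]]$children
        scores <- vapply(kids, function(k) {
          uct_score(nodes[[k]], max(nodes[[ni]]$visits, 1),
                    exploration_c, visit_penalty)
        }, numeric(1))
        ni <- kids[which.max(scores)]
        path <- c(path, ni)
      }
      nd <- nodes[[ni]]
      reward <- 0
      if (nd$status == "win") {
        reward <- 1
      } else if (nd$status == "loss") {
        reward <- 0
      } else if (!nd$expanded) {
        # expansion: add all children of the first open molecule at once
        m <- nd$state$open[1]
        rxns <- node_children(g, m)
        kid_ids <- integer(0)
        for (rx in rxns) {
          res <- mcts_apply(g, nd$state$open, nd$state$used, rx)
          ch <- nd$choices
          ch[[m]] <- rx
          status <- res$status
          if (status == "win") record_win(ch)
          kid_ids <- c(kid_ids, length(nodes) + 1L)
          nodes[[length(nodes) + 1L]] <- list(
            state = list(open = res$open, used = res$used), choices = ch,
            status = if (status == "open") "open" else status,
            visits = 0, value_sum = 0, children = integer(0),
            expanded = FALSE, parent = ni)
        }
        nodes[[ni]]$expanded <- TRUE
        nodes[[ni]]$children <- kid_ids
        if (length(kid_ids) == 0) {
          nodes[[ni]]$status <- "loss"
        } else {
          ci <- kid_ids[1]
          path <- c(path, ci)
          kid <- nodes[[ci]]
          reward <- if (kid$status == "win") 1 else if (kid$status == "loss")
            0 else rollout(kid$state$open, kid$state$used)
        }
      }
      for (p in path) {
        nodes[[p]]$visits <- nodes[[p]]$visits + 1
        nodes[[p]]$value_sum <- nodes[[p]]$value_sum + reward
      }
    }
  })
  routes
}
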