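#' Benchmark multi-solution search against the MCTS baseline
#'
#' Runs the requested algorithms on a collection of target graphs at one or
#' more search budgets and tabulates per-target route-set metrics: whether
#' the target was solved, number of routes, chemical diversity score,
#' mean reactions per route and mean route viability. Budgets are search
#' steps for DFPN* and iterations for MCTS (deterministic counts rather
#' than wall-clock, for reproducibility).
#'
#' @param graphs list of [and_or_graph()] objects (the targets).
#' @param budgets integer vector of search budgets.
#' @param algorithms subset of `c("dfpn_star", "mcts")`.
#' @param seed base RNG seed (per-target seeds are derived from it).
#' @param p_reac penalty used by the DFPN* runs.
#' @param out optional path: write the per-target table as TSV.
#' @return List with `per_target` (data.frame: target, algorithm, budget,
#'   solved, n_routes, cds, mean_reactions, mean_viability) and
#'   `aggregates` (medians and IQRs per algorithm and budget).
#' @export
run_bench <- function(graphs, budgets, algorithms = c("dfpn_star", "mcts"),
                      seed = 1, p_reac = 5, out = NULL) {
  stopifnot(length(graphs) >= 1, length(budgets) >= 1)
  algorithms <- match.arg(algorithms, c("dfpn_star", "mcts"),
                          several.ok = TRUE)
  rows <- list()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    for (b in budgets) {
      for (alg in algorithms) {
        routes <- if (alg == "dfpn_star") {
          find_route_set(g, max_solutions = 25, p_reac = p_reac,
                         max_expansions = b, use_tca = TRUE)
        } else {
          mcts_search(g, iterations = b, seed = seed + gi)
        }
        solved <- length(routes) > 0
        cds_val <- if (solved) {
          res <- tryCatch(suppressWarnings(cds(routes)),
                          error = function(e) NULL)
          if (is.null(res)) NA_real_ else res$score
        } else NA_real_
        mean_rxn <- if (solved) {
          mean(vapply(routes, function(r) length(route_reactions(r)),
                      numeric(1)))
        } else NA_real_
        mean_via <- if (solved) {
          v <- vapply(routes, function(r)
            tryCatch(route_viability(r), error = function(e) NA_real_),
            numeric(1))
          mean(v)
        } else NA_real_
        rows[[length(rows) + 1]] <- data.frame(
          target = gi, algorithm = alg, budget = b, solved = solved,
          n_routes = length(routes), cds = cds_val,
          mean_reactions = mean_rxn, mean_viability = mean_via,
          stringsAsFactors = FALSE)
      }
    }
  }
  per_target <- do.call(rbind, rows)
  agg_rows <- list()
  for (alg in algorithms) {
    for (b in budgets) {
      sub <- per_target[per_target$algorithm == alg &
                          per_target$budget == b, ]
      agg_rows[[length(agg_rows) + 1]] <- data.frame(
        algorithm = alg, budget = b,
        solved_fraction = mean(sub$solved),
        median_cds = stats::median(sub$cds, na.rm = TRUE),
        iqr_cds = stats::IQR(sub$cds, na.rm = TRUE),
        median_n_routes = stats::median(sub$n_routes),
        median_mean_reactions = stats::median(sub$mean_reactions,
                                              na.rm = TRUE),
        median_mean_viability = stats::median(sub$mean_viability,
                                              na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  aggregates <- do.call(rbind, agg_rows)
  if (!is.null(out)) {
    utils::write.table(per_target, out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  list(per_target = per_target, aggregates = aggregates)
}
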