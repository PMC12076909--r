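#' Bonds formed by a reaction (forward direction)
#'
#' Given the bond sets of the product and of the combined reactants, in a
#' consistent atom-label frame, the formed bonds are those present in the
#' product but absent from the reactants; from the retrosynthetic point of
#' view these are the disconnections the reaction contributes.
#'
#' @param product_bonds,reactant_bonds character vectors of canonical bond
#'   keys, or lists of length-2 atom-label pairs.
#' @return Character vector of canonical bond keys.
#' @export
formed_bonds <- function(product_bonds, reactant_bonds) {
  norm <- function(x) {
    if (is.list(x)) {
      vapply(x, function(b) canonical_bond(b[[1]], b[[2]]), character(1))
    } else {
      vapply(strsplit(as.character(x), "|", fixed = TRUE),
             function(p) canonical_bond(p[1], p[2]), character(1))
    }
  }
  sort(setdiff(unique(norm(product_bonds)), norm(reactant_bonds)))
}

#' Disconnection set of a route
#'
#' The union, over all reactions of the route, of the bonds they form,
#' keyed in the target molecule's atom frame. Two routes with the same
#' disconnection set realise the same chemical idea even if they use
#' different named reactions.
#'
#' @param r a [synthesis_route()].
#' @return Character vector of canonical bond keys (sorted, unique).
#' @export
extract_disconnections <- function(r) {
  keys <- route_walk(r, function(s, d) {
    if (is_route_leaf(s)) return(NULL)
    if (length(s$via$bonds) == 0) {
      stop(sprintf("reaction '%s' carries no bond labels", s$via$rxn))
    }
    s$via$bonds
  })
  sort(unique(unlist(keys)))
}

#' Jaccard distance between two disconnection sets
#'
#' `1 - |a intersect b| / |a union b|`; two empty sets have distance 0.
#'
#' @param a,b character vectors of bond keys.
#' @return Number in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  1 - length(intersect(a, b)) / u
}

#' Retained family of disconnection sets (C_M)
#'
#' Deduplicates the input sets, drops empty ones, and keeps only sets that
#' cannot be represented by a strictly smaller set found among the routes.
#' Under the default `"subset"` rule a set is dropped when some other input
#' set is a strict subset of it; under the `"cover"` rule it is dropped
#' when the union of strictly smaller input sets covers it. This eliminates
#' miscellaneous extra disconnections that do not carry a distinct chemical
#' idea. Output order is deterministic (by size, then lexicographically).
#'
#' @param sets list of character vectors of bond keys.
#' @param minimality `"subset"` (default) or `"cover"`.
#' @return List of character vectors (the retained family).
#' @export
build_cm <- function(sets, minimality = c("subset", "cover")) {
  minimality <- match.arg(minimality)
  sets <- lapply(sets, function(s) sort(unique(s)))
  sets <- Filter(function(s) length(s) > 0, sets)
  sig <- vapply(sets, paste, character(1), collapse = ";")
  sets <- sets[!duplicated(sig)]
  if (length(sets) <= 1) return(sets)
  keep <- vapply(seq_along(sets), function(i) {
    smaller <- Filter(function(s) length(s) < length(sets[[i]]), sets)
    if (minimality == "subset") {
      !any(vapply(smaller, function(s) all(s %in% sets[[i]]), logical(1)))
    } else {
      inside <- unlist(Filter(function(s) all(s %in% sets[[i]]), smaller))
      !all(sets[[i]] %in% (inside %||% character(0)))
    }
  }, logical(1))
  sets <- sets[keep]
  ord <- order(lengths(sets),
               vapply(sets, paste, character(1), collapse = ";"))
  sets[ord]
}

#' Chemical diversity score of a route set
#'
#' `CDS = 1 + (1/|C_M|) * sum over ordered pairs (T, T') in C_M of
#' d_J(T, T')`, where `C_M` is the retained family of disconnection sets
#' (see [build_cm()]) and `d_J` the Jaccard distance. The score can be read
#' as the number of distinct chemical ideas in the set: one route gives 1,
#' and `n` pairwise-disjoint minimal disconnection sets give exactly `n`.
#' An empty route list (or routes with no usable disconnections) scores 0
#' with `empty = TRUE`.
#'
#' @param routes list of [synthesis_route()] objects carrying bond labels,
#'   or a list of disconnection sets (character vectors).
#' @return An object of class `cds_result`: list with `score`, `c_m` (the
#'   retained sets), `distance_matrix` and `empty`.
#' @export
cds <- function(routes) {
  sets <- lapply(routes, function(r) {
    if (inherits(r, "synthesis_route")) extract_disconnections(r)
    else sort(unique(as.character(r)))
  })
  cm <- build_cm(sets)
  n <- length(cm)
  if (n == 0) {
    out <- list(score = 0, c_m = cm,
                distance_matrix = matrix(numeric(0), 0, 0), empty = TRUE)
    class(out) <- "cds_result"
    warning("no non-empty disconnection sets; CDS undefined, reported as 0")
    return(out)
  }
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) d[i, j] <- jaccard_distance(cm[[i]], cm[[j]])
    }
  }
  d <- d + t(d)
  out <- list(score = 1 + sum(d) / n, c_m = cm, distance_matrix = d,
              empty = FALSE)
  class(out) <- "cds_result"
  out
}

#' @export
print.cds_result <- function(x, ...) {
  cat(sprintf("<cds_result> score %.4g over %d retained disconnection sets\n",
              x$score, length(x$c_m)))
  invisible(x)
}

#' Unique intermediates and building blocks across a route set
#'
#' Baseline diversity proxy: counts unique molecule ids over the union of
#' all routes, splitting non-root non-leaf positions (intermediates) from
#' leaves (building blocks).
#'
#' @param routes list of [synthesis_route()] objects.
#' @return List with `unique_intermediates` and `unique_building_blocks`.
#' @export
unique_molecule_counts <- function(routes) {
  inter <- unique(unlist(lapply(routes, route_intermediates)))
  leaves <- unique(unlist(lapply(routes, route_leaves)))
  list(unique_intermediates = length(inter %||% character(0)),
       unique_building_blocks = length(leaves %||% character(0)))
}

#' Route-length statistics across targets
#'
#' Computes the mean number of reactions per route for each target, then
#' summarises the per-target means across targets.
#'
#' @param route_sets named list: target id -> list of routes.
#' @return List with `mean_reactions` (mean of per-target means), `median`
#'   and `iqr` across targets, and `per_target` (named numeric vector).
#' @export
route_length_stats <- function(route_sets) {
  route_sets <- Filter(function(rs) length(rs) > 0, route_sets)
  if (length(route_sets) == 0) stop("no solved targets: empty input")
  per <- vapply(route_sets, function(rs) {
    mean(vapply(rs, function(r) length(route_reactions(r)), numeric(1)))
  }, numeric(1))
  list(mean_reactions = mean(per), median = stats::median(per),
       iqr = stats::IQR(per), per_target = per)
}
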