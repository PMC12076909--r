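#' Create an empty search-record store
#'
#' Holds the mutable per-node state of a proof-number search: current
#' pn/dn estimates, expansion flags, minimum root distance `md`, cumulative
#' proof-number penalties, and the path-keyed proof/disproof cache used to
#' handle the graph-history-interaction (GHI) problem.
#'
#' @return An object of class `search_records` (an environment).
#' @export
new_search_records <- function() {
  st <- new.env(parent = emptyenv())
  st$rec <- new.env(parent = emptyenv())   # node -> list(pn, dn, expanded, md)
  st$ghi <- new.env(parent = emptyenv())   # node -> list of (status, dep, forced)
  st$pen <- new.env(parent = emptyenv())   # node -> cumulative pn penalty
  class(st) <- "search_records"
  st
}

#' @export
print.search_records <- function(x, ...) {
  cat(sprintf("<search_records> %d nodes touched, %d cached (dis)proofs\n",
              length(ls(x$rec)), sum(lengths(mget(ls(x$ghi), envir = x$ghi,
                                                  ifnotfound = list(NULL))))))
  invisible(x)
}

get_rec <- function(st, v) {
  r <- st$rec[[v]]
  if (is.null(r)) r <- list(pn = 1, dn = 1, expanded = FALSE, md = Inf)
  r
}

set_rec <- function(st, v, rec) assign(v, rec, envir = st$rec)

get_pen <- function(st, v) st$pen[[v]] %||% 0

#' Proof/disproof-number update rule
#'
#' The defining aggregation of proof-number search: a molecule (OR) node
#' takes the minimum proof number and the sum of disproof numbers over its
#' children; a reaction (AND) node takes the sum of proof numbers and the
#' minimum disproof number. Sums saturate at `Inf`.
#'
#' @param role `"molecule"` or `"reaction"`.
#' @param child_pns,child_dns aligned numeric vectors (may contain `Inf`).
#' @return Numeric vector `c(pn, dn)`.
#' @export
update_numbers <- function(role, child_pns, child_dns) {
  if (length(child_pns) == 0 || length(child_pns) != length(child_dns)) {
    stop("child pn/dn sequences must be non-empty and aligned ",
         "(terminal nodes are handled by terminal_status, not here)")
  }
  if (role == "molecule") {
    c(min(child_pns), sat_sum(child_dns))
  } else {
    c(sat_sum(child_pns), min(child_dns))
  }
}

#' DFPN threshold propagation
#'
#' Computes the thresholds handed to the child chosen by DFPN. With a single
#' child the parent's thresholds are passed on unchanged. Otherwise, at a
#' molecule node the child's proof-number threshold is capped by one more
#' than the second-best child's proof number, and the disproof-number
#' threshold passes the parent's surplus; at a reaction node the roles of
#' pn and dn are exchanged. All arithmetic saturates at `Inf`.
#'
#' @param role `"molecule"` or `"reaction"`.
#' @param th_pn_v,th_dn_v thresholds currently in force at the parent.
#' @param pn_v,dn_v the parent's current proof/disproof numbers.
#' @param chosen numeric `c(pn, dn)` of the chosen child (the minimum-pn
#'   child at a molecule node, the minimum-dn child at a reaction node).
#' @param second_best numeric `c(pn, dn)` of the second-best child
#'   (`c(Inf, Inf)` when there is none).
#' @param single_child `TRUE` when the parent has exactly one child.
#' @return Numeric vector `c(th_pn_child, th_dn_child)`.
#' @export
child_thresholds <- function(role, th_pn_v, th_dn_v, pn_v, dn_v,
                             chosen, second_best = c(Inf, Inf),
                             single_child = FALSE) {
  if (single_child) return(c(th_pn_v, th_dn_v))
  if (role == "molecule") {
    c(min(th_pn_v, sat_add(second_best[1], 1)),
      sat_surplus(th_dn_v, dn_v, chosen[2]))
  } else {
    c(sat_surplus(th_pn_v, pn_v, chosen[1]),
      min(th_dn_v, sat_add(second_best[2], 1)))
  }
}

#' Threshold controlling adjustment (TCA)
#'
#' When a visited node has an unproved *old* child -- a child whose minimum
#' root distance does not exceed the node's own (`md(c) <= md(v)`), the
#' signature of a cycle in the explored graph -- TCA raises the node's
#' thresholds to the minimal values that keep the strict threshold
#' inequalities satisfied, so DFPN does not backtrack and the loop is
#' eventually broken by an expansion or a closed cycle.
#'
#' @param g an [and_or_graph()].
#' @param records a [new_search_records()] store.
#' @param v node id (must have been visited).
#' @param ctx molecule ids on the path above `v`.
#' @return List with `raised` (logical), and when raised the new `th_pn`
#'   and `th_dn` (`pn(v) + 1`, `dn(v) + 1`).
#' @export
tca_adjust <- function(g, records, v, ctx = character(0)) {
  rec <- get_rec(records, v)
  newpath <- if (node_role(g, v) == "molecule") c(ctx, v) else ctx
  agg <- aggregate_node(g, records, v, newpath, ghi_safe = TRUE,
                        edge_costs = FALSE)
  if (has_old_unproved_child(records, v, agg)) {
    list(raised = TRUE, th_pn = sat_add(agg$pn, 1),
         th_dn = sat_add(agg$dn, 1))
  } else {
    list(raised = FALSE, th_pn = NA_real_, th_dn = NA_real_)
  }
}

has_old_unproved_child <- function(st, v, agg) {
  md_v <- get_rec(st, v)$md
  for (i in seq_along(agg$ids)) {
    if (agg$certain[i]) next
    c_md <- get_rec(st, agg$ids[i])$md
    if (c_md <= md_v) return(TRUE)
  }
  FALSE
}

#' Path-keyed proof cache (GHI handling)
#'
#' A proof or disproof found while visiting a node through one path is not
#' automatically valid through another (the graph-history-interaction
#' problem). Each cached entry therefore carries the set of path molecules
#' the result actually depended on: a cached *proof* is valid for a query
#' context disjoint from its dependency set (no molecule of the proof
#' subtree is already on the path), and a cached *disproof* -- whose
#' dependencies are the path molecules its repetition arguments relied on --
#' is valid for a context containing its dependency set.
#'
#' @param records a [new_search_records()] store.
#' @param v node id.
#' @param status `"proved"` or `"disproved"`.
#' @param dep character vector of molecule ids the result depends on.
#' @param ctx molecule ids on the root-to-`v` path (exclusive of `v`).
#' @param forced internal flag marking forced disproofs of the
#'   multi-solution search, which survive cache purges.
#' @return `ghi_lookup` returns `"proved"`, `"disproved"` or `"unknown"`;
#'   `ghi_store` returns the records invisibly.
#' @export
ghi_store <- function(records, v, status, dep = character(0),
                      forced = FALSE, res = list()) {
  entries <- records$ghi[[v]] %||% list()
  for (e in entries) {
    dominated <- if (status == "disproved") {
      e$status == "disproved" && all(e$dep %in% dep) && (e$forced || !forced)
    } else {
      e$status == "proved" && setequal(e$dep, dep) &&
        length(e$res %||% list()) == length(res)
    }
    if (dominated) return(invisible(records))
  }
  entries[[length(entries) + 1]] <- list(status = status, dep = unique(dep),
                                         forced = forced, res = res)
  assign(v, entries, envir = records$ghi)
  invisible(records)
}

#' @rdname ghi_store
#' @export
ghi_lookup <- function(records, v, ctx = character(0)) {
  e <- ghi_lookup_dep(records, v, ctx)
  if (is.null(e)) "unknown" else e$status
}

# Returns the first entry valid under ctx, or NULL. Disproofs are checked
# before proofs (a forced disproof overrides any cached proof on a path
# matching its key). A proof entry is valid when no molecule it depends on
# is already on the path AND none of its residual forced-key constraints is
# completed by the path.
ghi_lookup_dep <- function(st, v, ctx) {
  entries <- st$ghi[[v]]
  if (is.null(entries)) return(NULL)
  for (e in entries) {
    if (e$status == "disproved" && all(e$dep %in% ctx)) return(e)
  }
  for (e in entries) {
    if (e$status == "proved" && length(intersect(e$dep, ctx)) == 0) {
      blocked <- any(vapply(e$res %||% list(), function(R)
        length(R) > 0 && all(R %in% ctx), logical(1)))
      if (!blocked) return(e)
    }
  }
  NULL
}

# Forced-disproof keys registered on a node.
forced_keys <- function(st, v) {
  lapply(Filter(function(e) isTRUE(e$forced), st$ghi[[v]] %||% list()),
         `[[`, "dep")
}

# Drop cached proofs (used after a forced disproof invalidates them);
# disproofs stay valid because forcing only removes options.
purge_proofs <- function(st) {
  for (v in ls(st$ghi)) {
    entries <- Filter(function(e) e$status != "proved", st$ghi[[v]])
    if (length(entries) == 0) rm(list = v, envir = st$ghi)
    else assign(v, entries, envir = st$ghi)
    rec <- st$rec[[v]]
    if (!is.null(rec) && (rec$pn == 0 || rec$dn == 0)) {
      rec$pn <- 1; rec$dn <- 1
      set_rec(st, v, rec)
    }
  }
  invisible(st)
}
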