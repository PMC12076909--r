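# Saturating extended arithmetic: pn/dn live in {0, 1, 2, ..., Inf} and sums
# must absorb Inf without producing NaN (Inf - Inf is undefined in IEEE).

sat_add <- function(a, b) {
  if (is.infinite(a) || is.infinite(b)) Inf else a + b
}

sat_sum <- function(x) {
  if (any(is.infinite(x))) Inf else sum(x)
}

# a - b + c with the convention that a = Inf dominates (used for threshold
# surplus computations where a is a threshold).
sat_surplus <- function(a, b, c) {
  if (is.infinite(a) || is.infinite(c)) return(Inf)
  v <- a - b + c
  if (v < 0) 0 else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Canonical bond key
#'
#' A disconnection is identified by the unordered pair of atom labels (in
#' the target molecule's atom frame) of the bond it breaks; the key is the
#' sorted pair joined by `"|"`, so `canonical_bond("a7", "a3")` and
#' `canonical_bond("a3", "a7")` coincide. Bond order/type is deliberately
#' not part of the key: a disconnection is a connectivity change.
#'
#' @param a,b atom labels.
#' @return A single string.
#' @export
canonical_bond <- function(a, b) {
  p <- sort(c(as.character(a), as.character(b)))
  paste(p, collapse = "|")
}

bond_key_atoms <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]
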